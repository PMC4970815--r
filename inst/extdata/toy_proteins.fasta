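>prot0001
STFNHDMHPCTIRHGQDDMVNCDLSMCKIHIHYPTFVFYTSNQVHATGSGGQGTMYSRWDEWMHDMNTATIVYMDFHPTIKHQPC
>prot0002
SQKMCSLIWNHPHEHEPGKWASTENVEMKFSVIKLVDEDTLMWKGLVRELFPGPISFRISE
>prot0003
LPNMANPKNSYLSNSGWKWAINKTNWEWSNFARHWMVTCQLMVPYFFQTMIAAEEFGHYVRIKDIFVKNMIMVGVIRPWSDDW
>prot0004
KYDWNERQNGYNLCKCECLSRGLFILRNPCEMGGYKFKFVHTFRVMAGEAKGAFWRDHMNKQQELHCQMQSYGRMRCILKGCIE
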