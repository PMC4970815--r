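@read0001
CAATATACAGCGCATTCGACCGTACGACTGCATTTGACAGTGCAACTCTTGTTGTTTATTCATATGGTCCCGCCAGAATGCCCCCTTCGCTTCCCCAGCCATGACTCTGAAAGTATGGACAAATTTGAACTTATATCCGCTCATTTCGCA
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@read0002
TGGTACGAACGCCAGAATGGCTACAATCTTTGCAAATGCGAATGCCTTTCCCGGGGATTATTTTTTCTTCGAAATCCGTGCGAGATGGGTGGATATAAGTTCAAATTCGTGCATACCTTTAGGGTTATGGCATGTGAAGCGAAAGGTGCG
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@read0003
CATATAGACAATTGTTACTGTATTCATGTCGTGCATACATTCTTCCCATCTACTGTACATCGTGCCTTGCCCGCCGCTCCCGGTTGCGTGCACTTGGTTGCTCGTGTAAAACACGAACGTTGGGTAATGGATCTGAATTTTGCACATTGA
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
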