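Synthetic toy fixture generated with clustx::simulate_dataset(
sim_config(seed = 11, n_proteins = 4, len_range = c(60, 90),
n_reads = 3, read_len = 150, sub_rate = 0.02)).
No real biological sequences.
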