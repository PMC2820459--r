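# Synthetic sweep-model FRC decay calibration.
#
# Sigmoid F(X) = a / (1 + exp(-(X - x0)/b)) fitted with nls() to the
# bundled synthetic decay table (sweep_frc_decay_synthetic.tsv), which was
# generated by this package's own simulator under a strong-sweep scenario
# (constant N = 10000, s = 0.05, favored-allele frequency 0.4, 1 Mb region,
# n = 120 chromosomes, 1 cM/Mb, 120 replicates) chosen to resemble the decay
# of FRC around a classic strong recent sweep.  These are configuration
# values, not estimates from real data.
a: 0.241473
x0: 140786
b: 74079.4
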