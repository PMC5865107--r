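quantity,value
reads_over_450bp,1810674
reads_identified,1791574
n_sidak_comparisons,7
family_wise_alpha,0.05
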