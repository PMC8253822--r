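dataset,n_tomograms,n_thin,n_thick
neonatal_rat_cardiomyocyte_a_band,9,4770,1648
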