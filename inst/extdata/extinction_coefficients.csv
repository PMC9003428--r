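wavelength_nm,alpha_hbo,alpha_hbr
690,0.000276,0.002051
760,0.000586,0.001548
780,0.000710,0.001096
830,0.000974,0.000693
850,0.001058,0.000691
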