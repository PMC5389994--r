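wavelength_nm,value
300,0.04
340,0.04
400,0.05
460,0.07
520,0.13
540,0.14
580,0.11
640,0.08
660,0.09
680,0.20
700,0.35
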