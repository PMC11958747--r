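# Default measurement conditions for the fluorophore panel
solvent: acetonitrile
concentration_M: 2.0e-5
path_length_cm: 1.0
excitation_nm: 340
refractive_index: 1.344
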