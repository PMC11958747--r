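# Synthetic log excerpt (constructed fixture, not an actual calculation
# output): three singlet roots with the reported energies and oscillator
# strengths of compound 10a; leading CI coefficients back-solved from the
# reported contribution percentages via the closed-shell 2c^2 convention.
# HOMO index 50.
 Excitation energies and oscillator strengths:

 Excited State   1:      Singlet-A      3.1911 eV  388.53 nm  f=0.0090
    48 -> 51        0.51473
    50 -> 51        0.41210
 Excited State   2:      Singlet-A      3.2518 eV  381.27 nm  f=0.0628
    50 -> 51        0.62833
    48 -> 51       -0.26074
 Excited State   3:      Singlet-A      3.4540 eV  358.96 nm  f=0.0004
    49 -> 51        0.66656
    50 -> 52        0.17320
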