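# Held-out cross-validation observables for the M274A mutant, from the
# main text: kcat/KM = 1.2 +/- 1.0 M^-1 s^-1, Kd(TCSA) = 116 +/- 12 uM,
# macroscopic inhibitor off-rate 1.19 +/- 0.15 s^-1. SI units.
variant,solvent,observable,value,sd
M274A,H2O,kcat_over_KM,1.2,1.0
M274A,H2O,kd,1.16e-4,1.2e-5
M274A,H2O,koff_macro,1.19,0.15
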