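# Macroscopic experimental constraints for wild-type HDAC8 and the L179A
# mutant, assembled from values printed in the main text of the study:
# kcat(WT,H2O) = 0.90 +/- 0.09 s^-1; the WT specific activity
# kcat/KM = 40 M^-1 s^-1 is reconstructed from the M274A relative
# activity (3 +/- 2% of WT) and the M274A kcat/KM of 1.2 M^-1 s^-1,
# giving KM(WT) ~ 22.5 mM; kcat/KM(H2O) = 6.2 x kcat/KM(D2O);
# L179A activity is 7 +/- 2% of WT; Kd(TCSA) = 5 +/- 2 uM (WT) and
# 110 +/- 11 uM (L179A); macroscopic inhibitor off-rates 0.13 and
# 0.19 s^-1 (10% uncertainty assumed; not printed). Values in SI units.
variant,solvent,observable,value,sd
WT,H2O,kcat,0.90,0.09
WT,H2O,KM,0.0225,0.011
WT,D2O,kcat_over_KM,6.45,1.3
L179A,H2O,kcat_over_KM,2.8,1.0
WT,H2O,kd,5.0e-6,2.0e-6
WT,H2O,koff_macro,0.13,0.013
L179A,H2O,kd,1.10e-4,1.1e-5
L179A,H2O,koff_macro,0.19,0.019
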