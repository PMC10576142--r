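# SYNTHETIC stand-in for the per-region exchange thermodynamics of HDAC8
# variants. Minor-state populations at 298 K are calibrated to the values
# reported in the main text (CAT: p_B 6.6% free, 1.4% inhibitor-bound;
# L2,6 free: B 10% -> 1% in L179A -> 0.25% in M274A, C 5% -> 25% in
# L179A). Exchange rates (kex, s^-1 at 298 K) and the L1 populations are
# NOT reported in the main text and are fixed here once at round,
# realistic millisecond-regime values; they are a synthetic stand-in,
# not measured data. Mutant bound-manifold L2,6 populations are likewise
# unprinted and are propagated from the free manifold by applying the
# same per-state ddG (a mutation shifts the free energy of a physical
# conformational state in both manifolds): L179A bound L2,6
# (A,B,C) = (0.246, 0.195, 0.559), M274A (0.146, 0.590, 0.265).
# Free-manifold loops exchange by the bifurcated topology (B<->A<->C),
# bound-manifold loops by the linear topology (A<->B<->C), CAT by
# two-site exchange.
# columns: variant,manifold,region,topology,p_B,p_C,kex_1,kex_2
# kex_1 is the first edge (A-B), kex_2 the second (A-C bifurcated,
# B-C linear); empty for two-site regions.
variant,manifold,region,topology,p_B,p_C,kex_1,kex_2
WT,free,L1,bifurcated_three_site,0.04,0.03,800,300
WT,free,L26,bifurcated_three_site,0.10,0.05,1500,400
WT,free,CAT,two_site,0.066,,1500,
WT,bound,L1,linear_three_site,0.06,0.03,900,250
WT,bound,L26,linear_three_site,0.08,0.04,1100,350
WT,bound,CAT,two_site,0.014,,2000,
L179A,free,L1,bifurcated_three_site,0.04,0.03,800,300
L179A,free,L26,bifurcated_three_site,0.01,0.25,1500,400
L179A,free,CAT,two_site,0.066,,1500,
L179A,bound,L1,linear_three_site,0.06,0.03,900,250
L179A,bound,L26,linear_three_site,0.1947,0.5592,1100,350
L179A,bound,CAT,two_site,0.014,,2000,
M274A,free,L1,bifurcated_three_site,0.04,0.03,800,300
M274A,free,L26,bifurcated_three_site,0.0025,0.05,1500,400
M274A,free,CAT,two_site,0.066,,1500,
M274A,bound,L1,linear_three_site,0.06,0.03,900,250
M274A,bound,L26,linear_three_site,0.5899,0.2646,1100,350
M274A,bound,CAT,two_site,0.014,,2000,
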