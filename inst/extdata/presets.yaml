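# Packaged folding-regime presets.
#
# cg: parameters of the coarse-grained bead model (kcal/mol, Angstrom),
#   calibrated against the qualitative regime targets at 270 K:
#   GB1p-like  - strong hydrophobic contacts + flexible loop: cooperative
#                two-state folding, folded slightly favoured, a >= 1 kT
#                barrier separating the N_HB basins.
#   HP5A-like  - weak contacts + rigid pre-organised loop: marginally
#                stable two-state folding (unfolded slightly favoured),
#                still bimodal.
#   GB1m3-like - strong contacts + rigid loop: folded-dominated,
#                essentially downhill (no significant barrier).
#   hbCoop is the nearest-neighbour H-bond cooperativity; narrow H-bond
#   wells (hbWidth) sharpen the transition, and the sidechain well plateau
#   (scPlateau) sits inside the counting cutoff so only native-like
#   contacts collect full energy.
#
# zipper: reduced-unit (kB = 1) analytic counterparts.  logOmega(N) is the
#   log degeneracy of the level with N native H-bonds formed; the
#   flexible-loop preset carries much larger unfolded-state entropy
#   (logOmega at N = 0, 1).
cg:
  GB1p-like:
    epsHb: 0.35
    epsSc: 2.0
    lambdaLoop: 0.05
    hbCoop: 0.78
    hbWidth: 0.35
    scWidth: 0.6
    scPlateau: 4.6
    angleK: 1.2
  HP5A-like:
    epsHb: 0.33
    epsSc: 0.55
    lambdaLoop: 1.5
    hbCoop: 0.93
    hbWidth: 0.25
    scWidth: 0.6
    scPlateau: 4.6
    angleK: 1.2
  GB1m3-like:
    epsHb: 0.5
    epsSc: 2.4
    lambdaLoop: 2.5
    hbCoop: 0.8
    hbWidth: 0.6
    scWidth: 0.6
    scPlateau: 4.6
    angleK: 1.2
zipper:
  GB1p-like:
    epsilon: 1.23
    logOmega: [8.0, 6.8, 3.0, 2.2, 1.5, 1.0, 0.5, 0.0]
  HP5A-like:
    epsilon: 0.5
    logOmega: [4.5, 3.8, 1.4, 2.0, 1.4, 0.9, 0.4, 0.0]
  GB1m3-like:
    epsilon: 2.4
    logOmega: [4.5, 3.8, 1.4, 2.0, 1.4, 0.9, 0.4, 0.0]
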