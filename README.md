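# ptxhybrid

Hybrid parallel-transmit (pTx) RF pulse design with simultaneous control of
the flip angle and the root-mean-squared transmit field (B1rms), plus the
downstream dual-flip-angle R1-mapping pipeline whose magnetization-transfer
(MT) bias the B1rms term controls. Everything runs on a bundled synthetic
8-channel head phantom; no scanner data is required.

## The problem

At ultra-high field (7T) the transmit field B1+ is spatially inhomogeneous.
pTx pulse designs usually homogenize only the flip angle α of the free-water
pool. But every on-resonance pulse also saturates the semisolid
(macromolecular) proton pool in proportion to the sequence B1rms (β), and
that saturation leaks into the observed signal through magnetization
transfer. A flip-angle-only design leaves β uncontrolled, so quantitative
maps — variable-flip-angle R1 in particular — acquire a spatially varying MT
bias. This package implements the hybrid design that homogenizes both
properties at once.

## The model

Under the small-tip-angle approximation, the transverse magnetization of a
kT-points pulse (rectangular subpulses **b** interleaved with gradient blips
**g**) is linear in the RF, with the system matrix

    A_mn = i γ m0 Δt · exp(i 2π ΔB0(r_m)(t_n − τ)) · exp(i r_m · k(t_n)),

and α_m = |Σ_q s_q(r_m) (A b_q)_m|. The sequence B1rms is
β_m = sqrt((1/TR) Σ_n Δt |Σ_q s_q(r_m) b_q(t_n)|²). The hybrid design solves

    min over (b, g) of (1−λ)·‖α − α_des‖²_W/‖α_des‖²_W + λ·‖β − β_des‖²_W/‖β_des‖²_W

subject to VOP local SAR, per-channel average power and peak voltage, and
gradient amplitude/slew limits (box bounds on the blip moments), with
analytic gradients and a multi-start augmented-Lagrangian solver. λ = 0 is a
pure flip-angle design ("FA"), λ = 1 a pure saturation design ("PUSH"), and
λ ∈ (0,1) the hybrid ("HY"). The two targets are consistent only if β_des is
at least

    β_min = √p2 / (γ p1 √(TR·τ)) · α_des,

where p1, p2 are the shape factors of the unit-normalized RF envelope.

Downstream, a binary spin-bath SPGR simulator and a linearized dual-flip-
angle fit quantify the resulting R1 maps; the apparent rate follows

    R̂1 = R1f + k_fs (1 − k_sf / (R1s + k_sf + π g(Δ) (γ β)²)).

## Worked example

```r
library(ptxhybrid)

ph     <- generate_phantom(phantom_config(seed = 1))
setup  <- ph$setup
timing <- seq_timing()                       # 5 x 200 us kT-points, TR 8 ms
safety <- generate_safety_model(setup, timing, seed = 1)
print(setup); print(safety)

bmin <- beta_min(deg2rad(15), kt_shape_factors(timing), timing)
cat(sprintf("beta_min = %.4f uT, design target 1.2*beta_min = %.2f uT\n",
            bmin, 1.2 * bmin))
hy   <- hybrid_design(setup, safety,
          design_spec(alpha_des = deg2rad(15), beta_des = 1.2 * bmin,
                      lambda = 0.5, n_starts = 10, seed = 1), timing)
print(hy)
print(hy$constraints)
```

which prints

```
pTx transmit setup: 32x32x32 grid, 240 mm FOV, 8 channels, 4416 masked voxels
SAR/hardware model: 8 channels, 8 VOPs; SAR10g<=20 W/kg, Vmax=207 V, Pmax=24 W
beta_min = 0.3460 uT, design target 1.2*beta_min = 0.42 uT
HYBRID pulse design: NRMSE(alpha) = 0.0114, NRMSE(beta) = 0.0115, cost = 1.307e-04
Constraints satisfied: SAR10g 2.76 W/kg (VOP 7), maxP 20.6 W, maxV 207 V
```

So the hybrid pulse reaches ~1.1% weighted NRMSE in *both* the flip-angle
and the B1rms map, inside all hardware/SAR limits (the voltage constraint is
active at 207 V). For comparison, a flip-angle-only design (`lambda = 0`)
reaches the same flip-angle error but leaves the B1rms map at ~17% NRMSE,
and the CP-mode pulse sits at ~25% flip-angle NRMSE on this phantom.

The end-to-end R1 experiment (design both 3° and 15° pulses per type,
simulate the two SPGR acquisitions with the two-pool MT model, fit R1):

```r
ex <- run_experiment(experiment_config(report = list(pulse_types = c("fa", "hy")),
                                       seed = 1))
report(ex)
```

prints, per tissue (s⁻¹),

```
 type label    n   mean        sd       cov
   fa   CSF 1168 0.2500 2.628e-14 1.051e-13
   fa    GM 2048 0.5308 1.012e-03 1.907e-03
   fa    WM 1200 0.8588 2.235e-03 2.603e-03
   hy   CSF 1168 0.2500 2.671e-14 1.068e-13
   hy    GM 2048 0.5307 6.170e-05 1.163e-04
   hy    WM 1200 0.8581 9.975e-05 1.162e-04
```

The white-matter R1 map is ~20x flatter (CoV 0.012% vs 0.26%) with the
hybrid pulses than with flip-angle-only pulses, because the latter leave the
MT saturation spatially structured; the FA-pulse R1 pattern correlates
strongly (|r| ≈ 0.9) with its own B1rms map. Noiseless simulation makes
these CoV values small in absolute terms; the ordering is the point.

A thin CLI over the same functions lives at `inst/cli/ptxhybrid.R`
(`phantom`, `design`, `sweep`, `check`, `run`, `report` subcommands), and
`vignettes/hybrid-pulse-design.Rmd` documents the model, solver and all
numerical choices.

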