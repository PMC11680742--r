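---
title: "Hybrid pTx pulse design and its effect on R1 mapping: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid pTx pulse design and its effect on R1 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the physics it implements and of
every numerical decision a maintainer might question: conventions, units,
solver settings, simulator assumptions, and what the synthetic phantom does
and does not emulate.

## 1. The forward model

A kT-points pulse is a train of `n_subpulses` rectangular RF subpulses
(default 5 × 200 µs) separated by short gradient blips (default 100 µs)
inside a repeating spoiled gradient-echo sequence (TR = 8 ms). Two spatial
properties of the pulse matter here:

* the **flip angle** α of the free-water pool, computed with the
  small-tip-angle (STA) spatial-domain model: `flip_angle_map()` evaluates
  `α_m = |Σ_q s_q(r_m) (A b_q)_m| / m0` with the system matrix of
  `system_matrix()`. Excitation phase is deliberately ignored: the design
  targets the magnitude only.
* the **sequence B1rms** β, the root-mean-squared combined transmit field
  over one TR (`b1rms_map()`). β drives the saturation of the semisolid
  proton pool and is independent of the gradient blips.

Conventions worth stating explicitly:

* Off-resonance maps are stored in **Hz** (their native unit); the system
  matrix phase is `exp(i 2π ΔB0 (t_n − τ))`. The gyromagnetic ratio is fixed
  at `γ = 2.6752218744e8 rad s⁻¹ T⁻¹`.
* RF samples exist only where RF can be nonzero — blip gaps carry no columns
  of the system matrix. Sample times are subpulse-relative **midpoints**
  (`t = start + (j − ½)Δt`), which makes the hard-pulse Bloch integration
  and the STA matrix agree to high order.
* Excitation k-space uses the reversed-cumulative convention
  `k(t) = −γ∫_t^τ G dt`: the final subpulse sits at k = 0, earlier
  subpulses at the negatives of the subsequent blip moments.
* Transmit sensitivities are in µT/V and RF amplitudes in volts; the µT→T
  conversion happens inside the operators, never at the user surface.

## 2. The flip-angle / B1rms bound

For an on-resonance pulse with unit-normalized envelope shape factors
`p1 = ∫b dt′` and `p2 = ∫|b|² dt′`, flip angle and B1rms obey
`α = γ p1 √(TR·τ/p2) · β` exactly, and `α ≤ γ p1 √(TR·τ/p2) · β` once
off-resonance or gradients are present (the polar-angle rate is bounded by
γ|B1|, and Cauchy–Schwarz bounds the envelope integral by its RMS). Hence a
target pair (α_des, β_des) is consistent only if
`β_des ≥ β_min = √p2·α_des/(γ p1 √(TR·τ))` (`beta_min()`).

For the default train, `p1 = p2 = 5/7` and β_min = 0.3460 µT at α_des = 15°,
so the standard target `1.2·β_min` rounds to 0.42 µT (and 0.08 µT at 3°; the
bound is linear in α_des). The bound is invariant to zero-padding the
waveform — lengthening the blip gaps changes τ, p1 and p2 consistently and
leaves β_min untouched; a test asserts this. `hybrid_design()` warns (but
proceeds) when asked for β_des < β_min with interior λ, since the sweep over
infeasible targets is itself informative.

## 3. The hybrid design problem and solver

The design minimizes the squared-NRMSE dual cost
`(1−λ)·NRMSE²(α) + λ·NRMSE²(β)` — squared inside the optimizer, while every
report quotes the square-root NRMSE. Constraints: worst-VOP local SAR,
optional global SAR, per-channel time-averaged power, per-channel peak
voltage, and the gradient limits. Since blips are symmetric triangle /
trapezoid lobes, the waveform-level amplitude and slew constraints reduce
*exactly* to a box bound `|Δk| ≤ Δk_max` per axis (`max_blip_moment()`), so
the optimizer's gradient variables are the blip moments themselves.

Choices that were genuinely open and how they were settled:

* **Power definition.** The per-channel limit is interpreted as forward
  power into 50 Ω with the ½ peak-to-average factor for a constant
  envelope: `P_q = mean_TR(|v_q|²)/100` W. This definition rescales what
  "24 W" means, so it is stated prominently.
* **Solver.** No installed R package offers a constrained nonlinear solver
  that accepts analytic constraint Jacobians, so the package carries a
  small PHR augmented-Lagrangian loop over `stats::optim(method =
  "L-BFGS-B")` (`R/solver.R`). Cost and constraint gradients are analytic
  (complex RF handled as interleaved real/imaginary parts); their
  correctness is enforced by central-finite-difference tests at 1e−5
  relative tolerance. Defaults: 8 outer iterations, 80 inner L-BFGS-B
  iterations, constraint tolerance 1e−7 on limit-normalized constraints,
  penalty growth ×5.
* **Multi-start.** Each start draws complex-Gaussian RF, rescales it to the
  least-squares optimal match of α_des, and draws blip moments uniformly in
  ±20% of Δk_max. Start `s` uses seed `seed + 131·s`, making the whole
  multi-start deterministic. The best *feasible* start wins; ties within
  1e−12 in cost break toward lower local SAR. Defaults: 10 starts for
  single designs, 5 for sweeps.
* **Voxel compression.** `cluster_compress()` k-means-clusters masked
  voxels on standardized `[Re s_q, Im s_q, ΔB0, x, y, z]` features (500
  clusters by default); the compressed problem uses centroid features with
  the cluster size as weight, so weights always sum to the voxel count.
  Reported maps, NRMSEs and the cost are **always recomputed on the full
  uncompressed setup**.
* **Gauge.** A global RF phase changes neither cost nor any constraint; the
  optimizer fixes it arbitrarily. A test verifies the invariance.
* **λ grid.** `lambda_grid(n, eps)` is log-spaced toward both endpoints
  (denser at the bounds, sparser in the middle) and contains 0 and 1
  exactly. Full sweeps use `n = 51, eps = 1e-3`; the reduced desk-scale
  sweep uses `n = 7, eps = 0.02`, chosen so the interior points exert a
  visible pull on both cost terms.

Baselines: `cp_pulse()` is a single 200 µs rectangle in CP mode, with the
closed-form least-squares amplitude `c* = ΣWaα_des/ΣWa²`; `rf_shim_mls()`
is a magnitude-least-squares static shim by variable exchange, whose first
start is the CP solution so it can never do worse than CP mode.

## 4. The synthetic phantom

`generate_phantom()` emulates the qualitative structure of measured 7T
head data without claiming anatomical realism:

* ellipsoidal head mask (semi-axes 140 × 170 × 150 mm scaled to the FOV)
  with concentric WM / GM / CSF shells; 32³ voxels over a 240 mm FOV by
  default — small enough that a full design runs in seconds on one core;
* 8 channels on an azimuthal ring, each with a smooth magnitude decay and a
  geometric phase plus a propagation-like phase `−κ·d` with distance. With
  the CP weights this yields coherent summation at the center and partial
  cancellation at the rim — central brightening ≥ 1.3× by default
  (`brightening = 1.5`; at `brightening = 1` the CP field is flat);
* a low-order smooth ΔB0 field plus one localized Gaussian hotspot,
  rescaled into ±150 Hz;
* a VOP SAR model built from seeded random Hermitian-PSD matrices, scaled so
  the CP reference pulse at 15° deposits 25% of the 10 g limit (global SAR
  scaled to 40% of that local value). It is synthetic: it reproduces the
  *structure* of a compressed SAR model, not any real coil. Note the CP
  reference needs ≈270 V on this phantom, above the 207 V limit — one more
  reason multi-subpulse designs are used in practice.
* Tissue parameters (`default_tissue_params()`) are plausible 7T binary
  spin-bath values (WM: R1f = 0.5 s⁻¹, R1s = 3 s⁻¹, k_fs = 2 s⁻¹,
  M0s = 0.13; GM: R1f = 0.35, k_fs = 1, M0s = 0.07; CSF free pool only;
  T2s = 10 µs everywhere). They are configuration defaults, not subject
  ground truth. `k_sf` is always derived from detailed balance
  (`k_fs·M0f = k_sf·M0s`), which also forces `k_fs = 0` wherever
  `M0s = 0`.

What the phantom does **not** emulate: electromagnetic coil simulation,
realistic anatomy or susceptibility fields, noise/Gibbs artifacts of B1
mapping, receive sensitivities, motion, or amplifier drift. Tests passing
on this phantom therefore demonstrate correctness of the algorithms and the
direction of the MT-bias mechanism, not in vivo performance figures.

## 5. Ground-truth simulation and R1 fitting

`bloch_simulate()` integrates the Bloch equation per RF sample with exact
Rodrigues rotations (relaxation neglected over the ≤1.4 ms pulse); blip
gaps are pure precession plus the blip's spatial phase ramp. It matches a
rotation-composition oracle built from matrix exponentials to 1e−10.

`spgr_two_pool_steady_state()` uses the **continuous-saturation** binary
spin-bath propagation: the free pool is rotated instantaneously each TR and
perfectly spoiled, while both longitudinal components relax/exchange
continuously with the semisolid saturated at the TR-averaged rate
`W = π g(Δ)(γβ)²`. This is the regime in which the apparent-R1 expression
(`apparent_r1()`) is derived, and the two agree: dual-flip-angle fits of
simulated signals with *shared* β match `apparent_r1(β)` to well under 2%.
The 2×2 propagator matrix exponential is evaluated in closed form
(eigenvalues are provably real for these rate matrices), vectorized over
voxels, with `Matrix::expm` as the independent oracle in tests.

The default lineshape is **Gaussian**, which is finite on resonance
(`g(0) = T2s/√(2π) ≈ 3.99 µs` at T2s = 10 µs). The super-Lorentzian is
available; its on-resonance divergence is handled by the standard cubic
extrapolation from |Δ| ≥ 1 kHz. Which lineshape underlies a given tissue is
treated as a free tissue parameter.

`dfa_fit()` is the exact two-point solution of the linearized fixed-TR
signal equation (`s/sinα = E1·s/tanα + M0(1−E1)`, `R̂1 = −log m/TR`),
generalizing to ordinary least squares for >2 angles. Fits use the
Bloch-simulated **actual** per-voxel flip angles, so flip-angle
inhomogeneity is corrected exactly and any residual spatial structure in
R̂1 comes from the uncorrected MT term. Slopes outside (0, 1) are flagged
invalid, never clamped. Noise is optional (complex Gaussian, magnitude
taken) and off by default.

One mechanism worth spelling out: with each acquisition carrying its *own*
β (the 3° pulse deposits ≈β15/5), the high-flip signal is saturated more
than the low-flip one, which biases the fitted R̂1 *downward* as β grows —
the opposite sign to the shared-β apparent-R1 curve. Spatially the fitted
map still tracks the β map almost perfectly (|r| ≈ 0.9 in WM on the default
phantom), which is exactly the shading mechanism the hybrid design removes;
the package's tests assert the magnitude of the correlation, not its sign.

## 6. Problem sizes and determinism

The shipped experiments use the 32³ phantom (≈4400 masked voxels), 500
clusters, 10 starts for single designs and 5 for the reduced sweep
(4 β_des × 7 λ points) — sizes chosen so the full end-to-end experiment
runs in about a minute and the sweep in under two on a single core, while
every qualitative conclusion (both errors ≈1% for the hybrid design at
β_des = 1.2 β_min; B1rms error collapsing from ≈17% to ≈1% relative to a
flip-angle-only design; SAR limits binding as β_des grows; flatter WM R1
with hybrid pulses) is reproduced. One seed controls every stochastic stage
(phantom, SAR model, multi-start, optional noise); rerunning any function
with the same inputs and seed is bit-identical.

## 7. Known limitations

* Small-tip designs only: no inversion/refocusing (large-tip) optimization,
  no spokes/spiral trajectories, no universal pulses.
* Perfect spoiling is assumed; incomplete-spoiling corrections are out of
  scope, as are acquisition, registration and segmentation of real data.
* The semisolid pool is assumed independent of the free pool *during* the
  short pulse (binary spin-bath); finite-T2s during-pulse dynamics are not
  modeled.
* The SAR model is a synthetic stand-in with the right algebraic structure;
  absolute SAR numbers have no physical meaning beyond their calibration
  rule.
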