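---
title: "Likelihood-guided refinement of predicted structures: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-guided refinement of predicted structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llgfold)
```

`llgfold` implements differentiable experimental likelihood targets for
atomic models — a crystallographic log-likelihood gain on intensities and a
cryo-EM Fourier-term log-likelihood gain — together with an inference-time
optimization loop that adjusts a multiple-sequence-alignment (MSA) cluster
profile so that a structure predictor's output maximizes agreement with the
experimental data. The structure predictor is abstracted behind a contract
(`predict` + exact `pullback`); the package ships a linear toy predictor so
the whole machinery runs and is testable on a desktop, without trained
network weights or a GPU. This vignette records the models, the parameters
that matter, and the design decisions taken where the problem was genuinely
open.

## The crystallographic target

For each unique reflection we work with normalized structure-factor
amplitudes. The *effective* observed amplitude `Ee` and the error factor
`Dobs` summarize the posterior of the true normalized amplitude `E` given
the measured intensity and its uncertainty; `EC` is the normalized
amplitude calculated from the model; and `sigmaA` is a per-resolution-bin
correlation between true and calculated normalized structure factors that
encodes model error.

Writing `x = Dobs * sigmaA` and `g = 1 / (1 - x^2)`, the log-likelihood
gain of one acentric reflection is

    -log(1 - x^2) - x^2 (Ee^2 + EC^2) g + log I0(2 x Ee EC g)

(the log ratio of a Rice density centred on `x EC` against the acentric
Wilson density), and for a centric reflection

    -log(1 - x^2)/2 - x^2 (Ee^2 + EC^2) g / 2 + log cosh(x Ee EC g).

Both vanish as `x -> 0`: with no usable model correlation the conditional
collapses to the Wilson distribution and the data carry no gain. The test
suite verifies that both conditional densities integrate to one and that
the implementation matches independently coded log-space densities.

### Ee and Dobs from intensities

Upstream of the target, `effective_amplitudes()` computes the posterior of
`E` under a Wilson prior (acentric or centric) given `(I_obs, sig_I)`,
by 64-node Gauss–Legendre quadrature in `E = sqrt(J)` (the substitution
removes the centric prior's integrable singularity). The two-moment
effective-amplitude representation is then

    Dobs = sqrt(1 - Var(E | I, sigI)),    Ee = E[E | I, sigI] / Dobs,

followed by a per-bin rescaling of `Ee` so its mean square is exactly 1.
This construction has the right limits — `Dobs = 1` and
`Ee = sqrt(I / (eps * Sigma))` at zero uncertainty, `Dobs` non-increasing
in `sig_I`, and finite positive `Ee` for slightly negative intensities —
and is verified against direct numerical integration in the tests. It is a
self-contained stand-in for the preprocessing that dedicated
phasing pipelines perform; we do not claim bit-compatibility with any
external implementation.

### sigmaA estimation

`refine_sigma_a()` maximizes the summed LLG over `sigmaA` separately in
each resolution bin with analytic first and second derivatives and a
safeguarded Newton iteration: steps fall back to a bounded uphill move
where the curvature is not negative, every iterate is clamped to
`[0.015, 0.99]`, and iteration stops when the step falls below `1e-4`.
The estimate matches a brute-force grid maximum of the likelihood to
better than `1e-3`.

Two statistical facts matter when interpreting recovery tests. The
likelihood depends on `sigmaA` largely through `sigmaA^2`, so (i) at
moderate `sigmaA` a single bin of 2000 reflections carries a sampling
standard deviation of about 0.01–0.04 (larger for smaller `sigmaA`) while
the estimator is essentially unbiased, and (ii) near `sigmaA = 0` the
Fisher information vanishes and the estimate has only `n^(-1/4)`
resolution — an uncorrelated model yields estimates around 0.1 at
`n = 8000`, not exactly at the clamp. Recovery is therefore asserted on
the *bias* across seeded replicates, and the "uncorrelated" check uses a
commensurately coarse bound.

### Bins, free set, R factors

Bins are equal-count in `1/d^3` (default around 100 reflections per bin,
never fewer than 50), which keeps the per-bin Newton problems
well-conditioned. The free ("test") set is stratified by bin with
largest-remainder allocation and a recorded seed; likelihood sums and
`sigmaA` refinement use the work set only, the free set is reserved for
R-free. R factors use the posterior-mean observed amplitude and per-bin
mean-matching scales (`k = sum|Fo| / sum|Fc|`), the convention under which
uncorrelated acentric Wilson amplitudes give the classical random-model
value of 0.586. Scaling for reporting optionally includes a two-parameter
Babinet bulk-solvent factor `Fc (1 - k_sol exp(-B_sol s^2/4))`; Babinet
was chosen over a solvent mask because it is differentiable, smooth and
fit by two parameters. The likelihood targets themselves use normalized
amplitudes and are invariant to any overall or per-bin scale.

## The cryo-EM target

From two half-maps, `estimate_signal_noise()` estimates per-resolution-bin
signal power `S = max(0, <Re F1 conj(F2)>)` and noise power
`N = <|F1 - F2|^2>/4`, sets `Dobs = sqrt(S / (S + N))`, and normalizes the
combined term `Fobs = (F1 + F2)/2` so that `<Ee^2> = 1` per bin. The
per-term gain couples amplitudes *and* phases:

    LLG = 2 x Ee Ecalc cos(dphi) g - x^2 (Ee^2 + Ecalc^2) g - log(1 - x^2)

with `dphi = phi_calc - phi_obs`, maximized at zero phase error. `sigmaA`
per bin is estimated by the same safeguarded Newton machinery. Bins are
spherical; directional (anisotropic) weighting is out of scope. Model
Fourier terms are computed by direct summation at the map frequencies
(exact at this scale; no gridding/interpolation), using the X-ray form
factor table by default.

Because phases enter the target, a rigid translation of the model *is*
observable against a map — unlike the crystallographic case, where
amplitudes are invariant under global translation (and inversion). In P1
that translation is a gauge freedom; pose-recovery demonstrations on
crystallographic data therefore use a P212121 cell, whose screw symmetry
pins all three translation directions.

## Geometry: pseudo-B, weights, superposition, rigid-body refinement

Predictor confidence (pLDDT, 0–100) converts to a pseudo displacement
parameter via the empirical relation
`B = (8 pi^2 / 3) (1.5 exp(0.7 - 0.01 pLDDT))^2` (Å²; ≈ 59.2 at pLDDT 70,
≈ 32.5 at 100), and reference pseudo-B converts to alignment weights by a
three-branch rule (1 below 11.5 Å², linear to 0.5 at 40 Å², exponential
decay beyond), continuous at both breakpoints.

`weighted_kabsch()` solves the weighted superposition problem exactly
(weighted centroids plus SVD of the weighted cross-covariance with
determinant correction); collinear configurations are rejected.
`rigid_body_refine()` maximizes a differentiable target over the six pose
parameters — axis-angle rotation about the centroid composed onto the
starting pose, plus translation — by quasi-Newton (L-BFGS) ascent with
exact pose gradients obtained by projecting the coordinate gradient
through the closed-form rotation Jacobian. The returned pose never scores
below the starting one. Re-estimating `sigmaA` at every pose evaluation
substantially widens the capture radius: resolution shells that disagree
with the data are automatically down-weighted early and recover weight as
the pose improves. This is how the recovery demonstrations at 1 Å / 3°
displacement reach their targets.

## The refinement loop

`run_refinement()` optimizes a linear bias on the MSA cluster profile,
`m = w * m0 + b` (elementwise, no renormalization — the predictor consumes
the biased profile as-is), with AdamW and separate learning rates for `w`
and `b`. Each iteration: bias → predict → pseudo-B from confidence →
confidence-weighted Kabsch alignment to the reference → rigid-body
refinement → per-bin `sigmaA` → loss `-LLG + omega_L2 * L2` → analytic
backward pass → optimizer step. The restraint is the weighted *sum* of
squared C-alpha deviations (so its magnitude scales with chain length —
the tiny default weight reflects that).

The two-phase schedule uses the published defaults: phase 1 runs three
independent traces of 100 iterations with `lr_mul = 1.0`,
`lr_add = 0.05`, `omega_L2 = 1e-11` and a 3 Å low-resolution cutoff
(applied to the likelihood; bins and `Ee` normalization are re-derived on
the truncated set); the best-LLG trace (ties: lowest index) seeds phase 2,
which runs up to 500 iterations at full resolution with both learning
rates `1e-3`, no restraint, and early stopping when the best LLG fails to
improve by more than 0.1 for 50 consecutive iterations. What distinguishes
the phase-1 traces is not stated by the published schedule; here trace
`k > 1` perturbs the additive bias with `N(0, 0.01)` noise under seed
`master + k - 1`, and trace 1 starts unperturbed. AdamW uses conventional
moment parameters (0.9/0.999, eps 1e-8) and *zero* decoupled weight decay:
the multiplicative bias is centred on 1, so decay toward 0 would be a
systematic pull away from the identity rather than a regularizer.

### The backward pass and detached poses

There is no automatic differentiation here; every gradient is analytic:
structure-factor summation, the per-bin E-normalization chain (including
the dependence of each bin's normalizer on every amplitude), the LLG
derivative in `EC` and in the calculated phase, the pseudo-B path
(pLDDT → B → Debye–Waller), and the predictor's linear readout. The two
poses are treated as constants in the backward pass, justified to first
order by stationarity: the Kabsch pose is the exact minimizer of the
weighted alignment residual, and the rigid-body pose is a stationary point
of the LLG at convergence, so first-order pose variation contributes
nothing. For this argument to be exact the pose must be stationary under
the *same* `sigmaA` at which the loss is evaluated; the loop therefore
alternates `sigmaA` estimation with rigid-body refinement
(`rbr_rounds`). One round — the default — leaves a small first-order
residual that the optimizer tolerates without measurable effect on
convergence; with several rounds and tight `rbr_tol`, the loss gradient
with respect to the bias matches finite differences to about `1e-3`
relative, which the test suite checks.

### Ranking subsampled MSA profiles

`rank_subsampled_profiles()` scores each candidate profile with a single
predict → align → rigid-body → `sigmaA` → work-set LLG pass and sorts by
LLG (stable ties). Subsampling itself is uniform over sequences
(`subsample_msa()`), and profiles are column frequencies over the
23-category alphabet; density-based clustering of the alignment is out of
scope.

## The synthetic generators and the toy predictor

`make_toy_model()` builds a compact self-avoiding solenoid of C-alpha
"carbon" atoms with exactly 3.8 Å consecutive spacing and B = 20 Å², in a
cell padded by 5 Å. `simulate_reflections()` produces a complete
asymmetric-unit index set to the requested resolution, intensities
`|Fc|^2` with Gaussian noise `sig_I = noise_frac (<I>_bin + I)/2`
(Gaussian rather than Poisson for analytic tractability), and runs the
full preparation pipeline. `simulate_halfmaps()` synthesizes a
band-limited density and adds independent Hermitian Fourier noise colored
by resolution shell so that *every* shell has per-half-map per-term SNR
equal to `snr`; the half-map FSC is then `snr/(snr+1)` and — because the
combined term `(F1+F2)/2` sees half the noise power — the estimated
`Dobs` is `sqrt(2 snr / (2 snr + 1))` (≈ 0.943 at `snr = 4`). The
signal-power estimator `max(0, <Re F1 conj F2>)` has half-normal sampling
scale `P/sqrt(n)` under pure noise, so zero-signal bins show `Dobs` of
order `n^{-1/4}`, not exactly zero; tests bound it accordingly.

The toy predictor is a *test double*, not a folding model: displacement is
a fixed random linear readout (per-residue 3×23 matrices) of the
per-residue mean profile deviation from `m0`, so the loop's optimum is
identifiable and gradients are exact; pLDDT decreases linearly with
displacement magnitude (slope 10 per Å, clamped to [30, 100]). Each
residue's readout is scaled to spectral norm 0.4 Å per unit-norm profile
deviation. That scale is the one genuinely free constant in the test
double, and it is chosen so that one AdamW step at the standard phase-1
learning rates moves coordinates by roughly 0.1 Å — the regime the
published schedule is designed for with a real folding network, whose
coordinate response to small profile changes is smooth and bounded. A much
stiffer readout makes any fixed-step-size schedule overshoot, which would
measure the test double's stiffness rather than the method.

What the generators deliberately do not emulate: sidechains and real
chemistry; Poisson counting statistics; anisotropic or directional map
noise; solvent contribution in the simulated data; MSA evolution (columns
are independent categorical draws); and any nonlinearity or multimodality
of a real predictor's profile-to-structure map. Passing the recovery
benchmark therefore demonstrates the correctness and coupling of the
likelihood targets, geometry and optimization loop — not that a real
folding network would be steered equally easily.

## The standard recovery benchmark

The end-to-end experiment used by the tests and the acceptance script:
50 residues, 2.0 Å data at 10% intensity noise, a hidden additive profile
bias encoding a 1.0 Å C-alpha perturbation (the "truth"), the unbiased
prediction as reference, and the full two-phase schedule. Across five
seeds the loop is required to at least halve the initial RMSD on four and
to improve the LLG on all. Typical behaviour is much stronger — final
RMSD around 0.01–0.05 Å and LLG within a few percent of the value at the
true bias. Problem sizes throughout the test suite (25–50 residues,
2.0–2.6 Å, boxes of 60–96 Å) were chosen as the smallest at which the
statistical assertions above are stable.

## Known limitations

* Space-group support covers the common protein groups P1, P-1, P2, P21,
  C2, P222, P212121 with hand-coded operators; no trigonal/tetragonal/
  hexagonal groups, no anomalous pairs, no twinning.
* Direct summation limits practical sizes to a few hundred atoms and a
  few thousand reflections; there is no FFT structure-factor path.
* The `Ee`/`Dobs` posterior construction is a reasonable two-moment
  summary, not a reproduction of any specific external preprocessing
  pipeline.
* The phase-1 resolution cutoff interacts with bin re-derivation; with
  very few low-resolution reflections the truncated set may hold a single
  bin.
* Amplitude-only targets cannot determine a global translation (or hand)
  in P1; the loop relies on the reference alignment for that gauge.
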