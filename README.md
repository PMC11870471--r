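# llgfold

Likelihood-guided refinement of predicted protein structures, in R.

Structure predictors are remarkably accurate but blind to the particular
conformational state an experiment has captured. `llgfold` implements the
computational core of inference-time, data-guided refinement: rather than
pushing atoms around in Cartesian space, it optimizes a *bias* on the
predictor's MSA cluster profile input so that the predicted structure
maximizes an experimental likelihood. The package provides

* a **crystallographic log-likelihood-gain target on intensities**: with
  normalized amplitudes `Ee` (effective observed, with error factor
  `Dobs`) and `EC` (calculated), and `x = Dobs·σA`, `g = 1/(1−x²)`,

      acentric:  −ln(1−x²) − x²(Ee²+EC²)g + ln I₀(2x·Ee·EC·g)
      centric:   −½ln(1−x²) − ½x²(Ee²+EC²)g + ln cosh(x·Ee·EC·g)

  with per-resolution-bin σA refined by safeguarded Newton iteration,
  clamped to [0.015, 0.99];
* a **cryo-EM Fourier-term target** coupling amplitudes and phases,
  `2x·Ee·Ec·cosΔφ·g − x²(Ee²+Ec²)g − ln(1−x²)`, with `Dobs` estimated per
  bin from half-map correlations and differences;
* **exact analytic gradients** of both targets with respect to atomic
  coordinates and B values, through structure-factor summation and
  per-bin E-normalization (no automatic differentiation);
* confidence geometry: pLDDT → pseudo-B (`(8π²/3)(1.5e^{0.7−0.01·pLDDT})²`),
  pseudo-B → alignment weights, weighted Kabsch superposition, and
  rigid-body refinement by quasi-Newton ascent of the likelihood;
* the **two-phase bias-optimization loop** (AdamW; three adventurous
  low-resolution traces with a weighted L2 restraint, then fine-tuning at
  full resolution with early stopping) plus likelihood ranking of
  subsampled-MSA profiles;
* **synthetic data generators** (toy Cα models, Wilson-statistics
  intensities with controlled noise, half-maps with controlled per-shell
  SNR, synthetic MSAs) and a differentiable **toy predictor**, so the
  entire pipeline runs and is testable on a desktop;
* reflection I/O (MTZ and reflection CIF), minimal MRC map I/O, PDB models
  via `bio3d`, and a small command-line front-end (`exec/llgfold`).

Everything is tidyverse-native: reflection sets, map terms, models, σA
bins and refinement histories are tibbles; fitted refinements support
`tidy()`, `glance()` and `autoplot()`.

## A worked example

Simulate a toy crystal, score the model, and refine σA:

```r
library(llgfold)
model <- make_toy_model(25, seed = 2)
refl  <- simulate_reflections(model, dmin = 2.2, noise_frac = 0.1, seed = 3)
refl
#> <reflections> 2405 unique reflections, P1, d = 24.69 - 2.2 A
#> # A tibble: 2,405 × 14   (h, k, l, i_obs, sig_i, d, centric, epsilon,
#> #   bin, ee, dobs, f_obs, is_test, ...)

sf      <- compute_structure_factors(model, model_symmetry(model), refl)
sigma_a <- refine_sigma_a(refl, sf)
llg_total(refl, sf, sigma_a)
#> [1] 4484.256
r_factors(refl, sf)
#> # A tibble: 1 × 4
#>   r_work r_free n_work n_test
#> 1 0.0649 0.0556   2285    120
```

The model is the one that generated the data, so σA sits at its upper
clamp, the LLG is large and positive, and R factors reflect only the 10%
intensity noise.

Now the full loop: hide a 1 Å Cα perturbation inside an additive profile
bias, simulate data from that "truth", and let the optimizer find it,
starting from the unbiased prediction (a compact schedule for the demo —
the defaults run 3×100 + ≤500 iterations):

```r
n_res <- 20
base  <- model_coords(make_toy_model(n_res, seed = 2))
m0    <- make_profile(3, n_res, seed = 5)$profile
pred  <- toy_predictor(toy_fold_spec(base, m0, seed = 6))

set.seed(7)
b_true <- array(rnorm(length(m0)), dim = dim(m0))
b_true <- b_true / sqrt(mean(rowSums((pred$predict(m0 + b_true)$coords - base)^2)))
truth  <- pred$predict(apply_bias(m0, array(1, dim(m0)), b_true))

truth_model <- atomic_model(truth$coords, b_iso = plddt_to_pseudo_b(truth$plddt))
attr(truth_model, "symmetry") <- model_symmetry(make_toy_model(n_res, seed = 2))
refl <- simulate_reflections(truth_model, dmin = 2.5, noise_frac = 0.1, seed = 8)

rd  <- refinement_data(refl, x_ref = base, plddt_ref = rep(90, n_res))
cfg <- refinement_config(seed = 1, n_iter_phase1 = 40, n_traces = 2,
                         n_iter_phase2 = 80)
fit <- run_refinement(m0, pred, rd, cfg)
fit
#> <fold_refinement> xtal target
#>   initial LLG 185.184 -> best LLG 2427.13
#>   iterations: 160 (2 phase-1 traces)
glance(fit)
#> # A tibble: 1 × 9
#>   llg_initial llg_final llg_gain r_work r_free rmsd_ref n_iter ...
#> 1        185.     2427.    2242. 0.0563 0.0643    0.972    160

attr(weighted_kabsch(fit$best$coords, truth$coords), "rmsd")
#> [1] 0.01516999
```

The work-set LLG climbs from 185 to 2427 and the model lands 0.015 Å from
the hidden truth — the initial error was 1.0 Å. `tidy(fit)` exposes the
per-iteration history and `autoplot(fit)` plots the LLG trajectories of
every trace.

The command-line front-end wraps the same functions:

```sh
exec/llgfold simulate --prefix toy --n-res 30 --dmin 2 --noise 0.1 --seed 1
exec/llgfold llg --mtz toy_data.mtz --model toy_model.pdb
exec/llgfold refine --mtz toy_data.mtz --model toy_model.pdb --prefix out
```

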