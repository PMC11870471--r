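# Shared fixtures, built in code and memoized per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small crystallographic dataset: 25 residues, P1, 2.2 A, 10% noise
small_xtal <- function() {
  memo("small_xtal", {
    model <- make_toy_model(25, seed = 2)
    refl <- simulate_reflections(model, dmin = 2.2, noise_frac = 0.1,
                                 seed = 3)
    list(model = model, sym = model_symmetry(model), refl = refl)
  })
}

# noise-free P212121 dataset for pose work
ortho_xtal <- function() {
  memo("ortho_xtal", {
    model <- make_toy_model(30, seed = 3, space_group = "P212121")
    refl <- simulate_reflections(model, dmin = 2.0, noise_frac = 0,
                                 seed = 5)
    list(model = model, sym = model_symmetry(model), refl = refl)
  })
}

# small cryo-EM half-map dataset
small_cryoem <- function() {
  memo("small_cryoem", {
    model <- make_toy_model(30, seed = 3)
    box <- model_symmetry(model)$cell[1:3] + 6
    hm <- simulate_halfmaps(model, box = box, voxel = 2, dmin = 8, snr = 4,
                            seed = 2)
    terms <- estimate_signal_noise(hm$half1, hm$half2, voxel = hm$voxel,
                                   dmin = 8)
    list(model = model, hm = hm, terms = terms)
  })
}

# The synthetic recovery experiment: a hidden additive profile bias encodes
# a coordinate perturbation of the requested RMSD; reflection data are
# simulated from the perturbed ("true") structure, and the unbiased
# prediction (the reference) starts that far from the truth.
recovery_fixture <- function(seed, n_res = 50, dmin = 2.0,
                             noise_frac = 0.1, perturb = 1.0,
                             n_clusters = 3) {
  base_m <- make_toy_model(n_res, seed = seed)
  base <- model_coords(base_m)
  m0 <- make_profile(n_clusters, n_res, seed = seed + 100)$profile
  predictor <- toy_predictor(toy_fold_spec(base, m0, seed = seed + 200))
  b_true <- llgfold:::.with_seed(seed + 300, {
    array(stats::rnorm(length(m0)), dim = dim(m0))
  })
  probe <- predictor$predict(m0 + b_true)
  b_true <- b_true * perturb / sqrt(mean(rowSums((probe$coords - base)^2)))
  truth <- predictor$predict(apply_bias(m0, array(1, dim(m0)), b_true))
  truth_model <- atomic_model(truth$coords,
                              b_iso = plddt_to_pseudo_b(truth$plddt))
  attr(truth_model, "symmetry") <- model_symmetry(base_m)
  refl <- simulate_reflections(truth_model, dmin = dmin,
                               noise_frac = noise_frac, seed = seed + 400)
  list(
    m0 = m0, predictor = predictor, b_true = b_true,
    truth = truth, base = base,
    rmsd_initial = sqrt(mean(rowSums((truth$coords - base)^2))),
    rd = refinement_data(refl, x_ref = base, plddt_ref = rep(90, n_res))
  )
}

rmsd_after_superposition <- function(a, b) {
  attr(weighted_kabsch(a, b), "rmsd")
}
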