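test_that("identical half-maps give zero noise and Dobs = 1", {
  fx <- small_cryoem()
  tm <- estimate_signal_noise(fx$hm$truth, fx$hm$truth, voxel = fx$hm$voxel,
                              dmin = 8)
  bs <- attr(tm, "bin_stats")
  expect_true(all(bs$noise == 0))
  expect_true(all(bs$dobs == 1))
  expect_true(all(abs(tapply(tm$ee^2, tm$bin, mean) - 1) < 1e-9))
})

test_that("pure-noise half-maps give near-zero Dobs with populated bins", {
  model <- make_toy_model(30, seed = 3)
  hm <- simulate_halfmaps(model, box = 76, voxel = 2, dmin = 8, snr = 0,
                          seed = 3)
  tm <- estimate_signal_noise(hm$half1, hm$half2, voxel = hm$voxel, dmin = 8,
                              n_bins = 5)
  bs <- attr(tm, "bin_stats")
  expect_true(all(bs$n >= 300))
  # S = max(0, mean cross-term) has half-normal sampling scale ~P/sqrt(n)
  # under zero signal, so Dobs^2 ~ 2|z|/sqrt(n); assert the 3-sigma bound
  # and that the estimated signal fraction is consistent with zero
  expect_true(all(bs$dobs^2 <= 2 * 3 / sqrt(bs$n)))
  expect_lt(mean(bs$fsc), 3 / sqrt(min(bs$n)))
})

test_that("known per-shell SNR is recovered as Dobs and FSC", {
  model <- make_toy_model(30, seed = 3)
  hm <- simulate_halfmaps(model, box = 76, voxel = 2, dmin = 8, snr = 4,
                          seed = 7)
  tm <- estimate_signal_noise(hm$half1, hm$half2, voxel = hm$voxel, dmin = 8,
                              n_bins = 5)
  bs <- attr(tm, "bin_stats")
  expect_true(all(bs$n >= 300))
  # per-half-map SNR = 4: the averaged term has twice that, so
  # Dobs = sqrt(2 snr / (2 snr + 1)); the half-map FSC is snr / (snr + 1)
  expect_true(all(abs(bs$dobs - sqrt(8 / 9)) < 0.05))
  expect_true(all(abs(bs$fsc - 4 / 5) < 0.05))
  expect_error(estimate_signal_noise(hm$half1, hm$half2[1:10, , ],
                                     voxel = 2, dmin = 8), "match")
})

test_that("the per-term LLG formula matches independent arithmetic", {
  expect_equal(cryoem_llg_term(1, 1, 0, 1, 0.6),
               2 * 0.6 / 0.64 - 0.36 * 2 / 0.64 - log(0.64))
  expect_equal(cryoem_llg_term(1.2, 0.7, 0.5, 0.9, 0.4), local({
    x2 <- (0.9 * 0.4)^2
    2 * 0.9 * 0.4 * 1.2 * 0.7 * cos(0.5) / (1 - x2) -
      x2 * (1.2^2 + 0.7^2) / (1 - x2) - log(1 - x2)
  }))
  expect_equal(cryoem_llg_term(1.3, 0.8, 1.1, 0, 0.5), 0)
  expect_error(cryoem_llg_term(1, 1, 0, 1, 1), "degenerate")
  # maximized over the phase difference at zero
  phis <- seq(-pi, pi, length.out = 201)
  vals <- cryoem_llg_term(1.1, 0.9, phis, 0.9, 0.7)
  expect_equal(phis[which.max(vals)], 0, tolerance = 1e-9)
})

test_that("cryo-EM sigmaA estimation hits clamps and recovers truth", {
  fx <- small_cryoem()
  tm0 <- estimate_signal_noise(fx$hm$truth, fx$hm$truth,
                               voxel = fx$hm$voxel, dmin = 8)
  sA <- estimate_sigma_a_cryoem(tm0, fx$model)
  expect_true(all(sA$sigma_a == 0.99))
  # uncorrelated model: lower clamp
  rot <- make_toy_model(30, seed = 77)
  rot <- set_model_coords(rot, model_coords(rot)[sample(30), ] +
                            matrix(runif(90, 0, 8), 30, 3))
  sA0 <- estimate_sigma_a_cryoem(tm0, rot)
  expect_true(mean(sA0$sigma_a) < 0.2)
  # generative recovery of sigmaA = 0.6 from synthetic normalized terms
  set.seed(31)
  n <- 3000
  Et <- complex(real = rnorm(n, 0, sqrt(0.5)),
                imaginary = rnorm(n, 0, sqrt(0.5)))
  Ec <- 0.6 * Et + sqrt(1 - 0.36) *
    complex(real = rnorm(n, 0, sqrt(0.5)),
            imaginary = rnorm(n, 0, sqrt(0.5)))
  terms <- tibble::tibble(ee = Mod(Et), phi_obs = Arg(Et), dobs = 1,
                          bin = 1L, d = 8, s = 1 / 8)
  class(terms) <- c("map_terms", class(tibble::tibble()))
  est <- estimate_sigma_a_cryoem(terms, list(e_calc = Mod(Ec),
                                             phi_calc = Arg(Ec)))
  expect_equal(est$sigma_a, 0.6, tolerance = 0.05)
})

test_that("the map likelihood prefers the true pose", {
  fx <- small_cryoem()
  tm <- estimate_signal_noise(fx$hm$truth, fx$hm$truth,
                              voxel = fx$hm$voxel, dmin = 8)
  sA <- estimate_sigma_a_cryoem(tm, fx$model)
  llg0 <- cryoem_llg_total(tm, fx$model, sA)
  shifted <- set_model_coords(fx$model, model_coords(fx$model) +
    matrix(c(attr(tm, "cell")[1] / 2, 0, 0), 30, 3, byrow = TRUE))
  expect_gt(llg0, cryoem_llg_total(tm, shifted, sA))
  X <- model_coords(fx$model)
  cen <- colMeans(X)
  R5 <- llgfold:::.rotation_from_axis_angle(c(5 * pi / 180, 0, 0))
  rot <- set_model_coords(fx$model, sweep(sweep(X, 2, cen) %*% t(R5), 2, -cen))
  expect_gt(llg0, cryoem_llg_total(tm, rot, sA))
})

test_that("the map likelihood is invariant to the map amplitude scale", {
  fx <- small_cryoem()
  sA <- estimate_sigma_a_cryoem(fx$terms, fx$model)
  tm2 <- estimate_signal_noise(2 * fx$hm$half1, 2 * fx$hm$half2,
                               voxel = fx$hm$voxel, dmin = 8)
  expect_equal(cryoem_llg_total(tm2, fx$model, sA),
               cryoem_llg_total(fx$terms, fx$model, sA), tolerance = 1e-9)
})

test_that("coordinate gradients traverse the cryo-EM chain", {
  fx <- small_cryoem()
  sA <- estimate_sigma_a_cryoem(fx$terms, fx$model)
  ev <- cryoem_llg_total(fx$terms, fx$model, sA, gradient = TRUE)
  X <- model_coords(fx$model); e <- 1e-4
  set.seed(12)
  for (idx in sample(length(X), 5)) {
    Xp <- X; Xp[idx] <- Xp[idx] + e
    Xm <- X; Xm[idx] <- Xm[idx] - e
    fd <- (cryoem_llg_total(fx$terms, set_model_coords(fx$model, Xp), sA) -
             cryoem_llg_total(fx$terms, set_model_coords(fx$model, Xm), sA)) /
      (2 * e)
    expect_equal(ev$grad_coords[idx], fd, tolerance = 1e-3)
  }
})

test_that("total map LLG decreases with growing coordinate perturbation", {
  fx <- small_cryoem()
  sizes <- c(0, 0.5, 1, 2, 3)
  means <- vapply(sizes, function(sz) {
    mean(vapply(1:5, function(s) {
      pert <- llgfold:::.with_seed(s, matrix(rnorm(90, 0, sz / sqrt(3)),
                                             30, 3))
      m <- set_model_coords(fx$model, model_coords(fx$model) + pert)
      cryoem_llg_total(fx$terms, m, sigma_a = NULL)
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("MRC maps round-trip through the minimal reader/writer", {
  fx <- small_cryoem()
  p1 <- tempfile(fileext = ".mrc")
  write_mrc(fx$hm$half1, fx$hm$voxel, p1)
  back <- read_mrc(p1)
  expect_equal(back$map, fx$hm$half1, tolerance = 1e-6)
  expect_equal(back$voxel, fx$hm$voxel, tolerance = 1e-6)
  # estimate_signal_noise accepts file paths
  p2 <- tempfile(fileext = ".mrc")
  write_mrc(fx$hm$half2, fx$hm$voxel, p2)
  tm <- estimate_signal_noise(p1, p2, dmin = 8)
  expect_equal(nrow(tm), nrow(fx$terms))
})

test_that("half-map FSC at the band limit follows the SNR relation", {
  model <- make_toy_model(30, seed = 3)
  for (snr in c(1, 4)) {
    hm <- simulate_halfmaps(model, box = 76, voxel = 2, dmin = 8, snr = snr,
                            seed = 11)
    bs <- attr(estimate_signal_noise(hm$half1, hm$half2, voxel = hm$voxel,
                                     dmin = 8, n_bins = 5), "bin_stats")
    expect_true(all(abs(bs$fsc - snr / (snr + 1)) < 0.05))
  }
  hmi <- simulate_halfmaps(model, box = 60, voxel = 2, dmin = 8,
                           snr = Inf, seed = 1)
  expect_identical(hmi$half1, hmi$half2)
})
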