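test_that("LLGI values agree with the conditional densities", {
  # independent log-space density implementations
  log_pa <- function(Ee, EC, D, sA) {
    x <- D * sA; g <- 1 / (1 - x^2); t <- 2 * x * Ee * EC * g
    log(2 * Ee * g) - (Ee^2 + (x * EC)^2) * g +
      log(besselI(t, 0, expon.scaled = TRUE)) + t
  }
  log_pc <- function(Ee, EC, D, sA) {
    x <- D * sA; g <- 1 / (1 - x^2); u <- x * Ee * EC * g
    0.5 * log(2 * g / pi) - (Ee^2 + (x * EC)^2) * g / 2 +
      abs(u) + log1p(exp(-2 * abs(u))) - log(2)
  }
  set.seed(3)
  for (i in 1:10) {
    Ee <- runif(1, 0.1, 2.5); EC <- runif(1, 0.1, 2.5)
    D <- runif(1, 0.2, 1); sA <- runif(1, 0.05, 0.95)
    expect_equal(llgi_acentric(Ee, EC, D, sA),
                 log_pa(Ee, EC, D, sA) - log(2 * Ee * exp(-Ee^2)),
                 tolerance = 1e-10)
    expect_equal(llgi_centric(Ee, EC, D, sA),
                 log_pc(Ee, EC, D, sA) - log(sqrt(2 / pi) * exp(-Ee^2 / 2)),
                 tolerance = 1e-10)
  }
  expect_error(llgi_acentric(1, 1, 1, 1), "degenerate")
  # extreme arguments stay finite (log-Bessel / log-cosh asymptotics)
  expect_true(is.finite(llgi_acentric(100, 100, 1, 0.98)))
  expect_true(is.finite(llgi_centric(100, 100, 1, 0.98)))
})

test_that("sigmaA derivatives match numerical differentiation", {
  set.seed(5)
  ee <- runif(60, 0.2, 2); ec <- runif(60, 0.2, 2)
  dob <- runif(60, 0.5, 1); cen <- runif(60) < 0.3
  f <- function(s) sum(ifelse(cen, llgi_centric(ee, ec, dob, s),
                              llgi_acentric(ee, ec, dob, s)))
  for (s0 in c(0.2, 0.6, 0.9)) {
    d <- llgfold:::.llgi_sigma_derivs(ee, ec, dob, rep(s0, 60), cen)
    e <- 1e-5
    expect_equal(d$g1, (f(s0 + e) - f(s0 - e)) / (2 * e), tolerance = 1e-5)
    expect_equal(d$g2, (f(s0 + e) - 2 * f(s0) + f(s0 - e)) / e^2,
                 tolerance = 1e-3)
  }
})

test_that("total LLG is additive over work and test sets", {
  fx <- small_xtal()
  sf <- compute_structure_factors(fx$model, fx$sym, fx$refl)
  sA <- refine_sigma_a(fx$refl, sf)
  all_ <- llg_total(fx$refl, sf, sA, use = "all")
  work <- llg_total(fx$refl, sf, sA, use = "work")
  test_only <- {
    refl_t <- fx$refl; refl_t$is_test <- !refl_t$is_test
    llg_total(refl_t, sf, sA, use = "work")
  }
  expect_equal(work + test_only, all_, tolerance = 1e-9)
})

test_that("LLG vanishes at the no-information clamp and ranks model quality", {
  fx <- small_xtal()
  sf <- compute_structure_factors(fx$model, fx$sym, fx$refl)
  n <- sum(!fx$refl$is_test)
  expect_lt(abs(llg_total(fx$refl, sf, 0.015)) / n, 1e-2)
  # perfect model scores above a 2-A-perturbed one on noise-free data
  refl0 <- simulate_reflections(fx$model, dmin = 2.2, noise_frac = 0,
                                seed = 13)
  sf0 <- compute_structure_factors(fx$model, fx$sym, refl0)
  sA0 <- refine_sigma_a(refl0, sf0)
  pert <- set_model_coords(fx$model, model_coords(fx$model) +
    llgfold:::.with_seed(2, matrix(rnorm(nrow(fx$model) * 3, 0, 2 / sqrt(3)),
                                   ncol = 3)))
  sfp <- compute_structure_factors(pert, fx$sym, refl0)
  sAp <- refine_sigma_a(refl0, sfp)
  expect_gt(llg_total(refl0, sf0, sA0), llg_total(refl0, sfp, sAp))
})

test_that("sigmaA refinement finds the per-bin optimum and stays clamped", {
  gen <- function(sa_true, n, seed) {
    llgfold:::.with_seed(seed, {
      Et <- complex(real = rnorm(n, 0, sqrt(0.5)),
                    imaginary = rnorm(n, 0, sqrt(0.5)))
      Ec <- sa_true * Et + sqrt(1 - sa_true^2) *
        complex(real = rnorm(n, 0, sqrt(0.5)),
                imaginary = rnorm(n, 0, sqrt(0.5)))
      list(ee = Mod(Et), ec = Mod(Ec))
    })
  }
  d <- gen(0.7, 2000, 21)
  refl <- tibble::tibble(ee = d$ee, dobs = 1, bin = 1L, centric = FALSE,
                         d = 2, is_test = FALSE, epsilon = 1L)
  sf <- tibble::new_tibble(list(e_calc = d$ec), nrow = 2000)
  est <- refine_sigma_a(refl, sf)
  expect_gte(est$sigma_a, 0.68); expect_lte(est$sigma_a, 0.72)
  # the returned value is a stationary point of the summed LLGI
  f <- function(s) sum(llgi_acentric(d$ee, d$ec, 1, s))
  e <- 1e-4
  expect_lt(abs((f(est$sigma_a + e) - f(est$sigma_a - e)) / (2 * e)),
            1e-3 * 2000)
  # matches a brute-force grid maximum
  grid <- seq(0.015, 0.99, by = 5e-4)
  expect_equal(est$sigma_a, grid[which.max(vapply(grid, f, 0))],
               tolerance = 1e-3)
  # uncorrelated model: clamped toward the lower bound (the likelihood
  # carries ~n^(-1/4) resolution near zero, so "near" is coarse)
  d0 <- gen(0.0, 8000, 22)
  refl0 <- tibble::tibble(ee = d0$ee, dobs = 1, bin = 1L, centric = FALSE,
                          d = 2, is_test = FALSE, epsilon = 1L)
  sf0 <- tibble::new_tibble(list(e_calc = d0$ec), nrow = 8000)
  expect_lt(refine_sigma_a(refl0, sf0)$sigma_a, 0.15)
  # clamp bounds always hold
  for (sa in c(0.0, 0.5, 0.999)) {
    dd <- gen(sa, 500, 23)
    rr <- tibble::tibble(ee = dd$ee, dobs = 1, bin = 1L, centric = FALSE,
                         d = 2, is_test = FALSE, epsilon = 1L)
    ss <- tibble::new_tibble(list(e_calc = dd$ec), nrow = 500)
    est <- refine_sigma_a(rr, ss)$sigma_a
    expect_gte(est, 0.015); expect_lte(est, 0.99)
  }
})

test_that("work-set LLG is non-decreasing over outer sigmaA re-refinements", {
  fx <- small_xtal()
  sf <- compute_structure_factors(fx$model, fx$sym, fx$refl)
  llg <- -Inf
  sA <- rep(0.3, length(unique(fx$refl$bin)))
  for (i in 1:4) {
    sA_t <- refine_sigma_a(fx$refl, sf, init = sA)
    llg_new <- llg_total(fx$refl, sf, sA_t)
    expect_gte(llg_new, llg - 1e-9)
    llg <- llg_new
    sA <- sA_t$sigma_a
  }
})

test_that("R factors hit the trivial and random-model limits", {
  n <- 4000
  set.seed(42)
  fo <- sqrt(rexp(n))
  refl <- tibble::tibble(f_obs = fo, bin = rep(1:8, each = n / 8),
                         is_test = rep(c(FALSE, TRUE), c(n - 200, 200)),
                         epsilon = 1L)
  sf_perfect <- tibble::new_tibble(list(f_calc = fo, s = rep(0.3, n)),
                                   nrow = n)
  r0 <- r_factors(refl, sf_perfect)
  expect_equal(r0$r_work, 0, tolerance = 1e-12)
  expect_equal(r0$r_free, 0, tolerance = 1e-12)
  # uncorrelated Wilson amplitudes: classical acentric random-model limit
  fc <- sqrt(rexp(n))
  r1 <- r_factors(refl, tibble::new_tibble(list(f_calc = fc,
                                                s = rep(0.3, n)), nrow = n))
  expect_equal(r1$r_work, 0.586, tolerance = 0.02)
  # Fc = 0 gives R = 1
  rz <- llgfold:::.r_factors_fast(refl, rep(0, n))
  expect_equal(unname(rz["r_work"]), 1)
  # empty test set reports missing R-free
  refl2 <- refl; refl2$is_test <- FALSE
  expect_true(is.na(r_factors(refl2, sf_perfect)$r_free))
})

test_that("xtal_target gradients traverse the full chain", {
  fx <- small_xtal()
  small <- make_toy_model(10, seed = 4)
  refl <- simulate_reflections(small, dmin = 2.6, noise_frac = 0.1, seed = 6)
  ev <- xtal_target(small, refl, sigma_a = 0.8)
  f <- function(X) {
    mm <- set_model_coords(small, X)
    sf <- normalize_to_E(compute_structure_factors(mm, model_symmetry(small),
                                                   refl), refl)
    llg_total(refl, sf, 0.8)
  }
  X <- model_coords(small); e <- 1e-4
  set.seed(10)
  for (idx in sample(length(X), 5)) {
    Xp <- X; Xp[idx] <- Xp[idx] + e
    Xm <- X; Xm[idx] <- Xm[idx] - e
    fd <- (f(Xp) - f(Xm)) / (2 * e)
    expect_equal(ev$grad_coords[idx], fd, tolerance = 1e-3)
  }
})
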