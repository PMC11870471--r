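# small, fast loop fixture shared across tests in this file
loop_fx <- function() {
  memo("loop_fx", recovery_fixture(1, n_res = 15, dmin = 2.6))
}

test_that("profile bias applies elementwise without renormalization", {
  m0 <- make_profile(2, 6, seed = 1)$profile
  one <- array(1, dim(m0)); zero <- array(0, dim(m0))
  expect_identical(apply_bias(m0, one, zero), m0)
  expect_identical(apply_bias(m0, zero, m0), m0)
  set.seed(2)
  w <- array(runif(length(m0)), dim(m0))
  b <- array(rnorm(length(m0)), dim(m0))
  out <- apply_bias(m0, w, b)
  for (i in sample(length(m0), 10)) {
    expect_identical(out[i], w[i] * m0[i] + b[i])
  }
  # rows are free to leave the simplex: no renormalization happens
  expect_false(all(abs(apply(out, c(1, 2), sum) - 1) < 1e-6))
  expect_error(apply_bias(m0, array(1, c(1, 6, 23)), b), "shape")
})

test_that("the weighted positional restraint is exact on hand cases", {
  x <- matrix(0, 4, 3)
  y <- x; y[2, 1] <- 2
  expect_equal(l2_restraint(x, x), 0)
  expect_equal(l2_restraint(y, x), 4)
  expect_equal(l2_restraint(y, x, weights = rep(0, 4)), 0)
  expect_equal(l2_restraint(y, x, weights = c(1, 0.5, 1, 1)), 2)
  expect_error(l2_restraint(x[1:3, ], x), "lengths")
})

test_that("the loop loss gradient matches finite differences through the predictor", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 1, rbr_steps = 80, rbr_tol = 1e-13,
                           rbr_rounds = 8)
  m0 <- fx$m0
  loss_of_b <- function(bb) {
    st <- llgfold:::.init_state(m0, cfg, phase = 2L)
    st$b <- bb
    st <- iterate_once(st, fx$predictor, fx$rd, cfg, update = FALSE)
    st$history[[1]]$loss
  }
  grad_of_b <- function(bb) {
    profile <- apply_bias(m0, array(1, dim(m0)), bb)
    p <- fx$predictor$predict(profile)
    pseudo_b <- plddt_to_pseudo_b(p$plddt)
    pose_k <- weighted_kabsch(p$coords, fx$rd$x_ref,
                              pseudo_b_to_weight(fx$rd$pseudo_b_ref))
    x_al <- apply_pose(p$coords, pose_k)
    lc <- llgfold:::.loop_context(fx$rd, pseudo_b)
    rbr <- llgfold:::.pose_sigma_alternate(lc, x_al, cfg)
    x_rbr <- rbr$x
    ev <- llgfold:::.loop_eval(lc, x_rbr, NULL, gradient = TRUE)
    g_pred <- (-ev$grad_coords) %*% compose_pose(rbr$pose, pose_k)$R
    d_plddt <- -ev$grad_b * llgfold:::.pseudo_b_dplddt(p$plddt)
    fx$predictor$pullback(profile, g_pred, d_plddt)
  }
  b0 <- fx$b_true * 0.6
  g <- grad_of_b(b0)
  set.seed(3)
  e <- 1e-5
  for (idx in sample(which(abs(g) > 0.1 * max(abs(g))), 4)) {
    bp <- b0; bp[idx] <- bp[idx] + e
    bm <- b0; bm[idx] <- bm[idx] - e
    fd <- (loss_of_b(bp) - loss_of_b(bm)) / (2 * e)
    expect_equal(g[idx], fd, tolerance = 1e-3)
  }
})

test_that("a dominating restraint pins the prediction to the reference", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 1, omega_l2_phase1 = 1e6,
                           n_iter_phase1 = 3, rbr_steps = 0)
  rd1 <- llgfold:::.phase_data(fx$rd, cfg$phase1_dmin)
  st <- llgfold:::.init_state(fx$m0, cfg, phase = 1L)
  st$b <- fx$b_true * 0.5       # start away from the reference
  for (i in 1:3) st <- iterate_once(st, fx$predictor, rd1, cfg)
  h <- dplyr::bind_rows(st$history)
  # the restraint dominates the loss and is driven down monotonically
  expect_true(all(diff(h$l2) < 0))
  expect_gt(h$l2[1] * cfg$omega_l2_phase1, abs(h$llg[1]) * 10)
})

test_that("zero-iteration schedules return the unbiased prediction", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 1, n_iter_phase1 = 0, n_iter_phase2 = 0)
  fit <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg)
  expect_equal(fit$best$llg, fit$initial$llg)
  # unbiased prediction = base coordinates, Kabsch-aligned to the reference
  expect_lt(rmsd_after_superposition(fit$best$coords, fx$base), 1e-8)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$llg_gain, 0)
})

test_that("early stopping triggers within patience of an LLG plateau", {
  fx <- loop_fx()
  # constant predictor: LLG can never improve
  const_pred <- structure(list(
    n_res = nrow(fx$base),
    predict = function(profile) list(coords = fx$base,
                                     plddt = rep(90, nrow(fx$base))),
    pullback = function(profile, d_coords, d_plddt = NULL) {
      array(0, dim(profile))
    }
  ), class = "fold_predictor")
  cfg <- refinement_config(seed = 1, n_iter_phase1 = 0, n_iter_phase2 = 400,
                           early_stop_patience = 6, rbr_steps = 0)
  fit <- run_refinement(fx$m0, const_pred, fx$rd, cfg)
  h2 <- fit$history[fit$history$phase == 2, ]
  expect_lte(nrow(h2), 6 + 1)
})

test_that("phase-1 trace selection takes the best LLG with stable ties", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 4, n_iter_phase1 = 3, n_traces = 3,
                           n_iter_phase2 = 2)
  fit <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg)
  per_trace <- vapply(fit$phase1_traces, function(t) t$best_llg, 0)
  expect_equal(fit$selected_trace, which.max(per_trace))
  expect_true(all(per_trace[fit$selected_trace] >= per_trace))
  h <- tidy(fit)
  expect_setequal(unique(h$trace[h$phase == 1]), 1:3)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("identical seeds give bitwise-identical LLG histories", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 11, n_iter_phase1 = 4, n_traces = 2,
                           n_iter_phase2 = 5)
  f1 <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg)
  f2 <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg)
  expect_identical(f1$history$llg, f2$history$llg)
  expect_identical(f1$best$w, f2$best$w)
  cfg2 <- refinement_config(seed = 12, n_iter_phase1 = 4, n_traces = 2,
                            n_iter_phase2 = 5)
  f3 <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg2)
  expect_false(identical(f1$history$llg, f3$history$llg))
})

test_that("subsampled profiles are ranked by experimental likelihood", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 1, rbr_steps = 2)
  # identical profiles: identical scores, stable order
  same <- list(a = fx$m0, b = fx$m0, c = fx$m0)
  r0 <- rank_subsampled_profiles(same, fx$predictor, fx$rd, config = cfg)
  expect_equal(length(unique(r0$llg)), 1)
  expect_identical(r0$id, c("a", "b", "c"))
  # two-state construction: the profile encoding the observed state wins
  biased <- apply_bias(fx$m0, array(1, dim(fx$m0)), fx$b_true)
  wrong <- apply_bias(fx$m0, array(1, dim(fx$m0)), -fx$b_true)
  r <- rank_subsampled_profiles(list(truth_like = biased, inverted = wrong),
                                fx$predictor, fx$rd, m0 = fx$m0,
                                config = cfg)
  expect_equal(r$id[1], "truth_like")
  expect_true("full" %in% r$id)
  expect_true(all(diff(r$llg) <= 0))
  # scores match an independent single-shot evaluation
  pred <- fx$predictor$predict(biased)
  pose_k <- weighted_kabsch(pred$coords, fx$rd$x_ref,
                            pseudo_b_to_weight(fx$rd$pseudo_b_ref))
  x_al <- apply_pose(pred$coords, pose_k)
  lc <- llgfold:::.loop_context(fx$rd, plddt_to_pseudo_b(pred$plddt))
  rbr <- llgfold:::.pose_sigma_alternate(lc, x_al, cfg)
  ref_llg <- llgfold:::.loop_eval(lc, rbr$x, NULL, gradient = FALSE)$value
  expect_equal(r$llg[r$id == "truth_like"], ref_llg, tolerance = 1e-9)
})

test_that("a short schedule already moves the model toward the truth", {
  fx <- loop_fx()
  cfg <- refinement_config(seed = 2, n_iter_phase1 = 25, n_traces = 1,
                           n_iter_phase2 = 25)
  fit <- run_refinement(fx$m0, fx$predictor, fx$rd, cfg)
  expect_gt(fit$best$llg, fit$initial$llg)
  rmsd_final <- rmsd_after_superposition(fit$best$coords, fx$truth$coords)
  expect_lt(rmsd_final, fx$rmsd_initial)
  g <- glance(fit)
  expect_equal(g$llg_final - g$llg_initial, g$llg_gain)
  expect_true(all(c("r_work", "r_free", "rmsd_ref") %in% names(tidy(fit))))
})
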