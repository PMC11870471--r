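# Inference-time refinement loop: optimize a linear bias (scales w, offsets
# b) on the MSA cluster profile so that the predictor's output maximizes the
# experimental log-likelihood gain. Each iteration: bias -> predict ->
# pseudo-B from confidence -> confidence-weighted Kabsch alignment to the
# reference -> rigid-body refinement -> per-bin sigmaA -> loss
# (-LLG + omega_L2 * weighted L2) -> analytic backward pass -> AdamW step.
# Two phases: an adventurous multi-trace phase at reduced resolution with
# the L2 restraint active, then a fine-tuning phase at full resolution.

#' Apply a linear bias to an MSA cluster profile
#'
#' Elementwise `w * m0 + b`, without renormalization (the predictor consumes
#' the biased profile as-is).
#'
#' @param m0 Profile array `[clusters x residues x 23]`.
#' @param w,b Bias arrays of the same shape.
#' @return The biased profile.
#' @export
apply_bias <- function(m0, w, b) {
  if (!identical(dim(m0), dim(w)) || !identical(dim(m0), dim(b))) {
    stop("bias shapes do not match the profile")
  }
  w * m0 + b
}

#' Confidence-weighted positional restraint
#'
#' Weighted sum of squared C-alpha distances
#' \eqn{\sum_i w_i \|x_i - x^{ref}_i\|^2} between aligned and reference
#' coordinates (Angstrom^2). Note the value scales with chain length.
#'
#' @param x_aligned,x_ref n x 3 coordinate matrices.
#' @param weights Per-residue weights (see [pseudo_b_to_weight()]).
#' @return Scalar restraint value.
#' @export
l2_restraint <- function(x_aligned, x_ref, weights = NULL) {
  x_aligned <- as.matrix(x_aligned); x_ref <- as.matrix(x_ref)
  if (nrow(x_aligned) != nrow(x_ref)) stop("coordinate lengths differ")
  if (is.null(weights)) weights <- rep(1, nrow(x_ref))
  sum(weights * rowSums((x_aligned - x_ref)^2))
}

#' Refinement configuration
#'
#' Defaults follow the two-phase schedule: phase 1 runs `n_traces`
#' independent traces of `n_iter` iterations with learning rates
#' `lr_mul = 1.0` / `lr_add = 0.05`, restraint weight `omega_l2 = 1e-11`
#' and a low-resolution cutoff of 3 Angstrom; phase 2 fine-tunes for up to
#' 500 iterations at full resolution with both learning rates `1e-3`, no
#' restraint, and early stopping when the LLG fails to improve by more than
#' `early_stop_delta = 0.1` for `early_stop_patience = 50` consecutive
#' iterations.
#'
#' @param n_iter_phase1,n_traces,lr_mul_phase1,lr_add_phase1,omega_l2_phase1
#'   Phase-1 settings.
#' @param phase1_dmin Low-resolution cutoff (Angstrom) for phase 1.
#' @param n_iter_phase2,lr_phase2,omega_l2_phase2 Phase-2 settings.
#' @param early_stop_delta,early_stop_patience Early-stop rule.
#' @param rbr_steps Optimizer iterations of rigid-body refinement per loop
#'   iteration.
#' @param rbr_tol Convergence tolerance of the rigid-body optimizer (tight
#'   values make the backward pass's pose-stationarity assumption sharper).
#' @param rbr_rounds Rounds of alternation between sigmaA estimation and
#'   rigid-body refinement per iteration. One round (the default) leaves a
#'   small first-order residual in the detached-pose backward pass that
#'   the optimizer tolerates; raise it when exact joint stationarity
#'   matters (e.g. gradient checks).
#' @param trace_init_sd Std-dev of the additive-bias perturbation that
#'   differentiates phase-1 traces (trace 1 starts unperturbed).
#' @param betas,eps,weight_decay AdamW internals (decoupled weight decay
#'   defaults to 0: the multiplicative bias is centered on 1, so decay
#'   toward 0 would be a systematic pull away from the identity).
#' @param seed Master seed; per-trace seeds are derived by fixed offsets.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(n_iter_phase1 = 100, n_traces = 3,
                              lr_mul_phase1 = 1.0, lr_add_phase1 = 0.05,
                              omega_l2_phase1 = 1e-11, phase1_dmin = 3.0,
                              n_iter_phase2 = 500, lr_phase2 = 1e-3,
                              omega_l2_phase2 = 0,
                              early_stop_delta = 0.1,
                              early_stop_patience = 50,
                              rbr_steps = 3, rbr_tol = 1e-8, rbr_rounds = 1,
                              trace_init_sd = 0.01,
                              betas = c(0.9, 0.999), eps = 1e-8,
                              weight_decay = 0, seed = 1) {
  structure(as.list(environment()), class = "refinement_config")
}

#' Bundle experimental data with the aligned reference model
#'
#' @param data A prepared `reflections` tibble (crystallographic) or
#'   `map_terms` tibble (cryo-EM).
#' @param x_ref n x 3 reference C-alpha coordinates (the approximately
#'   posed model the predictions are aligned to).
#' @param plddt_ref Per-residue confidence of the reference; used to derive
#'   the reference pseudo-B and alignment weights. Defaults to 90.
#' @param pseudo_b_ref Optional explicit reference pseudo-B, overriding
#'   `plddt_ref`.
#' @return A `refinement_data` list with fields `type` (`"xtal"` or
#'   `"cryoem"`), `data`, `x_ref`, `pseudo_b_ref`, `weights_ref`.
#' @export
refinement_data <- function(data, x_ref, plddt_ref = NULL,
                            pseudo_b_ref = NULL) {
  x_ref <- as.matrix(x_ref)
  type <- if (inherits(data, "map_terms")) "cryoem" else "xtal"
  if (is.null(pseudo_b_ref)) {
    if (is.null(plddt_ref)) plddt_ref <- rep(90, nrow(x_ref))
    pseudo_b_ref <- plddt_to_pseudo_b(plddt_ref)
  }
  structure(list(type = type, data = data, x_ref = x_ref,
                 pseudo_b_ref = pseudo_b_ref,
                 weights_ref = pseudo_b_to_weight(pseudo_b_ref)),
            class = "refinement_data")
}

# resolution-limited view of the experimental data for phase 1
.phase_data <- function(rd, dmin) {
  if (is.null(dmin)) return(rd)
  d <- rd$data
  sub <- d[d$d >= dmin, ]
  for (a in c("symmetry", "cell", "dims", "bin_stats")) {
    attr(sub, a) <- attr(d, a)
  }
  class(sub) <- class(d)
  if (rd$type == "xtal") {
    sub <- make_bins(sub, max(table(sub$bin)))
    # rescale Ee within the new bins so <Ee^2> stays 1
    sc <- tapply(sub$ee^2, sub$bin, mean)
    sub$ee <- sub$ee / sqrt(as.numeric(sc[as.character(sub$bin)]))
  } else {
    nb <- max(1L, length(unique(sub$bin)))
    sub$bin <- rep(seq_len(nb), each = ceiling(nrow(sub) / nb))[
      order(order(sub$s))]
    sc <- tapply(sub$ee^2, sub$bin, mean)
    sub$ee <- sub$ee / sqrt(as.numeric(sc[as.character(sub$bin)]))
  }
  out <- rd
  out$data <- sub
  out
}

# target closure at fixed sigmaA over a shared per-iteration context
.make_target <- function(lc, sigma_a) {
  force(lc); force(sigma_a)
  function(coords) .loop_eval(lc, coords, sigma_a)
}

# Alternate per-bin sigmaA estimation with rigid-body refinement until the
# pose stops moving, so the final pose is stationary under the final
# sigmaA (which makes the detached-pose backward pass exact to first
# order). Converges in 2-3 rounds in practice.
.pose_sigma_alternate <- function(lc, x_start, config,
                                  max_rounds = config$rbr_rounds) {
  x <- x_start
  pose_acc <- pose()
  if (config$rbr_steps > 0) {
    for (round in seq_len(max_rounds)) {
      sA <- .loop_eval(lc, x, sigma_a = NULL, gradient = FALSE)$sigma_a
      p_new <- rigid_body_refine(x, .make_target(lc, sA),
                                 steps = config$rbr_steps,
                                 tol = config$rbr_tol)
      x <- apply_pose(x, p_new)
      pose_acc <- compose_pose(p_new, pose_acc)
      if (rotation_angle(p_new$R) < 1e-6 &&
          sqrt(sum(p_new$t^2)) < 1e-6) break
    }
  }
  list(pose = pose_acc, x = x)
}

.adamw_step <- function(par, grad, state, lr, betas, eps, weight_decay, t) {
  state$m <- betas[1] * state$m + (1 - betas[1]) * grad
  state$v <- betas[2] * state$v + (1 - betas[2]) * grad^2
  mhat <- state$m / (1 - betas[1]^t)
  vhat <- state$v / (1 - betas[2]^t)
  par <- par - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * par)
  list(par = par, state = state)
}

# initialize the per-trace optimization state
.init_state <- function(m0, config, phase, trace = 1L) {
  z <- array(0, dim = dim(m0))
  b <- z
  if (phase == 1L && trace > 1L && config$trace_init_sd > 0) {
    b <- .with_seed(config$seed + trace - 1L,
                    array(stats::rnorm(length(m0), 0, config$trace_init_sd),
                          dim = dim(m0)))
  }
  list(w = array(1, dim = dim(m0)), b = b,
       adam_w = list(m = z, v = z), adam_b = list(m = z, v = z),
       t = 0L, m0 = m0, phase = phase, trace = trace,
       history = list(), best_llg = -Inf, best = NULL)
}

#' One refinement iteration
#'
#' Runs a single bias -> predict -> align -> rigid-body -> sigmaA -> loss ->
#' backward -> optimizer step cycle and appends to the state's history.
#' Exposed mainly for inspection and testing; [run_refinement()] drives it.
#'
#' @param state Optimization state from the internal initializer (or a
#'   previous call).
#' @param predictor A predictor contract (e.g. [toy_predictor()]).
#' @param rd A [refinement_data()] (already resolution-limited for the
#'   current phase).
#' @param config A [refinement_config()].
#' @param update Apply the optimizer update (set `FALSE` to only evaluate).
#' @return The updated state. The appended history row carries the work-set
#'   LLG, restraint value, loss and diagnostic R factors.
#' @export
iterate_once <- function(state, predictor, rd, config, update = TRUE) {
  profile <- apply_bias(state$m0, state$w, state$b)
  pred <- predictor$predict(profile)
  pseudo_b <- plddt_to_pseudo_b(pred$plddt)

  pose_k <- weighted_kabsch(pred$coords, rd$x_ref,
                            pseudo_b_to_weight(rd$pseudo_b_ref))
  x_al <- apply_pose(pred$coords, pose_k)

  lc <- .loop_context(rd, pseudo_b)
  lc$warm$sigma_a <- state$sigma_warm
  rbr <- .pose_sigma_alternate(lc, x_al, config)
  pose_r <- rbr$pose
  x_rbr <- rbr$x
  # at the joint pose/sigmaA stationary point; gradients at that sigmaA
  ev <- .loop_eval(lc, x_rbr, sigma_a = NULL, gradient = TRUE)
  omega <- if (state$phase == 1L) config$omega_l2_phase1 else config$omega_l2_phase2
  l2 <- l2_restraint(x_rbr, rd$x_ref, rd$weights_ref)
  loss <- -ev$value + omega * l2
  if (!is.finite(loss)) stop("non-finite loss at iteration ", state$t + 1L)

  # backward: detach the poses (Kabsch is the exact minimizer of the
  # weighted alignment residual; the rigid-body pose is stationary for the
  # LLG at convergence), so dL/dx_pred = R_total^T dL/dx_rbr
  g_rbr <- -ev$grad_coords +
    omega * 2 * rd$weights_ref * (x_rbr - rd$x_ref)
  R_tot <- compose_pose(pose_r, pose_k)$R
  g_pred <- g_rbr %*% R_tot
  d_plddt <- -ev$grad_b * .pseudo_b_dplddt(pred$plddt)
  d_profile <- predictor$pullback(profile, g_pred, d_plddt)

  t_new <- state$t + 1L
  if (update) {
    lr_w <- if (state$phase == 1L) config$lr_mul_phase1 else config$lr_phase2
    lr_b <- if (state$phase == 1L) config$lr_add_phase1 else config$lr_phase2
    up_w <- .adamw_step(state$w, d_profile * state$m0, state$adam_w, lr_w,
                        config$betas, config$eps, config$weight_decay, t_new)
    up_b <- .adamw_step(state$b, d_profile, state$adam_b, lr_b,
                        config$betas, config$eps, config$weight_decay, t_new)
    state$w <- up_w$par; state$adam_w <- up_w$state
    state$b <- up_b$par; state$adam_b <- up_b$state
  }
  state$t <- t_new
  state$sigma_warm <- ev$sigma_a

  rfac <- if (rd$type == "xtal") {
    .r_factors_fast(rd$data, Mod(ev$fc))
  } else c(r_work = NA_real_, r_free = NA_real_)

  row <- tibble::new_tibble(list(
    trace = state$trace, phase = state$phase, iter = state$t,
    llg = ev$value, l2 = l2, loss = loss,
    r_work = unname(rfac["r_work"]), r_free = unname(rfac["r_free"]),
    rmsd_ref = sqrt(mean(rowSums((x_rbr - rd$x_ref)^2)))
  ), nrow = 1L)
  state$history[[length(state$history) + 1L]] <- row
  if (ev$value > state$best_llg) {
    state$best_llg <- ev$value
    state$best <- list(w = state$w, b = state$b, coords = x_rbr,
                       plddt = pred$plddt, pseudo_b = pseudo_b,
                       sigma_a = .sigma_tibble(lc$prep, ev$sigma_a),
                       pose = compose_pose(pose_r, pose_k),
                       llg = ev$value)
  }
  state
}

#' Run the full two-phase refinement
#'
#' Phase 1 runs `n_traces` independent traces at the phase-1 resolution
#' cutoff with the weighted L2 restraint active; the trace with the best
#' work-set LLG (ties: lowest trace index) seeds phase 2, which runs at
#' full resolution without the restraint until the iteration budget or the
#' early-stop rule is reached. Fully reproducible given `config$seed`.
#'
#' @param m0 Starting MSA cluster profile `[clusters x residues x 23]`.
#' @param predictor A predictor contract (see [toy_predictor()]).
#' @param rd A [refinement_data()].
#' @param config A [refinement_config()].
#' @return A `fold_refinement` object: list with `history` (per-iteration
#'   tibble across traces and phases), `best` (bias, coordinates, sigmaA,
#'   pose at the best phase-2 LLG), `initial` (the unbiased prediction and
#'   its LLG at full resolution), `config`, and `type`.
#' @export
run_refinement <- function(m0, predictor, rd, config = refinement_config()) {
  rd1 <- .phase_data(rd, config$phase1_dmin)

  # reference evaluation: unbiased prediction at full resolution
  st0 <- .init_state(m0, config, phase = 2L)
  st0 <- iterate_once(st0, predictor, rd, config, update = FALSE)
  initial <- st0$best
  initial$llg <- st0$best_llg

  traces <- list()
  best_k <- NA_integer_
  if (config$n_iter_phase1 > 0 && config$n_traces > 0) {
    for (k in seq_len(config$n_traces)) {
      st <- .init_state(m0, config, phase = 1L, trace = k)
      for (i in seq_len(config$n_iter_phase1)) {
        st <- iterate_once(st, predictor, rd1, config)
      }
      traces[[k]] <- st
    }
    best_k <- which.max(vapply(traces, function(s) s$best_llg, 0))
    seed_state <- traces[[best_k]]
  } else {
    seed_state <- .init_state(m0, config, phase = 1L)
  }

  st2 <- .init_state(m0, config, phase = 2L)
  if (!is.null(seed_state$best)) {
    st2$w <- seed_state$best$w
    st2$b <- seed_state$best$b
  }
  stall <- 0L
  if (config$n_iter_phase2 > 0) {
    for (i in seq_len(config$n_iter_phase2)) {
      prev_best <- st2$best_llg
      st2 <- iterate_once(st2, predictor, rd, config)
      gain <- st2$best_llg - prev_best
      stall <- if (is.finite(prev_best) && gain <= config$early_stop_delta)
        stall + 1L else 0L
      if (stall >= config$early_stop_patience) break
    }
  } else {
    st2 <- iterate_once(st2, predictor, rd, config, update = FALSE)
  }

  history <- dplyr::bind_rows(c(
    purrr::map(traces, function(s) dplyr::bind_rows(s$history)),
    list(dplyr::bind_rows(st2$history))
  ))
  structure(list(
    history = history, best = st2$best, initial = initial,
    phase1_traces = purrr::map(traces, function(s)
      list(best_llg = s$best_llg, w = s$best$w, b = s$best$b)),
    selected_trace = best_k,
    config = config, type = rd$type
  ), class = "fold_refinement")
}

#' @export
print.fold_refinement <- function(x, ...) {
  cat("<fold_refinement> ", x$type, " target\n",
      "  initial LLG ", signif(x$initial$llg, 6),
      " -> best LLG ", signif(x$best$llg, 6), "\n",
      "  iterations: ", nrow(x$history), " (",
      length(x$phase1_traces), " phase-1 traces)\n", sep = "")
  invisible(x)
}

#' Rank MSA profiles by experimental likelihood
#'
#' Scores each candidate profile by a single prediction -> weighted Kabsch
#' -> rigid-body refinement -> sigmaA -> work-set LLG pass and returns the
#' candidates sorted by decreasing LLG (stable for ties). Supply the
#' full-MSA profile via `m0` to guarantee it is always ranked alongside the
#' subsamples.
#'
#' @param profiles List of profile arrays.
#' @param predictor A predictor contract.
#' @param rd A [refinement_data()].
#' @param m0 Optional full-MSA profile, prepended as entry `"full"`.
#' @param config A [refinement_config()] (for `rbr_steps`).
#' @return Tibble with `id`, `llg`, `rmsd_ref`, sorted by decreasing `llg`.
#' @export
rank_subsampled_profiles <- function(profiles, predictor, rd, m0 = NULL,
                                     config = refinement_config()) {
  stopifnot(length(profiles) >= 1 || !is.null(m0))
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("subsample_", seq_along(profiles))
  if (!is.null(m0)) {
    profiles <- c(list(m0), profiles)
    ids <- c("full", ids)
  }
  rows <- purrr::map_dfr(seq_along(profiles), function(i) {
    pred <- predictor$predict(profiles[[i]])
    pseudo_b <- plddt_to_pseudo_b(pred$plddt)
    pose_k <- weighted_kabsch(pred$coords, rd$x_ref,
                              pseudo_b_to_weight(rd$pseudo_b_ref))
    x_al <- apply_pose(pred$coords, pose_k)
    lc <- .loop_context(rd, pseudo_b)
    rbr <- .pose_sigma_alternate(lc, x_al, config)
    x_rbr <- rbr$x
    ev <- .loop_eval(lc, x_rbr, sigma_a = NULL, gradient = FALSE)
    tibble::tibble(id = ids[i], llg = ev$value,
                   rmsd_ref = sqrt(mean(rowSums((x_rbr - rd$x_ref)^2))))
  })
  rows[order(-rows$llg, seq_len(nrow(rows))), ]
}
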