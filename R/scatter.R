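# Differentiable structure factors by direct summation over atoms and
# symmetry operators. Each forward computation carries a "pullback" closure
# that maps the adjoint of a scalar loss with respect to the complex
# coefficients (Wirtinger convention, W = dL/dRe(F) + i dL/dIm(F)) to exact
# gradients with respect to coordinates and isotropic B values.

#' Structure factors of an atomic model
#'
#' Direct summation
#' \eqn{F(h) = \sum_{ops} \sum_{atoms} occ \, f(s) \, e^{-B s^2/4}
#' e^{2\pi i h \cdot x}} over the symmetry copies of the model. Hydrogens are
#' skipped by default, following the usual X-ray convention.
#'
#' @param model An [atomic_model()].
#' @param sym A [crystal_symmetry()].
#' @param hkl Data frame (or matrix) with columns `h`, `k`, `l`; a
#'   reflections tibble works directly.
#' @param include_h Include hydrogen atoms.
#' @return A tibble of class `structure_factors` with columns `h`, `k`, `l`,
#'   `s` (1/d), `fc` (complex), `f_calc` (amplitude) and `phi_calc`
#'   (radians), carrying a `pullback` attribute: a
#'   `function(W)` returning `list(coords = n_atoms x 3, b_iso = n_atoms)`
#'   gradients of the scalar whose adjoint is `W`.
#' @export
compute_structure_factors <- function(model, sym, hkl, include_h = FALSE) {
  ctx <- .sf_context(model, sym, hkl, include_h)
  ev <- .sf_eval(ctx, model_coords(model))
  out <- tibble::new_tibble(list(
    h = as.integer(ctx$H[, 1]), k = as.integer(ctx$H[, 2]),
    l = as.integer(ctx$H[, 3]),
    s = ctx$s, fc = ev$fc, f_calc = Mod(ev$fc), phi_calc = Arg(ev$fc)
  ), nrow = nrow(ctx$H),
  class = "structure_factors")
  attr(out, "pullback") <- ev$pullback
  out
}

# Precompute everything that does not depend on coordinates: symmetry
# images of the index set, phase shifts, and the per-reflection x per-atom
# amplitude envelope (form factor, Debye-Waller, occupancy). Reused across
# the many evaluations inside one refinement iteration, where B values and
# the index set are fixed and only coordinates move.
.sf_context <- function(model, sym, hkl, include_h = FALSE) {
  H <- .as_hkl_matrix(hkl)
  keep <- rep(TRUE, nrow(model))
  if (!include_h) keep <- model$element != "H"
  m <- model[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("model has no scattering atoms")
  s <- 1 / d_spacing(H, sym)
  s2_4 <- s^2 / 4
  fmat <- matrix(0, nrow(H), nrow(m))
  for (e in unique(m$element)) {
    fmat[, m$element == e] <- form_factor(e, s)
  }
  C <- fmat * exp(-outer(s2_4, m$b_iso)) *
    matrix(m$occ, nrow(H), nrow(m), byrow = TRUE)
  ops <- sym$ops
  Hops <- lapply(ops, function(o) H %*% o$R)
  shift_phase <- lapply(ops, function(o) 2 * pi * as.vector(H %*% o$t))
  list(H = H, s = s, s2_4 = s2_4, C = C, Hops = Hops,
       shift_phase = shift_phase,
       M_inv = sym$M_inv, idx = which(keep), n_all = nrow(model),
       n_at = nrow(m))
}

# Forward structure factors + pullback closure for one coordinate set.
# All-real arithmetic: the symmetry translation phase is folded into the
# per-atom phase matrix, so only cos/sin matrices are formed.
.sf_eval <- function(ctx, coords) {
  X <- as.matrix(coords)[ctx$idx, , drop = FALSE]
  frac_t <- ctx$M_inv %*% t(X)              # 3 x n_at
  n_ops <- length(ctx$Hops)
  CR <- vector("list", n_ops)
  CI <- vector("list", n_ops)
  one <- rep(1, ctx$n_at)
  f_re <- numeric(nrow(ctx$H)); f_im <- numeric(nrow(ctx$H))
  for (k in seq_len(n_ops)) {
    ph <- (2 * pi) * (ctx$Hops[[k]] %*% frac_t) + ctx$shift_phase[[k]]
    cr <- ctx$C * cos(ph)
    ci <- ctx$C * sin(ph)
    CR[[k]] <- cr; CI[[k]] <- ci
    f_re <- f_re + as.vector(cr %*% one)
    f_im <- f_im + as.vector(ci %*% one)
  }
  pullback <- function(W) {
    wr <- Re(W); wi <- Im(W)
    dfrac <- matrix(0, ctx$n_at, 3)
    db <- numeric(ctx$n_at)
    for (k in seq_len(n_ops)) {
      imA <- wr * CI[[k]] - wi * CR[[k]]   # Im(conj(W) * contrib)
      reA <- wr * CR[[k]] + wi * CI[[k]]
      dfrac <- dfrac - 2 * pi * crossprod(imA, ctx$Hops[[k]])
      db <- db + colSums(reA * (-ctx$s2_4))
    }
    dX <- matrix(0, ctx$n_all, 3)
    dX[ctx$idx, ] <- dfrac %*% ctx$M_inv
    dB <- numeric(ctx$n_all)
    dB[ctx$idx] <- db
    list(coords = dX, b_iso = dB)
  }
  list(fc = complex(real = f_re, imaginary = f_im), pullback = pullback)
}

#' Add a fixed partial structure contribution
#'
#' Complex per-reflection sum of a refinable and a fixed set of structure
#' factors (for example a second chain held rigid). Gradients flow only
#' through the first argument.
#'
#' @param sf,sf_fixed `structure_factors` tibbles on identical index sets.
#' @return A `structure_factors` tibble for the sum.
#' @export
add_fixed_partial <- function(sf, sf_fixed) {
  if (nrow(sf) != nrow(sf_fixed) ||
      any(sf$h != sf_fixed$h | sf$k != sf_fixed$k | sf$l != sf_fixed$l)) {
    stop("hkl sets of the two structure-factor sets do not match")
  }
  out <- sf
  out$fc <- sf$fc + sf_fixed$fc
  out$f_calc <- Mod(out$fc)
  out$phi_calc <- Arg(out$fc)
  attr(out, "pullback") <- attr(sf, "pullback")
  out
}

#' Normalize calculated amplitudes to E values
#'
#' \eqn{E_C = |F_c| / \sqrt{\epsilon \Sigma_{bin}}} with
#' \eqn{\Sigma_{bin} = \langle |F_c|^2/\epsilon \rangle} taken over each
#' resolution bin, so that the per-bin mean of \eqn{E_C^2} is exactly 1 on
#' the normalization set.
#'
#' @param sf A `structure_factors` tibble aligned row-for-row with `refl`.
#' @param refl A reflections tibble with `epsilon` and `bin` columns.
#' @return `sf` with an `e_calc` column and a `norm` attribute (per-bin
#'   `Sigma` and counts) used by the gradient chain.
#' @export
normalize_to_E <- function(sf, refl) {
  stopifnot(nrow(sf) == nrow(refl))
  if (!"bin" %in% names(refl) || anyNA(refl$bin)) stop("reflections lack bin assignment")
  eps <- refl$epsilon
  bin <- refl$bin
  ssq <- sf$f_calc^2 / eps
  Sigma <- tapply(ssq, bin, mean)
  nb <- tapply(ssq, bin, length)
  if (any(nb == 0)) stop("empty resolution bin in normalization")
  Sb <- as.numeric(Sigma[as.character(bin)])
  sf$e_calc <- sf$f_calc / sqrt(eps * Sb)
  attr(sf, "norm") <- list(Sigma = Sigma, n = nb, bin = bin, eps = eps)
  sf
}

# Backward through normalize_to_E: v = dL/d(e_calc) -> dL/d|F| -> complex
# adjoint W. Includes the dependence of the per-bin Sigma on every |F|.
.e_calc_pullback_W <- function(sf, v) {
  norm <- attr(sf, "norm")
  if (is.null(norm)) stop("structure factors are not normalized")
  bin <- norm$bin; eps <- norm$eps
  Sb <- as.numeric(norm$Sigma[as.character(bin)])
  nb <- as.numeric(norm$n[as.character(bin)])
  ve <- tapply(v * sf$e_calc, bin, sum)
  Svb <- as.numeric(ve[as.character(bin)])
  g <- v / sqrt(eps * Sb) - sf$f_calc / (nb * eps * Sb) * Svb
  phase <- ifelse(sf$f_calc > 0, sf$fc / sf$f_calc, 1 + 0i)
  g * phase
}

#' Scale calculated to observed amplitudes, with optional solvent term
#'
#' Fits an overall scale and a two-parameter Babinet bulk-solvent factor
#' \eqn{F_c (1 - k_{sol} e^{-B_{sol} s^2/4})} to the observed amplitudes on
#' the work set by least squares, then applies a per-bin residual scale.
#' Used for amplitude-based reporting (R factors); the likelihood targets use
#' normalized amplitudes and are scale-free.
#'
#' @param sf A `structure_factors` tibble aligned with `refl`.
#' @param refl Reflections with `f_obs`, `bin` and (optionally) `is_test`.
#' @param babinet Fit the Babinet solvent term (default) or scale only.
#' @return `sf` with an `f_scaled` column and a `scaling` attribute
#'   (`k_overall`, `k_sol`, `b_sol`, per-bin scales).
#' @export
solvent_and_scale <- function(sf, refl, babinet = TRUE) {
  stopifnot(nrow(sf) == nrow(refl))
  if (!"f_obs" %in% names(refl)) stop("reflections lack f_obs (run effective_amplitudes)")
  work <- if ("is_test" %in% names(refl)) !refl$is_test else rep(TRUE, nrow(refl))
  fo <- refl$f_obs; fc <- sf$f_calc; s2_4 <- sf$s^2 / 4
  k0 <- sum(fo[work] * fc[work]) / sum(fc[work]^2)
  if (babinet) {
    obj <- function(p) {
      k <- exp(p[1]); ks <- p[2]; bs <- exp(p[3])
      pred <- k * fc[work] * pmax(1 - ks * exp(-bs * s2_4[work]), 1e-6)
      sum((fo[work] - pred)^2)
    }
    fit <- stats::optim(c(log(k0), 0.2, log(50)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    k_overall <- exp(fit$par[1]); k_sol <- fit$par[2]; b_sol <- exp(fit$par[3])
  } else {
    k_overall <- k0; k_sol <- 0; b_sol <- 0
  }
  fmod <- k_overall * fc * pmax(1 - k_sol * exp(-b_sol * s2_4), 1e-6)
  # residual per-bin scale (conventional mean matching), fit on work set
  num <- tapply(fo[work], refl$bin[work], sum)
  den <- tapply(fmod[work], refl$bin[work], sum)
  kb <- num / pmax(den, .Machine$double.eps)
  kb_full <- as.numeric(kb[as.character(refl$bin)])
  kb_full[is.na(kb_full)] <- 1
  sf$f_scaled <- fmod * kb_full
  attr(sf, "scaling") <- list(k_overall = k_overall, k_sol = k_sol,
                              b_sol = b_sol, k_bin = kb)
  sf
}
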