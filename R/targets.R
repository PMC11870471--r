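# Internal fast paths for the refinement loop: tibble-free target
# evaluation built on the cached scattering context. One "prep" object per
# data set precomputes bin bookkeeping; each evaluation is then a handful
# of matrix products and vector reductions.

.bin_prep <- function(bin) {
  bin <- as.integer(bin)
  nb_tab <- tabulate(bin)
  list(bin = bin, nb = nb_tab[bin], n_bins = max(bin),
       counts = nb_tab)
}

.xtal_prep <- function(refl, use = "work") {
  keep <- .llg_use_mask(refl, use)
  bp <- .bin_prep(refl$bin)
  c(bp, list(ee = refl$ee, dobs = refl$dobs, centric = refl$centric,
             eps = refl$epsilon, keep = keep, d = refl$d))
}

# per-bin sigmaA by safeguarded Newton over the work subset, vectors only
.sigma_newton_vec <- function(prep, e_calc, init = NULL) {
  out <- numeric(prep$n_bins)
  if (is.null(init)) init <- rep(0.5, prep$n_bins)
  for (b in seq_len(prep$n_bins)) {
    i <- prep$keep & prep$bin == b
    derivs <- function(s) {
      .llgi_sigma_derivs(prep$ee[i], e_calc[i], prep$dobs[i],
                         rep(s, sum(i)), prep$centric[i])
    }
    out[b] <- .newton_sigma_a(derivs, init = init[b])
  }
  out
}

# normalize amplitudes to E within bins; returns e_calc plus the pieces the
# backward pass needs
.normalize_fast <- function(prep, famp) {
  ssq <- famp^2 / prep$eps
  Sigma <- as.vector(rowsum(ssq, prep$bin)) / prep$counts
  Sb <- Sigma[prep$bin]
  list(e_calc = famp / sqrt(prep$eps * Sb), Sb = Sb)
}

# full crystallographic target: value + gradients at coordinates X
# sigma_a: per-bin vector, or NULL to refine it here
.xtal_eval_fast <- function(ctx, prep, X, sigma_a = NULL,
                            gradient = TRUE, warm = new.env()) {
  ev <- .sf_eval(ctx, X)
  famp <- Mod(ev$fc)
  nf <- .normalize_fast(prep, famp)
  e_calc <- nf$e_calc
  if (is.null(sigma_a)) {
    sigma_a <- .sigma_newton_vec(prep, e_calc, init = warm$sigma_a)
    warm$sigma_a <- sigma_a
  }
  sA <- sigma_a[prep$bin]
  per <- numeric(length(famp))
  a <- !prep$centric
  per[a] <- llgi_acentric(prep$ee[a], e_calc[a], prep$dobs[a], sA[a])
  per[!a] <- llgi_centric(prep$ee[!a], e_calc[!a], prep$dobs[!a], sA[!a])
  value <- sum(per[prep$keep])
  if (!gradient) {
    return(list(value = value, sigma_a = sigma_a, e_calc = e_calc))
  }
  v <- .llgi_dec(prep$ee, e_calc, prep$dobs, sA, prep$centric)
  v[!prep$keep] <- 0
  Svb <- as.vector(rowsum(v * e_calc, prep$bin))[prep$bin]
  g <- v / sqrt(prep$eps * nf$Sb) - famp / (prep$nb * prep$eps * nf$Sb) * Svb
  phase <- ifelse(famp > 0, ev$fc / famp, 1 + 0i)
  gr <- ev$pullback(g * phase)
  list(value = value, grad_coords = gr$coords, grad_b = gr$b_iso,
       sigma_a = sigma_a, e_calc = e_calc, fc = ev$fc)
}

.cryoem_prep <- function(terms) {
  bp <- .bin_prep(terms$bin)
  c(bp, list(ee = terms$ee, dobs = terms$dobs, phi_obs = terms$phi_obs,
             eps = rep(1, nrow(terms)), keep = rep(TRUE, nrow(terms)),
             d = terms$d))
}

.sigma_newton_cryoem_vec <- function(prep, e_calc, dphi, init = NULL) {
  out <- numeric(prep$n_bins)
  if (is.null(init)) init <- rep(0.5, prep$n_bins)
  for (b in seq_len(prep$n_bins)) {
    i <- prep$bin == b
    a <- 2 * prep$ee[i] * e_calc[i] * cos(dphi[i])
    bb <- prep$ee[i]^2 + e_calc[i]^2
    dob <- prep$dobs[i]
    derivs <- function(sg) {
      x <- dob * sg
      g <- 1 / (1 - x^2)
      f1 <- a * g^2 * (1 + x^2) - bb * 2 * x * g^2 + 2 * x * g
      f2 <- a * 2 * x * g^3 * (3 + x^2) - bb * 2 * g^3 * (1 + 3 * x^2) +
        2 * g^2 * (1 + x^2)
      list(g1 = sum(f1 * dob), g2 = sum(f2 * dob^2))
    }
    out[b] <- .newton_sigma_a(derivs, init = init[b])
  }
  out
}

.cryoem_eval_fast <- function(ctx, prep, X, sigma_a = NULL,
                              gradient = TRUE, warm = new.env()) {
  ev <- .sf_eval(ctx, X)
  famp <- Mod(ev$fc)
  nf <- .normalize_fast(prep, famp)
  e_calc <- nf$e_calc
  phi_calc <- Arg(ev$fc)
  dphi <- phi_calc - prep$phi_obs
  if (is.null(sigma_a)) {
    sigma_a <- .sigma_newton_cryoem_vec(prep, e_calc, dphi,
                                        init = warm$sigma_a)
    warm$sigma_a <- sigma_a
  }
  x <- prep$dobs * sigma_a[prep$bin]
  .check_degenerate(x)
  g <- 1 / (1 - x^2)
  value <- sum(2 * x * prep$ee * e_calc * cos(dphi) * g -
                 x^2 * (prep$ee^2 + e_calc^2) * g - log1p(-x^2))
  if (!gradient) {
    return(list(value = value, sigma_a = sigma_a, e_calc = e_calc))
  }
  v_amp <- 2 * x * prep$ee * cos(dphi) * g - 2 * x^2 * e_calc * g
  v_phi <- -2 * x * prep$ee * e_calc * sin(dphi) * g
  Svb <- as.vector(rowsum(v_amp * e_calc, prep$bin))[prep$bin]
  gamp <- v_amp / sqrt(nf$Sb) - famp / (prep$nb * nf$Sb) * Svb
  phase <- ifelse(famp > 0, ev$fc / famp, 1 + 0i)
  W <- gamp * phase + v_phi * 1i * phase / pmax(famp, 1e-300)
  gr <- ev$pullback(W)
  list(value = value, grad_coords = gr$coords, grad_b = gr$b_iso,
       sigma_a = sigma_a, e_calc = e_calc, fc = ev$fc)
}

# shared context/prep builder for one refinement iteration (B values fixed)
.loop_context <- function(rd, pseudo_b) {
  n <- nrow(rd$x_ref)
  model <- tibble::new_tibble(
    list(element = rep("C", n), occ = rep(1, n), b_iso = pseudo_b,
         x = rd$x_ref[, 1], y = rd$x_ref[, 2], z = rd$x_ref[, 3]),
    nrow = n)
  if (rd$type == "xtal") {
    sym <- reflection_symmetry(rd$data)
    list(type = "xtal", ctx = .sf_context(model, sym, rd$data),
         prep = .xtal_prep(rd$data), warm = new.env())
  } else {
    cell <- attr(rd$data, "cell")
    sym <- crystal_symmetry(c(cell, 90, 90, 90), "P1")
    list(type = "cryoem", ctx = .sf_context(model, sym, rd$data),
         prep = .cryoem_prep(rd$data), warm = new.env())
  }
}

.loop_eval <- function(lc, X, sigma_a = NULL, gradient = TRUE) {
  if (lc$type == "xtal") {
    .xtal_eval_fast(lc$ctx, lc$prep, X, sigma_a, gradient, warm = lc$warm)
  } else {
    .cryoem_eval_fast(lc$ctx, lc$prep, X, sigma_a, gradient, warm = lc$warm)
  }
}

# fast R factors given amplitudes from a loop evaluation
.r_factors_fast <- function(refl, famp) {
  fo <- refl$f_obs
  test <- if ("is_test" %in% names(refl)) refl$is_test else rep(FALSE, nrow(refl))
  work <- !test
  num <- rowsum(fo[work], refl$bin[work])
  den <- rowsum(famp[work], refl$bin[work])
  kb <- as.vector(num / pmax(den, .Machine$double.eps))
  names(kb) <- rownames(num)
  fsc <- famp * kb[as.character(refl$bin)]
  rfac <- function(i) if (any(i)) sum(abs(fo[i] - fsc[i])) / sum(fo[i]) else NA_real_
  c(r_work = rfac(work), r_free = rfac(test))
}

.sigma_tibble <- function(prep, sigma_a) {
  out <- tibble::new_tibble(list(
    bin = seq_len(prep$n_bins),
    n = prep$counts,
    d_min = as.numeric(tapply(prep$d, prep$bin, min)),
    d_max = as.numeric(tapply(prep$d, prep$bin, max)),
    sigma_a = sigma_a
  ), nrow = prep$n_bins, class = "sigma_a_bins")
  out
}
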