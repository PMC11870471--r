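# Reflection data as a tibble: one row per unique reflection in the
# reciprocal asymmetric unit, with observed intensities, derived statistics
# (centricity, epsilon, resolution bins, effective normalized amplitudes Ee
# with error factors Dobs) and the work/test split.

#' Build a reflections tibble
#'
#' Attaches crystal symmetry, maps indices to the canonical asymmetric unit
#' (merging symmetry duplicates by their precision-weighted mean), removes
#' systematic absences, and computes resolution, centricity and epsilon.
#'
#' @param df Data frame with columns `h`, `k`, `l`, `i_obs`, `sig_i`.
#' @param sym A [crystal_symmetry()].
#' @return A tibble of class `reflections` with columns `h`, `k`, `l`, `d`,
#'   `centric`, `epsilon`, `i_obs`, `sig_i` and a `symmetry` attribute.
#' @export
as_reflections <- function(df, sym) {
  need <- c("h", "k", "l", "i_obs", "sig_i")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  H <- map_to_asu(df[, c("h", "k", "l")], sym)
  out <- tibble::tibble(h = H[, 1], k = H[, 2], l = H[, 3],
                        i_obs = df$i_obs, sig_i = df$sig_i)
  out <- out[!(out$h == 0 & out$k == 0 & out$l == 0), ]
  out <- out[!is_absent(out, sym), ]
  # merge symmetry duplicates (inverse-variance weighting)
  key <- paste(out$h, out$k, out$l)
  if (anyDuplicated(key)) {
    w <- 1 / pmax(out$sig_i, 1e-12)^2
    sp <- split(seq_len(nrow(out)), key)
    rows <- vapply(sp, function(i) i[1], integer(1))
    i_m <- vapply(sp, function(i) sum(out$i_obs[i] * w[i]) / sum(w[i]),
                  numeric(1))
    s_m <- vapply(sp, function(i) 1 / sqrt(sum(w[i])), numeric(1))
    out <- out[rows, ]
    out$i_obs <- i_m
    out$sig_i <- s_m
  }
  out$d <- d_spacing(out, sym)
  ce <- .centric_epsilon(.as_hkl_matrix(out), sym)
  out$centric <- ce$centric
  out$epsilon <- ce$epsilon
  out <- out[order(-out$d, out$h, out$k, out$l), ]
  attr(out, "symmetry") <- sym
  class(out) <- c("reflections", class(tibble::tibble()))
  out
}

#' @export
print.reflections <- function(x, ...) {
  sym <- attr(x, "symmetry")
  cat("<reflections> ", nrow(x), " unique reflections, ",
      sym$space_group, ", d = ",
      signif(max(x$d), 4), " - ", signif(min(x$d), 4), " A\n", sep = "")
  NextMethod()
}

#' Symmetry of a reflections tibble
#' @param refl A `reflections` tibble.
#' @return The attached [crystal_symmetry()].
#' @export
reflection_symmetry <- function(refl) attr(refl, "symmetry")

#' Re-derive centricity and epsilon
#'
#' Centric flag is true when some operator maps hkl to its Friedel mate;
#' epsilon counts the rotations fixing hkl.
#'
#' @param refl A `reflections` tibble.
#' @param sym Optional symmetry (defaults to the attached one).
#' @return `refl` with `centric` and `epsilon` recomputed.
#' @export
assign_centric_epsilon <- function(refl, sym = reflection_symmetry(refl)) {
  if (is.null(sym$ops)) stop("symmetry operators not populated")
  ce <- .centric_epsilon(.as_hkl_matrix(refl), sym)
  refl$centric <- ce$centric
  refl$epsilon <- ce$epsilon
  refl
}

#' Equal-count resolution bins
#'
#' Bins reflections by 1/d^3 into equal-count bins, ordered by decreasing d
#' (bin 1 holds the lowest-resolution reflections). The bin count is chosen
#' so each bin holds at least `max(50, target_per_bin / 2)` reflections;
#' fewer reflections than that give a single bin.
#'
#' @param refl A `reflections` tibble.
#' @param target_per_bin Target reflections per bin.
#' @return `refl` with a `bin` column and a `binning` attribute: a tibble
#'   with per-bin `d_max`, `d_min` and counts.
#' @export
make_bins <- function(refl, target_per_bin = 100) {
  n <- nrow(refl)
  mn <- max(50, target_per_bin / 2)
  n_bins <- max(1L, min(n %/% as.integer(target_per_bin), n %/% as.integer(mn)))
  ord <- order(1 / refl$d^3)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  refl$bin <- bin
  attr(refl, "binning") <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, d = refl$d), .data$bin),
    d_max = max(.data$d), d_min = min(.data$d), n = dplyr::n(),
    .groups = "drop")
  refl
}

#' Stratified work/test split
#'
#' Flags a random test ("free") set for cross-validation, stratified by
#' resolution bin with largest-remainder allocation so the total matches
#' `round(fraction * n)` and each bin's share is proportional. Deterministic
#' given the seed.
#'
#' @param refl A binned `reflections` tibble.
#' @param fraction Test fraction in (0, 0.5].
#' @param seed Integer RNG seed (recorded in the `test_seed` attribute).
#' @return `refl` with a logical `is_test` column.
#' @export
split_work_test <- function(refl, fraction = 0.05, seed = 42) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (!"bin" %in% names(refl)) refl <- make_bins(refl)
  n <- nrow(refl)
  n_test <- round(fraction * n)
  tab <- table(refl$bin)
  quota <- fraction * as.numeric(tab)
  base <- floor(quota)
  rem <- quota - base
  extra <- n_test - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  is_test <- logical(n)
  .with_seed(seed, {
    for (b in seq_along(tab)) {
      idx <- which(refl$bin == as.integer(names(tab)[b]))
      if (base[b] > 0) is_test[sample(idx, base[b])] <- TRUE
    }
  })
  refl$is_test <- is_test
  attr(refl, "test_seed") <- as.integer(seed)
  refl
}

#' Effective normalized amplitudes and error factors
#'
#' For each reflection, computes the posterior of the true normalized
#' amplitude E given the observed intensity and its uncertainty under a
#' Wilson prior (acentric or centric as appropriate), by Gauss-Legendre
#' quadrature in E. The two-moment effective-amplitude representation is
#' then `Dobs = sqrt(1 - Var(E))` and `Ee = E[E] / Dobs`, after which `Ee`
#' is rescaled per bin so its mean square is exactly 1. `f_obs` stores the
#' posterior-mean amplitude on the absolute scale for R-factor reporting.
#'
#' Negative observed intensities are handled naturally: the posterior under
#' the nonnegative-amplitude prior keeps `Ee` finite and positive.
#'
#' @param refl A binned `reflections` tibble.
#' @param n_quad Number of quadrature nodes.
#' @return `refl` with columns `ee`, `dobs`, `f_obs`.
#' @export
effective_amplitudes <- function(refl, n_quad = 64) {
  if (any(refl$sig_i < 0)) stop("sig_i must be non-negative")
  if (!"bin" %in% names(refl)) stop("reflections lack bins; run make_bins() first")
  # merge underpopulated bins into their lower-resolution neighbor
  tab <- table(refl$bin)
  if (any(tab < 10)) {
    warning("resolution bin(s) with fewer than 10 reflections merged with neighbor")
    small <- as.integer(names(tab)[tab < 10])
    for (b in small) {
      target <- if (b > 1) b - 1L else b + 1L
      refl$bin[refl$bin == b] <- target
    }
    refl$bin <- as.integer(factor(refl$bin))
  }
  eps <- refl$epsilon
  Sigma <- tapply(refl$i_obs / eps, refl$bin, mean)
  Sigma <- pmax(Sigma, .Machine$double.eps)
  Sb <- as.numeric(Sigma[as.character(refl$bin)])
  z <- refl$i_obs / (eps * Sb)
  sz <- refl$sig_i / (eps * Sb)

  n <- length(z)
  mu1 <- numeric(n); mu2 <- numeric(n)
  exact <- sz < 1e-10
  if (any(exact)) {
    if (any(z[exact] < 0)) stop("negative intensity with zero uncertainty")
    mu1[exact] <- sqrt(pmax(z[exact], 0))
    mu2[exact] <- pmax(z[exact], 0)
  }
  if (any(!exact)) {
    gl <- .gauss_legendre_01(n_quad)
    zi <- z[!exact]; si <- sz[!exact]
    umax <- sqrt(pmax(zi, 0) + 8 * si + 8)
    U <- outer(umax, gl$nodes)              # n x q, u = sqrt(J)
    Wq <- outer(umax, gl$weights)
    J <- U^2
    loglik <- -(zi - J)^2 / (2 * si^2)
    logprior <- ifelse(matrix(refl$centric[!exact], nrow(U), ncol(U)),
                       -J / 2, -J + log(2 * U + 1e-300))
    lg <- loglik + logprior
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg) * Wq
    Z0 <- rowSums(g)
    mu1[!exact] <- rowSums(g * U) / Z0
    mu2[!exact] <- rowSums(g * J) / Z0
  }
  v <- pmax(mu2 - mu1^2, 0)
  dobs <- sqrt(pmin(pmax(1 - v, 0), 1))
  ee_raw <- ifelse(dobs > 0, mu1 / dobs, 0)
  scale_b <- tapply(ee_raw^2, refl$bin, mean)
  refl$ee <- ee_raw / sqrt(as.numeric(scale_b[as.character(refl$bin)]))
  refl$dobs <- dobs
  refl$f_obs <- mu1 * sqrt(eps * Sb)
  refl
}
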