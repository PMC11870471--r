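# Crystallographic log-likelihood-gain-on-intensity (LLGI) target.
#
# For acentric reflections the conditional density of the effective
# normalized amplitude Ee given the calculated normalized amplitude EC is a
# Rice distribution with center Dobs*sigmaA*EC and complex variance
# 1 - (Dobs*sigmaA)^2; for centric reflections it is the corresponding
# folded normal with a cosh coupling. The LLG is the log ratio against the
# Wilson (no-model) density. Writing x = Dobs*sigmaA and g = 1/(1-x^2):
#   acentric: -ln(1-x^2) - x^2 (Ee^2+EC^2) g + ln I0(2 x Ee EC g)
#   centric:  -ln(1-x^2)/2 - x^2 (Ee^2+EC^2) g / 2 + ln cosh(x Ee EC g)
# both vanishing as x -> 0.

.check_degenerate <- function(x) {
  if (any(x >= 1)) stop("Dobs * sigmaA >= 1: degenerate variance")
}

#' Acentric and centric LLGI per reflection
#'
#' @param ee Effective observed normalized amplitudes.
#' @param ec Calculated normalized amplitudes.
#' @param dobs Observation error factors in `[0, 1]`.
#' @param sigma_a Model-quality correlation(s) in `[0.015, 0.99]`.
#' @return Per-reflection log-likelihood gain.
#' @export
llgi_acentric <- function(ee, ec, dobs, sigma_a) {
  x <- dobs * sigma_a
  .check_degenerate(x)
  g <- 1 / (1 - x^2)
  -log1p(-x^2) - x^2 * (ee^2 + ec^2) * g + .log_bessel_i0(2 * x * ee * ec * g)
}

#' @rdname llgi_acentric
#' @export
llgi_centric <- function(ee, ec, dobs, sigma_a) {
  x <- dobs * sigma_a
  .check_degenerate(x)
  g <- 1 / (1 - x^2)
  -0.5 * log1p(-x^2) - 0.5 * x^2 * (ee^2 + ec^2) * g +
    .log_cosh(x * ee * ec * g)
}

# derivative of the per-reflection LLGI with respect to EC
.llgi_dec <- function(ee, ec, dobs, sigma_a, centric) {
  x <- dobs * sigma_a
  g <- 1 / (1 - x^2)
  out <- numeric(length(ee))
  a <- !centric
  if (any(a)) {
    t <- 2 * x[a] * ee[a] * ec[a] * g[a]
    r <- .bessel_ratio_i1_i0(t)
    out[a] <- -2 * x[a]^2 * ec[a] * g[a] + r * 2 * x[a] * ee[a] * g[a]
  }
  if (any(centric)) {
    i <- centric
    u <- x[i] * ee[i] * ec[i] * g[i]
    out[i] <- -x[i]^2 * ec[i] * g[i] + tanh(u) * x[i] * ee[i] * g[i]
  }
  out
}

# first and second derivatives of the summed LLGI with respect to sigmaA,
# for the reflections of one bin (analytic; verified against finite
# differences in the tests)
.llgi_sigma_derivs <- function(ee, ec, dobs, sigma_a, centric) {
  x <- dobs * sigma_a
  g <- 1 / (1 - x^2)
  E2C2 <- ee^2 + ec^2
  n <- length(ee)
  f1 <- numeric(n); f2 <- numeric(n)
  a <- !centric
  if (any(a)) {
    t <- 2 * ee[a] * ec[a] * x[a] * g[a]
    tp <- 2 * ee[a] * ec[a] * g[a]^2 * (1 + x[a]^2)
    tpp <- 4 * ee[a] * ec[a] * x[a] * g[a]^3 * (3 + x[a]^2)
    r <- .bessel_ratio_i1_i0(t)
    rp <- ifelse(t < 1e-6, 0.5, 1 - r / t - r^2)
    f1[a] <- 2 * x[a] * g[a] - 2 * x[a] * g[a]^2 * E2C2[a] + r * tp
    f2[a] <- 2 * g[a]^2 * (1 + x[a]^2) -
      2 * g[a]^3 * (1 + 3 * x[a]^2) * E2C2[a] + rp * tp^2 + r * tpp
  }
  if (any(centric)) {
    i <- centric
    u <- ee[i] * ec[i] * x[i] * g[i]
    up <- ee[i] * ec[i] * g[i]^2 * (1 + x[i]^2)
    upp <- 2 * ee[i] * ec[i] * x[i] * g[i]^3 * (3 + x[i]^2)
    th <- tanh(u)
    f1[i] <- x[i] * g[i] - x[i] * g[i]^2 * E2C2[i] + th * up
    f2[i] <- g[i]^2 * (1 + x[i]^2) - g[i]^3 * (1 + 3 * x[i]^2) * E2C2[i] +
      (1 - th^2) * up^2 + th * upp
  }
  # chain rule x = dobs * sigma_a
  list(g1 = sum(f1 * dobs), g2 = sum(f2 * dobs^2))
}

# resolve a per-bin sigmaA specification to a per-reflection vector
.sigma_a_per_refl <- function(refl, sigma_a) {
  if (is.data.frame(sigma_a)) {
    v <- sigma_a$sigma_a[match(refl$bin, sigma_a$bin)]
  } else if (length(sigma_a) == 1) {
    v <- rep(sigma_a, nrow(refl))
  } else {
    v <- sigma_a[refl$bin]
  }
  if (anyNA(v)) stop("sigma_a does not cover every resolution bin")
  v
}

.llg_use_mask <- function(refl, use) {
  if (use == "all" || !"is_test" %in% names(refl)) rep(TRUE, nrow(refl))
  else !refl$is_test
}

#' Total crystallographic LLG
#'
#' Sum of the per-reflection LLGI over the selected reflection set,
#' dispatching on centricity.
#'
#' @param refl A `reflections` tibble with `ee`, `dobs`, `bin`, `centric`.
#' @param sf Normalized structure factors (see [normalize_to_E()]); a
#'   tibble aligned row-for-row with `refl` carrying `e_calc`.
#' @param sigma_a Per-bin sigmaA: a tibble with `bin` and `sigma_a` columns,
#'   or a numeric vector indexed by bin.
#' @param use `"work"` (default) or `"all"`.
#' @return Scalar LLG.
#' @export
llg_total <- function(refl, sf, sigma_a, use = c("work", "all")) {
  use <- match.arg(use)
  if (!"e_calc" %in% names(sf)) sf <- normalize_to_E(sf, refl)
  sA <- .sigma_a_per_refl(refl, sigma_a)
  keep <- .llg_use_mask(refl, use)
  per <- numeric(nrow(refl))
  a <- !refl$centric
  per[a] <- llgi_acentric(refl$ee[a], sf$e_calc[a], refl$dobs[a], sA[a])
  per[!a] <- llgi_centric(refl$ee[!a], sf$e_calc[!a], refl$dobs[!a], sA[!a])
  sum(per[keep])
}

# safeguarded per-bin Newton ascent shared by the crystallographic and
# cryo-EM sigmaA estimators: `derivs(sigma)` returns list(g1, g2) for one bin
.newton_sigma_a <- function(derivs, init = 0.5, max_iter = 50,
                            lower = 0.015, upper = 0.99, tol = 1e-4) {
  s <- min(max(init, lower), upper)
  for (it in seq_len(max_iter)) {
    d <- derivs(s)
    if (!is.finite(d$g1) || !is.finite(d$g2)) break
    if (d$g2 < 0) {
      step <- -d$g1 / d$g2
    } else {
      step <- sign(d$g1) * 0.05      # non-concave: walk uphill, bounded
    }
    step <- max(min(step, 0.2), -0.2)
    s_new <- min(max(s + step, lower), upper)
    if (abs(s_new - s) < tol) { s <- s_new; break }
    s <- s_new
  }
  s
}

#' Refine per-bin sigmaA by safeguarded Newton iteration
#'
#' Maximizes the summed LLGI over sigmaA separately in each resolution bin
#' using analytic first and second derivatives, Newton steps with a
#' gradient-sign fallback where the curvature is not negative, and clamping
#' to `[0.015, 0.99]`. Uses the work reflections.
#'
#' @inheritParams llg_total
#' @param init Initial sigmaA (scalar or per-bin).
#' @param max_iter Maximum Newton iterations per bin.
#' @return A tibble of class `sigma_a_bins` with columns `bin`, `n`,
#'   `d_min`, `d_max`, `sigma_a`.
#' @export
refine_sigma_a <- function(refl, sf, init = 0.5, max_iter = 50,
                           use = c("work", "all")) {
  use <- match.arg(use)
  if (!"e_calc" %in% names(sf)) sf <- normalize_to_E(sf, refl)
  keep <- .llg_use_mask(refl, use)
  bins <- sort(unique(refl$bin))
  init <- rep_len(init, length(bins))
  out <- purrr::map_dfr(seq_along(bins), function(j) {
    b <- bins[j]
    i <- keep & refl$bin == b
    derivs <- function(s) {
      .llgi_sigma_derivs(refl$ee[i], sf$e_calc[i], refl$dobs[i],
                         rep(s, sum(i)), refl$centric[i])
    }
    tibble::tibble(
      bin = b, n = sum(i),
      d_min = min(refl$d[refl$bin == b]), d_max = max(refl$d[refl$bin == b]),
      sigma_a = .newton_sigma_a(derivs, init = init[j], max_iter = max_iter)
    )
  })
  class(out) <- c("sigma_a_bins", class(tibble::tibble()))
  out
}

#' R factors
#'
#' Conventional amplitude residuals `sum(||Fo| - |Fc||) / sum(|Fo|)` on the
#' work and test sets, using the posterior-mean observed amplitudes and
#' scaled calculated amplitudes (per-bin scaling is applied if the
#' structure factors have not been through [solvent_and_scale()]).
#'
#' @inheritParams llg_total
#' @return A one-row tibble: `r_work`, `r_free`, `n_work`, `n_test`.
#' @export
r_factors <- function(refl, sf) {
  if (!"f_scaled" %in% names(sf)) sf <- solvent_and_scale(sf, refl, babinet = FALSE)
  fo <- refl$f_obs
  fc <- sf$f_scaled
  test <- if ("is_test" %in% names(refl)) refl$is_test else rep(FALSE, nrow(refl))
  rfac <- function(i) if (any(i)) sum(abs(fo[i] - fc[i])) / sum(fo[i]) else NA_real_
  tibble::tibble(r_work = rfac(!test), r_free = rfac(test),
                 n_work = sum(!test), n_test = sum(test))
}

#' Crystallographic target with coordinate gradients
#'
#' Evaluates the total LLGI of a model against reflection data and returns
#' exact gradients with respect to the model coordinates and isotropic B
#' values, propagated through structure-factor summation and per-bin E
#' normalization.
#'
#' @param model An [atomic_model()].
#' @param refl A prepared `reflections` tibble (`ee`, `dobs`, `bin`).
#' @param sigma_a Per-bin sigmaA (tibble or vector); `NULL` refines it
#'   first.
#' @param sym Crystal symmetry (defaults to the one attached to `refl`).
#' @param use Reflection set for the sum.
#' @return List: `value` (scalar LLG), `grad_coords` (n_atoms x 3),
#'   `grad_b` (n_atoms), `sf` (the normalized structure factors), and
#'   `sigma_a`.
#' @export
xtal_target <- function(model, refl, sigma_a = NULL,
                        sym = reflection_symmetry(refl),
                        use = c("work", "all")) {
  use <- match.arg(use)
  sf <- compute_structure_factors(model, sym, refl)
  sf <- normalize_to_E(sf, refl)
  if (is.null(sigma_a)) sigma_a <- refine_sigma_a(refl, sf, use = use)
  sA <- .sigma_a_per_refl(refl, sigma_a)
  keep <- .llg_use_mask(refl, use)
  value <- llg_total(refl, sf, sigma_a, use = use)
  v <- .llgi_dec(refl$ee, sf$e_calc, refl$dobs, sA, refl$centric)
  v[!keep] <- 0
  W <- .e_calc_pullback_W(sf, v)
  g <- attr(sf, "pullback")(W)
  list(value = value, grad_coords = g$coords, grad_b = g$b_iso,
       sf = sf, sigma_a = sigma_a)
}
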