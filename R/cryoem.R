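# Cryo-EM Fourier-term log-likelihood gain. Signal and noise power are
# estimated per resolution bin from two half-maps: the signal from the
# correlation of their Fourier terms, the noise from their differences.
# The per-term LLG couples observed and calculated normalized amplitudes
# and their phase difference through Dobs and sigmaA.

#' Estimate signal, noise and observation weights from half-maps
#'
#' Fourier-transforms both half-maps, keeps the unique (Friedel) half of the
#' frequency grid inside the resolution cutoff, bins terms by resolution
#' (equal count), and per bin estimates signal power
#' `S = max(0, <Re(F1 conj(F2))>)`, noise power `N = <|F1 - F2|^2> / 4` and
#' `Dobs = sqrt(S / (S + N))`. The combined observed term is
#' `Fobs = (F1 + F2)/2` with amplitude normalized per bin so `<Ee^2> = 1`.
#'
#' @param half1,half2 3D arrays (identical dimensions) or paths to MRC
#'   files.
#' @param voxel Voxel size in Angstrom (required when arrays are given).
#' @param n_bins Number of resolution bins.
#' @param dmin Resolution cutoff in Angstrom.
#' @return A tibble of class `map_terms`, one row per Fourier term: `h`,
#'   `k`, `l` (grid frequencies), `s`, `d`, `bin`, `f_obs` (complex), `ee`,
#'   `phi_obs`, `dobs`; attributes `cell` (box edge lengths), `dims`,
#'   `bin_stats` (per-bin signal/noise power and half-map FSC).
#' @export
estimate_signal_noise <- function(half1, half2, voxel = NULL, n_bins = 10,
                                  dmin) {
  if (is.character(half1)) {
    m1 <- read_mrc(half1); m2 <- read_mrc(half2)
    if (max(abs(m1$voxel - m2$voxel)) > 1e-6) stop("half-map voxel sizes differ")
    voxel <- m1$voxel
    half1 <- m1$map; half2 <- m2$map
  }
  if (is.null(voxel)) stop("voxel size required")
  if (!identical(dim(half1), dim(half2))) {
    stop("half-map grids do not match: ", paste(dim(half1), collapse = "x"),
         " vs ", paste(dim(half2), collapse = "x"))
  }
  dims <- dim(half1)
  voxel <- rep_len(voxel, 3)
  cell <- dims * voxel
  F1 <- stats::fft(half1)
  F2 <- stats::fft(half2)

  idx <- expand.grid(i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1,
                     k = seq_len(dims[3]) - 1)
  signed <- function(p, n) ifelse(p > n / 2, p - n, p)
  h <- signed(idx$i, dims[1]); k <- signed(idx$j, dims[2])
  l <- signed(idx$k, dims[3])
  s <- sqrt((h / cell[1])^2 + (k / cell[2])^2 + (l / cell[3])^2)
  half <- (h > 0) | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0)
  keep <- half & s > 0 & (1 / s) >= dmin
  lin <- which(keep)
  ord <- order(s[lin])
  lin <- lin[ord]

  n <- length(lin)
  if (n < n_bins * 5) n_bins <- max(1L, n %/% 5L)
  bin <- rep(seq_len(n_bins), each = ceiling(n / n_bins))[seq_len(n)]
  f1 <- F1[lin]; f2 <- F2[lin]
  fobs <- (f1 + f2) / 2

  cross <- Re(f1 * Conj(f2))
  diff2 <- Mod(f1 - f2)^2
  S <- pmax(tapply(cross, bin, mean), 0)
  N <- tapply(diff2, bin, mean) / 4
  dobs_bin <- sqrt(S / pmax(S + N, .Machine$double.eps))
  fsc <- tapply(cross, bin, sum) /
    pmax(sqrt(tapply(Mod(f1)^2, bin, sum) * tapply(Mod(f2)^2, bin, sum)),
         .Machine$double.eps)
  p_obs <- tapply(Mod(fobs)^2, bin, mean)
  ee <- Mod(fobs) / sqrt(pmax(as.numeric(p_obs[bin]), .Machine$double.eps))

  out <- tibble::tibble(
    h = h[lin], k = k[lin], l = l[lin], s = s[lin], d = 1 / s[lin],
    bin = bin, f_obs = fobs, ee = ee, phi_obs = Arg(fobs),
    dobs = as.numeric(dobs_bin[bin])
  )
  attr(out, "cell") <- cell
  attr(out, "dims") <- dims
  dmin_b <- tapply(1 / s[lin], bin, min)
  dmax_b <- tapply(1 / s[lin], bin, max)
  nb <- as.integer(table(bin))
  attr(out, "bin_stats") <- tibble::tibble(
    bin = as.integer(names(S)), n = nb,
    d_min = as.numeric(dmin_b), d_max = as.numeric(dmax_b),
    signal = as.numeric(S), noise = as.numeric(N),
    dobs = as.numeric(dobs_bin), fsc = as.numeric(fsc))
  class(out) <- c("map_terms", class(tibble::tibble()))
  out
}

#' Per-term cryo-EM log-likelihood gain
#'
#' \deqn{LLG = \frac{2 D_{obs} \sigma_A E_e E_{calc} \cos\Delta\phi}
#' {1 - D_{obs}^2\sigma_A^2} - \frac{D_{obs}^2\sigma_A^2 (E_e^2 +
#' E_{calc}^2)}{1 - D_{obs}^2\sigma_A^2} - \ln(1 - D_{obs}^2\sigma_A^2)}
#'
#' @param ee,e_calc Observed and calculated normalized amplitudes.
#' @param delta_phi Phase difference `phi_calc - phi_obs` (radians).
#' @param dobs Observation error factor in `[0, 1]`.
#' @param sigma_a Model-quality correlation.
#' @return Per-term LLG values.
#' @export
cryoem_llg_term <- function(ee, e_calc, delta_phi, dobs, sigma_a) {
  x <- dobs * sigma_a
  .check_degenerate(x)
  g <- 1 / (1 - x^2)
  2 * x * ee * e_calc * cos(delta_phi) * g - x^2 * (ee^2 + e_calc^2) * g -
    log1p(-x^2)
}

# model structure factors at map Fourier frequencies, normalized per bin
.model_map_sf <- function(model, terms) {
  cell <- attr(terms, "cell")
  sym <- crystal_symmetry(c(cell, 90, 90, 90), "P1")
  sf <- compute_structure_factors(model, sym, terms)
  fake <- tibble::tibble(bin = terms$bin, epsilon = rep(1, nrow(terms)))
  normalize_to_E(sf, fake)
}

#' Cryo-EM sigmaA estimation per resolution bin
#'
#' Maximizes the summed per-term LLG over sigmaA in each bin by the same
#' safeguarded Newton iteration used for the crystallographic target,
#' clamped to `[0.015, 0.99]`.
#'
#' @param terms A `map_terms` tibble.
#' @param model An [atomic_model()], or a numeric vector/list giving
#'   calculated normalized amplitudes and phases (`e_calc`, `phi_calc`).
#' @param max_iter Newton iterations per bin.
#' @return A `sigma_a_bins` tibble.
#' @export
estimate_sigma_a_cryoem <- function(terms, model, max_iter = 50) {
  mc <- .cryoem_calc_terms(terms, model)
  dphi <- mc$phi_calc - terms$phi_obs
  bins <- sort(unique(terms$bin))
  out <- purrr::map_dfr(bins, function(b) {
    i <- terms$bin == b
    a <- 2 * terms$ee[i] * mc$e_calc[i] * cos(dphi[i])
    bb <- terms$ee[i]^2 + mc$e_calc[i]^2
    derivs <- function(sg) {
      x <- terms$dobs[i] * sg
      g <- 1 / (1 - x^2)
      f1 <- a * g^2 * (1 + x^2) - bb * 2 * x * g^2 + 2 * x * g
      f2 <- a * 2 * x * g^3 * (3 + x^2) - bb * 2 * g^3 * (1 + 3 * x^2) +
        2 * g^2 * (1 + x^2)
      list(g1 = sum(f1 * terms$dobs[i]), g2 = sum(f2 * terms$dobs[i]^2))
    }
    tibble::tibble(bin = b, n = sum(i), d_min = min(terms$d[i]),
                   d_max = max(terms$d[i]),
                   sigma_a = .newton_sigma_a(derivs, max_iter = max_iter))
  })
  class(out) <- c("sigma_a_bins", class(tibble::tibble()))
  out
}

.cryoem_calc_terms <- function(terms, model) {
  if (is.data.frame(model) && "x" %in% names(model)) {
    sf <- .model_map_sf(model, terms)
    list(e_calc = sf$e_calc, phi_calc = sf$phi_calc, sf = sf)
  } else {
    list(e_calc = model$e_calc, phi_calc = model$phi_calc, sf = NULL)
  }
}

#' Total cryo-EM LLG, with optional coordinate gradients
#'
#' Computes model Fourier terms by direct summation at the map frequencies,
#' normalizes them per bin, and sums the per-term LLG. With
#' `gradient = TRUE` the exact gradient with respect to model coordinates
#' (through both the normalized amplitude and the calculated phase) and
#' isotropic B values is returned.
#'
#' @param terms A `map_terms` tibble from [estimate_signal_noise()].
#' @param model An [atomic_model()].
#' @param sigma_a Per-bin sigmaA (tibble or vector); `NULL` estimates it
#'   first.
#' @param gradient Also compute gradients.
#' @return With `gradient = FALSE`, scalar LLG. Otherwise a list
#'   `value`, `grad_coords`, `grad_b`, `sigma_a`.
#' @export
cryoem_llg_total <- function(terms, model, sigma_a = NULL, gradient = FALSE) {
  if (is.null(sigma_a)) sigma_a <- estimate_sigma_a_cryoem(terms, model)
  sf <- .model_map_sf(model, terms)
  sA <- .sigma_a_per_refl(terms, sigma_a)
  dphi <- sf$phi_calc - terms$phi_obs
  x <- terms$dobs * sA
  .check_degenerate(x)
  g <- 1 / (1 - x^2)
  value <- sum(2 * x * terms$ee * sf$e_calc * cos(dphi) * g -
                 x^2 * (terms$ee^2 + sf$e_calc^2) * g - log1p(-x^2))
  if (!gradient) return(value)
  v_amp <- 2 * x * terms$ee * cos(dphi) * g - 2 * x^2 * sf$e_calc * g
  v_phi <- -2 * x * terms$ee * sf$e_calc * sin(dphi) * g
  W <- .e_calc_pullback_W(sf, v_amp)
  phase <- exp(1i * sf$phi_calc)
  W <- W + v_phi * 1i * phase / pmax(sf$f_calc, 1e-300)
  gr <- attr(sf, "pullback")(W)
  list(value = value, grad_coords = gr$coords, grad_b = gr$b_iso,
       sigma_a = sigma_a)
}

#' Cryo-EM target closure for rigid-body refinement and the loop
#'
#' @inheritParams cryoem_llg_total
#' @return List: `value`, `grad_coords`, `grad_b`, `sigma_a`.
#' @export
cryoem_target <- function(terms, model, sigma_a = NULL) {
  cryoem_llg_total(terms, model, sigma_a, gradient = TRUE)
}
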