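# Synthetic data: toy atomic models, simulated noisy reflection data under
# Wilson statistics, simulated half-maps with controlled signal-to-noise,
# and synthetic MSAs with cluster profiles. Every generator is
# deterministic given its seed and records its generation parameters.

#' Toy C-alpha model
#'
#' A compact, self-avoiding helix-like C-alpha trace: points follow a
#' solenoid (a helix whose axis advances slowly) re-stepped to exactly
#' 3.8 Angstrom consecutive spacing, with a small seeded jitter applied
#' before re-stepping. Atoms are carbons with B = 20, placed in a padded
#' P1 (or P21) cell.
#'
#' @param n_res Number of residues (>= 5).
#' @param seed RNG seed for the jitter.
#' @param space_group `"P1"` (default) or `"P21"`.
#' @param padding Minimum gap to the cell walls (Angstrom).
#' @return An [atomic_model()] with a `symmetry` attribute holding the
#'   [crystal_symmetry()] of the padded cell.
#' @export
make_toy_model <- function(n_res, seed = 1, space_group = "P1",
                           padding = 5) {
  stopifnot(n_res >= 5)
  th <- (seq_len(n_res) - 1) * (2 * pi / 12)    # 12 residues per turn
  R0 <- 7.3
  curve <- cbind(R0 * cos(th), R0 * sin(th),
                 (seq_len(n_res) - 1) * 0.42)   # ~5 A pitch between turns
  jitter <- .with_seed(seed, matrix(stats::runif(n_res * 3, -0.05, 0.05),
                                    n_res, 3))
  curve <- curve + jitter
  coords <- matrix(0, n_res, 3)
  coords[1, ] <- curve[1, ]
  for (i in seq_len(n_res - 1)) {
    step <- curve[i + 1, ] - curve[i, ]
    coords[i + 1, ] <- coords[i, ] + 3.8 * step / sqrt(sum(step^2))
  }
  # self-avoidance guard (construction should always satisfy it)
  d2 <- as.matrix(stats::dist(coords))
  d2[abs(row(d2) - col(d2)) <= 1] <- Inf
  if (min(d2) <= 3.0) stop("toy trace self-collides; adjust parameters")

  span <- apply(coords, 2, range)
  coords <- sweep(coords, 2, span[1, ]) + padding
  cell <- c(span[2, ] - span[1, ] + 2 * padding, 90, 90, 90)
  model <- atomic_model(coords, element = "C", b_iso = 20)
  attr(model, "symmetry") <- crystal_symmetry(cell, space_group)
  attr(model, "params") <- list(n_res = n_res, seed = as.integer(seed),
                                space_group = space_group, padding = padding)
  model
}

#' Symmetry attached to a simulated model
#' @param model A model from [make_toy_model()].
#' @return The attached [crystal_symmetry()].
#' @export
model_symmetry <- function(model) attr(model, "symmetry")

#' Simulate noisy reflection data from a model
#'
#' Computes intensities `I_true = |Fc|^2` on a complete asymmetric-unit
#' index set to `dmin`, adds Gaussian noise with
#' `sig_i = noise_frac * (<I>_bin + I_true) / 2`, and runs the full
#' preparation pipeline (bins, effective amplitudes, work/test split).
#'
#' @param model An [atomic_model()].
#' @param sym A [crystal_symmetry()] (defaults to the model's).
#' @param dmin Resolution limit (Angstrom).
#' @param noise_frac Relative noise level (0 = noise-free).
#' @param seed RNG seed.
#' @param target_per_bin,test_fraction Passed to [make_bins()] /
#'   [split_work_test()].
#' @return A prepared `reflections` tibble with an `i_true` column.
#' @export
simulate_reflections <- function(model, sym = model_symmetry(model), dmin,
                                 noise_frac = 0.1, seed = 1,
                                 target_per_bin = 100,
                                 test_fraction = 0.05) {
  stopifnot(dmin > 0)
  hkl <- .complete_asu_hkl(sym, dmin)
  sf <- compute_structure_factors(model, sym, hkl)
  i_true <- sf$f_calc^2
  refl <- tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                         i_obs = i_true, sig_i = 0, d = d_spacing(hkl, sym))
  ce <- .centric_epsilon(.as_hkl_matrix(refl), sym)
  refl$centric <- ce$centric
  refl$epsilon <- ce$epsilon
  attr(refl, "symmetry") <- sym
  class(refl) <- c("reflections", class(tibble::tibble()))
  refl <- make_bins(refl, target_per_bin)
  ibar <- tapply(i_true, refl$bin, mean)
  sig <- noise_frac * (as.numeric(ibar[as.character(refl$bin)]) + i_true) / 2
  refl$sig_i <- sig
  refl$i_obs <- i_true +
    .with_seed(seed, stats::rnorm(nrow(refl), 0, 1)) * sig
  refl$i_true <- i_true
  refl <- effective_amplitudes(refl)
  refl <- split_work_test(refl, test_fraction, seed = seed + 1000L)
  attr(refl, "params") <- list(dmin = dmin, noise_frac = noise_frac,
                               seed = as.integer(seed))
  refl
}

# complete set of unique ASU indices to dmin (absences removed)
.complete_asu_hkl <- function(sym, dmin) {
  lim <- ceiling(sym$cell[1:3] / dmin) + 1
  grid <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                                l = 0:lim[3]))
  d <- d_spacing(grid, sym)
  grid <- grid[is.finite(d) & d >= dmin, , drop = FALSE]
  asu <- map_to_asu(grid, sym)
  asu <- unique(tibble::as_tibble(asu))
  asu <- asu[!(asu$h == 0 & asu$k == 0 & asu$l == 0), ]
  asu <- asu[!is_absent(asu, sym), ]
  # the l >= 0 half plus ASU mapping covers the full sphere for the
  # supported groups; verify completeness by re-mapping the full shell
  as.matrix(asu)
}

#' Simulate a pair of cryo-EM half-maps
#'
#' Generates a band-limited density (Fourier synthesis of the model's
#' scattering to `dmin`) on a regular grid in an orthogonal box, and adds
#' independent Gaussian Fourier noise to two copies. The noise is colored
#' by resolution shell so that every shell has per-term signal-to-noise
#' ratio `snr` (hence half-map FSC about `snr / (snr + 1)`); `snr = 0`
#' yields pure-noise maps and `snr = Inf` identical noise-free maps.
#'
#' @param model An [atomic_model()].
#' @param box Box edge length(s) in Angstrom (length 1 or 3).
#' @param voxel Voxel size (Angstrom).
#' @param dmin Band limit (Angstrom).
#' @param snr Per-term signal-to-noise ratio in each resolution shell.
#' @param seed RNG seed.
#' @return List: `half1`, `half2` (3D arrays), `truth` (noise-free map),
#'   `voxel`, `cell`, `params`.
#' @export
simulate_halfmaps <- function(model, box, voxel = 2, dmin, snr = 4,
                              seed = 1) {
  box <- rep_len(box, 3)
  dims <- pmax(8L, 2L * as.integer(ceiling(box / voxel / 2)))
  cell <- dims * voxel
  span <- apply(model_coords(model), 2, range)
  if (any(span[1, ] < 0) || any(span[2, ] > cell)) {
    stop("box does not accommodate the model")
  }
  sym <- crystal_symmetry(c(cell, 90, 90, 90), "P1")
  # frequencies inside the band limit
  idx <- expand.grid(i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1,
                     k = seq_len(dims[3]) - 1)
  signed <- function(p, n) ifelse(p > n / 2, p - n, p)
  h <- signed(idx$i, dims[1]); k <- signed(idx$j, dims[2])
  l <- signed(idx$k, dims[3])
  s <- sqrt((h / cell[1])^2 + (k / cell[2])^2 + (l / cell[3])^2)
  inside <- s > 0 & 1 / s >= dmin
  sf <- compute_structure_factors(model, sym,
                                  cbind(h = h[inside], k = k[inside],
                                        l = l[inside]))
  Farr <- array(0 + 0i, dims)
  Farr[which(inside)] <- sf$fc
  Farr[1, 1, 1] <- sum(form_factor(model$element, 0) * model$occ)
  truth <- Re(stats::fft(Farr, inverse = TRUE)) / prod(dims)

  # shell-colored Hermitian Fourier noise: each of ~12 equal-count
  # resolution shells receives complex noise of variance
  # (shell mean signal power) / snr, so every shell has the requested
  # per-term SNR and half-map FSC ~ snr / (snr + 1)
  half_set <- (h > 0) | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0)
  keep <- which(inside & half_set)
  ord <- keep[order(s[keep])]
  n_shell <- max(1L, min(12L, length(ord) %/% 30L))
  shell_id <- rep(seq_len(n_shell),
                  each = ceiling(length(ord) / n_shell))[seq_along(ord)]
  p_shell <- tapply(Mod(Farr[ord])^2, shell_id, mean)
  sigma_t <- if (is.infinite(snr)) {
    rep(0, length(ord))
  } else if (snr <= 0) {
    rep(sqrt(mean(p_shell)), length(ord))
  } else {
    sqrt(as.numeric(p_shell[shell_id]) / snr)
  }
  conj_index <- function(lin) {
    # linear index of the Friedel mate -h on the FFT grid
    ai <- arrayInd(lin, dims) - 1L
    mi <- (-ai) %% matrix(dims, nrow(ai), 3, byrow = TRUE)
    1L + mi[, 1] + dims[1] * (mi[, 2] + dims[2] * mi[, 3])
  }
  mates <- conj_index(ord)
  base <- if (snr <= 0 && !is.infinite(snr)) truth * 0 else truth
  make_half <- function() {
    z <- complex(real = stats::rnorm(length(ord), 0, 1 / sqrt(2)),
                 imaginary = stats::rnorm(length(ord), 0, 1 / sqrt(2)))
    Narr <- array(0 + 0i, dims)
    Narr[ord] <- sigma_t * z
    Narr[mates] <- Conj(sigma_t * z)
    base + Re(stats::fft(Narr, inverse = TRUE)) / prod(dims)
  }
  halves <- .with_seed(seed, list(make_half(), make_half()))
  list(half1 = halves[[1]], half2 = halves[[2]], truth = truth,
       voxel = rep_len(voxel, 3), cell = cell,
       params = list(box = box, voxel = voxel, dmin = dmin, snr = snr,
                     seed = as.integer(seed)))
}

#' Synthetic MSA and cluster profile
#'
#' `make_synthetic_msa()` draws an alignment of categorical symbols (23
#' classes: 20 amino acids, unknown, gap, mask) with a seeded per-column
#' preference; `msa_profile()` converts an alignment to the
#' `[clusters x residues x 23]` cluster-profile array by column frequencies
#' over contiguous sequence blocks; `subsample_msa()` takes a uniform random
#' subset of sequences (at full depth it returns the alignment unchanged).
#'
#' @param n_seq,n_res Alignment dimensions.
#' @param seed RNG seed.
#' @param concentration Sharpness of per-column preferences (larger =
#'   flatter columns).
#' @return `make_synthetic_msa()`: integer matrix `n_seq x n_res` with
#'   values in 1..23.
#' @export
make_synthetic_msa <- function(n_seq, n_res, seed = 1, concentration = 0.5) {
  .with_seed(seed, {
    msa <- matrix(0L, n_seq, n_res)
    for (r in seq_len(n_res)) {
      p <- stats::rgamma(23, concentration)
      p <- p / sum(p)
      msa[, r] <- sample.int(23, n_seq, replace = TRUE, prob = p)
    }
    msa
  })
}

#' @rdname make_synthetic_msa
#' @param msa Integer alignment matrix (values 1..23).
#' @param n_clusters Number of contiguous sequence blocks.
#' @return `msa_profile()`: numeric array `[n_clusters x n_res x 23]` with
#'   each trailing vector summing to 1.
#' @export
msa_profile <- function(msa, n_clusters = 1) {
  n_seq <- nrow(msa); n_res <- ncol(msa)
  stopifnot(n_clusters >= 1, n_seq >= n_clusters)
  blocks <- split(seq_len(n_seq),
                  ceiling(seq_len(n_seq) / (n_seq / n_clusters)))
  blocks <- blocks[seq_len(min(n_clusters, length(blocks)))]
  prof <- array(0, c(length(blocks), n_res, 23))
  for (c_ in seq_along(blocks)) {
    sub <- msa[blocks[[c_]], , drop = FALSE]
    for (r in seq_len(n_res)) {
      prof[c_, r, ] <- tabulate(sub[, r], 23) / nrow(sub)
    }
  }
  prof
}

#' @rdname make_synthetic_msa
#' @param depth Number of sequences to keep.
#' @export
subsample_msa <- function(msa, depth, seed = 1) {
  stopifnot(depth >= 1, depth <= nrow(msa))
  rows <- .with_seed(seed, sort(sample.int(nrow(msa), depth)))
  msa[rows, , drop = FALSE]
}

#' Reference profile plus subsample generator
#'
#' Convenience wrapper: a synthetic alignment, its full cluster profile
#' `m0`, and a generator for profiles of random subsampled alignments.
#'
#' @param n_clusters,n_res Profile dimensions.
#' @param seed RNG seed.
#' @param n_seq Alignment depth.
#' @return List: `profile` (the `[n_clusters x n_res x 23]` array), `msa`,
#'   and `subsample(depth, seed)` returning a subsampled profile.
#' @export
make_profile <- function(n_clusters, n_res, seed = 1,
                         n_seq = 64 * n_clusters) {
  msa <- make_synthetic_msa(n_seq, n_res, seed)
  list(
    profile = msa_profile(msa, n_clusters),
    msa = msa,
    subsample = function(depth, seed = 1) {
      msa_profile(subsample_msa(msa, depth, seed), n_clusters)
    }
  )
}
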