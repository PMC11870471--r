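# Pluggable predictor contract and a differentiable toy predictor.
#
# A predictor maps an MSA cluster profile (array [clusters x residues x 23])
# to C-alpha coordinates and per-residue confidence, and exposes an exact
# backward pass from gradients on coordinates/confidence to gradients on the
# profile. The toy predictor is a linear test double: its displacement field
# is a fixed random linear readout of the per-residue profile deviation, so
# the refinement loop's optimum is identifiable. It is not a folding model.

#' Specification of the toy fold predictor
#'
#' @param base_coords n x 3 C-alpha coordinates returned at zero bias.
#' @param m0 Reference MSA cluster profile (`[clusters x residues x 23]`);
#'   deviations are measured against it.
#' @param seed Seed for the fixed random readout.
#' @param max_disp Bound on the displacement (Angstrom) produced by a
#'   unit-norm per-residue profile deviation; each residue's 3 x 23 readout
#'   is scaled to this spectral norm. The default keeps the predictor's
#'   coordinate response to one optimizer step at the standard phase-1
#'   learning rates in the sub-Angstrom range, comparable to a folding
#'   network's smooth response to small profile changes.
#' @param plddt_slope Confidence drop per Angstrom of displacement:
#'   `pLDDT = 100 - plddt_slope * |displacement|`, clamped to `[30, 100]`.
#' @return A `toy_fold_spec` list.
#' @export
toy_fold_spec <- function(base_coords, m0, seed = 1, max_disp = 0.4,
                          plddt_slope = 10) {
  base_coords <- as.matrix(base_coords)
  n_res <- nrow(base_coords)
  stopifnot(length(dim(m0)) == 3, dim(m0)[2] == n_res, dim(m0)[3] == 23)
  readout <- .with_seed(seed, {
    lapply(seq_len(n_res), function(r) {
      W <- matrix(stats::rnorm(3 * 23), 3, 23)
      W * (max_disp / svd(W, nu = 0, nv = 0)$d[1])
    })
  })
  structure(list(base_coords = base_coords, m0 = m0, readout = readout,
                 n_res = n_res, max_disp = max_disp,
                 plddt_slope = plddt_slope, seed = as.integer(seed)),
            class = "toy_fold_spec")
}

#' Differentiable toy predictor
#'
#' Builds the predictor contract from a [toy_fold_spec()]: coordinates are
#' `base + W_r . dev_r` where `dev_r` is the per-residue mean (over
#' clusters) deviation of the biased profile from `m0`, and pLDDT decreases
#' linearly with displacement magnitude. Deterministic given the profile;
#' gradients are exact.
#'
#' @param spec A [toy_fold_spec()].
#' @return A `fold_predictor`: list with `n_res`,
#'   `predict(profile) -> list(coords, plddt)` and
#'   `pullback(profile, d_coords, d_plddt) -> d_profile`.
#' @export
toy_predictor <- function(spec) {
  stopifnot(inherits(spec, "toy_fold_spec"))
  n_res <- spec$n_res
  n_clu <- dim(spec$m0)[1]

  deviation <- function(profile) {
    stopifnot(identical(dim(profile), dim(spec$m0)))
    d <- profile - spec$m0
    # mean over clusters -> n_res x 23
    apply(d, c(2, 3), mean)
  }
  forward <- function(profile) {
    dev <- deviation(profile)
    disp <- t(vapply(seq_len(n_res),
                     function(r) as.numeric(spec$readout[[r]] %*% dev[r, ]),
                     numeric(3)))
    mag <- sqrt(rowSums(disp^2))
    plddt <- pmin(pmax(100 - spec$plddt_slope * mag, 30), 100)
    list(coords = spec$base_coords + disp, plddt = plddt, disp = disp,
         mag = mag)
  }
  structure(list(
    n_res = n_res,
    predict = function(profile) {
      f <- forward(profile)
      list(coords = f$coords, plddt = f$plddt)
    },
    pullback = function(profile, d_coords, d_plddt = NULL) {
      f <- forward(profile)
      dd <- as.matrix(d_coords)                    # dL/d(disp) via coords
      if (!is.null(d_plddt)) {
        raw <- 100 - spec$plddt_slope * f$mag
        interior <- raw > 30 & raw < 100 & f$mag > 1e-12
        coef <- ifelse(interior,
                       -spec$plddt_slope * d_plddt / pmax(f$mag, 1e-12), 0)
        dd <- dd + f$disp * coef
      }
      ddev <- t(vapply(seq_len(n_res),
                       function(r) as.numeric(crossprod(spec$readout[[r]],
                                                        dd[r, ])),
                       numeric(23)))
      dprofile <- array(0, dim = dim(spec$m0))
      for (c_ in seq_len(n_clu)) dprofile[c_, , ] <- ddev / n_clu
      dprofile
    }
  ), class = "fold_predictor")
}
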