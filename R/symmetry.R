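# Crystal symmetry: unit cell, space-group operators, and the reflection
# attributes (centricity, epsilon, systematic absence) they induce.

# Rotation parts are integer matrices acting on fractional coordinates,
# x' = R x + t. The equivalent of reflection h under (R, t) is h' = R^T h,
# with F(h') = F(h) * exp(-2*pi*i * h.t).
.sg_table <- local({
  I3 <- diag(3)
  rot <- function(dx, dy, dz) diag(c(dx, dy, dz))
  op <- function(R, t = c(0, 0, 0)) list(R = R, t = t)
  add_centering <- function(ops, cvec) {
    c(ops, lapply(ops, function(o) list(R = o$R, t = (o$t + cvec) %% 1)))
  }
  p2_ops <- list(op(I3), op(rot(-1, 1, -1)))
  list(
    "P1"       = list(op(I3)),
    "P-1"      = list(op(I3), op(-I3)),
    "P2"       = p2_ops,
    "P21"      = list(op(I3), op(rot(-1, 1, -1), c(0, 0.5, 0))),
    "C2"       = add_centering(p2_ops, c(0.5, 0.5, 0)),
    "P222"     = list(op(I3), op(rot(1, -1, -1)), op(rot(-1, 1, -1)),
                      op(rot(-1, -1, 1))),
    "P212121"  = list(op(I3),
                      op(rot(-1, -1, 1), c(0.5, 0, 0.5)),
                      op(rot(-1, 1, -1), c(0, 0.5, 0.5)),
                      op(rot(1, -1, -1), c(0.5, 0.5, 0)))
  )
})

#' Crystal symmetry
#'
#' Bundle a unit cell with the symmetry operators of a space group. The
#' supported groups are the common protein groups `P1`, `P-1`, `P2`, `P21`,
#' `C2`, `P222` and `P212121`; operators are stored as rotation matrices plus
#' fractional translations acting on fractional coordinates.
#'
#' @param cell Numeric length-6: a, b, c in Angstrom, alpha, beta, gamma in
#'   degrees.
#' @param space_group Hermann-Mauguin symbol (spaces ignored), e.g. `"P21"`.
#' @return An object of class `crystal_symmetry`: a list with elements
#'   `cell`, `space_group`, `ops` (list of `list(R, t)`), the
#'   orthogonalization matrix `M` (fractional to orthogonal Angstrom, PDB
#'   convention with a along x), its inverse `M_inv`, the cell volume
#'   `volume`, and the reciprocal metric tensor `G_star`.
#' @examples
#' sym <- crystal_symmetry(c(30, 40, 50, 90, 90, 90), "P212121")
#' length(sym$ops)
#' @export
crystal_symmetry <- function(cell, space_group = "P1") {
  stopifnot(is.numeric(cell), length(cell) == 6, all(is.finite(cell)),
            all(cell[1:3] > 0), all(cell[4:6] > 0 & cell[4:6] < 180))
  sg <- gsub("[[:space:]]", "", space_group)
  sg <- sub("^P-1$", "P-1", sg)
  if (!sg %in% names(.sg_table)) {
    stop("unknown or unsupported space group '", space_group,
         "'; supported: ", paste(names(.sg_table), collapse = ", "))
  }
  abc <- cell[1:3]
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg_ <- sin(ang[3])
  vol <- prod(abc) * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  # PDB orthogonalization: a along x, b in the xy plane
  M <- matrix(c(
    abc[1], abc[2] * cg, abc[3] * cb,
    0,      abc[2] * sg_, abc[3] * (ca - cb * cg) / sg_,
    0,      0,            vol / (abc[1] * abc[2] * sg_)
  ), nrow = 3, byrow = TRUE)
  G <- crossprod(M)          # direct metric tensor
  structure(list(
    cell = cell, space_group = sg, ops = .sg_table[[sg]],
    M = M, M_inv = solve(M), volume = vol, G_star = solve(G)
  ), class = "crystal_symmetry")
}

#' @export
print.crystal_symmetry <- function(x, ...) {
  cat("<crystal_symmetry> ", x$space_group, "  cell: ",
      paste(signif(x$cell, 5), collapse = " "),
      "  (", length(x$ops), " ops)\n", sep = "")
  invisible(x)
}

#' Resolution of reflections
#'
#' d-spacing in Angstrom for Miller indices under a given cell,
#' 1/d^2 = h^T G* h with G* the reciprocal metric tensor.
#'
#' @param hkl Integer matrix or data frame with columns h, k, l.
#' @param sym A [crystal_symmetry()].
#' @return Numeric vector of d (Angstrom); `Inf` for (0,0,0).
#' @export
d_spacing <- function(hkl, sym) {
  H <- .as_hkl_matrix(hkl)
  inv_d2 <- rowSums((H %*% sym$G_star) * H)
  ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
}

.as_hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  storage.mode(hkl) <- "double"
  stopifnot(ncol(hkl) == 3)
  hkl
}

# Apply rotation parts to hkl rows: returns list over ops of n x 3 matrices
.hkl_images <- function(H, sym) {
  lapply(sym$ops, function(o) H %*% o$R)   # rows h^T R = (R^T h)^T
}

#' Systematic absence test
#'
#' A reflection is systematically absent when some operator fixes its index
#' (R^T h = h) but carries a translation with non-integral h.t, forcing
#' F(h) = 0.
#'
#' @inheritParams d_spacing
#' @return Logical vector.
#' @export
is_absent <- function(hkl, sym) {
  H <- .as_hkl_matrix(hkl)
  absent <- rep(FALSE, nrow(H))
  for (o in sym$ops) {
    fixes <- rowSums(abs(H %*% o$R - H)) < 1e-9
    if (any(fixes)) {
      ht <- as.vector(H %*% o$t)
      shift <- abs(ht - round(ht))
      absent <- absent | (fixes & shift > 1e-9)
    }
  }
  absent
}

# centric flag and epsilon multiplicity for an hkl matrix
.centric_epsilon <- function(H, sym) {
  n <- nrow(H)
  centric <- rep(FALSE, n)
  epsilon <- rep(0L, n)
  for (o in sym$ops) {
    img <- H %*% o$R
    centric <- centric | rowSums(abs(img + H)) < 1e-9
    epsilon <- epsilon + as.integer(rowSums(abs(img - H)) < 1e-9)
  }
  list(centric = centric, epsilon = epsilon)
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' Each reflection is replaced by the lexicographically greatest member
#' (ordered by h, then k, then l) of its orbit under the space-group rotations
#' and Friedel inversion, so that symmetry-equivalent observations share an
#' index.
#'
#' @inheritParams d_spacing
#' @return Integer matrix of the same shape.
#' @export
map_to_asu <- function(hkl, sym) {
  H <- .as_hkl_matrix(hkl)
  images <- .hkl_images(H, sym)
  images <- c(images, lapply(images, function(m) -m))
  best <- images[[1]]
  for (m in images[-1]) {
    better <- (m[, 1] > best[, 1]) |
      (m[, 1] == best[, 1] & m[, 2] > best[, 2]) |
      (m[, 1] == best[, 1] & m[, 2] == best[, 2] & m[, 3] > best[, 3])
    best[better, ] <- m[better, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}
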