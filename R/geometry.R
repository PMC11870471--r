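# Confidence-derived weights and rigid-body geometry: pLDDT to pseudo-B,
# pseudo-B to alignment weight, weighted Kabsch superposition, and
# gradient-ascent rigid-body refinement of a likelihood target.

#' Convert pLDDT confidence to pseudo-B
#'
#' Empirical conversion of per-residue confidence to an equivalent
#' coordinate RMSD and on to an isotropic displacement parameter:
#' \eqn{B = (8\pi^2/3)\,(1.5\,e^{0.7 - 0.01\,pLDDT})^2} (Angstrom^2),
#' strictly decreasing in pLDDT.
#'
#' @param plddt Numeric vector in `[0, 100]`.
#' @return Pseudo-B values (Angstrom^2).
#' @export
plddt_to_pseudo_b <- function(plddt) {
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    stop("plddt must lie in [0, 100]")
  }
  (8 * pi^2 / 3) * (1.5 * exp(0.7 - 0.01 * plddt))^2
}

# derivative of pseudo-B with respect to pLDDT (for the backward pass)
.pseudo_b_dplddt <- function(plddt) {
  -0.02 * plddt_to_pseudo_b(plddt)
}

#' Convert pseudo-B to alignment weight
#'
#' Empirical three-branch rule: weight 1 for pseudo-B at or below 11.5,
#' linear decay from 1 to 0.5 up to 40.0, and `0.5 exp(-(B - 40))` beyond;
#' continuous at both breakpoints and non-increasing.
#'
#' @param pseudo_b Positive numeric vector (Angstrom^2).
#' @return Weights in `(0, 1]`.
#' @export
pseudo_b_to_weight <- function(pseudo_b) {
  stopifnot(all(pseudo_b > 0))
  ifelse(pseudo_b <= 11.5, 1,
         ifelse(pseudo_b <= 40,
                1 - 0.5 * (pseudo_b - 11.5) / (40 - 11.5),
                0.5 * exp(-(pseudo_b - 40))))
}

#' Rigid-body pose
#'
#' @param rotation Proper 3 x 3 rotation matrix.
#' @param translation Length-3 vector (Angstrom).
#' @return A `pose` object.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be a proper orthogonal matrix")
  }
  structure(list(R = rotation, t = as.numeric(translation)), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  ang <- rotation_angle(x$R) * 180 / pi
  cat("<pose> rotation ", signif(ang, 4), " deg, translation ",
      signif(sqrt(sum(x$t^2)), 4), " A\n", sep = "")
  invisible(x)
}

#' Apply or compose poses
#'
#' `apply_pose()` maps coordinates through `R x + t`; `compose_pose(p, q)`
#' returns the pose equivalent to applying `q` first, then `p`.
#'
#' @param coords n x 3 coordinate matrix.
#' @param p,q `pose` objects.
#' @return Transformed coordinates / composed pose.
#' @export
apply_pose <- function(coords, p) {
  sweep(as.matrix(coords) %*% t(p$R), 2, -p$t)
}

#' @rdname apply_pose
#' @export
compose_pose <- function(p, q) {
  pose(p$R %*% q$R, as.numeric(p$R %*% q$t) + p$t)
}

#' Rotation angle of a rotation matrix
#' @param R 3 x 3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1))
}

# axis-angle to rotation matrix (Rodrigues)
.rotation_from_axis_angle <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.cross_matrix <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

# dR/dv_i for the axis-angle parameterization (Gallego & Yezzi closed form)
.rotation_jacobian <- function(v) {
  R <- .rotation_from_axis_angle(v)
  th2 <- sum(v^2)
  if (th2 < 1e-12) {
    return(lapply(1:3, function(i) .cross_matrix(diag(3)[, i])))
  }
  lapply(1:3, function(i) {
    e <- diag(3)[, i]
    ((v[i] * .cross_matrix(v) +
        .cross_matrix(.cross3(v, (diag(3) - R) %*% e))) / th2) %*% R
  })
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Weighted Kabsch superposition
#'
#' Finds the proper roto-translation `C` minimizing
#' \eqn{\tfrac12 \sum_i w_i \| x^{ref}_i - C x^{pred}_i \|^2}: translation
#' from the weighted centroids, rotation from the SVD of the weighted
#' cross-covariance with determinant correction.
#'
#' @param x_pred,x_ref n x 3 coordinate matrices (e.g. C-alpha traces).
#' @param weights Non-negative per-point weights (see
#'   [pseudo_b_to_weight()]); default uniform.
#' @return A `pose` mapping `x_pred` onto `x_ref`, with attributes
#'   `residual` (weighted sum of squares) and `rmsd` (unweighted, after
#'   superposition).
#' @export
weighted_kabsch <- function(x_pred, x_ref, weights = NULL) {
  x_pred <- as.matrix(x_pred); x_ref <- as.matrix(x_ref)
  stopifnot(nrow(x_pred) == nrow(x_ref), ncol(x_pred) == 3)
  n <- nrow(x_pred)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights > 0) < 3) stop("need at least 3 points with nonzero weight")
  w <- weights / sum(weights)
  cp <- colSums(x_pred * w); cr <- colSums(x_ref * w)
  A <- sweep(x_pred, 2, cp); B <- sweep(x_ref, 2, cr)
  H <- t(A * w) %*% B                 # weighted cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    stop("degenerate (collinear) weighted configuration: rotation undetermined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.numeric(R %*% cp)
  p <- pose(R, t)
  moved <- apply_pose(x_pred, p)
  attr(p, "residual") <- 0.5 * sum(weights * rowSums((x_ref - moved)^2))
  attr(p, "rmsd") <- sqrt(mean(rowSums((x_ref - moved)^2)))
  p
}

#' Rigid-body refinement by gradient optimization of a likelihood target
#'
#' Starting from `pose0`, optimizes the six pose parameters — an axis-angle
#' rotation about the model centroid composed onto the starting pose, plus a
#' translation — to maximize a differentiable target, using quasi-Newton
#' (L-BFGS) ascent with exact pose gradients obtained by projecting the
#' target's coordinate gradient through the rotation Jacobian. The returned
#' pose never scores below the starting one. When `domains` is supplied
#' (a list of residue-index vectors), each domain is refined independently.
#'
#' @param coords n x 3 coordinate matrix to which `pose0` applies.
#' @param target `function(coords)` returning `list(value, grad_coords)`.
#' @param pose0 Starting [pose()].
#' @param steps Maximum optimizer iterations.
#' @param step0 Unused (kept for backward compatibility).
#' @param domains Optional list of row-index vectors.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @param restarts Number of deterministic perturbed starting poses (small
#'   axis rotations of about 1.7 degrees and 0.6 Angstrom axis
#'   translations composed onto `pose0`) tried in addition to `pose0`
#'   itself, keeping the best result. Useful when the likelihood surface
#'   has nearby local optima; 0 (the default) is appropriate when the
#'   starting pose is already close.
#' @return A `pose` (or list of per-domain poses) with attribute `value`,
#'   the achieved target value; the value is never below the starting one.
#' @export
rigid_body_refine <- function(coords, target, pose0 = pose(), steps = 30,
                              step0 = NULL, domains = NULL, tol = 1e-6,
                              restarts = 0) {
  coords <- as.matrix(coords)
  if (!is.null(domains)) {
    out <- lapply(domains, function(i) {
      tgt <- function(x_sub) {
        x <- coords
        x[i, ] <- x_sub
        ev <- target(x)
        list(value = ev$value,
             grad_coords = ev$grad_coords[i, , drop = FALSE])
      }
      rigid_body_refine(coords[i, , drop = FALSE], tgt, pose0, steps,
                        step0, domains = NULL, tol = tol)
    })
    return(out)
  }
  x0 <- apply_pose(coords, pose0)
  ev0 <- target(x0)
  if (!is.finite(ev0$value)) stop("non-finite target at the starting pose")
  centroid <- colMeans(x0)
  if (restarts > 0) {
    nudges <- rbind(matrix(0, 1, 6),
                    cbind(diag(3) * 0.03, matrix(0, 3, 3)),
                    cbind(-diag(3) * 0.03, matrix(0, 3, 3)),
                    cbind(matrix(0, 3, 3), diag(3) * 0.6),
                    cbind(matrix(0, 3, 3), -diag(3) * 0.6))
    nudges <- nudges[seq_len(min(nrow(nudges), restarts + 1)), , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(nudges))) {
      Rn <- .rotation_from_axis_angle(nudges[i, 1:3])
      p0i <- compose_pose(
        pose(Rn, centroid - as.numeric(Rn %*% centroid) + nudges[i, 4:6]),
        pose0)
      pi_ <- rigid_body_refine(coords, target, p0i, steps, step0,
                               domains = NULL, tol = tol, restarts = 0)
      if (is.null(best) || attr(pi_, "value") > attr(best, "value")) {
        best <- pi_
      }
    }
    return(best)
  }
  xc <- sweep(x0, 2, centroid)

  place <- function(par) {
    R <- .rotation_from_axis_angle(par[1:3])
    sweep(xc %*% t(R), 2, -(centroid + par[4:6]))
  }
  last <- new.env()
  fn <- function(par) {
    ev <- target(place(par))
    assign("ev", ev, envir = last)
    if (!is.finite(ev$value)) return(1e30)
    -ev$value
  }
  gr <- function(par) {
    ev <- get("ev", envir = last)
    if (!is.finite(ev$value)) return(numeric(6))
    G <- ev$grad_coords
    J <- .rotation_jacobian(par[1:3])
    gv <- vapply(J, function(Ji) sum((xc %*% t(Ji)) * G), numeric(1))
    -c(gv, colSums(G))
  }
  fit <- stats::optim(numeric(6), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = steps, factr = tol / 1e-15,
                                     lmm = 6))
  if (-fit$value > ev0$value) {
    v <- fit$par[1:3]
    R <- .rotation_from_axis_angle(v)
    p <- compose_pose(
      pose(R, centroid - as.numeric(R %*% centroid) + fit$par[4:6]), pose0)
    val <- -fit$value
  } else {
    p <- pose0
    val <- ev0$value
  }
  attr(p, "value") <- val
  p
}
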