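# Atomic models as tibbles: one row per atom, orthogonal Angstrom
# coordinates, element, occupancy, isotropic B (the pseudo-B when derived
# from predictor confidence) and per-residue pLDDT.

#' Construct an atomic model
#'
#' @param coords Numeric n x 3 matrix of orthogonal coordinates (Angstrom).
#' @param element Element symbols, recycled (default carbon).
#' @param occ Occupancies in `[0, 1]`, recycled.
#' @param b_iso Isotropic displacement parameters (Angstrom^2), recycled;
#'   must be positive.
#' @param plddt Optional per-atom confidence in `[0, 100]`.
#' @param chain,resno,atom Optional identifiers, recycled.
#' @return A tibble of class `atomic_model` with columns `chain`, `resno`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ`, `b_iso`, `plddt`.
#' @export
atomic_model <- function(coords, element = "C", occ = 1, b_iso = 20,
                         plddt = NA_real_, chain = "A",
                         resno = NULL, atom = "CA") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  n <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(n)
  out <- tibble::tibble(
    chain = rep_len(chain, n), resno = rep_len(as.integer(resno), n),
    atom = rep_len(atom, n), element = rep_len(toupper(element), n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occ = rep_len(occ, n), b_iso = rep_len(b_iso, n),
    plddt = rep_len(plddt, n)
  )
  if (any(out$b_iso <= 0)) stop("b_iso must be positive")
  if (any(out$occ < 0 | out$occ > 1)) stop("occupancy must lie in [0, 1]")
  if (any(!is.na(out$plddt) & (out$plddt < 0 | out$plddt > 100))) {
    stop("plddt must lie in [0, 100]")
  }
  class(out) <- c("atomic_model", class(tibble::tibble()))
  out
}

#' Extract or replace model coordinates
#'
#' @param model An [atomic_model()].
#' @return `model_coords()` returns the n x 3 coordinate matrix;
#'   `set_model_coords()` returns the model with coordinates replaced.
#' @export
model_coords <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

#' @rdname model_coords
#' @param coords Replacement n x 3 matrix.
#' @export
set_model_coords <- function(model, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(model), ncol(coords) == 3)
  model$x <- coords[, 1]; model$y <- coords[, 2]; model$z <- coords[, 3]
  model
}

#' Read an atomic model from PDB
#'
#' Thin wrapper over [bio3d::read.pdb()]. For predictor output the B-factor
#' column conventionally stores pLDDT; set `plddt_from_b = TRUE` to copy it
#' into the `plddt` column and derive pseudo-B via [plddt_to_pseudo_b()].
#'
#' @param path PDB file.
#' @param plddt_from_b Interpret the B column as pLDDT.
#' @return An [atomic_model()] tibble.
#' @export
read_model <- function(path, plddt_from_b = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  el <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                              substr(trimws(a$elety), 1, 1), a$elesy)))
  m <- atomic_model(
    cbind(a$x, a$y, a$z), element = el, occ = a$o,
    b_iso = pmax(a$b, 1e-3), chain = a$chain, resno = a$resno,
    atom = trimws(a$elety)
  )
  if (plddt_from_b) {
    m$plddt <- pmin(pmax(a$b, 0), 100)
    m$b_iso <- plddt_to_pseudo_b(m$plddt)
  }
  m
}

#' Write an atomic model to PDB
#'
#' @param model An [atomic_model()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  n <- nrow(model)
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(model_coords(model))),
    type = rep("ATOM", n), resno = model$resno, chain = model$chain,
    resid = rep("ALA", n), elety = model$atom, o = model$occ,
    b = model$b_iso, elesy = model$element
  )
  invisible(path)
}
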