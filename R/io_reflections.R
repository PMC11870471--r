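# Reflection file reading and writing. Two dialects: reflection CIF (text,
# _refln loop) and the classic binary MTZ layout (80-character header
# records after the float32 data block). No installed R package covers
# these formats, so compact readers/writers are provided here; the MTZ
# writer/reader pair is cross-checked against an independent implementation
# in the test suite.

.sg_numbers <- c("P1" = 1, "P-1" = 2, "P2" = 3, "P21" = 4, "C2" = 5,
                 "P222" = 16, "P212121" = 19)

.sg_pretty <- c("P1" = "P 1", "P-1" = "P -1", "P2" = "P 1 2 1",
                "P21" = "P 1 21 1", "C2" = "C 1 2 1", "P222" = "P 2 2 2",
                "P212121" = "P 21 21 21")

.normalize_sg_name <- function(name) {
  sg <- gsub("[[:space:]]", "", name)
  sg <- sub("^P121$", "P2", sg)
  sg <- sub("^P1211$", "P21", sg)
  sg <- sub("^C121$", "C2", sg)
  sg
}

#' Read crystallographic reflections
#'
#' Reads intensities and uncertainties plus cell/space-group metadata from a
#' reflection CIF or MTZ file and returns a [as_reflections()] tibble
#' (mapped to the asymmetric unit, systematic absences removed).
#'
#' @param path Input file.
#' @param dialect `"auto"` (by magic/extension), `"mtz"` or `"cif"`.
#' @param i_col,sig_col Optional column-label overrides for MTZ input.
#' @return A `reflections` tibble with a `symmetry` attribute.
#' @examples
#' path <- system.file("extdata", "toy_p212121.cif", package = "llgfold")
#' refl <- read_reflections(path)
#' refl
#' @export
read_reflections <- function(path, dialect = c("auto", "mtz", "cif"),
                             i_col = NULL, sig_col = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    magic <- readBin(path, "raw", 4)
    dialect <- if (rawToChar(magic) == "MTZ ") "mtz" else "cif"
  }
  raw <- if (dialect == "mtz") .read_mtz_raw(path, i_col, sig_col)
         else .read_refln_cif_raw(path)
  sym <- crystal_symmetry(raw$cell, raw$space_group)
  as_reflections(raw$data, sym)
}

#' Write reflections
#'
#' Writes `h, k, l, i_obs, sig_i` plus any derived columns present
#' (`ee`, `dobs`, `bin`, `is_test`) with cell and space-group metadata.
#'
#' @param refl A `reflections` tibble.
#' @param path Output file.
#' @param dialect `"cif"` or `"mtz"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_reflections <- function(refl, path,
                              dialect = c("auto", "mtz", "cif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.mtz$", path, ignore.case = TRUE)) "mtz" else "cif"
  }
  sym <- reflection_symmetry(refl)
  if (dialect == "mtz") .write_mtz(refl, sym, path) else .write_refln_cif(refl, sym, path)
  invisible(path)
}

# ---- reflection CIF ----

.read_refln_cif_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  grab <- function(tags) {
    for (tag in tags) {
      hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
      if (length(hit)) {
        val <- trimws(sub(paste0("^", tag), "", hit[1]))
        return(gsub("^['\"]|['\"]$", "", val))
      }
    }
    NA_character_
  }
  cell <- as.numeric(c(
    grab(c("_cell\\.length_a", "_cell_length_a")),
    grab(c("_cell\\.length_b", "_cell_length_b")),
    grab(c("_cell\\.length_c", "_cell_length_c")),
    grab(c("_cell\\.angle_alpha", "_cell_angle_alpha")),
    grab(c("_cell\\.angle_beta", "_cell_angle_beta")),
    grab(c("_cell\\.angle_gamma", "_cell_angle_gamma"))
  ))
  if (anyNA(cell)) stop("reflection CIF lacks complete _cell metadata")
  sg <- grab(c("_symmetry\\.space_group_name_H-M",
               "_symmetry_space_group_name_H-M",
               "_space_group\\.name_H-M_alt", "_space_group\\.name_H-M"))
  if (is.na(sg)) stop("reflection CIF lacks a space-group name")

  loops <- grep("^loop_$", lines)
  for (start in loops) {
    i <- start + 1
    tags <- character()
    while (i <= length(lines) && grepl("^_", lines[i])) {
      tags <- c(tags, lines[i]); i <- i + 1
    }
    if (!any(grepl("^_refln", tags))) next
    rows <- character()
    while (i <= length(lines) && nzchar(lines[i]) &&
           !grepl("^(_|loop_|data_|#)", lines[i])) {
      rows <- c(rows, lines[i]); i <- i + 1
    }
    tab <- utils::read.table(text = rows, col.names = make.names(tags))
    names(tab) <- tags
    pick <- function(cands) {
      hit <- intersect(cands, tags)
      if (length(hit)) tab[[hit[1]]] else NULL
    }
    h <- pick(c("_refln.index_h", "_refln_index_h"))
    k <- pick(c("_refln.index_k", "_refln_index_k"))
    l <- pick(c("_refln.index_l", "_refln_index_l"))
    iobs <- pick(c("_refln.intensity_meas", "_refln_intensity_meas"))
    sigi <- pick(c("_refln.intensity_sigma", "_refln_intensity_sigma",
                   "_refln.intensity_meas_su"))
    if (is.null(iobs) || is.null(sigi)) {
      stop("no intensity columns in reflection loop; available: ",
           paste(tags, collapse = ", "))
    }
    return(list(
      data = tibble::tibble(h = h, k = k, l = l, i_obs = iobs, sig_i = sigi),
      cell = cell, space_group = .normalize_sg_name(sg)
    ))
  }
  stop("no _refln loop found in ", path)
}

.write_refln_cif <- function(refl, sym, path) {
  sg <- .sg_pretty[[sym$space_group]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_llgfold",
    sprintf("_cell.length_a    %.4f", sym$cell[1]),
    sprintf("_cell.length_b    %.4f", sym$cell[2]),
    sprintf("_cell.length_c    %.4f", sym$cell[3]),
    sprintf("_cell.angle_alpha %.4f", sym$cell[4]),
    sprintf("_cell.angle_beta  %.4f", sym$cell[5]),
    sprintf("_cell.angle_gamma %.4f", sym$cell[6]),
    sprintf("_symmetry.space_group_name_H-M '%s'", sg),
    "loop_",
    "_refln.index_h",
    "_refln.index_k",
    "_refln.index_l",
    "_refln.intensity_meas",
    "_refln.intensity_sigma"
  ), con)
  extra <- intersect(c("ee", "dobs", "bin", "is_test"), names(refl))
  if (length(extra)) {
    writeLines(paste0("_refln.llgfold_", extra), con)
  }
  cols <- cbind(refl$h, refl$k, refl$l,
                formatC(refl$i_obs, format = "g", digits = 9),
                formatC(refl$sig_i, format = "g", digits = 9))
  for (e in extra) {
    v <- refl[[e]]
    cols <- cbind(cols, if (is.logical(v)) as.integer(v)
                  else formatC(v, format = "g", digits = 9))
  }
  writeLines(apply(cols, 1, paste, collapse = " "), con)
}

# ---- MTZ ----

.mtz_header_records <- function(path_con, n) {
  recs <- character()
  repeat {
    chunk <- readChar(path_con, 80, useBytes = TRUE)
    if (length(chunk) == 0 || nchar(chunk) == 0) break
    recs <- c(recs, trimws(chunk))
    if (grepl("^END", chunk)) break
  }
  recs
}

.read_mtz_raw <- function(path, i_col = NULL, sig_col = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "MTZ ") stop("not an MTZ file: ", path)
  headerposn <- readBin(con, "integer", 1, size = 4)
  seek(con, 20 * 4)                       # data block starts at word 21
  n_data_words <- headerposn - 21
  data <- readBin(con, "numeric", n_data_words, size = 4)
  recs <- .mtz_header_records(con)

  getrec <- function(key) grep(paste0("^", key, "\\b"), recs, value = TRUE)
  ncolrec <- strsplit(getrec("NCOL"), "[[:space:]]+")[[1]]
  ncol <- as.integer(ncolrec[2]); nref <- as.integer(ncolrec[3])
  cell <- as.numeric(strsplit(getrec("CELL"), "[[:space:]]+")[[1]][2:7])
  syminf <- getrec("SYMINF")
  sgname <- sub(".*'([^']+)'.*", "\\1", syminf)
  cols <- getrec("COLUMN")
  parts <- strsplit(cols, "[[:space:]]+")
  labels <- vapply(parts, `[`, "", 2)
  types <- vapply(parts, `[`, "", 3)
  mat <- matrix(data[seq_len(nref * ncol)], nrow = nref, ncol = ncol,
                byrow = TRUE)
  colnames(mat) <- labels
  idx <- match(c("H", "K", "L"), labels)
  if (anyNA(idx)) stop("MTZ lacks H K L index columns")
  pick_label <- function(lab, type) {
    if (!is.null(lab)) {
      j <- match(lab, labels)
      if (is.na(j)) stop("MTZ has no column '", lab, "'")
      return(j)
    }
    j <- which(types == type)
    if (!length(j)) {
      stop("no intensity (type ", type, ") column in MTZ; available: ",
           paste(paste0(labels, "(", types, ")"), collapse = ", "))
    }
    j[1]
  }
  ji <- pick_label(i_col, "J")
  js <- if (!is.null(sig_col)) pick_label(sig_col, "Q") else {
    j <- which(types == "Q")
    if (!length(j)) stop("no sigma (type Q) column in MTZ; available: ",
                         paste(paste0(labels, "(", types, ")"), collapse = ", "))
    # prefer the sigma whose label references the chosen intensity
    cand <- j[grepl(labels[ji], labels[j], fixed = TRUE)]
    if (length(cand)) cand[1] else j[1]
  }
  list(
    data = tibble::tibble(h = as.integer(round(mat[, idx[1]])),
                          k = as.integer(round(mat[, idx[2]])),
                          l = as.integer(round(mat[, idx[3]])),
                          i_obs = mat[, ji], sig_i = mat[, js]),
    cell = cell, space_group = .normalize_sg_name(sgname)
  )
}

.write_mtz <- function(refl, sym, path) {
  sg <- sym$space_group
  cols <- list(H = refl$h, K = refl$k, L = refl$l,
               IOBS = refl$i_obs, SIGIOBS = refl$sig_i)
  types <- c("H", "H", "H", "J", "Q")
  if ("ee" %in% names(refl))   { cols$EE <- refl$ee;     types <- c(types, "R") }
  if ("dobs" %in% names(refl)) { cols$DOBS <- refl$dobs; types <- c(types, "R") }
  if ("bin" %in% names(refl))  { cols$BIN <- refl$bin;   types <- c(types, "I") }
  if ("is_test" %in% names(refl)) {
    cols$FREE <- as.integer(refl$is_test); types <- c(types, "I")
  }
  mat <- do.call(cbind, lapply(cols, as.numeric))
  nref <- nrow(mat); ncol_ <- ncol(mat)
  srange <- range(1 / refl$d^2)

  rec <- function(...) {
    s <- paste(...)
    formatC(s, width = 80, flag = "-")
  }
  recs <- c(
    rec("VERS MTZ:V1.1"),
    rec("TITLE llgfold reflections"),
    rec(sprintf("NCOL %d %d 0", ncol_, nref)),
    rec(sprintf("CELL  %.4f %.4f %.4f %.4f %.4f %.4f", sym$cell[1],
                sym$cell[2], sym$cell[3], sym$cell[4], sym$cell[5],
                sym$cell[6])),
    rec("SORT  1 2 3 0 0"),
    rec(sprintf("SYMINF %d %d %s %d '%s' PG1",
                length(sym$ops), length(sym$ops),
                substr(sg, 1, 1), .sg_numbers[[sg]], .sg_pretty[[sg]])),
    rec(sprintf("RESO %.8f %.8f", srange[1], srange[2])),
    vapply(seq_len(ncol_), function(j) {
      rec(sprintf("COLUMN %-30s %s %16.4f %16.4f 0",
                  names(cols)[j], types[j], min(mat[, j]), max(mat[, j])))
    }, ""),
    rec("END")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MTZ ", con, 4, eos = NULL)
  writeBin(as.integer(21 + nref * ncol_), con, size = 4)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  writeBin(integer(17), con, size = 4)
  writeBin(as.numeric(t(mat)), con, size = 4)
  for (r in recs) writeChar(r, con, 80, eos = NULL)
  writeChar(formatC("MTZENDOFHEADERS", width = 80, flag = "-"), con, 80,
            eos = NULL)
}
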