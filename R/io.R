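#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one point per residue bearing a CA atom from the ATOM records of
#' the first model (CASP evaluation practice: HETATM ignored, first MODEL
#' only). Residues are ordered by chain, residue number, insertion code
#' (lexicographic). Alternate locations are resolved by highest occupancy,
#' ties by alphabetical altloc id. Residues without a CA atom are skipped
#' with a warning.
#'
#' @param path PDB file path.
#' @param chain_filter optional character vector of chain ids to keep.
#' @return A `protein_structure` with labels "chain:resno\[icode\]".
#' @export
read_calpha_pdb <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  reskey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  resorder <- order(at$chain, at$resno, at$insert)
  reskeys <- unique(reskey[resorder])
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("empty structure: no CA atoms")
  # altloc: highest occupancy, then alphabetical altloc id
  ca$o[is.na(ca$o)] <- 1
  ca$alt[is.na(ca$alt)] <- ""
  ca <- ca[order(-ca$o, ca$alt), , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "\r")), ,
           drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno, ca$insert), , drop = FALSE]
  missing_ca <- length(reskeys) - nrow(ca)
  if (missing_ca > 0L)
    warning(sprintf("%d residue(s) without a CA atom were skipped", missing_ca))
  labels <- paste0(ca$chain, ":", ca$resno,
                   ifelse(ca$insert == "", "", ca$insert))
  protein_structure(cbind(ca$x, ca$y, ca$z), labels)
}

#' Read coordinates from a plain-text xyz table
#'
#' Whitespace- or tab-separated rows, either `x y z` or `label x y z`.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return A `protein_structure`.
#' @export
read_xyz_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("empty structure: no data rows")
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  nfield <- lengths(rows)
  if (any(!nfield %in% c(3L, 4L)))
    stop("parse error at line ", keep[which(!nfield %in% c(3L, 4L))[1]],
         ": expected 3 or 4 fields")
  labelled <- nfield == 4L
  labels <- ifelse(labelled, vapply(rows, `[`, "", 1L), NA_character_)
  coords <- t(vapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(tail(rows[[i]], 3L)))
    if (any(is.na(v)))
      stop("parse error at line ", keep[i], ": non-numeric coordinate")
    v
  }, numeric(3L)))
  if (all(is.na(labels))) labels <- NULL
  else labels[is.na(labels)] <- as.character(which(is.na(labels)))
  protein_structure(coords, labels)
}

#' Write a structure as a plain-text xyz table
#'
#' @param s a `protein_structure`.
#' @param path output path.
#' @param labels include the label column? Default TRUE.
#' @export
write_xyz_table <- function(s, path, labels = TRUE) {
  stopifnot(inherits(s, "protein_structure"))
  xyz <- formatC(s$xyz, format = "f", digits = 6)
  rows <- if (labels) paste(s$labels, xyz[, 1], xyz[, 2], xyz[, 3], sep = "\t")
          else paste(xyz[, 1], xyz[, 2], xyz[, 3], sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Write curve records to a TSV file
#'
#' @param records data.frame with columns `theta`, `fraction` and `source`
#'   (one of "exact_oracle", "near_optimal").
#' @param path output path.
#' @return The path, invisibly. Rows are written sorted by theta with six
#'   decimal places under a `theta\\tfraction\\tsource` header.
#' @export
write_curve_tsv <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  stopifnot(all(c("theta", "fraction", "source") %in% names(records)),
            all(records$theta >= 0),
            all(records$fraction > 0 & records$fraction <= 1))
  records <- records[order(records$theta), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("theta\tfraction\tsource", con)
  writeLines(sprintf("%.6f\t%.6f\t%s", records$theta, records$fraction,
                     as.character(records$source)), con)
  invisible(path)
}

#' Write a GDT score report as JSON
#'
#' @param report a named list (e.g. n, epsilon, theta_max, H_values, area,
#'   normalized, gdt_ts, gdt_ha).
#' @param path output path.
#' @export
write_score_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
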