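#' Read a protein-dsDNA complex structure
#'
#' Parses a PDB file into a tidy atom table.  Each atom is classified as
#' `protein` (the 20 standard amino acids) or `dna` (DA/DC/DG/DT or
#' single-letter nucleotide residue names).  Alternate-location records are
#' reduced to the highest-occupancy conformer (ties keep the first
#' encountered).
#'
#' @param path path to a PDB file.
#' @param unknown what to do with residue names that are neither standard
#'   amino acids nor nucleotides: `"error"` (default) or `"skip"` (dropped
#'   with a warning).
#' @return a tibble with one row per atom: `element`, `name`, `x`, `y`, `z`,
#'   `residue_name`, `chain`, `residue_number`, `kind`.
#' @export
read_complex <- function(path, unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- as_tibble(pdb$atom)

  # alternate locations: keep the highest-occupancy conformer per atom site
  at$o[is.na(at$o)] <- 1
  at <- at |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    slice_max(.data$o, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$.row)

  kind <- dplyr::case_when(
    at$resid %in% names(AA3_TO_1) ~ "protein",
    at$resid %in% names(DNA_RESNAMES) ~ "dna",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) {
    offenders <- unique(at$resid[is.na(kind)])
    if (unknown == "error") {
      abort(sprintf(
        "unknown residue name(s) in %s: %s",
        path, paste(offenders, collapse = ", ")
      ), class = "dbd_unknown_residue")
    }
    warn(sprintf("skipping unknown residue name(s): %s",
                 paste(offenders, collapse = ", ")))
    at <- at[!is.na(kind), ]
    kind <- kind[!is.na(kind)]
  }

  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(gsub("[^A-Za-z].*$", "", at$elety[blank]), 1, 1)

  atoms <- tibble(
    element = toupper(element),
    name = at$elety,
    x = at$x, y = at$y, z = at$z,
    residue_name = at$resid,
    chain = at$chain,
    residue_number = as.integer(at$resno),
    kind = kind
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort(sprintf("non-finite coordinates in %s", path))
  }
  for (side in c("protein", "dna")) {
    if (!any(atoms$kind == side)) {
      abort(sprintf("no %s atoms found in %s", side, path),
            class = "dbd_missing_side")
    }
  }
  atoms
}

#' Write an atom table as a PDB file
#'
#' Companion writer for [read_complex()]; used by the synthetic-structure
#' generator.
#'
#' @param atoms atom tibble (columns as returned by [read_complex()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(atoms, path) {
  require_columns(atoms, c("element", "name", "x", "y", "z",
                           "residue_name", "chain", "residue_number"),
                  "atom table")
  n <- nrow(atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$residue_number,
    resid = atoms$residue_name,
    eleno = seq_len(n),
    elety = atoms$name,
    chain = atoms$chain,
    o = rep(1, n), b = rep(0, n),
    elesy = atoms$element
  )
  invisible(path)
}
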