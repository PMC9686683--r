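#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

NUCS <- c("A", "C", "G", "T")

# Watson-Crick complement, uppercase only; N maps to N.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

DNA_RESNAMES <- c(
  DA = "A", DC = "C", DG = "G", DT = "T",
  A = "A", C = "C", G = "G", T = "T"
)

# Heavy backbone atoms of a protein residue; all other heavy atoms are
# side chain.  Glycine has no side-chain heavy atom, so it can only
# contribute backbone-class contacts.
PROTEIN_BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

CONTACT_CLASSES <- c("protein-backbone", "protein-side-chain")

#' Complement a vector of nucleotides
#' @param x character vector of single-letter nucleotides (A/C/G/T/N).
#' @return character vector of complements.
#' @keywords internal
complement_base <- function(x) {
  out <- unname(COMPLEMENT[x])
  if (anyNA(out)) {
    abort(paste0(
      "cannot complement non-nucleotide character(s): ",
      paste(unique(x[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Reverse-complement a nucleotide string
#' @param s character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(complement_base(strsplit(toupper(x), "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map a strand-B position to its paired strand-A position (and vice versa)
# under the antiparallel convention A_i <-> B_{2L+1-i}.
paired_position <- function(position, fragment_length) {
  2L * as.integer(fragment_length) + 1L - as.integer(position)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
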