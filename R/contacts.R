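#' Detect and classify protein-DNA contacts
#'
#' Scans all heavy-atom pairs between the protein and DNA sides of a
#' complex.  A contact record (residue, base, class) exists when some heavy
#' atom of the base lies within `cutoff` of some heavy atom of the residue
#' belonging to that class.  The protein backbone atom set is
#' N, CA, C, O, OXT; every other protein heavy atom counts as side chain,
#' so glycine can contribute backbone-class contacts only.  Hydrogens are
#' ignored.
#'
#' @param atoms atom tibble from [read_complex()], containing both protein
#'   and DNA atoms.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5, a
#'   conventional van-der-Waals contact threshold).
#' @param domain_id identifier stored on the resulting records.
#' @param dna_strands named character vector mapping strand labels to DNA
#'   chain identifiers, e.g. `c(A = "C", B = "D")`.  Defaults to the DNA
#'   chains in order of first appearance.
#' @param fragment_length declared fragment length in bp, stored as
#'   metadata (may be `NA`).
#' @return a `dbd_contact_map` tibble (see [contact_map()]) with computed
#'   `min_distance` per record.
#' @export
detect_contacts <- function(atoms, cutoff = 4.5, domain_id = "domain",
                            dna_strands = NULL, fragment_length = NA) {
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  atoms <- atoms[atoms$element != "H", ]
  prot <- atoms[atoms$kind == "protein", ]
  dna <- atoms[atoms$kind == "dna", ]
  if (nrow(prot) == 0L || nrow(dna) == 0L) {
    abort("atom table must contain both protein and dna heavy atoms")
  }
  if (is.null(dna_strands)) {
    chains <- unique(dna$chain)
    if (length(chains) > 2L) {
      abort("more than two DNA chains; supply `dna_strands` explicitly")
    }
    dna_strands <- stats::setNames(chains, c("A", "B")[seq_along(chains)])
  }
  strand_of <- stats::setNames(names(dna_strands), dna_strands)

  pm <- as.matrix(prot[, c("x", "y", "z")])
  dm <- as.matrix(dna[, c("x", "y", "z")])
  # squared cross-distance matrix, protein rows x dna columns
  d2 <- outer(rowSums(pm^2), rowSums(dm^2), `+`) - 2 * tcrossprod(pm, dm)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(contact_map(tibble(
      domain_id = character(), fragment_length = integer(),
      aa = character(), prot_chain = character(), prot_number = integer(),
      base = character(), strand = character(), position = integer(),
      contact_class = character(), min_distance = numeric()
    )))
  }
  p <- prot[hit[, 1L], ]
  d <- dna[hit[, 2L], ]
  records <- tibble(
    domain_id = domain_id,
    fragment_length = as.integer(fragment_length),
    aa = unname(AA3_TO_1[p$residue_name]),
    prot_chain = p$chain,
    prot_number = p$residue_number,
    base = unname(DNA_RESNAMES[d$residue_name]),
    strand = unname(strand_of[d$chain]),
    position = d$residue_number,
    contact_class = ifelse(p$name %in% PROTEIN_BACKBONE_ATOMS,
                           "protein-backbone", "protein-side-chain"),
    min_distance = sqrt(pmax(d2[hit], 0))
  )
  if (anyNA(records$strand)) {
    abort("DNA chain(s) not covered by `dna_strands` mapping")
  }
  contact_map(records)
}

#' Summarize candidate DNA-binding domains
#'
#' Per domain, counts the unique protein residues and the unique DNA base
#' positions appearing across both contact classes.  Counts are invariant
#' to record order and to duplicate records.
#'
#' @param cm a `dbd_contact_map` tibble.
#' @return a tibble with one row per domain: `domain_id`,
#'   `fragment_length`, `n_protein_residues`, `n_dna_contacts`.
#' @export
summarize_domains <- function(cm) {
  cm |>
    as_tibble() |>
    group_by(.data$domain_id) |>
    summarise(
      fragment_length = .data$fragment_length[1L],
      n_protein_residues = n_distinct(
        paste(.data$aa, .data$prot_chain, .data$prot_number)
      ),
      n_dna_contacts = n_distinct(paste(.data$strand, .data$position)),
      .groups = "drop"
    )
}

#' Filter domains by DNA contact count
#'
#' Retains the domains whose dsDNA fragment has at least
#' `min_dna_contacts` DNA contact positions (default 3); the boundary is
#' inclusive.  Input order is preserved.
#'
#' @param summaries domain summary tibble from [summarize_domains()].
#' @param min_dna_contacts minimum number of distinct DNA contact
#'   positions.
#' @return the retained rows of `summaries`.
#' @export
filter_domains <- function(summaries, min_dna_contacts = 3L) {
  if (!is.numeric(min_dna_contacts) || min_dna_contacts < 1) {
    abort("`min_dna_contacts` must be >= 1")
  }
  require_columns(summaries, "n_dna_contacts", "domain summary table")
  summaries[summaries$n_dna_contacts >= min_dna_contacts, ]
}
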