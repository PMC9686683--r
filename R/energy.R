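#' Read a per-position mutational-scan energy file
#'
#' Parses the tab-separated energy dialect written by the in-house tools
#' and by [simulate_energy_file()]: a header line, then one row per
#' (domain, strand, position) with the change in Gibbs free energy
#' (kcal/mol) incurred by mutating that fragment position to each of the
#' four nucleotides.
#'
#' Columns: `domain_id`, `strand` (A or B), `position`, `ddG_A`, `ddG_C`,
#' `ddG_G`, `ddG_T`.  Strand-A rows of a domain must cover positions
#' `1..L` exactly; strand-B rows, when present, cover `L+1..2L`.
#'
#' @param path path to the energy TSV.
#' @return a `dbd_energy_matrix` tibble with columns `domain_id`, `strand`,
#'   `position`, `A`, `C`, `G`, `T`.
#' @export
read_energy_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("domain_id", "strand", "position",
              "ddG_A", "ddG_C", "ddG_G", "ddG_T")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("energy file '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "dbd_parse_error")
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("%s: row %d: non-numeric value in column %s",
                    path, bad[1L] + 1L, col),
            class = "dbd_parse_error")
    }
    v
  }
  m <- tibble(
    domain_id = raw$domain_id,
    strand = raw$strand,
    position = {
      p <- suppressWarnings(as.integer(raw$position))
      bad <- which(is.na(p))
      if (length(bad) > 0L) {
        abort(sprintf("%s: row %d: non-integer position", path, bad[1L] + 1L),
              class = "dbd_parse_error")
      }
      p
    },
    A = num("ddG_A"), C = num("ddG_C"), G = num("ddG_G"), T = num("ddG_T")
  )
  dup <- duplicated(m[, c("domain_id", "strand", "position")])
  if (any(dup)) {
    abort(sprintf("%s: row %d: duplicate (domain, strand, position) row",
                  path, which(dup)[1L] + 1L),
          class = "dbd_parse_error")
  }
  energy_matrix(m)
}

#' Construct an energy matrix
#'
#' @param df data frame with columns `domain_id`, `strand`, `position`,
#'   `A`, `C`, `G`, `T` (delta-delta-G in kcal/mol).
#' @return a validated `dbd_energy_matrix` tibble.
#' @export
energy_matrix <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("domain_id", "strand", "position", NUCS),
                  "energy matrix")
  if (!all(df$strand %in% c("A", "B"))) abort("strand must be \"A\" or \"B\"")
  vals <- as.matrix(df[, NUCS])
  if (!all(is.finite(vals))) abort("all ddG entries must be finite")
  for (dom in unique(df$domain_id)) {
    a <- sort(df$position[df$domain_id == dom & df$strand == "A"])
    L <- length(a)
    if (L < 1L || !identical(a, seq_len(L))) {
      abort(sprintf("domain %s: strand-A positions must be exactly 1..L", dom))
    }
    b <- sort(df$position[df$domain_id == dom & df$strand == "B"])
    if (length(b) > 0L && !identical(b, seq.int(L + 1L, 2L * L))) {
      abort(sprintf("domain %s: strand-B positions must be exactly L+1..2L",
                    dom))
    }
  }
  df <- arrange(df, .data$domain_id, .data$strand, .data$position)
  class(df) <- c("dbd_energy_matrix", class(df))
  df
}

#' Write an energy matrix in the energy TSV dialect
#' @param m a `dbd_energy_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(m, path) {
  out <- tibble(
    domain_id = m$domain_id, strand = m$strand, position = m$position,
    ddG_A = sprintf("%.4f", m$A), ddG_C = sprintf("%.4f", m$C),
    ddG_G = sprintf("%.4f", m$G), ddG_T = sprintf("%.4f", m$T)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

row_argmin <- function(vals, tie_tolerance) {
  # first column within tolerance of the row minimum wins, so ties break
  # lexicographically A < C < G < T (columns are in that order)
  mins <- apply(vals, 1L, min)
  within <- vals <= mins + tie_tolerance
  choice <- NUCS[apply(within, 1L, which.max)]
  list(choice = choice, min = mins, tie = rowSums(within) >= 2L)
}

#' Lowest-free-energy consensus binding sequence
#'
#' Per fragment position, selects the nucleotide with the lowest
#' delta-delta-G (the most stable complex).  Because the per-position
#' energies are additive, the per-position argmin is also the global
#' minimum over all 4^L sequences.  Ties (minima within `tie_tolerance`)
#' are broken A < C < G < T and flagged.
#'
#' When strand-B rows are present, the strand-B minimum at the paired
#' position `2L+1-i` is complemented onto strand A and reconciled with the
#' strand-A choice: on disagreement the nucleotide with the lower of the
#' two minima wins and a warning is emitted; exact ties keep the strand-A
#' choice silently.
#'
#' @param m a `dbd_energy_matrix`.
#' @param tie_tolerance energies within this of the row minimum count as
#'   tied (kcal/mol, default 1e-9).
#' @return a `dbd_consensus` tibble with one row per domain and strand-A
#'   position: `domain_id`, `position`, `nucleotide`, `min_ddg`, `tie`.
#' @seealso [consensus_string()] to collapse to one string per domain.
#' @export
consensus_sequence <- function(m, tie_tolerance = 1e-9) {
  stopifnot_scalar_number(tie_tolerance, "tie_tolerance")
  out <- purrr::map_dfr(unique(m$domain_id), function(dom) {
    a <- m[m$domain_id == dom & m$strand == "A", ]
    a <- a[order(a$position), ]
    L <- nrow(a)
    res <- row_argmin(as.matrix(a[, NUCS]), tie_tolerance)
    choice <- res$choice
    min_ddg <- res$min

    b <- m[m$domain_id == dom & m$strand == "B", ]
    if (nrow(b) > 0L) {
      b <- b[order(b$position), ]
      resb <- row_argmin(as.matrix(b[, NUCS]), tie_tolerance)
      # strand-B row at position p constrains strand-A position 2L+1-p
      a_pos <- paired_position(b$position, L)
      mapped <- complement_base(resb$choice)
      disagreements <- integer()
      for (k in seq_len(nrow(b))) {
        i <- a_pos[k]
        if (mapped[k] == choice[i]) next
        if (abs(resb$min[k] - min_ddg[i]) <= tie_tolerance) next
        disagreements <- c(disagreements, i)
        if (resb$min[k] < min_ddg[i]) {
          choice[i] <- mapped[k]
          min_ddg[i] <- resb$min[k]
        }
      }
      if (length(disagreements) > 0L) {
        warn(sprintf(
          "domain %s: strand A/B consensus disagreement at position(s) %s; kept the lower-energy nucleotide",
          dom, paste(sort(disagreements), collapse = ", ")
        ), class = "dbd_reconciliation_warning")
      }
    }
    tibble(domain_id = dom, position = seq_len(L),
           nucleotide = choice, min_ddg = min_ddg, tie = res$tie)
  })
  class(out) <- c("dbd_consensus", class(out))
  out
}

#' Collapse a consensus table to one string per domain
#' @param cons a `dbd_consensus` tibble.
#' @return named character vector, one consensus string per domain.
#' @export
consensus_string <- function(cons) {
  cons |>
    group_by(.data$domain_id) |>
    arrange(.data$position, .by_group = TRUE) |>
    summarise(seq = paste(.data$nucleotide, collapse = ""),
              .groups = "drop") |>
    (\(d) stats::setNames(d$seq, d$domain_id))()
}

#' GC content of nucleotide sequences
#'
#' Fraction of G + C among non-N characters.
#'
#' @param sequence character vector of sequences over A/C/G/T/N.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' gc_content(c("GCGC", "GCAT"))
#' @export
gc_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    if (nchar(s) == 0L) abort("empty sequence")
    chars <- strsplit(s, "")[[1]]
    if (!all(chars %in% c(NUCS, "N"))) {
      abort("sequence contains characters outside A/C/G/T/N")
    }
    denom <- sum(chars != "N")
    if (denom == 0L) abort("sequence is all N")
    sum(chars %in% c("G", "C")) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Boltzmann weight matrix from an energy matrix
#'
#' Soft alternative to the hard argmin consensus: each strand-A row is
#' mapped to nucleotide probabilities `exp(-beta * ddG) / sum(...)`.
#'
#' @param m a `dbd_energy_matrix`.
#' @param beta inverse temperature in 1/(kcal/mol); larger beta
#'   concentrates mass on the minimum-energy nucleotide.
#' @return a tibble `domain_id`, `position`, `A`, `C`, `G`, `T` with each
#'   row summing to 1.
#' @export
to_weight_matrix <- function(m, beta = 1) {
  stopifnot_scalar_number(beta, "beta", positive = TRUE)
  a <- m[m$strand == "A", ]
  vals <- as.matrix(a[, NUCS])
  e <- exp(-beta * (vals - apply(vals, 1L, min)))
  probs <- e / rowSums(e)
  out <- tibble(domain_id = a$domain_id, position = a$position)
  out[NUCS] <- as_tibble(probs)
  out
}
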