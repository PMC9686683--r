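#' Compile a contact-restricted binding profile
#'
#' Builds the threading query for one domain: the fragment length, the
#' strand-A-mapped DNA contact positions, and the allowed nucleotide set at
#' each contact position.  Non-contact positions are wildcards — only
#' positions shown to directly contact the protein constrain threading.
#'
#' In `strict` mode the allowed set is the single consensus nucleotide; in
#' `threshold` mode it is every nucleotide whose delta-delta-G lies within
#' `epsilon` of the row minimum (`epsilon = 0` reduces to strict).
#' Profiles with fewer than `min_contacts` distinct contact positions are
#' rejected, mirroring the at-least-three-DNA-contact-positions rule used
#' to screen candidate domains.
#'
#' @param consensus a `dbd_consensus` tibble (see [consensus_sequence()]).
#' @param cm a `dbd_contact_map` for the same domain, with positions in the
#'   fragment numbering `1..2L` (strand-B positions are mapped to strand A
#'   via the pairing `i <-> 2L+1-i`).
#' @param domain_id which domain to compile (default: the single domain
#'   shared by both inputs).
#' @param mode `"strict"` or `"threshold"`.
#' @param epsilon allowed-energy band above the row minimum (kcal/mol),
#'   threshold mode only.
#' @param energy `dbd_energy_matrix`, required for threshold mode.
#' @param min_contacts minimum number of distinct contact positions
#'   (default 3).
#' @return a `dbd_binding_profile`: a tibble with one row per contact
#'   position (`position`, `allowed` list-column), with attributes
#'   `domain_id` and `length`.
#' @export
compile_profile <- function(consensus, cm, domain_id = NULL,
                            mode = c("strict", "threshold"), epsilon = 0,
                            energy = NULL, min_contacts = 3L) {
  mode <- match.arg(mode)
  if (is.null(domain_id)) {
    domain_id <- unique(consensus$domain_id)
    if (length(domain_id) != 1L) {
      abort("multiple domains in consensus; supply `domain_id`")
    }
  }
  cons <- consensus[consensus$domain_id == domain_id, ]
  cons <- cons[order(cons$position), ]
  L <- nrow(cons)
  if (L == 0L) abort(sprintf("domain %s absent from consensus", domain_id))
  contacts <- as_tibble(cm)[cm$domain_id == domain_id, ]
  if (nrow(contacts) == 0L) {
    abort(sprintf("domain %s absent from contact map", domain_id))
  }
  if (any(contacts$position > 2L * L)) {
    abort(sprintf(
      "domain %s: contact positions exceed fragment numbering 1..%d",
      domain_id, 2L * L
    ))
  }
  pos_a <- ifelse(contacts$strand == "A", contacts$position,
                  paired_position(contacts$position, L))
  pos_a <- sort(unique(as.integer(pos_a)))
  if (length(pos_a) < min_contacts) {
    abort(sprintf(
      "domain %s has %d DNA contact position(s); at least %d are required for threading",
      domain_id, length(pos_a), min_contacts
    ), class = "dbd_contact_filter_error")
  }

  allowed <- if (mode == "strict" || epsilon == 0) {
    as.list(cons$nucleotide[pos_a])
  } else {
    if (is.null(energy)) abort("threshold mode requires `energy`")
    a <- energy[energy$domain_id == domain_id & energy$strand == "A", ]
    a <- a[order(a$position), ]
    if (nrow(a) != L) {
      abort(sprintf("energy matrix for domain %s does not match length %d",
                    domain_id, L))
    }
    purrr::map(pos_a, function(i) {
      row <- as.numeric(a[i, NUCS])
      NUCS[row <= min(row) + epsilon]
    })
  }

  prof <- tibble(position = pos_a, allowed = allowed)
  attr(prof, "domain_id") <- domain_id
  attr(prof, "length") <- L
  class(prof) <- c("dbd_binding_profile", class(prof))
  prof
}

# allowed sets of the reverse-complemented profile: contact position i maps
# to L+1-i with complemented nucleotides
revcomp_profile_sets <- function(profile) {
  L <- attr(profile, "length")
  tibble(
    position = L + 1L - rev(profile$position),
    allowed = rev(purrr::map(profile$allowed, complement_base))
  )
}

match_windows <- function(chars, positions, allowed, L) {
  n <- length(chars) - L + 1L
  if (n < 1L) return(logical(0))
  ok <- rep(TRUE, n)
  for (k in seq_along(positions)) {
    i <- positions[k]
    ok <- ok & chars[seq.int(i, i + n - 1L)] %in% allowed[[k]]
  }
  ok
}

#' Thread a binding profile through gene sequences
#'
#' Slides the profile over every window of each gene and over the
#' reverse-complemented profile simultaneously, so both the genomic strand
#' and its complement are threaded in one pass.  A window is a hit when
#' every contact position carries an allowed nucleotide; `N` never
#' matches.  A window matching in both orientations (palindromic profile)
#' is one physical site and is counted once, with strand `"±"`.
#'
#' @param genes a tibble with columns `gene_id`, `sequence` (see
#'   [read_genes_fasta()]).
#' @param profile a `dbd_binding_profile`.
#' @return a tibble of hits: `gene_id`, `start` (0-based), `end`
#'   (exclusive), `strand` (`"+"`, `"-"` or `"±"`), `n_matched_contacts`,
#'   `domain_id`; sorted by gene then start.  Genes shorter than the
#'   profile yield no hits.
#' @export
scan_genes <- function(genes, profile) {
  require_columns(genes, c("gene_id", "sequence"), "gene table")
  L <- attr(profile, "length")
  rc <- revcomp_profile_sets(profile)
  purrr::map_dfr(seq_len(nrow(genes)), function(g) {
    chars <- strsplit(toupper(genes$sequence[g]), "")[[1]]
    fwd <- match_windows(chars, profile$position, profile$allowed, L)
    rev_ <- match_windows(chars, rc$position, rc$allowed, L)
    hit <- fwd | rev_
    if (!any(hit)) return(NULL)
    starts <- which(hit) - 1L
    tibble(
      gene_id = genes$gene_id[g],
      start = starts,
      end = starts + L,
      strand = dplyr::case_when(
        fwd[hit] & rev_[hit] ~ "±",
        fwd[hit] ~ "+",
        TRUE ~ "-"
      ),
      n_matched_contacts = nrow(profile),
      domain_id = attr(profile, "domain_id")
    )
  }) |>
    (\(h) if (nrow(h) == 0L) {
      tibble(gene_id = character(), start = integer(), end = integer(),
             strand = character(), n_matched_contacts = integer(),
             domain_id = character())
    } else h)() |>
    arrange(.data$gene_id, .data$start)
}

#' Rank genes by binding-site density
#'
#' Normalizes each gene's compatible-site count by its length and ranks by
#' the resulting density (sites per bp), descending; ties break by
#' `gene_id` ascending.  Genes without hits get zero sites.
#'
#' @param hits hit tibble from [scan_genes()] (possibly several domains —
#'   ranking is within the supplied rows).
#' @param genes gene tibble (`gene_id`, `sequence`); every hit's gene must
#'   appear here.
#' @param top_n number of rows marked as the top table (default 10).
#' @return a `dbd_gene_rank` tibble: `gene_id`, `n_sites`, `length`,
#'   `density`, `rank`, `top` (logical, first `min(top_n, n)` rows).
#' @export
count_and_rank <- function(hits, genes, top_n = 10L) {
  require_columns(genes, c("gene_id", "sequence"), "gene table")
  if (top_n < 1L) abort("`top_n` must be >= 1")
  unknown <- setdiff(unique(hits$gene_id), genes$gene_id)
  if (length(unknown) > 0L) {
    abort(sprintf("hit(s) reference unknown gene_id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  counts <- hits |> count(.data$gene_id, name = "n_sites")
  tab <- tibble(gene_id = genes$gene_id,
                length = nchar(genes$sequence)) |>
    left_join(counts, by = "gene_id") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           density = .data$n_sites / .data$length) |>
    arrange(dplyr::desc(.data$density), .data$gene_id) |>
    mutate(rank = dplyr::row_number(),
           top = .data$rank <= min(top_n, dplyr::n())) |>
    select("gene_id", "n_sites", "length", "density", "rank", "top")
  class(tab) <- c("dbd_gene_rank", class(tab))
  tab
}

#' Read gene sequences from FASTA
#'
#' @param path FASTA path.  Sequences may contain A/C/G/T/N (case
#'   folded to upper); other IUPAC ambiguity codes are rejected.
#' @return tibble `gene_id`, `sequence`, `length`.
#' @export
read_genes_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "gene(s) with characters outside A/C/G/T/N: %s",
      paste(names(set)[bad], collapse = ", ")
    ))
  }
  tibble(gene_id = names(set), sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write gene sequences to FASTA
#' @param genes tibble with `gene_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_fasta <- function(genes, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(genes$sequence,
                                                  genes$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write binding-site hits as BED
#'
#' Six-column BED, 0-based half-open: chrom (= gene id), start, end,
#' name (= domain id), score (= matched contact count), strand.
#' Palindromic `"±"` hits are written with strand `"."`; the companion
#' reader maps `"."` back to `"±"`.
#'
#' @param hits hit tibble from [scan_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$gene_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = ifelse(hits$strand == "±", "*", hits$strand),
    name = hits$domain_id,
    score = hits$n_matched_contacts
  )
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read binding-site hits from BED
#' @param path BED path written by [write_hits_bed()].
#' @return hit tibble (`gene_id`, `start`, `end`, `strand`,
#'   `n_matched_contacts`, `domain_id`).
#' @export
read_hits_bed <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(tibble(gene_id = character(), start = integer(), end = integer(),
                  strand = character(), n_matched_contacts = integer(),
                  domain_id = character()))
  }
  gr <- rtracklayer::import.bed(path)
  strand <- as.character(BiocGenerics::strand(gr))
  tibble(
    gene_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand == "*", "±", strand),
    n_matched_contacts = as.integer(gr$score),
    domain_id = as.character(gr$name)
  ) |>
    arrange(.data$gene_id, .data$start)
}

#' Write / read the gene rank table
#' @param table a `dbd_gene_rank` tibble.
#' @param path output path.
#' @return `path` (writer, invisibly) or the rank tibble (reader).
#' @export
write_rank_tsv <- function(table, path) {
  out <- table
  out$density <- sprintf("%.10g", out$density)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rank_tsv
#' @export
read_rank_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ciidil", progress = FALSE)
  class(tab) <- c("dbd_gene_rank", class(tab))
  tab
}
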