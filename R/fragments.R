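#' Build a fragment cloud from an atom table
#'
#' A docked dsDNA backbone fragment is represented by its base-pair list
#' and the coordinates of the four terminal backbone atoms (the 5' P and
#' 3' O3' of each strand).  A cloud is a list of such fragments positioned
#' in the protein's coordinate frame.
#'
#' @param atoms atom tibble (from [read_complex()]) holding the DNA chains
#'   of the docked fragments.
#' @param fragments a data frame with columns `fragment_id`, `chain_a`,
#'   `chain_b` naming, per fragment, the PDB chains carrying strand A and
#'   strand B.
#' @return a `dbd_fragment_cloud`: a list of fragments, each a list with
#'   `fragment_id`, `base_pairs` (tibble `index`, `resno_a`, `resno_b`) and
#'   `terminal` (tibble `strand`, `end`, `x`, `y`, `z`).
#' @export
as_fragment_cloud <- function(atoms, fragments) {
  require_columns(fragments, c("fragment_id", "chain_a", "chain_b"),
                  "fragment chain table")
  dna <- atoms[atoms$kind == "dna", ]

  strand_info <- function(chain) {
    s <- dna[dna$chain == chain, ]
    if (nrow(s) == 0L) abort(sprintf("no DNA atoms on chain %s", chain))
    resnos <- sort(unique(s$residue_number))
    pick <- function(resno, atom_name) {
      a <- s[s$residue_number == resno & s$name == atom_name, ]
      if (nrow(a) == 0L) {
        abort(sprintf(
          "chain %s residue %d lacks backbone atom %s", chain, resno, atom_name
        ))
      }
      a[1L, c("x", "y", "z")]
    }
    list(
      resnos = resnos,
      p5 = pick(resnos[1L], "P"),
      o3 = pick(resnos[length(resnos)], "O3'")
    )
  }

  cloud <- purrr::pmap(fragments, function(fragment_id, chain_a, chain_b, ...) {
    a <- strand_info(chain_a)
    b <- strand_info(chain_b)
    if (length(a$resnos) != length(b$resnos)) {
      abort(sprintf("fragment %s: strands have unequal length", fragment_id))
    }
    n <- length(a$resnos)
    list(
      fragment_id = as.character(fragment_id),
      base_pairs = tibble(
        index = seq_len(n),
        resno_a = a$resnos,
        resno_b = rev(b$resnos)
      ),
      terminal = tibble(
        strand = c("A", "A", "B", "B"),
        end = c("5p", "3p", "5p", "3p"),
        dplyr::bind_rows(a$p5, a$o3, b$p5, b$o3)
      )
    )
  })
  structure(cloud, class = "dbd_fragment_cloud")
}

fragment_terminal <- function(frag, strand, end) {
  t <- frag$terminal
  as.numeric(t[t$strand == strand & t$end == end, c("x", "y", "z")])
}

#' Fragment length in base pairs
#' @param frag a fragment from a `dbd_fragment_cloud`.
#' @return integer number of base pairs.
#' @export
fragment_bp <- function(frag) nrow(frag$base_pairs)

# f's right duplex end (A 3', B 5') joins g's left end (A 5', B 3') when
# both backbone gaps (O3' -> P on each strand) are within max_gap.
joinable <- function(f, g, max_gap) {
  gap_a <- sqrt(sum((fragment_terminal(f, "A", "3p") -
                       fragment_terminal(g, "A", "5p"))^2))
  gap_b <- sqrt(sum((fragment_terminal(g, "B", "3p") -
                       fragment_terminal(f, "B", "5p"))^2))
  if (gap_a <= max_gap && gap_b <= max_gap) gap_a else NA_real_
}

merge_chain <- function(frags) {
  if (length(frags) == 1L) return(frags[[1L]])
  bp <- purrr::map_dfr(frags, "base_pairs")
  bp$index <- seq_len(nrow(bp))
  first <- frags[[1L]]
  last <- frags[[length(frags)]]
  pick <- function(frag, strand, end) {
    t <- frag$terminal
    t[t$strand == strand & t$end == end, ]
  }
  list(
    fragment_id = paste(purrr::map_chr(frags, "fragment_id"), collapse = "+"),
    base_pairs = bp,
    terminal = dplyr::bind_rows(
      pick(first, "A", "5p"), pick(last, "A", "3p"),
      pick(last, "B", "5p"), pick(first, "B", "3p")
    )
  )
}

#' Chain short dsDNA backbone fragments into extended fragments
#'
#' Searches the cloud for continuous stretches of short dsDNA backbones:
#' two fragments are linked when the 3' terminal O3' of one strand lies
#' within `max_gap` of the 5' terminal P of the next on both strands with
#' consistent antiparallel directionality.  Linked runs are merged into
#' maximal extended fragments, preserving base-pair order; the output is a
#' partition of the input base pairs.
#'
#' @param cloud a `dbd_fragment_cloud` (see [as_fragment_cloud()]).
#' @param max_gap maximum terminal-atom gap in Angstrom (default 2.0; a
#'   covalent O3'-P bond is about 1.6 Angstrom).
#' @return a `dbd_fragment_cloud` of maximal extended fragments.
#' @export
chain_fragments <- function(cloud, max_gap = 2.0) {
  stopifnot_scalar_number(max_gap, "max_gap", positive = TRUE)
  n <- length(cloud)
  if (n <= 1L) return(cloud)

  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    gaps <- vapply(seq_len(n), function(j) {
      if (i == j) return(NA_real_)
      joinable(cloud[[i]], cloud[[j]], max_gap)
    }, numeric(1))
    if (any(!is.na(gaps))) succ[i] <- which.min(gaps)
  }
  # a fragment can accept only one predecessor: keep the nearest
  for (j in seq_len(n)) {
    preds <- which(succ == j)
    if (length(preds) > 1L) {
      gaps <- vapply(preds, function(i) joinable(cloud[[i]], cloud[[j]], max_gap),
                     numeric(1))
      succ[preds[-which.min(gaps)]] <- NA_integer_
    }
  }

  starts <- setdiff(which(!is.na(succ) | TRUE), succ[!is.na(succ)])
  chains <- list()
  visited <- rep(FALSE, n)
  for (s in starts) {
    chain <- integer()
    i <- s
    while (!is.na(i)) {
      if (visited[i]) abort("cyclic fragment chaining detected",
                            class = "dbd_cycle_error")
      visited[i] <- TRUE
      chain <- c(chain, i)
      i <- succ[i]
    }
    chains[[length(chains) + 1L]] <- chain
  }
  if (!all(visited)) {
    abort("cyclic fragment chaining detected", class = "dbd_cycle_error")
  }
  structure(
    purrr::map(chains, function(idx) merge_chain(cloud[idx])),
    class = "dbd_fragment_cloud"
  )
}
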