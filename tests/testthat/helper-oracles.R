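# Independent brute-force oracles. These deliberately re-derive each result
# by the most literal method available (all-pairs loops, per-window checks,
# exhaustive enumeration) and stay independent of the package's vectorized
# implementations.

NUCS4 <- c("A", "C", "G", "T")
BB_ATOMS <- c("N", "CA", "C", "O", "OXT")

# all-pairs heavy-atom distance scan
oracle_contacts <- function(atoms, cutoff, dna_strands) {
  atoms <- atoms[atoms$element != "H", ]
  prot <- atoms[atoms$kind == "protein", ]
  dna <- atoms[atoms$kind == "dna", ]
  out <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(dna))) {
      d <- sqrt((prot$x[i] - dna$x[j])^2 + (prot$y[i] - dna$y[j])^2 +
                  (prot$z[i] - dna$z[j])^2)
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          prot_chain = prot$chain[i], prot_number = prot$residue_number[i],
          strand = names(dna_strands)[match(dna$chain[j], dna_strands)],
          position = dna$residue_number[j],
          contact_class = if (prot$name[i] %in% BB_ATOMS) {
            "protein-backbone"
          } else "protein-side-chain",
          dist = d
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(prot_chain = character(), prot_number = integer(),
                      strand = character(), position = integer(),
                      contact_class = character(), min_distance = numeric()))
  }
  df <- do.call(rbind, out)
  agg <- stats::aggregate(
    dist ~ prot_chain + prot_number + strand + position + contact_class,
    data = df, FUN = min
  )
  names(agg)[names(agg) == "dist"] <- "min_distance"
  agg[order(agg$prot_chain, agg$prot_number, agg$strand, agg$position,
            agg$contact_class), ]
}

contact_key <- function(df) {
  sort(paste(df$prot_chain, df$prot_number, df$strand, df$position,
             df$contact_class))
}

# naive per-window scan of both orientations
oracle_scan <- function(sequence, positions, allowed, L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  len <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  hits <- list()
  if (len < L) return(data.frame(start = integer(), strand = character()))
  for (s in 0:(len - L)) {
    fwd <- TRUE
    for (k in seq_along(positions)) {
      if (!chars[s + positions[k]] %in% allowed[[k]]) { fwd <- FALSE; break }
    }
    rev_ <- TRUE
    for (k in seq_along(positions)) {
      # revcomp(window)[i] = comp(window[L+1-i]) must be allowed at i
      if (!comp[[chars[s + L + 1L - positions[k]]]] %in% allowed[[k]]) {
        rev_ <- FALSE; break
      }
    }
    if (fwd || rev_) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s,
        strand = if (fwd && rev_) "±" else if (fwd) "+" else "-"
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), strand = character()))
  }
  do.call(rbind, hits)
}

# exhaustive minimum over all 4^L sequences of the separable energy sum,
# ties resolved by alphabetical sequence order
oracle_consensus <- function(vals) {
  L <- nrow(vals)
  grid <- do.call(expand.grid,
                  c(rep(list(NUCS4), L), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reorder so column 1 is the
  # slowest (alphabetical order of the pasted string = row order)
  grid <- grid[, rev(seq_len(L)), drop = FALSE]
  seqs <- apply(grid, 1L, paste, collapse = "")
  energies <- apply(grid, 1L, function(nucs) {
    sum(vals[cbind(seq_len(L), match(nucs, NUCS4))])
  })
  ord <- order(energies, seqs)
  seqs[ord[1L]]
}

random_atom_fixture <- function(n_res = 8L, n_bases = 6L, box = 15) {
  prot <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    nm <- c("N", "CA", "C", "O", "CB")
    data.frame(
      element = substr(nm, 1L, 1L), name = nm,
      x = runif(5, 0, box), y = runif(5, 0, box), z = runif(5, 0, box),
      residue_name = "ALA", chain = "A", residue_number = r,
      kind = "protein"
    )
  }))
  dna <- do.call(rbind, lapply(seq_len(n_bases), function(b) {
    nm <- c("N1", "C2", "P")
    strand <- if (b %% 2L == 0L) "C" else "B"
    data.frame(
      element = substr(nm, 1L, 1L), name = nm,
      x = runif(3, 0, box), y = runif(3, 0, box), z = runif(3, 0, box),
      residue_name = sample(c("DA", "DC", "DG", "DT"), 1L),
      chain = strand, residue_number = b, kind = "dna"
    )
  }))
  tibble::as_tibble(rbind(prot, dna))
}

random_profile <- function(L = NULL) {
  L <- L %||% sample(4:12, 1L)
  k <- sample(3:min(5L, L), 1L)
  positions <- sort(sample(seq_len(L), k))
  allowed <- lapply(seq_len(k), function(i) {
    sample(NUCS4, sample(1:2, 1L))
  })
  prof <- tibble::tibble(position = positions, allowed = allowed)
  attr(prof, "domain_id") <- "rand"
  attr(prof, "length") <- L
  class(prof) <- c("dbd_binding_profile", class(prof))
  prof
}

random_gene <- function(len, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(NUCS4, len, replace = TRUE, prob = probs), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ho1_contacts_path <- function() {
  system.file("extdata", "ho1_dbd_contacts.tsv", package = "dbdthreadr")
}
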