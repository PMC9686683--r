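AA1_TO_3 <- stats::setNames(names(AA3_TO_1), AA3_TO_1)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults describe
#' a desk-scale study: 20 genes of 1-5 kb at mammalian-like background GC
#' (0.41), a 10-bp binding fragment with 5 contact positions, and energy
#' files whose designated minimum sits a 1.0 kcal/mol margin below the
#' alternatives with 0.1 kcal/mol noise (margin >= 3 x noise, so the
#' designated consensus is always recoverable).
#'
#' The `seed` is split per artifact by a fixed derivation (`seed + 1`
#' genes, `seed + 2` energies, `seed + 3` complex), so partial
#' regeneration is stable.  A fixed seed yields byte-identical outputs.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes.
#' @param gene_lengths integer vector of gene lengths in bp, recycled to
#'   `n_genes`; `NULL` draws lengths uniformly from 1000-5000 bp.
#' @param gc_background background GC fraction in \[0, 1\]; bases are drawn
#'   i.i.d. with P(G) = P(C) = `gc_background / 2`.
#' @param planted_sites_per_gene sites planted per gene (scalar or length
#'   `n_genes`); `NULL` draws 0-4 per gene.
#' @param profile_spec list with `length` (fragment bp), `contact_positions`
#'   (strand-A positions), `consensus` (length-L string).
#' @param complex_spec data frame of intended contacts (`domain_id`,
#'   `residue`, `base`, `contact_class`, `distance`); `NULL` uses a
#'   default layout consistent with `profile_spec`.
#' @param noise_ddg standard deviation of delta-delta-G perturbations
#'   (kcal/mol).
#' @param margin_ddg energy margin separating the designated minimum from
#'   the other nucleotides (kcal/mol).
#' @param zero_background if `TRUE`, background sequence is rewritten until
#'   it contains no spurious profile matches, so hit counts equal planted
#'   counts exactly.
#' @param include_strand_b emit strand-B energy rows as the complemented
#'   copy of strand A.
#' @return a `dbd_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 20L,
                              gene_lengths = NULL,
                              gc_background = 0.41,
                              planted_sites_per_gene = NULL,
                              profile_spec = list(
                                length = 10L,
                                contact_positions = c(1L, 3L, 5L, 8L, 10L),
                                consensus = "GGCCAATTGG"
                              ),
                              complex_spec = NULL,
                              noise_ddg = 0.1,
                              margin_ddg = 1.0,
                              zero_background = FALSE,
                              include_strand_b = FALSE) {
  if (gc_background < 0 || gc_background > 1) {
    abort("`gc_background` must lie in [0, 1]")
  }
  if (nchar(profile_spec$consensus) != profile_spec$length) {
    abort("profile consensus length must equal the fragment length")
  }
  if (any(profile_spec$contact_positions < 1L |
            profile_spec$contact_positions > profile_spec$length)) {
    abort("contact positions must lie in 1..L")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_lengths = gene_lengths, gc_background = gc_background,
    planted_sites_per_gene = planted_sites_per_gene,
    profile_spec = profile_spec,
    complex_spec = complex_spec %||% default_complex_spec(profile_spec),
    noise_ddg = noise_ddg, margin_ddg = margin_ddg,
    zero_background = zero_background,
    include_strand_b = include_strand_b
  ), class = "dbd_sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intended contact list consistent with the profile: side-chain contacts on
# most strand-A contact positions plus one backbone contact through the
# strand-B partner of the last contact position.
default_complex_spec <- function(profile_spec) {
  L <- profile_spec$length
  pos <- profile_spec$contact_positions
  cons <- strsplit(profile_spec$consensus, "")[[1]]
  residues <- c("K", "R", "E", "Q", "R", "T", "I", "S", "Y", "F")
  n <- length(pos)
  res_tok <- paste0(residues[seq_len(n)], "A", 110L + seq_len(n))
  base_tok <- character(n)
  cls <- rep("protein-side-chain", n)
  for (k in seq_len(n)) {
    if (k == n) {
      # express the last contact through strand B to exercise the pairing
      bpos <- paired_position(pos[k], L)
      base_tok[k] <- paste0(tolower(complement_base(cons[pos[k]])), "B", bpos)
      cls[k] <- "protein-backbone"
    } else {
      base_tok[k] <- paste0(tolower(cons[pos[k]]), "A", pos[k])
    }
  }
  tibble(domain_id = "DBD-S1", residue = res_tok, base = base_tok,
         contact_class = cls, distance = 3.0)
}

profile_from_spec <- function(spec) {
  cons <- strsplit(spec$consensus, "")[[1]]
  prof <- tibble(position = sort(unique(as.integer(spec$contact_positions))),
                 allowed = as.list(cons[sort(unique(spec$contact_positions))]))
  attr(prof, "domain_id") <- "DBD-S1"
  attr(prof, "length") <- as.integer(spec$length)
  class(prof) <- c("dbd_binding_profile", class(prof))
  prof
}

draw_background <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(NUCS, n, replace = TRUE, prob = probs[NUCS])
}

#' Simulate a gene set with planted binding sites
#'
#' Background bases are drawn i.i.d. with the configured GC fraction;
#' consensus copies (forward or reverse-complement) are inserted at
#' recorded, non-overlapping coordinates at least L away from the
#' sequence ends.  With `zero_background = TRUE`, any accidental
#' background match is rewritten (at a position outside all planted
#' sites) until the only matches are the planted ones.
#'
#' @param cfg a `dbd_sim_config`.
#' @return list with `genes` (tibble `gene_id`, `sequence`, `length`) and
#'   `manifest` (tibble `gene_id`, `start`, `end`, `strand` of planted
#'   sites, 0-based half-open).
#' @export
simulate_genes <- function(cfg) {
  set.seed(cfg$seed + 1L)
  L <- cfg$profile_spec$length
  cons <- cfg$profile_spec$consensus
  lens <- cfg$gene_lengths %||% sample(1000:5000, cfg$n_genes, replace = TRUE)
  lens <- as.integer(rep_len(lens, cfg$n_genes))
  plants <- cfg$planted_sites_per_gene %||%
    sample(0:4, cfg$n_genes, replace = TRUE)
  plants <- as.integer(rep_len(plants, cfg$n_genes))

  ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  seqs <- character(cfg$n_genes)
  manifest <- list()

  for (g in seq_len(cfg$n_genes)) {
    len <- lens[g]
    k <- plants[g]
    if (k > 0L && (len - 2L * L) < k * L) {
      abort(sprintf("gene %s (%d bp) too short for %d planted sites",
                    ids[g], len, k))
    }
    chars <- draw_background(len, cfg$gc_background)
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < k) {
      s <- sample(L:(len - 2L * L), 1L)
      if (all(abs(s - starts) >= L)) starts <- c(starts, s)
      tries <- tries + 1L
      if (tries > 10000L) {
        abort(sprintf("could not place %d non-overlapping sites in gene %s",
                      k, ids[g]))
      }
    }
    starts <- sort(starts)
    strands <- if (k > 0L) sample(c("+", "-"), k, replace = TRUE) else character(0)
    for (j in seq_along(starts)) {
      ins <- if (strands[j] == "+") cons else revcomp(cons)
      chars[(starts[j] + 1L):(starts[j] + L)] <- strsplit(ins, "")[[1]]
    }
    seqs[g] <- paste(chars, collapse = "")
    if (k > 0L) {
      manifest[[length(manifest) + 1L]] <- tibble(
        gene_id = ids[g], start = starts, end = starts + L, strand = strands
      )
    }
  }

  genes <- tibble(gene_id = ids, sequence = seqs, length = lens)
  manifest <- if (length(manifest) > 0L) dplyr::bind_rows(manifest) else {
    tibble(gene_id = character(), start = integer(), end = integer(),
           strand = character())
  }
  if (cfg$zero_background) {
    genes <- scrub_background(genes, manifest, profile_from_spec(cfg$profile_spec))
  }
  list(genes = genes, manifest = manifest)
}

# Rewrite spurious (non-planted) matches by mutating one contact position
# outside every planted interval until the scan is clean.
scrub_background <- function(genes, manifest, profile) {
  L <- attr(profile, "length")
  rc <- revcomp_profile_sets(profile)
  for (round in seq_len(100L)) {
    hits <- scan_genes(genes, profile)
    spurious <- anti_join(hits, manifest,
                          by = c("gene_id", "start"))
    if (nrow(spurious) == 0L) return(genes)
    for (h in seq_len(nrow(spurious))) {
      gid <- spurious$gene_id[h]
      s <- spurious$start[h]
      gi <- match(gid, genes$gene_id)
      chars <- strsplit(genes$sequence[gi], "")[[1]]
      planted <- manifest[manifest$gene_id == gid, ]
      # candidate gene indices: contact positions of either orientation
      cand <- sort(unique(c(s + profile$position, s + rc$position)))
      cand <- cand[purrr::map_lgl(cand, function(ix) {
        !any(ix > planted$start & ix <= planted$end)
      })]
      if (length(cand) == 0L) next
      ix <- cand[1L]
      i_f <- ix - s                       # profile position, forward frame
      banned <- unlist(c(
        profile$allowed[match(i_f, profile$position)],
        rc$allowed[match(i_f, rc$position)]
      ))
      repl <- setdiff(NUCS, c(banned, chars[ix]))
      if (length(repl) == 0L) next
      chars[ix] <- repl[1L]
      genes$sequence[gi] <- paste(chars, collapse = "")
    }
  }
  abort("failed to scrub background matches after 100 rounds")
}

#' Simulate a mutational-scan energy file
#'
#' Writes per-position delta-delta-G rows in which the designated
#' (consensus) nucleotide holds the row minimum, separated from the other
#' three nucleotides by at least `margin_ddg` plus non-negative noise.
#' Running [consensus_sequence()] on the output recovers the designated
#' string exactly whenever `margin_ddg > 0`.
#'
#' @param cfg a `dbd_sim_config`.
#' @param path optional output path; when supplied the energy TSV is
#'   written there.
#' @return list with `energy` (a `dbd_energy_matrix`) and `manifest`
#'   (tibble `domain_id`, `position`, `nucleotide` of designated minima).
#' @export
simulate_energy_file <- function(cfg, path = NULL) {
  set.seed(cfg$seed + 2L)
  L <- cfg$profile_spec$length
  cons <- strsplit(cfg$profile_spec$consensus, "")[[1]]
  rows <- purrr::map_dfr(seq_len(L), function(i) {
    v_min <- stats::rnorm(1, mean = -1, sd = cfg$noise_ddg)
    vals <- v_min + cfg$margin_ddg +
      abs(stats::rnorm(4, mean = 0, sd = cfg$noise_ddg))
    names(vals) <- NUCS
    vals[cons[i]] <- v_min
    tibble(domain_id = "DBD-S1", strand = "A", position = i,
           A = vals[["A"]], C = vals[["C"]], G = vals[["G"]], T = vals[["T"]])
  })
  if (cfg$include_strand_b) {
    b <- rows
    b$strand <- "B"
    b$position <- paired_position(rows$position, L)
    # complemented copy: ddG_B(p, n) = ddG_A(2L+1-p, comp(n))
    b[NUCS] <- rows[complement_base(NUCS)]
    rows <- dplyr::bind_rows(rows, b)
  }
  m <- energy_matrix(rows)
  if (!is.null(path)) write_energy_tsv(m, path)
  list(
    energy = m,
    manifest = tibble(domain_id = "DBD-S1", position = seq_len(L),
                      nucleotide = cons)
  )
}

#' Simulate a protein-dsDNA complex structure with designed contacts
#'
#' Places minimal heavy-atom residues and bases so that each intended
#' (residue, base, class) pair has exactly one atom pair at its target
#' distance while every unintended protein-DNA atom pair is far beyond the
#' contact cutoff.  Backbone-class contacts are realized through a
#' backbone atom (N, CA, C, O, OXT), side-chain contacts through a
#' side-chain carbon/nitrogen; unused mandatory atoms are parked in
#' separate protein and DNA regions.  [detect_contacts()] on the output
#' reproduces the intended contact list exactly.
#'
#' @param cfg a `dbd_sim_config` (uses `complex_spec`).
#' @param path optional PDB output path.
#' @return list with `atoms` (atom tibble), `dna_strands` (named chain
#'   mapping), and `manifest` (the intended contacts as a
#'   `dbd_contact_map`).
#' @export
simulate_complex <- function(cfg, path = NULL) {
  spec <- as_tibble(cfg$complex_spec)
  require_columns(spec, c("domain_id", "residue", "base", "contact_class"),
                  "complex spec")
  if (!"distance" %in% names(spec)) spec$distance <- 3.0
  if (anyDuplicated(spec[, c("residue", "base", "contact_class")])) {
    abort("duplicate (residue, base, class) in complex spec")
  }
  res <- parse_residue_token(spec$residue)
  bas <- parse_base_token(spec$base)
  if (any(res$aa == "G" & spec$contact_class == "protein-side-chain")) {
    abort("infeasible geometry: glycine has no side-chain heavy atom")
  }

  prot_chains <- unique(res$prot_chain)
  free <- setdiff(LETTERS, prot_chains)
  dna_strands <- c(A = free[1L], B = free[2L])

  sc_pool <- c("CB", "CG", "CD", "CE", "CZ", "CG1", "CD1", "CD2", "NZ",
               "OD1", "OE1", "NE")
  bb_pool <- PROTEIN_BACKBONE_ATOMS
  base_pool <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

  n <- nrow(spec)
  slot <- function(k) c(25 * ((k - 1) %% 40), 0, 25 * ((k - 1) %/% 40))

  res_key <- paste(res$prot_chain, res$prot_number)
  base_key <- paste(bas$strand, bas$position)

  atoms <- list()
  add_atom <- function(name, xyz, resname, chain, resno, kind) {
    atoms[[length(atoms) + 1L]] <<- tibble(
      element = substr(name, 1L, 1L), name = name,
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      residue_name = resname, chain = chain,
      residue_number = as.integer(resno), kind = kind
    )
  }

  park_p <- 0L
  park_d <- 0L
  # protein residues
  for (rk in unique(res_key)) {
    idx <- which(res_key == rk)
    r <- res[idx[1L], ]
    resname <- AA1_TO_3[[r$aa]]
    bb_ct <- idx[spec$contact_class[idx] == "protein-backbone"]
    sc_ct <- idx[spec$contact_class[idx] == "protein-side-chain"]
    if (length(bb_ct) > length(bb_pool)) {
      abort(sprintf("infeasible geometry: residue %s needs %d backbone atoms",
                    spec$residue[idx[1L]], length(bb_ct)))
    }
    if (length(sc_ct) > length(sc_pool)) {
      abort(sprintf("infeasible geometry: residue %s needs %d side-chain atoms",
                    spec$residue[idx[1L]], length(sc_ct)))
    }
    used_bb <- bb_pool[seq_along(bb_ct)]
    for (j in seq_along(bb_ct)) {
      add_atom(used_bb[j], slot(bb_ct[j]), resname, r$prot_chain,
               r$prot_number, "protein")
    }
    for (j in seq_along(sc_ct)) {
      add_atom(sc_pool[j], slot(sc_ct[j]), resname, r$prot_chain,
               r$prot_number, "protein")
    }
    # park the mandatory backbone atoms not used for a contact
    for (a in setdiff(c("N", "CA", "C", "O"), used_bb)) {
      park_p <- park_p + 1L
      add_atom(a, c(25 * park_p, 1000, 0), resname, r$prot_chain,
               r$prot_number, "protein")
    }
  }
  # DNA bases
  for (bk in unique(base_key)) {
    idx <- which(base_key == bk)
    b <- bas[idx[1L], ]
    resname <- paste0("D", b$base)
    chain <- dna_strands[[b$strand]]
    if (length(idx) > length(base_pool)) {
      abort(sprintf("infeasible geometry: base %s needs %d atoms",
                    spec$base[idx[1L]], length(idx)))
    }
    for (j in seq_along(idx)) {
      k <- idx[j]
      xyz <- slot(k) + c(spec$distance[k], 0, 0)
      add_atom(base_pool[j], xyz, resname, chain, b$position, "dna")
    }
    park_d <- park_d + 1L
    add_atom("P", c(25 * park_d, -1000, 0), resname, chain, b$position, "dna")
  }

  atoms <- dplyr::bind_rows(atoms)
  if (!is.null(path)) write_complex(atoms, path)
  manifest <- contact_map(tibble(
    domain_id = spec$domain_id,
    fragment_length = as.integer(cfg$profile_spec$length),
    res, bas[, c("base", "strand", "position")],
    contact_class = spec$contact_class,
    min_distance = spec$distance
  ))
  list(atoms = atoms, dna_strands = dna_strands, manifest = manifest)
}

#' Simulate a docked dsDNA backbone fragment cloud
#'
#' Lays idealized backbone fragments along the x axis (3.4 Angstrom rise)
#' with antiparallel strands, exposing only the atoms fragment chaining
#' needs (per-nucleotide P and O3').  Consecutive fragments are separated
#' by a 1.6 Angstrom O3'-P gap (the covalent bond length) unless an
#' `x_offset` pushes them apart.
#'
#' @param n_fragments number of fragments.
#' @param bp base pairs per fragment.
#' @param x_offsets numeric vector of per-fragment x shifts (default 0:
#'   all fragments chainable into one).
#' @return list with `cloud` (a `dbd_fragment_cloud`) and `atoms` (the
#'   underlying DNA atom tibble).
#' @export
simulate_fragment_cloud <- function(n_fragments = 2L, bp = 5L,
                                    x_offsets = NULL) {
  x_offsets <- rep_len(x_offsets %||% 0, n_fragments)
  free <- LETTERS
  atoms <- list()
  chain_tbl <- list()
  for (f in seq_len(n_fragments)) {
    ca <- free[2L * f - 1L]
    cb <- free[2L * f]
    idx0 <- (f - 1L) * bp
    for (j in seq_len(bp)) {
      gx <- 3.4 * (idx0 + j) + x_offsets[f]
      atoms[[length(atoms) + 1L]] <- tibble(
        element = c("P", "O", "P", "O"),
        name = c("P", "O3'", "P", "O3'"),
        x = c(gx, gx + 1.8, gx, gx - 1.8),
        y = c(1, 1, -1, -1),
        z = 0,
        residue_name = "DA",
        chain = c(ca, ca, cb, cb),
        # strand B runs 3'->5' left to right: ascending resno = 5'->3'
        # means right to left
        residue_number = as.integer(c(j, j, bp - j + 1L, bp - j + 1L)),
        kind = "dna"
      )
    }
    chain_tbl[[f]] <- tibble(fragment_id = sprintf("frag%02d", f),
                             chain_a = ca, chain_b = cb)
  }
  atoms <- dplyr::bind_rows(atoms)
  list(cloud = as_fragment_cloud(atoms, dplyr::bind_rows(chain_tbl)),
       atoms = atoms)
}

#' Generate the full synthetic input bundle
#'
#' Writes `genes.fasta`, `energies.tsv`, `complex.pdb`, `contacts.tsv`
#' (the intended contact list) and `manifest.json` (ground truth:
#' planted site coordinates, designated consensus, intended contacts,
#' DNA chain mapping) under `out_dir`.
#'
#' @param cfg a `dbd_sim_config`.
#' @param out_dir output directory (created if needed).
#' @return list of paths plus the in-memory truth objects, invisibly.
#' @export
simulate_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  genes <- simulate_genes(cfg)
  write_genes_fasta(genes$genes, p("genes.fasta"))
  energy <- simulate_energy_file(cfg, p("energies.tsv"))
  cplx <- simulate_complex(cfg, p("complex.pdb"))
  write_contact_table(cplx$manifest, p("contacts.tsv"))
  truth <- list(
    config = cfg[c("seed", "n_genes", "gc_background", "noise_ddg",
                   "margin_ddg", "zero_background")],
    profile_spec = cfg$profile_spec,
    dna_strands = as.list(cplx$dna_strands),
    planted_sites = genes$manifest,
    designated_consensus = cfg$profile_spec$consensus,
    intended_contacts = as_tibble(cplx$manifest)
  )
  jsonlite::write_json(truth, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    genes_fasta = p("genes.fasta"), energies_tsv = p("energies.tsv"),
    complex_pdb = p("complex.pdb"), contacts_tsv = p("contacts.tsv"),
    manifest_json = p("manifest.json"),
    genes = genes, energy = energy, complex = cplx
  ))
}
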