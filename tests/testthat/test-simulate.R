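test_that("the same seed gives byte-identical bundles; seeds differ", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 9, n_genes = 5L, gene_lengths = 800L,
                           planted_sites_per_gene = 2L)
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in c("genes.fasta", "energies.tsv", "complex.pdb", "contacts.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  simulate_bundle(simulation_config(seed = 10, n_genes = 5L,
                                    gene_lengths = 800L,
                                    planted_sites_per_gene = 2L), d3)
  expect_false(identical(readLines(file.path(d1, "genes.fasta")),
                         readLines(file.path(d3, "genes.fasta"))))
})

test_that("all planted site coordinates are recovered by the scanner", {
  cfg <- simulation_config(seed = 1, n_genes = 1L, gene_lengths = 500L,
                           planted_sites_per_gene = 3L)
  sim <- simulate_genes(cfg)
  prof <- dbdthreadr:::profile_from_spec(cfg$profile_spec)
  hits <- scan_genes(sim$genes, prof)
  expect_gte(nrow(hits), 3L)
  planted_keys <- paste(sim$manifest$gene_id, sim$manifest$start)
  expect_true(all(planted_keys %in% paste(hits$gene_id, hits$start)))
})

test_that("zero-background genes contain exactly the planted matches", {
  cfg <- simulation_config(seed = 4, n_genes = 8L, zero_background = TRUE)
  sim <- simulate_genes(cfg)
  prof <- dbdthreadr:::profile_from_spec(cfg$profile_spec)
  # verify with the independent naive oracle, not the package scanner
  total <- 0L
  for (g in seq_len(nrow(sim$genes))) {
    o <- oracle_scan(sim$genes$sequence[g], prof$position, prof$allowed,
                     attr(prof, "length"))
    total <- total + nrow(o)
    planted <- sim$manifest[sim$manifest$gene_id == sim$genes$gene_id[g], ]
    expect_setequal(o$start, planted$start)
  }
  expect_identical(total, nrow(sim$manifest))
})

test_that("planted sites sit clear of the sequence ends and of each other", {
  cfg <- simulation_config(seed = 12, n_genes = 10L,
                           planted_sites_per_gene = 3L)
  sim <- simulate_genes(cfg)
  L <- cfg$profile_spec$length
  m <- dplyr::left_join(sim$manifest,
                        sim$genes[, c("gene_id", "length")], by = "gene_id")
  expect_true(all(m$start >= L & m$end <= m$length - L))
  by_gene <- split(m, m$gene_id)
  for (g in by_gene) {
    s <- sort(g$start)
    if (length(s) > 1L) expect_true(all(diff(s) >= L))
  }
})

test_that("degenerate compositions behave: pure-GC background, short genes error", {
  cfg <- simulation_config(seed = 2, n_genes = 1L, gene_lengths = 300L,
                           gc_background = 1.0, planted_sites_per_gene = 0L)
  sim <- simulate_genes(cfg)
  expect_true(grepl("^[GC]+$", sim$genes$sequence))
  expect_equal(gc_content(sim$genes$sequence), 1.0)

  too_short <- simulation_config(seed = 2, n_genes = 1L, gene_lengths = 40L,
                                 planted_sites_per_gene = 5L)
  expect_error(simulate_genes(too_short), "too short")
})

test_that("designated consensus is recovered from simulated energy files", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, noise_ddg = 0.1, margin_ddg = 1.0)
    path <- withr::local_tempfile(fileext = ".tsv")
    sim <- simulate_energy_file(cfg, path)
    cons <- consensus_sequence(read_energy_tsv(path))
    expect_identical(unname(consensus_string(cons)),
                     cfg$profile_spec$consensus)
    expect_false(any(cons$tie))
  }
  # noiseless file with equal non-minimum values: exact recovery, no ties
  quiet <- simulation_config(seed = 3, noise_ddg = 0, margin_ddg = 1.0)
  sim <- simulate_energy_file(quiet)
  cons <- consensus_sequence(sim$energy)
  expect_identical(unname(consensus_string(cons)),
                   quiet$profile_spec$consensus)
  expect_false(any(cons$tie))
  # zero margin: every position degenerate, all ties reported
  flat <- simulation_config(seed = 3, noise_ddg = 0, margin_ddg = 0)
  expect_true(all(consensus_sequence(simulate_energy_file(flat)$energy)$tie))
})

test_that("strand-B energy rows are the complemented copy and reconcile silently", {
  cfg <- simulation_config(seed = 6, include_strand_b = TRUE)
  sim <- simulate_energy_file(cfg)
  expect_no_warning(cons <- consensus_sequence(sim$energy))
  expect_identical(unname(consensus_string(cons)),
                   cfg$profile_spec$consensus)
})

test_that("designed complexes reproduce the intended contact list exactly", {
  cfg <- simulation_config(seed = 5)
  cx <- simulate_complex(cfg)
  got <- detect_contacts(cx$atoms, cutoff = 4.5, domain_id = "DBD-S1",
                         dna_strands = cx$dna_strands, fragment_length = 10L)
  key <- function(cm) sort(paste(cm$aa, cm$prot_chain, cm$prot_number,
                                 cm$base, cm$strand, cm$position,
                                 cm$contact_class))
  expect_identical(key(got), key(cx$manifest))
  expect_equal(sort(got$min_distance), sort(cx$manifest$min_distance))
  # and equals the brute-force oracle on the same atoms
  want <- oracle_contacts(cx$atoms, 4.5, cx$dna_strands)
  expect_identical(contact_key(got), contact_key(want))

  # worked example shaped like the published DBD-2 block: 7 residues x 6 bases
  tab2 <- read_contact_table(ho1_contacts_path())
  dbd2 <- tibble::as_tibble(tab2)[tab2$domain_id == "DBD-2", ]
  spec2 <- tibble::tibble(
    domain_id = "DBD-2",
    residue = format_residue_token(dbd2$aa, dbd2$prot_chain,
                                   dbd2$prot_number),
    base = format_base_token(dbd2$base, dbd2$strand, dbd2$position),
    contact_class = dbd2$contact_class, distance = 3.0
  )
  cfg2 <- simulation_config(seed = 5, complex_spec = spec2)
  cx2 <- simulate_complex(cfg2)
  got2 <- detect_contacts(cx2$atoms, cutoff = 4.5, domain_id = "DBD-2",
                          dna_strands = cx2$dna_strands)
  s <- summarize_domains(got2)
  expect_identical(s$n_protein_residues, 7L)
  expect_identical(s$n_dna_contacts, 6L)

  # empty intended list is rejected as infeasible input
  expect_identical(nrow(detect_contacts(
    dplyr::mutate(cx$atoms, x = ifelse(kind == "dna", x + 500, x)),
    cutoff = 4.5, dna_strands = cx$dna_strands)), 0L)
})

test_that("infeasible geometry requests are rejected", {
  bad <- simulation_config(
    seed = 1,
    complex_spec = tibble::tibble(domain_id = "d", residue = "GA10",
                                  base = "gA1",
                                  contact_class = "protein-side-chain",
                                  distance = 3.0)
  )
  expect_error(simulate_complex(bad), "glycine")
})

test_that("genes generated with decreasing planted density rank in that order", {
  cfg <- simulation_config(seed = 8, n_genes = 3L,
                           gene_lengths = c(1000L, 1000L, 1000L),
                           planted_sites_per_gene = c(6L, 3L, 1L),
                           zero_background = TRUE)
  sim <- simulate_genes(cfg)
  prof <- dbdthreadr:::profile_from_spec(cfg$profile_spec)
  hits <- scan_genes(sim$genes, prof)
  tab <- count_and_rank(hits, sim$genes)
  expect_identical(tab$gene_id, c("gene001", "gene002", "gene003"))
  expect_identical(tab$n_sites, c(6L, 3L, 1L))
})
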