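toy_consensus <- function(seq, domain = "d") {
  chars <- strsplit(seq, "")[[1]]
  cons <- tibble::tibble(domain_id = domain,
                         position = seq_along(chars),
                         nucleotide = chars,
                         min_ddg = -1, tie = FALSE)
  class(cons) <- c("dbd_consensus", class(cons))
  cons
}

toy_cm <- function(positions, strands = NULL, domain = "d", L = 10L,
                   consensus = NULL) {
  strands <- strands %||% rep("A", length(positions))
  base <- rep("A", length(positions))
  if (!is.null(consensus)) {
    chars <- strsplit(consensus, "")[[1]]
    a_pos <- ifelse(strands == "A", positions, 2L * L + 1L - positions)
    base <- ifelse(strands == "A", chars[a_pos],
                   unname(c(A = "T", C = "G", G = "C", T = "A")[chars[a_pos]]))
  }
  contact_map(tibble::tibble(
    domain_id = domain, fragment_length = L,
    aa = "K", prot_chain = "A", prot_number = 100L + seq_along(positions),
    base = base, strand = strands, position = as.integer(positions),
    contact_class = "protein-side-chain"
  ))
}

test_that("profiles keep contact positions and wildcard the rest", {
  cons <- toy_consensus("GGCCAATTGG")
  cm <- toy_cm(c(2L, 4L, 5L, 7L, 9L), consensus = "GGCCAATTGG")
  p <- compile_profile(cons, cm)
  expect_s3_class(p, "dbd_binding_profile")
  expect_identical(p$position, c(2L, 4L, 5L, 7L, 9L))
  expect_identical(unlist(p$allowed), c("G", "C", "A", "T", "G"))
  g <- glance(p)
  expect_identical(g$n_contact_positions, 5L)
  expect_identical(g$n_wildcards, 5L)
})

test_that("strand-B contacts map onto strand A through the pairing", {
  cons <- toy_consensus("GGCCAATTGG")
  # B20 pairs with A1, B12 pairs with A9
  cm <- toy_cm(c(20L, 12L, 5L), strands = c("B", "B", "A"),
               consensus = "GGCCAATTGG")
  p <- compile_profile(cons, cm)
  expect_identical(p$position, c(1L, 5L, 9L))
  expect_identical(unlist(p$allowed), c("G", "A", "G"))
})

test_that("profiles with fewer than three contact positions are rejected", {
  cons <- toy_consensus("GGCCAATTGG")
  expect_error(compile_profile(cons, toy_cm(5L, consensus = "GGCCAATTGG")),
               "at least 3", class = "dbd_contact_filter_error")
})

test_that("threshold mode with epsilon 0 equals strict; epsilon widens sets", {
  cons <- toy_consensus("GCA", domain = "d")
  cons$position <- 1:3
  m <- energy_matrix(tibble::tibble(
    domain_id = "d", strand = "A", position = 1:3,
    A = c(0.5, 0.9, -1.0), C = c(0.2, -0.8, 0.0),
    G = c(-0.4, 0.1, 0.3), T = c(0.8, 0.2, 0.1)
  ))
  cm <- toy_cm(c(1L, 2L, 3L), L = 3L, consensus = "GCA")
  strict <- compile_profile(cons, cm, mode = "strict")
  thr0 <- compile_profile(cons, cm, mode = "threshold", epsilon = 0,
                          energy = m)
  expect_identical(thr0$allowed, strict$allowed)
  # position 1 energies (A 0.5, C 0.2, G -0.4, T 0.8), min -0.4: a 0.7
  # band admits C and G only
  thr <- compile_profile(cons, cm, mode = "threshold", epsilon = 0.7,
                         energy = m)
  expect_identical(thr$allowed[[1L]], c("C", "G"))
  wide <- compile_profile(cons, cm, mode = "threshold", epsilon = 1.5,
                          energy = m)
  expect_identical(wide$allowed[[1L]], c("A", "C", "G", "T"))
})

test_that("threading finds planted forward and reverse-complement windows", {
  # contacts {1:G, 4:C, 7:A} in a 10-bp profile
  cons <- toy_consensus("GTTCGGATTT")
  cm <- toy_cm(c(1L, 4L, 7L), consensus = "GTTCGGATTT")
  p <- compile_profile(cons, cm)
  win <- "GTTCGGATTT"
  seq <- paste0(
    strrep("C", 5), win, strrep("C", 25), revcomp(win), strrep("C", 10)
  )
  genes <- tibble::tibble(gene_id = "g1", sequence = seq)
  hits <- scan_genes(genes, p)
  expect_identical(hits$start, c(5L, 40L))
  expect_identical(hits$strand, c("+", "-"))
  expect_identical(unique(hits$n_matched_contacts), 3L)
  expect_identical(unique(hits$end - hits$start), 10L)
})

test_that("short genes and all-N genes yield no hits", {
  cons <- toy_consensus("GGCCAATTGG")
  cm <- toy_cm(c(1L, 5L, 10L), consensus = "GGCCAATTGG")
  p <- compile_profile(cons, cm)
  short <- tibble::tibble(gene_id = "s", sequence = strrep("G", 9))
  expect_identical(nrow(scan_genes(short, p)), 0L)
  alln <- tibble::tibble(gene_id = "n", sequence = strrep("N", 100))
  expect_identical(nrow(scan_genes(alln, p)), 0L)
})

test_that("palindromic double-orientation windows count once with strand ±", {
  # profile {1:G, 6:C} on L=6; window GAATTC is its own reverse complement
  cons <- toy_consensus("GAATTC")
  cm <- toy_cm(c(1L, 6L), L = 6L, consensus = "GAATTC")
  cm <- contact_map(dplyr::bind_rows(
    tibble::as_tibble(cm),
    dplyr::mutate(tibble::as_tibble(cm)[1L, ], position = 3L, base = "A")
  ))
  p <- compile_profile(cons, cm)
  genes <- tibble::tibble(gene_id = "g", sequence = "TTGAATTCTT")
  hits <- scan_genes(genes, p)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "±")
})

test_that("scan_genes equals the naive window-by-window oracle", {
  set.seed(77)
  for (rep in 1:40) {
    p <- random_profile()
    L <- attr(p, "length")
    genes <- tibble::tibble(gene_id = "g",
                            sequence = random_gene(sample(50:400, 1L)))
    got <- scan_genes(genes, p)
    want <- oracle_scan(genes$sequence, p$position, p$allowed, L)
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$strand, want$strand)
  }
})

test_that("hit counts are invariant under reverse-complementing the gene", {
  set.seed(78)
  for (rep in 1:20) {
    p <- random_profile()
    L <- attr(p, "length")
    seq <- random_gene(300)
    fwd <- scan_genes(tibble::tibble(gene_id = "g", sequence = seq), p)
    rc <- scan_genes(tibble::tibble(gene_id = "g", sequence = revcomp(seq)), p)
    expect_identical(nrow(fwd), nrow(rc))
    # coordinates map via s -> len - L - s
    expect_identical(sort(rc$start), sort(300L - L - fwd$start))
  }
})

test_that("hits over disjoint segments add up minus junction windows", {
  set.seed(79)
  p <- random_profile(L = 6L)
  L <- 6L
  s1 <- random_gene(150)
  s2 <- random_gene(150)
  h1 <- nrow(scan_genes(tibble::tibble(gene_id = "g", sequence = s1), p))
  h2 <- nrow(scan_genes(tibble::tibble(gene_id = "g", sequence = s2), p))
  cat_hits <- scan_genes(tibble::tibble(gene_id = "g",
                                        sequence = paste0(s1, s2)), p)
  junction <- sum(cat_hits$start > 150L - L & cat_hits$start < 150L)
  expect_identical(nrow(cat_hits) - junction, h1 + h2)
})

test_that("density ranking normalizes by length with deterministic ties", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"),
    sequence = c(strrep("A", 1000), strrep("A", 100))
  )
  hits <- tibble::tibble(
    gene_id = c(rep("g1", 5), rep("g2", 2)),
    start = 0L, end = 10L, strand = "+", n_matched_contacts = 3L,
    domain_id = "d"
  )
  tab <- count_and_rank(hits, genes)
  expect_identical(tab$gene_id, c("g2", "g1"))
  expect_equal(tab$density, c(0.02, 0.005))
  expect_identical(tab$rank, 1:2)

  single <- count_and_rank(hits[hits$gene_id == "g1", ], genes[1L, ])
  expect_identical(single$rank, 1L)

  # ties break by gene_id ascending
  tie_genes <- tibble::tibble(gene_id = c("b", "a"),
                              sequence = rep(strrep("A", 100), 2L))
  tie_hits <- tibble::tibble(gene_id = c("a", "b"), start = 0L, end = 10L,
                             strand = "+", n_matched_contacts = 3L,
                             domain_id = "d")
  expect_identical(count_and_rank(tie_hits, tie_genes)$gene_id, c("a", "b"))

  many <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                         sequence = strrep("A", 100))
  tab12 <- count_and_rank(tie_hits[0, ], many, top_n = 10L)
  expect_identical(sum(tab12$top), 10L)
  expect_identical(nrow(tab12), 12L)

  expect_error(count_and_rank(tibble::tibble(gene_id = "nope", start = 0L,
                                             end = 10L, strand = "+",
                                             n_matched_contacts = 3L,
                                             domain_id = "d"),
                              genes), "nope")
})

test_that("density scales by length/(length+k) under a match-free spacer", {
  cons <- toy_consensus("GGCCAATTGG")
  cm <- toy_cm(c(1L, 5L, 10L), consensus = "GGCCAATTGG")
  p <- compile_profile(cons, cm)
  base <- paste0(strrep("C", 20), "GGCCAATTGG", strrep("C", 20))
  spacer <- strrep("C", 50)
  g1 <- tibble::tibble(gene_id = "g", sequence = base)
  g2 <- tibble::tibble(gene_id = "g", sequence = paste0(base, spacer))
  t1 <- count_and_rank(scan_genes(g1, p), g1)
  t2 <- count_and_rank(scan_genes(g2, p), g2)
  expect_identical(t1$n_sites, t2$n_sites)
  expect_equal(t2$density, t1$density * 50 / 100)
})

test_that("BED and rank TSV outputs round-trip; empty hit lists are fine", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"), start = c(5L, 40L, 0L),
    end = c(15L, 50L, 10L), strand = c("+", "-", "±"),
    n_matched_contacts = 3L, domain_id = "d"
  )
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, bed)
  lines <- readLines(bed)
  expect_length(lines, 3L)
  back <- read_hits_bed(bed)
  expect_equal(tibble::as_tibble(back), hits)

  empty_bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits[0, ], empty_bed)
  expect_identical(nrow(read_hits_bed(empty_bed)), 0L)

  genes <- tibble::tibble(gene_id = c("g1", "g2"),
                          sequence = c(strrep("A", 60), strrep("A", 30)))
  tab <- count_and_rank(hits, genes)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_rank_tsv(tab, tsv)
  expect_equal(tibble::as_tibble(read_rank_tsv(tsv)), tibble::as_tibble(tab))
})
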