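test_that("IUPAC scanning matches hand-placed sites, palindromes, and wildcards", {
  expect_equal(scan_promoter("AACCGACGG", iupac_motif("DRE", "RCCGAC"),
                             both_strands = FALSE), 1)
  # palindromic site counted once per strand
  expect_equal(scan_promoter("TTTCACGTGTTT", iupac_motif("G-box", "CACGTG"),
                             both_strands = TRUE), 2)
  expect_equal(scan_promoter("TTTCACGTGTTT", iupac_motif("G-box", "CACGTG"),
                             both_strands = FALSE), 1)
  expect_equal(scan_promoter("ACGTACGTAC", iupac_motif("any4", "NNNN"),
                             both_strands = FALSE), 7)
  # sequence N is matched only by motif N
  expect_equal(scan_promoter("ACGNACGT", iupac_motif("m", "ACGT"),
                             both_strands = FALSE), 1)
  expect_equal(scan_promoter("ACGNACGT", iupac_motif("m", "ACGN"),
                             both_strands = FALSE), 2)
  expect_error(iupac_motif("bad", "ACGU"), "invalid IUPAC")
  expect_error(iupac_motif("bad", ""), "non-empty")
  expect_error(scan_promoter("ACG", iupac_motif("m", "ACGT")), "shorter")
})

test_that("scanning both strands is invariant under reverse complement of the promoter", {
  set.seed(55)
  motifs <- c("RCCGAC", "CANNTG", "MACCWAMC", "TGAC", "YAACKG")
  for (i in 1:20) {
    s <- random_dna(80)
    m <- iupac_motif("m", sample(motifs, 1))
    expect_identical(scan_promoter(s, m), scan_promoter(revcomp_str(s), m))
  }
})

test_that("match counts agree with an independent regex scanner", {
  set.seed(66)
  motifs <- c("RCCGAC", "CANNTG", "WAACCA", "CATGCA", "GRWAAW", "ACGTG")
  for (i in 1:30) {
    s <- random_dna(sample(50:150, 1))
    cons <- sample(motifs, 1)
    want <- regex_count(s, cons) + regex_count(revcomp_str(s), cons)
    expect_identical(scan_promoter(s, iupac_motif("m", cons)), want)
  }
})

test_that("the hit index records promoters with at least one match", {
  proms <- c(g1 = "AAAACCGACAAAA",   # RCCGAC site
             g2 = "TTTTTTTTTTTTT",
             g3 = paste0(strrep("A", 5), "GTCGGT", strrep("A", 5))) # rc site
  idx <- build_hit_index(proms, list(iupac_motif("DRE", "RCCGAC"),
                                     iupac_motif("allN", "N"),
                                     iupac_motif("gc", "CCCCCCCC")))
  expect_setequal(idx$hits$DRE, c("g1", "g3"))
  expect_setequal(idx$hits$allN, c("g1", "g2", "g3"))
  expect_length(idx$hits$gc, 0)
  expect_identical(idx$background_size, 3L)
})

test_that("hypergeometric upper tail is exact against combinatorial enumeration", {
  expect_equal(hypergeometric_upper_tail(0, 5, 8, 20), 1)
  expect_equal(hypergeometric_upper_tail(7, 8, 10, 20), 1826 / 184756)
  # boundary k = n = K
  expect_equal(hypergeometric_upper_tail(4, 4, 4, 12),
               choose(4, 4) / choose(12, 4) * choose(8, 0))
  set.seed(31)
  for (i in 1:40) {
    N <- sample(5:20, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_upper_tail(k, K, n, N),
                 brute_hyper_upper(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeometric_upper_tail(5, 4, 10, 20), "bounds")
  expect_error(hypergeometric_upper_tail(1, 25, 10, 20), "bounds")
})

test_that("enrichment p decreases monotonically in the overlap count", {
  ps <- vapply(0:10, function(k) hypergeometric_upper_tail(k, 40, 10, 200),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment reproduces the worked step-up example and its invariants", {
  got <- bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.9))
  expect_equal(got, c(0.025, 0.0275, 0.02 * 5 / 3, 0.05, 0.9))
  expect_equal(bh_adjust(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("motif significance requires both the p threshold and the promoter floor", {
  # 9 of 10 set genes hit, only 30 of 2000 background: tiny p but k < 10
  hits <- list(rare = c(sprintf("set%02d", 1:9), sprintf("bg%04d", 1:21)),
               common = c(sprintf("set%02d", 1:10), sprintf("bg%04d", 1:999)))
  idx <- structure(list(hits = hits, background_size = 2000L,
                        background = c(sprintf("set%02d", 1:10),
                                       sprintf("bg%04d", 1:1990))),
                   class = "motif_hit_index")
  res <- motif_enrichment(sprintf("set%02d", 1:10), idx)
  rare <- res[res$id == "rare", ]
  expect_lt(rare$p, 1e-6)
  expect_false(rare$significant)   # k = 9 < 10 promoters
  expect_equal(res$score, -log10(res$p))
  expect_true(all(diff(res$p) >= 0))
  expect_error(motif_enrichment(c("set01", "ghost"), idx), "ghost")
})

test_that("GO-slim enrichment ranks a planted category first and controls the null", {
  background <- sprintf("g%03d", 1:200)
  term_map <- list(planted = background[1:40],
                   other1 = background[101:140], other2 = background[141:180])
  gene_set <- background[1:25]
  res <- go_slim_enrichment(gene_set, background, term_map)
  expect_identical(res$id[1], "planted")
  expect_true(res$significant[1])
  expect_equal(res$p_adjusted, bh_adjust(res$p), tolerance = 1e-12)
  # gene_set = background makes every term's enrichment certain
  all_res <- go_slim_enrichment(background, background, term_map)
  expect_true(all(all_res$p == 1))
  expect_warning(empty <- go_slim_enrichment(gene_set, background, list()),
                 "empty term map")
  expect_identical(nrow(empty), 0L)
})

test_that("null GO gene sets are rarely called significant at FDR 0.05", {
  set.seed(19)
  background <- sprintf("g%03d", 1:300)
  any_sig <- vapply(1:60, function(i) {
    term_map <- lapply(1:20, function(j) sample(background, 30))
    names(term_map) <- sprintf("t%02d", 1:20)
    res <- go_slim_enrichment(sample(background, 40), background, term_map)
    any(res$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.12)
})

test_that("the planted regulon motif is recovered end-to-end on synthetic promoters", {
  cfg <- synth_config(seed = 15, n_metabolites = 6, n_genes = 400,
                      regulon_size = 60, modules = list(),
                      promoter_length = 600)
  gm <- generate_metabolite_matrix(cfg)
  prom <- generate_promoters(cfg, gm$truth)
  idx <- build_hit_index(prom, cfg$motif_library)
  res <- motif_enrichment(gm$truth$regulon_genes, idx)
  planted <- cfg$planted_motif_ids
  expect_true(all(res$significant[res$id %in% planted]))
  expect_true(res$id[1] %in% planted)
})

test_that("motif table and promoter FASTA round-trip through their readers", {
  dir <- withr::local_tempdir()
  lib <- default_motif_library()
  write.table(lib, file.path(dir, "motifs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  motifs <- read_motif_tsv(file.path(dir, "motifs.tsv"))
  expect_identical(vapply(motifs, `[[`, character(1), "consensus"),
                   setNames(lib$consensus, lib$motif_id))
  proms <- Biostrings::DNAStringSet(c(gA = "ACGTACGT", gB = "GGGGCCCC"))
  Biostrings::writeXStringSet(proms, file.path(dir, "p.fa"))
  back <- read_promoters(file.path(dir, "p.fa"))
  expect_identical(as.character(back), as.character(proms))
})
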