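test_that("default design produces the 74 x 48 metabolite and 2000 x 18 transcript matrices", {
  cfg <- synth_config(seed = 4)
  gm <- generate_metabolite_matrix(cfg)
  expect_identical(dim(gm$matrix$values), c(74L, 48L))
  md <- gm$matrix$metadata
  expect_identical(sort(unique(md$treatment)), c("C", "D"))
  expect_identical(sort(unique(md$stage_daa)), c(27L, 41L, 54L, 68L, 82L, 93L))
  expect_true(all(table(md$treatment, md$stage_daa) == 4))
  tr <- generate_transcript_matrix(cfg, gm$truth)
  expect_identical(dim(tr$values), c(2000L, 18L))
  expect_true(all(table(tr$metadata$treatment, tr$metadata$stage_daa) == 3))
  expect_true(all(gm$matrix$values > 0))
  expect_true(all(tr$values > 0))
})

test_that("generation is bit-identical given the same configuration and seed", {
  cfg <- tiny_config(seed = 9)
  a <- generate_metabolite_matrix(cfg)
  b <- generate_metabolite_matrix(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$planted_edges, b$truth$planted_edges)
  ta <- generate_transcript_matrix(cfg, a$truth)
  tb <- generate_transcript_matrix(cfg, b$truth)
  expect_identical(ta$values, tb$values)
  pa <- generate_promoters(cfg, a$truth)
  pb <- generate_promoters(cfg, b$truth)
  expect_identical(as.character(pa), as.character(pb))
  d <- generate_metabolite_matrix(tiny_config(seed = 10))
  expect_false(identical(a$matrix$values, d$matrix$values))
})

test_that("metabolite substream is unaffected by the gene count", {
  a <- generate_metabolite_matrix(tiny_config(seed = 5, n_genes = 10))
  b <- generate_metabolite_matrix(tiny_config(seed = 5, n_genes = 300))
  expect_identical(a$matrix$values, b$matrix$values)
})

test_that("noise-free module members are perfectly correlated in each condition", {
  cfg <- tiny_config(seed = 2, noise_sd = 0,
                     modules = list(module_spec("m", 3, 1, "both", 0)))
  gm <- generate_metabolite_matrix(cfg)
  for (cond in c("C", "D")) {
    v <- gm$matrix$values[1:3, gm$matrix$metadata$treatment == cond]
    r <- cor(t(v))
    expect_equal(unname(r[upper.tri(r)]), rep(1, 3))
  }
})

test_that("noise-free linked gene tracks its partner metabolite exactly", {
  cfg <- tiny_config(seed = 3, noise_sd = 0,
                     modules = list(module_spec("m", 3, 1, "both", 1)))
  gm <- generate_metabolite_matrix(cfg)
  tr <- generate_transcript_matrix(cfg, gm$truth)
  link <- gm$truth$planted_gene_metabolite_links[1, ]
  shared <- intersect(colnames(tr$values), colnames(gm$matrix$values))
  expect_gt(length(shared), 3)
  expect_equal(pearson(gm$matrix$values[link$metabolite_id, shared],
                       tr$values[link$gene_id, shared]), 1)
})

test_that("without linked genes, gene-metabolite correlations center on zero", {
  cfg <- tiny_config(seed = 6, n_genes = 60,
                     modules = list(module_spec("m", 4, 0.9, "both", 0)))
  gm <- generate_metabolite_matrix(cfg)
  tr <- generate_transcript_matrix(cfg, gm$truth)
  expect_identical(nrow(gm$truth$planted_gene_metabolite_links), 0L)
  shared <- intersect(colnames(tr$values), colnames(gm$matrix$values))
  r <- cor(t(tr$values[, shared]), t(gm$matrix$values[, shared]))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("planted within-module pairs clear the correlation gate in nearly all seeds", {
  # Monte-Carlo oracle: loading 0.9, noise_sd 0.15, 24 samples per condition
  mods <- list(module_spec("m", 6, 0.9, "both", 0))
  rate <- vapply(1:60, function(seed) {
    cfg <- tiny_config(seed = seed, n_metabolites = 8, modules = mods,
                       treatment_effect_log2fc = 0)
    gm <- generate_metabolite_matrix(cfg)
    v <- gm$matrix$values[1:6, gm$matrix$metadata$treatment == "C"]
    r <- cor(t(v))
    mean(abs(r[upper.tri(r)]) > 0.8)
  }, numeric(1))
  expect_gte(mean(rate), 0.95)
})

test_that("stronger loading never weakens expected within-module correlation", {
  mean_abs_r <- function(loading) {
    mean(vapply(1:20, function(seed) {
      cfg <- tiny_config(seed = seed, n_metabolites = 6,
                         modules = list(module_spec("m", 4, loading, "both", 0)))
      gm <- generate_metabolite_matrix(cfg)
      v <- gm$matrix$values[1:4, gm$matrix$metadata$treatment == "C"]
      r <- cor(t(v))
      mean(abs(r[upper.tri(r)]))
    }, numeric(1)))
  }
  r_by_loading <- vapply(c(0.3, 0.6, 0.9), mean_abs_r, numeric(1))
  expect_true(all(diff(r_by_loading) > 0))
})

test_that("promoters have the requested length and deterministic planted sites", {
  cfg <- tiny_config(seed = 7, motif_plant_rate_regulon = 1,
                     motif_plant_rate_background = 0)
  gm <- generate_metabolite_matrix(cfg)
  prom <- generate_promoters(cfg, gm$truth)
  expect_identical(length(prom), cfg$n_genes)
  expect_true(all(Biostrings::width(prom) == cfg$promoter_length))
  lib <- cfg$motif_library
  for (mid in cfg$planted_motif_ids) {
    consensus <- lib$consensus[lib$motif_id == mid]
    hits <- vapply(gm$truth$regulon_genes, function(g)
      scan_promoter(as.character(prom[[g]]), iupac_motif(mid, consensus)),
      numeric(1))
    expect_true(all(hits >= 1))
  }
})

test_that("spontaneous match rate of a 6-mer agrees with the closed-form expectation", {
  # both strands, 1 kb, uniform base composition: 2 * 995 / 4^6 ~ 0.486
  cfg <- synth_config(seed = 11, n_metabolites = 4, n_genes = 3000,
                      regulon_size = 2, modules = list(), gc_content = 0.5,
                      planted_motif_ids = character(0))
  gm <- generate_metabolite_matrix(cfg)
  prom <- generate_promoters(cfg, gm$truth)
  cnt <- Biostrings::vcountPattern("CATGCA", prom, fixed = "subject") +
    Biostrings::vcountPattern("TGCATG", prom, fixed = "subject")
  expect_lt(abs(mean(cnt) - 2 * 995 / 4^6), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(modules = list(module_spec("m", 100))),
               "module sizes")
  expect_error(tiny_config(noise_sd = -0.1), "noise_sd")
  expect_error(tiny_config(stages_trans = c(41, 99)), "subset")
  expect_error(tiny_config(promoter_length = 3), "motif longer")
  expect_error(tiny_config(gc_content = 1.4), "probabilities")
  expect_error(tiny_config(planted_motif_ids = "NOSUCH"), "planted motifs")
  expect_error(module_spec("m", 2, loading = 1.7), "loading")
})

test_that("dataset bundle is internally consistent", {
  ds <- generate_dataset(tiny_config(seed = 8))
  expect_s3_class(ds$metabolites, "omics_matrix")
  expect_identical(length(ds$promoters), ds$config$n_genes)
  expect_true(all(ds$truth$regulon_genes %in% names(ds$promoters)))
  expect_identical(length(ds$truth$regulon_genes), ds$config$regulon_size)
  links <- ds$truth$planted_gene_metabolite_links
  expect_true(all(links$gene_id %in% ds$de_flags))
  expect_true(all(links$gene_id %in% ds$truth$regulon_genes))
  expect_true(all(unlist(ds$go_map) %in% names(ds$promoters)))
  pe <- ds$truth$planted_edges
  mm <- ds$truth$module_membership
  expect_true(all(mm[pe$feature_a] == pe$module_id))
  expect_true(all(mm[pe$feature_b] == pe$module_id))
})
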