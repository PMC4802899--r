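make_small_merged <- function(seed = 1, noise_sd = 0.15, n_genes = 40,
                              strategy = "replicate_pairing") {
  cfg <- tiny_config(seed = seed, n_genes = n_genes, noise_sd = noise_sd,
                     modules = list(module_spec("m", 4, 0.9, "both", 3)))
  gm <- generate_metabolite_matrix(cfg)
  tr <- generate_transcript_matrix(cfg, gm$truth)
  list(cfg = cfg, truth = gm$truth,
       merged = align_samples(gm$matrix, tr, strategy))
}

test_that("replicate pairing aligns 18 samples and stage means 6 on the default design", {
  cfg <- synth_config(seed = 13, n_genes = 20, regulon_size = 5)
  gm <- generate_metabolite_matrix(cfg)
  tr <- generate_transcript_matrix(cfg, gm$truth)
  mg <- align_samples(gm$matrix, tr, "replicate_pairing")
  expect_identical(nrow(mg$sample_info), 18L)
  expect_true(all(table(mg$sample_info$treatment, mg$sample_info$stage_daa) == 3))
  ms <- align_samples(gm$matrix, tr, "stage_means")
  expect_identical(nrow(ms$sample_info), 6L)
  expect_identical(sum(mg$origin == "metabolite"), 74L)
  expect_identical(sum(mg$origin == "transcript"), 20L)
  # stage_means cells equal replicate averages
  cell <- gm$matrix$metadata$treatment == "C" & gm$matrix$metadata$stage_daa == 41
  expect_equal(unname(ms$values["met_001", "C_41"]),
               mean(gm$matrix$values["met_001", cell]))
})

test_that("alignment fails on disjoint designs", {
  cfg <- tiny_config(seed = 3, n_genes = 10)
  gm <- generate_metabolite_matrix(cfg)
  tr <- generate_transcript_matrix(cfg, gm$truth)
  shifted <- tr$metadata
  shifted$stage_daa <- shifted$stage_daa + 500L
  bad <- omics_matrix(tr$values, shifted)
  expect_error(align_samples(gm$matrix, bad), "fewer than 2")
})

test_that("noise-free planted links rank first with |r| = 1", {
  sm <- make_small_merged(seed = 2, noise_sd = 0)
  links <- sm$truth$planted_gene_metabolite_links
  met <- links$metabolite_id[1]
  tc <- top_correlators(sm$merged, met, k = 10, B = 1999, seed = 1)
  planted_genes <- links$gene_id[links$metabolite_id == met]
  expect_true(all(planted_genes %in% tc$gene_id))
  top <- tc[tc$rank == 1, ]
  expect_true(top$gene_id %in% planted_genes)
  expect_equal(abs(top$r), 1)
  expect_true(all(tc$p < 0.001))
  expect_true(all(tc$rank == seq_len(nrow(tc))))
})

test_that("top correlator lists are capped at k, gated at alpha, and order-invariant", {
  sm <- make_small_merged(seed = 4)
  met <- sm$truth$planted_gene_metabolite_links$metabolite_id[1]
  tc_all <- top_correlators(sm$merged, met, k = 100, B = 1999, seed = 7)
  expect_lte(nrow(tc_all), 100)
  expect_true(all(tc_all$p < 0.001))
  tc_two <- top_correlators(sm$merged, met, k = 2, B = 1999, seed = 7)
  expect_identical(tc_two$gene_id, tc_all$gene_id[1:2])
  # permuting feature rows must not change the result
  shuf <- sm$merged
  perm <- rev(seq_len(nrow(shuf$values)))
  shuf$values <- shuf$values[perm, ]
  shuf$origin <- shuf$origin[perm]
  expect_identical(top_correlators(shuf, met, k = 100, B = 1999, seed = 7),
                   tc_all)
  expect_error(top_correlators(sm$merged, "not_a_met", seed = 1),
               "unknown metabolite")
  expect_error(top_correlators(sm$merged, met, k = 0, seed = 1), "k must")
})

test_that("overlap accounting matches hand-enumerated and brute-force set algebra", {
  ov <- overlap_summary(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"),
                             C = "g3"))
  expect_equal(unname(ov$per_metabolite_specific), c(1L, 0L, 0L))
  expect_identical(unname(ov$pairwise_shared[["A|B"]]), 1L)
  expect_identical(ov$shared_by_all, 1L)

  same <- overlap_summary(list(A = c("x", "y"), B = c("y", "x")))
  expect_true(all(same$per_metabolite_specific == 0))
  expect_identical(same$shared_by_all, 2L)

  set.seed(77)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(sprintf("g%03d", 1:60),
                                           sample(5:40, 1)))
    names(sets) <- c("A", "B", "C")
    ov <- overlap_summary(sets)
    # independent set-algebra oracle
    expect_identical(ov$shared_by_all,
                     length(Reduce(intersect, sets)))
    for (m in names(sets)) {
      others <- unlist(sets[setdiff(names(sets), m)])
      expect_identical(unname(ov$per_metabolite_specific[m]),
                       length(setdiff(sets[[m]], others)))
    }
    expect_identical(unname(ov$pairwise_shared[["A|B"]]),
                     length(setdiff(intersect(sets$A, sets$B), sets$C)))
    # inclusion-exclusion: every gene is counted in exactly one stratum
    univ <- length(unique(unlist(sets)))
    in2 <- sum(vapply(unique(unlist(sets)), function(g)
      sum(vapply(sets, function(s) g %in% s, logical(1))) == 2, logical(1)))
    expect_identical(sum(ov$per_metabolite_specific) + in2 + ov$shared_by_all,
                     univ)
    expect_identical(sum(ov$pairwise_shared), in2)
  }
  expect_error(overlap_summary(list(A = "g1")), "at least 2")
})

test_that("bipartite network assembly annotates genes and counts the union", {
  links <- list(
    m1 = data.frame(gene_id = c("g1", "g2"), metabolite_id = "m1",
                    r = c(0.9, -0.85), p = 5e-4, rank = 1:2),
    m2 = data.frame(gene_id = c("g3", "g4"), metabolite_id = "m2",
                    r = c(0.95, 0.9), p = 5e-4, rank = 1:2),
    m3 = data.frame(gene_id = c("g5", "g6"), metabolite_id = "m3",
                    r = c(0.99, -0.9), p = 5e-4, rank = 1:2))
  net <- build_gene_metabolite_network(links, de_flags = c("g1", "g5"),
                                       pathway_map = c(g1 = "terpenoid",
                                                       g3 = "flavonoid"))
  expect_identical(net$n_genes, 6L)
  expect_identical(net$n_de, 2L)
  expect_equal(net$de_fraction, 2 / 6)
  expect_equal(igraph::vcount(net$graph), 9)
  expect_equal(igraph::ecount(net$graph), 6)
  expect_true(igraph::bipartite_mapping(
    igraph::set_vertex_attr(net$graph, "type",
      value = igraph::V(net$graph)$type == "gene"))$res)
  expect_identical(net$links$pathway[net$links$gene_id == "g2"], "unannotated")
})

test_that("pathway edge tallies split signed links correctly", {
  links <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g9"),
    r = c(0.9, 0.8, -0.85, 0.99, -0.9, 0.81))
  pw <- c(g1 = "terpenoid", g2 = "terpenoid", g3 = "terpenoid",
          g4 = "flavonoid", g5 = "flavonoid")
  out <- pathway_edge_summary(links, pw, condition = "D")
  terp <- out[out$pathway == "terpenoid", ]
  expect_identical(c(terp$n_positive, terp$n_negative), c(2L, 1L))
  expect_identical(out$n_positive[out$pathway == "unannotated"], 1L)
  expect_true(all(out$n_positive + out$n_negative ==
                    as.integer(table(ifelse(links$gene_id %in% names(pw),
                                            pw[links$gene_id],
                                            "unannotated"))[out$pathway])))
  all_pos <- pathway_edge_summary(links[links$r > 0, ], pw)
  expect_true(all(all_pos$n_negative == 0))
})
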