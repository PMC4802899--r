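#' Pipeline configuration
#'
#' One object drives the whole analysis: either a simulation block (a
#' [synth_config()]) or paths to input files, plus the thresholds of every
#' stage. Threshold defaults are the study's: network gate |r| > 0.8 with
#' permutation p < 0.001 at B = 2000; top-100 correlators; motif enrichment
#' p < 0.01 with >= 10 promoters; GO-slim FDR 0.05; per-stage ANOVA
#' alpha 0.05.
#'
#' @param simulate a [synth_config()], or `NULL` when reading inputs.
#' @param inputs named list of file paths (`metab_values`, `metab_meta`,
#'   `trans_values`, `trans_meta`, `promoters`, `motifs`, optional `go_map`,
#'   `pathway_map`, `de_flags`); ignored when `simulate` is given.
#' @param r_min,alpha_network,B network gate parameters.
#' @param k_top,alpha_link top-correlator selection parameters.
#' @param alpha_motif,min_promoters,fdr_go enrichment parameters.
#' @param alpha_anova stage-wise treatment test level.
#' @param target_metabolites metabolites for the gene-correlator networks;
#'   `NULL` (with simulation) uses the metabolites carrying planted
#'   gene links.
#' @param alignment_strategy `"replicate_pairing"` or `"stage_means"`.
#' @param seed master seed for all pipeline randomness.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = synth_config(), inputs = NULL,
                            r_min = 0.8, alpha_network = 0.001, B = 2000,
                            k_top = 100, alpha_link = 0.001,
                            alpha_motif = 0.01, min_promoters = 10,
                            fdr_go = 0.05, alpha_anova = 0.05,
                            target_metabolites = NULL,
                            alignment_strategy = "replicate_pairing",
                            seed = 1, out_dir = "drynet_out") {
  structure(list(simulate = simulate, inputs = inputs,
                 thresholds = list(r_min = r_min, alpha_network = alpha_network,
                                   B = as.integer(B), k_top = as.integer(k_top),
                                   alpha_link = alpha_link,
                                   alpha_motif = alpha_motif,
                                   min_promoters = as.integer(min_promoters),
                                   fdr_go = fdr_go, alpha_anova = alpha_anova),
                 target_metabolites = target_metabolites,
                 alignment_strategy = alignment_strategy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns human-readable findings, one per violation; an empty character
#' vector means the configuration is valid. Findings beginning with
#' `"warning:"` do not stop [run_pipeline()]; all others do.
#'
#' @param config a `pipeline_config`.
#' @return character vector of findings.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  f <- character()
  if (th$r_min < 0 || th$r_min > 1)
    f <- c(f, sprintf("r_min = %g out of [0, 1]", th$r_min))
  for (nm in c("alpha_network", "alpha_link", "alpha_motif", "fdr_go",
               "alpha_anova"))
    if (th[[nm]] <= 0 || th[[nm]] >= 1)
      f <- c(f, sprintf("%s = %g out of (0, 1)", nm, th[[nm]]))
  if (th$B < 1) f <- c(f, sprintf("B = %d must be >= 1", th$B))
  if (th$k_top < 1) f <- c(f, sprintf("k_top = %d must be >= 1", th$k_top))
  if (th$min_promoters < 0)
    f <- c(f, sprintf("min_promoters = %d must be >= 0", th$min_promoters))
  if (th$B >= 1 && th$alpha_network > 0 && 1 / (th$B + 1) >= th$alpha_network)
    f <- c(f, sprintf(
      "warning: minimum attainable permutation p = 1/%d = %.4g >= alpha_network = %g; the significance gate is unsatisfiable",
      th$B + 1, 1 / (th$B + 1), th$alpha_network))
  if (!config$alignment_strategy %in% c("replicate_pairing", "stage_means"))
    f <- c(f, sprintf("unknown alignment_strategy '%s'",
                      config$alignment_strategy))
  if (is.null(config$simulate) && is.null(config$inputs))
    f <- c(f, "either a simulate block or input paths must be given")
  if (!is.null(config$inputs)) {
    req <- c("metab_values", "metab_meta", "trans_values", "trans_meta",
             "promoters", "motifs")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss))
      f <- c(f, sprintf("missing input path(s): %s", paste(miss, collapse = ", ")))
    for (nm in intersect(req, names(config$inputs)))
      if (!file.exists(config$inputs[[nm]]))
        f <- c(f, sprintf("input file not found: %s = %s", nm,
                          config$inputs[[nm]]))
  }
  f
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or ingest) -> stage-wise treatment response ->
#' condition-specific metabolite networks -> merged metabolite-transcript
#' networks -> promoter motif and GO-slim enrichment. All outputs are
#' plain-text TSV/JSON/SIF/FASTA under `config$out_dir`; re-running with an
#' identical configuration and seed reproduces them byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list (also written as `report.json`):
#'   file manifest, topology summaries, comparison, overlap summary,
#'   enrichment tables, provenance.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  hard <- findings[!startsWith(findings, "warning:")]
  if (length(hard))
    stop("invalid pipeline configuration:\n  ", paste(hard, collapse = "\n  "))
  for (w in findings[startsWith(findings, "warning:")]) warning(w)
  th <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out, ...)
  manifest <- character()
  note <- function(...) message(sprintf("[drynet] %s", sprintf(...)))

  ## -- data -----------------------------------------------------------------
  dataset <- pipeline_stage("data", {
    if (!is.null(config$simulate)) {
      note("simulating dataset (seed %d)", config$simulate$seed)
      ds <- generate_dataset(config$simulate)
      write_dataset(ds, p("data"))
      manifest <- c(manifest, list.files(p("data"), full.names = TRUE))
      ds
    } else {
      note("reading input files")
      inp <- config$inputs
      list(metabolites = read_omics_tsv(inp$metab_values, inp$metab_meta),
           transcripts = read_omics_tsv(inp$trans_values, inp$trans_meta),
           promoters = read_promoters(inp$promoters),
           motif_library = utils::read.table(inp$motifs, sep = "\t",
                                             header = TRUE,
                                             stringsAsFactors = FALSE),
           go_map = if (!is.null(inp$go_map)) read_term_map(inp$go_map),
           pathway_map = if (!is.null(inp$pathway_map)) {
             pw <- utils::read.table(inp$pathway_map, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
             stats::setNames(pw$pathway, pw$gene_id)
           },
           de_flags = if (!is.null(inp$de_flags)) readLines(inp$de_flags)
                      else character(),
           truth = NULL)
    }
  })

  ## -- stage-wise treatment response ----------------------------------------
  response <- pipeline_stage("response", {
    note("stage-wise treatment response (alpha = %g)", th$alpha_anova)
    rt <- response_table(dataset$metabolites, alpha = th$alpha_anova)
    utils::write.table(rt, p("response_table.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, p("response_table.tsv"))
    rt
  })

  ## -- condition networks ----------------------------------------------------
  nets <- pipeline_stage("corrnet", {
    note("condition networks (|r| > %g, p < %g, B = %d)", th$r_min,
         th$alpha_network, th$B)
    nets <- lapply(c(C = "C", D = "D"), function(cond)
      build_condition_network(dataset$metabolites, cond, r_min = th$r_min,
                              alpha = th$alpha_network, B = th$B,
                              seed = config$seed))
    for (cond in names(nets)) {
      write_network(nets[[cond]], p(sprintf("network_%s.sif", cond)),
                    p(sprintf("network_%s_edges.tsv", cond)))
      manifest <- c(manifest, p(sprintf("network_%s.sif", cond)),
                    p(sprintf("network_%s_edges.tsv", cond)))
    }
    comparison <- compare_conditions(nets$C, nets$D)
    jsonlite::write_json(
      list(C = topology_summary(nets$C), D = topology_summary(nets$D),
           difference = as.list(comparison$difference),
           shared_edges = comparison$shared_edges,
           unique_to_c = comparison$unique_to_c,
           unique_to_d = comparison$unique_to_d),
      p("topology.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest <- c(manifest, p("topology.json"))
    c(nets, list(comparison = comparison))
  })

  ## -- integration ------------------------------------------------------------
  integration <- pipeline_stage("integrate", {
    merged <- align_samples(dataset$metabolites, dataset$transcripts,
                            config$alignment_strategy)
    targets <- config$target_metabolites
    if (is.null(targets)) {
      if (is.null(dataset$truth))
        stop("target_metabolites must be given when not simulating")
      targets <- sort(unique(
        dataset$truth$planted_gene_metabolite_links$metabolite_id))
    }
    miss <- setdiff(targets, rownames(dataset$metabolites$values))
    if (length(miss))
      stop(sprintf("unknown metabolite target(s): %s",
                   paste(miss, collapse = ", ")))
    note("top-%d correlators for %d target metabolite(s), %d aligned samples",
         th$k_top, length(targets), nrow(merged$sample_info))
    links <- lapply(stats::setNames(targets, targets), function(m)
      top_correlators(merged, m, k = th$k_top, alpha = th$alpha_link,
                      B = th$B, seed = config$seed))
    net <- build_gene_metabolite_network(links, dataset$de_flags,
                                         dataset$pathway_map)
    utils::write.table(net$links, p("gene_metabolite_links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sif <- with(net$links, paste(metabolite_id,
                                 ifelse(r > 0, "pcc_pos", "pcc_neg"),
                                 gene_id, sep = "\t"))
    writeLines(sif, p("gene_metabolite_network.sif"))
    ov <- if (length(links) >= 2) overlap_summary(links)
    if (!is.null(ov))
      jsonlite::write_json(ov, p("overlap_summary.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    pw <- if (!is.null(dataset$pathway_map))
      pathway_edge_summary(net$links, dataset$pathway_map)
    if (!is.null(pw))
      utils::write.table(pw, p("pathway_edge_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, p("gene_metabolite_links.tsv"),
                  p("gene_metabolite_network.sif"),
                  if (!is.null(ov)) p("overlap_summary.json"),
                  if (!is.null(pw)) p("pathway_edge_summary.tsv"))
    list(merged = merged, links = links, network = net, overlap = ov,
         pathway_summary = pw)
  })

  ## -- enrichment --------------------------------------------------------------
  enrichment <- pipeline_stage("motifs", {
    note("promoter motif scan: %d motifs x %d promoters",
         nrow(dataset$motif_library), length(dataset$promoters))
    hit_index <- build_hit_index(dataset$promoters, dataset$motif_library)
    gene_sets <- lapply(integration$links, function(l) l$gene_id)
    gene_sets <- gene_sets[vapply(gene_sets, length, integer(1)) > 0]
    motif_res <- lapply(gene_sets, motif_enrichment, hit_index = hit_index,
                        alpha = th$alpha_motif,
                        min_promoters = th$min_promoters)
    for (set in names(motif_res)) {
      f <- p(sprintf("motif_enrichment_%s.tsv", set))
      utils::write.table(motif_res[[set]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- c(manifest, f)
    }
    if (length(motif_res)) {
      sm <- enrichment_score_matrix(motif_res)
      utils::write.table(
        data.frame(motif_id = rownames(sm), sm, check.names = FALSE),
        p("motif_score_matrix.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      manifest <- c(manifest, p("motif_score_matrix.tsv"))
    }
    go_res <- NULL
    if (!is.null(dataset$go_map) && length(gene_sets)) {
      background <- names(dataset$promoters)
      go_res <- lapply(gene_sets, go_slim_enrichment, background = background,
                       term_map = dataset$go_map, fdr = th$fdr_go)
      for (set in names(go_res)) {
        f <- p(sprintf("go_enrichment_%s.tsv", set))
        utils::write.table(go_res[[set]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest <- c(manifest, f)
      }
    }
    list(hit_index = hit_index, motif = motif_res, go = go_res)
  })

  ## -- report ------------------------------------------------------------------
  report <- pipeline_stage("report", {
    missing <- manifest[!file.exists(manifest) | file.size(manifest) == 0]
    if (length(missing))
      stop(sprintf("missing or empty output(s): %s",
                   paste(missing, collapse = ", ")))
    rel <- sort(sub(paste0("^", out, "/?"), "", unname(manifest)))
    rep <- list(
      manifest = rel,
      topology = list(C = topology_summary(nets$C),
                      D = topology_summary(nets$D)),
      topology_difference = as.list(nets$comparison$difference),
      n_response_records = nrow(response),
      n_significant_responses = sum(response$significant, na.rm = TRUE),
      overlap = integration$overlap,
      n_network_genes = integration$network$n_genes,
      de_fraction = integration$network$de_fraction,
      provenance = list(
        seed = config$seed,
        thresholds = th,
        alignment_strategy = config$alignment_strategy,
        config_hash = substream_seed(config$seed, "config",
                                     jsonlite::toJSON(th, auto_unbox = TRUE)),
        package_version = as.character(utils::packageVersion("drynet"))))
    jsonlite::write_json(rep, p("report.json"), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    rep
  })
  note("pipeline complete: %d artifacts in %s", length(report$manifest), out)
  report$manifest <- file.path(out, report$manifest)
  invisible(structure(report, class = "pipeline_report"))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `seed`, `out_dir`,
#' `alignment_strategy`, `target_metabolites`, a `thresholds` block, and
#' either a `simulate` block (fields of [synth_config()], with modules as a
#' list of `{module_id, size, loading, treatment_coupling,
#' linked_gene_count}`) or an `inputs` block of file paths.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    args <- y$simulate
    if (!is.null(args$modules))
      args$modules <- lapply(args$modules, function(m) do.call(module_spec, m))
    if (!is.null(seed)) args$seed <- seed else if (is.null(args$seed))
      args$seed <- if (!is.null(y$seed)) y$seed else 1
    sim <- do.call(synth_config, args)
  }
  args <- c(list(simulate = sim, inputs = y$inputs),
            y$thresholds,
            list(target_metabolites = unlist(y$target_metabolites),
                 alignment_strategy = if (!is.null(y$alignment_strategy))
                   y$alignment_strategy else "replicate_pairing",
                 seed = if (!is.null(seed)) seed
                        else if (!is.null(y$seed)) y$seed else 1,
                 out_dir = if (!is.null(out_dir)) out_dir
                           else if (!is.null(y$out_dir)) y$out_dir
                           else "drynet_out"))
  do.call(pipeline_config, args[!vapply(args, is.null, logical(1)) |
                                  names(args) %in% c("simulate", "inputs")])
}
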