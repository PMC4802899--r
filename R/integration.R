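#' Align metabolite and transcript samples into one merged matrix
#'
#' The two assay designs differ (six metabolite stages with four replicates
#' versus three transcriptome stages with three replicates), so merging
#' requires a sample alignment. `replicate_pairing` restricts both assays to
#' the shared (treatment, stage) cells and pairs replicate i with replicate
#' i up to the smaller replicate count (default design: 3 stages x 3
#' replicates x 2 treatments = 18 aligned samples). `stage_means` averages
#' replicates within each shared cell (default design: 6 aligned samples).
#'
#' @param metab,trans [omics_matrix()] objects sharing >= 2
#'   (treatment, stage) cells.
#' @param strategy `"replicate_pairing"` or `"stage_means"`.
#' @return a `merged_matrix`: list with `values` (features x aligned
#'   samples), `origin` (named vector, `"metabolite"` or `"transcript"` per
#'   feature), `sample_info`, `strategy`.
#' @export
align_samples <- function(metab, trans,
                          strategy = c("replicate_pairing", "stage_means")) {
  strategy <- match.arg(strategy)
  md_m <- metab$metadata; md_t <- trans$metadata
  cell <- function(md) paste(md$treatment, md$stage_daa, sep = "_")
  shared <- intersect(unique(cell(md_m)), unique(cell(md_t)))
  if (length(shared) < 2)
    stop("matrices share fewer than 2 (treatment, stage) cells")
  if (any(rownames(metab$values) %in% rownames(trans$values)))
    stop("feature IDs overlap between the two matrices")

  if (strategy == "replicate_pairing") {
    keep <- list()
    for (cl in shared) {
      r_m <- md_m$replicate[cell(md_m) == cl]
      r_t <- md_t$replicate[cell(md_t) == cl]
      reps <- intersect(r_m, r_t)[seq_len(min(length(r_m), length(r_t)))]
      for (rp in sort(reps))
        keep[[paste(cl, rp)]] <- c(cell = cl, rep = rp)
    }
    ids <- vapply(keep, function(k) paste0(k[["cell"]], "_", k[["rep"]]),
                  character(1))
    pick <- function(x, md) {
      sel <- vapply(keep, function(k)
        md$sample_id[cell(md) == k[["cell"]] &
                       md$replicate == as.integer(k[["rep"]])][1],
        character(1))
      x$values[, sel, drop = FALSE]
    }
    vm <- pick(metab, md_m); vt <- pick(trans, md_t)
    colnames(vm) <- colnames(vt) <- ids
    info <- data.frame(
      sample_id = ids,
      treatment = sub("_.*", "", ids),
      stage_daa = as.integer(vapply(keep, function(k)
        sub(".*_", "", k[["cell"]]), character(1))),
      replicate = as.integer(vapply(keep, `[[`, character(1), "rep")),
      stringsAsFactors = FALSE)
  } else {
    cell_mean <- function(x, md) {
      sapply(shared, function(cl)
        rowMeans(x$values[, md$sample_id[cell(md) == cl], drop = FALSE]))
    }
    vm <- cell_mean(metab, md_m); vt <- cell_mean(trans, md_t)
    ids <- shared
    colnames(vm) <- colnames(vt) <- ids
    if (length(ids) < 3)
      stop("stage_means alignment yields fewer than 3 samples; ",
           "correlation would be undefined")
    info <- data.frame(
      sample_id = ids, treatment = sub("_.*", "", ids),
      stage_daa = as.integer(sub(".*_", "", ids)), replicate = NA_integer_,
      stringsAsFactors = FALSE)
  }
  ord <- order(info$treatment, info$stage_daa, info$replicate)
  info <- info[ord, , drop = FALSE]; rownames(info) <- NULL
  values <- rbind(vm, vt)[, info$sample_id, drop = FALSE]
  origin <- stats::setNames(
    rep(c("metabolite", "transcript"), c(nrow(vm), nrow(vt))),
    c(rownames(vm), rownames(vt)))
  structure(list(values = values, origin = origin, sample_info = info,
                 strategy = strategy), class = "merged_matrix")
}

# Permutation p with early stopping for a fixed significance gate: once the
# exceedance count can no longer satisfy p < alpha, stop permuting. The
# permutation stream is consumed in fixed chunks from the pair substream, so
# the pass/fail decision and the full-B p of passing pairs are deterministic.
permutation_gate <- function(x, y, B, seed, alpha, chunk = 250L) {
  r_obs <- abs(pearson(x, y))
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  max_count <- alpha * (B + 1) - 1  # count must stay <= this to pass
  with_seed(seed, {
    count <- 0L; done <- 0L
    while (done < B) {
      m <- min(chunk, B - done)
      perms <- vapply(seq_len(m), function(b) sample.int(n), integer(n))
      r_b <- abs(as.numeric(crossprod(xs, matrix(ys[perms], nrow = n)))) /
        (n - 1)
      count <- count + sum(r_b >= r_obs)
      done <- done + m
      if (count > max_count) break
    }
    if (count > max_count)
      list(passed = FALSE, p = NA_real_)
    else
      list(passed = (count + 1) / (B + 1) < alpha, p = (count + 1) / (B + 1))
  })
}

#' Top-k gene correlators of a metabolite
#'
#' Among transcripts whose permutation p-value against the metabolite is
#' below `alpha`, returns the `k` with the largest `|r|` (ties broken by
#' gene ID), ranked 1..k — the selection rule behind the per-monoterpene
#' "top 100 correlating genes" networks. Fewer than `k` links are returned
#' when fewer genes pass the gate.
#'
#' @param merged a `merged_matrix` from [align_samples()].
#' @param metabolite_id metabolite feature ID present in `merged`.
#' @param k maximum number of links (default 100).
#' @param alpha permutation p gate (default 0.001).
#' @param B permutations per gene (default 2000).
#' @param seed master seed for per-pair permutation substreams.
#' @param condition optional `"C"` or `"D"` to correlate within one
#'   condition only; default uses all aligned samples jointly.
#' @param rank_by `"abs"` (default) ranks by `|r|`; `"signed"` ranks by `r`
#'   descending.
#' @return data.frame `gene_id`, `metabolite_id`, `r`, `p`, `rank`.
#' @export
top_correlators <- function(merged, metabolite_id, k = 100, alpha = 0.001,
                            B = 2000, seed = 1, condition = NULL,
                            rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  if (k < 1) stop("k must be >= 1")
  if (!metabolite_id %in% names(merged$origin) ||
      merged$origin[[metabolite_id]] != "metabolite")
    stop(sprintf("unknown metabolite '%s'", metabolite_id))
  genes <- names(merged$origin)[merged$origin == "transcript"]
  if (!length(genes)) stop("no transcript features in merged matrix")
  cols <- merged$sample_info$sample_id
  if (!is.null(condition))
    cols <- cols[merged$sample_info$treatment == condition]
  if (length(cols) < 3) stop("fewer than 3 aligned samples selected")
  x <- merged$values[metabolite_id, cols]
  rows <- list()
  for (g in genes) {
    y <- merged$values[g, cols]
    if (stats::sd(y) == 0) next
    res <- permutation_gate(x, y, B = B, seed = pair_seed(seed, g, metabolite_id),
                            alpha = alpha)
    if (res$passed)
      rows[[g]] <- data.frame(gene_id = g, metabolite_id = metabolite_id,
                              r = pearson(x, y), p = res$p,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), metabolite_id = character(),
                      r = numeric(), p = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  key <- if (rank_by == "abs") -abs(df$r) else -df$r
  df <- df[order(key, df$gene_id), , drop = FALSE]
  df <- utils::head(df, k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Assemble the annotated bipartite gene-metabolite network
#'
#' Union of per-metabolite link lists as a bipartite graph; gene nodes carry
#' a DE flag and a pathway label.
#'
#' @param links_by_metabolite named list of [top_correlators()] data.frames.
#' @param de_flags character vector of DE gene IDs.
#' @param pathway_map named character vector, gene ID -> pathway label;
#'   genes absent from the map are labelled `"unannotated"`.
#' @return list with `graph` (bipartite [igraph::graph]), `links` (annotated
#'   data.frame), `genes`, `metabolites`, `n_genes`, `n_de`, `de_fraction`.
#' @export
build_gene_metabolite_network <- function(links_by_metabolite,
                                          de_flags = character(),
                                          pathway_map = NULL) {
  links <- do.call(rbind, c(links_by_metabolite, list(make.row.names = FALSE)))
  if (is.null(links) || !nrow(links))
    links <- data.frame(gene_id = character(), metabolite_id = character(),
                        r = numeric(), p = numeric(), rank = integer(),
                        stringsAsFactors = FALSE)
  links$is_de <- links$gene_id %in% de_flags
  links$pathway <- if (is.null(pathway_map)) "unannotated" else
    ifelse(links$gene_id %in% names(pathway_map),
           pathway_map[links$gene_id], "unannotated")
  genes <- sort(unique(links$gene_id))
  metabolites <- sort(unique(links$metabolite_id))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, type = "gene",
                            is_de = genes %in% de_flags,
                            pathway = if (is.null(pathway_map)) "unannotated"
                                      else ifelse(genes %in% names(pathway_map),
                                                  pathway_map[genes],
                                                  "unannotated"))
  g <- igraph::add_vertices(g, length(metabolites), name = metabolites,
                            type = "metabolite", is_de = FALSE,
                            pathway = "metabolite")
  if (nrow(links))
    g <- igraph::add_edges(
      g, rbind(match(links$gene_id, c(genes, metabolites)),
               match(links$metabolite_id, c(genes, metabolites))),
      r = links$r, p = links$p)
  n_de <- sum(genes %in% de_flags)
  list(graph = g, links = links, genes = genes, metabolites = metabolites,
       n_genes = length(genes), n_de = n_de,
       de_fraction = if (length(genes)) n_de / length(genes) else NA_real_)
}

#' Venn-style overlap accounting of per-metabolite gene link sets
#'
#' Exact counts of genes specific to one metabolite, shared by exactly each
#' pair, and shared by all metabolites.
#'
#' @param links_by_metabolite named list of link data.frames (or character
#'   vectors of gene IDs).
#' @return list with `per_metabolite_specific` (named integer),
#'   `pairwise_shared` (named integer, names `"a|b"`, genes in exactly those
#'   two sets), `shared_by_all` (integer).
#' @export
overlap_summary <- function(links_by_metabolite) {
  if (length(links_by_metabolite) < 2)
    stop("need at least 2 metabolites for overlap accounting")
  sets <- lapply(links_by_metabolite, function(l)
    unique(if (is.data.frame(l)) l$gene_id else as.character(l)))
  mets <- names(sets)
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s,
                 logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, mets))
  n_in <- rowSums(memb)
  specific <- vapply(mets, function(m) sum(memb[, m] & n_in == 1), integer(1))
  prs <- utils::combn(mets, 2)
  pairwise <- stats::setNames(integer(ncol(prs)),
                              apply(prs, 2, paste, collapse = "|"))
  for (j in seq_len(ncol(prs)))
    pairwise[j] <- sum(memb[, prs[1, j]] & memb[, prs[2, j]] & n_in == 2)
  list(per_metabolite_specific = specific,
       pairwise_shared = pairwise,
       shared_by_all = sum(n_in == length(mets)))
}

#' Pathway-level tally of positive and negative gene-metabolite links
#'
#' Counts, per pathway, the links with positive and negative correlation —
#' the Table S7-style summary of how treatment reshapes pathway-level
#' coupling.
#'
#' @param links a link data.frame with columns `gene_id` and `r`.
#' @param pathway_map named character vector, gene ID -> pathway; unmapped
#'   genes are tallied under `"unannotated"`.
#' @param condition label copied into the output (e.g. `"C"`, `"D"`,
#'   `"joint"`).
#' @return data.frame `pathway`, `n_positive`, `n_negative`, `condition`.
#' @export
pathway_edge_summary <- function(links, pathway_map, condition = "joint") {
  pw <- ifelse(links$gene_id %in% names(pathway_map),
               pathway_map[links$gene_id], "unannotated")
  out <- do.call(rbind, lapply(sort(unique(pw)), function(p) {
    sel <- pw == p
    data.frame(pathway = p, n_positive = sum(links$r[sel] > 0),
               n_negative = sum(links$r[sel] < 0), condition = condition,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(pathway = character(), n_positive = integer(),
                      n_negative = integer(), condition = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
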