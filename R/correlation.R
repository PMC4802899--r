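#' Pearson correlation with explicit preconditions
#'
#' The similarity index used throughout: the sample Pearson correlation
#' coefficient (PCC). Errors on length mismatch, fewer than 3 paired
#' observations, or zero variance in either vector.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the PCC, in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided permutation test: `y` is permuted `B` times, and
#' `p = (#\{b : |r_b| >= |r_obs|\} + 1) / (B + 1)`. The +1 correction makes
#' the smallest attainable p equal to `1/(B+1)` (so with B = 2000 the
#' P < 0.001 gate is attainable, min p ~ 0.0005); ties in `|r|` count
#' toward the exceedance set.
#'
#' @param x,y numeric vectors (see [pearson()] for preconditions).
#' @param B number of permutations (default 2000).
#' @param seed integer seed for the permutation stream.
#' @return the permutation p-value, in `[1/(B+1), 1]`.
#' @export
permutation_pvalue <- function(x, y, B = 2000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  r_obs <- pearson(x, y)
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  perms <- with_seed(seed,
    vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  # r_b = <xs, ys[perm]> / (n - 1), all permutations in one matrix product
  r_b <- as.numeric(crossprod(xs, matrix(ys[perms], nrow = n))) / (n - 1)
  (sum(abs(r_b) >= abs(r_obs)) + 1) / (B + 1)
}

# Substream seed for the permutation test of one unordered feature pair.
pair_seed <- function(seed, a, b) {
  pr <- sort(c(a, b))
  substream_seed(seed, "perm", pr[1], pr[2])
}

#' Build the condition-specific metabolite correlation network
#'
#' Computes all pairwise PCCs on the samples of one condition and keeps the
#' edges passing the study gate `|r| > r_min` and permutation `p < alpha`.
#' Because the gate is a conjunction, the permutation test is only run for
#' pairs that already exceed `r_min`; each pair uses its own RNG substream
#' derived from `(seed, feature_a, feature_b)`, so results do not depend on
#' evaluation order. Features with zero variance in the condition are kept
#' as isolated nodes and reported with a warning.
#'
#' @param x an [omics_matrix()].
#' @param condition `"C"` or `"D"`.
#' @param r_min PCC magnitude threshold (default 0.8).
#' @param alpha permutation p threshold (default 0.001).
#' @param B permutations per pair (default 2000).
#' @param seed master seed for the permutation substreams.
#' @param log_scale correlate log-transformed abundances instead of raw
#'   concentrations (default `FALSE`).
#' @return a `corr_network`: list with `condition`, `nodes`, `edges`
#'   (data.frame `feature_a`, `feature_b`, `r`, `p`, `sign`), `thresholds`.
#' @export
build_condition_network <- function(x, condition, r_min = 0.8, alpha = 0.001,
                                    B = 2000, seed = 1, log_scale = FALSE) {
  vals <- condition_samples(x, condition)
  if (ncol(vals) < 3) stop("need at least 3 samples in the condition")
  if (log_scale) vals <- log(vals)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    warning(sprintf("%d zero-variance feature(s) kept as isolated nodes: %s",
                    sum(sds == 0),
                    paste(utils::head(rownames(vals)[sds == 0], 5),
                          collapse = ", ")))
  ok <- rownames(vals)[sds > 0]
  rmat <- stats::cor(t(vals[ok, , drop = FALSE]))
  idx <- which(upper.tri(rmat) & abs(rmat) > r_min, arr.ind = TRUE)
  edges <- list()
  if (nrow(idx)) {
    for (j in seq_len(nrow(idx))) {
      a <- ok[idx[j, 1]]; b <- ok[idx[j, 2]]
      pr <- sort(c(a, b))
      p <- permutation_pvalue(vals[pr[1], ], vals[pr[2], ], B = B,
                              seed = pair_seed(seed, a, b))
      if (p < alpha) {
        r <- rmat[idx[j, 1], idx[j, 2]]
        edges[[length(edges) + 1L]] <- data.frame(
          feature_a = pr[1], feature_b = pr[2], r = r, p = p,
          sign = if (r > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(feature_a = character(), feature_b = character(),
               r = numeric(), p = numeric(), sign = character(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition = condition, nodes = rownames(vals),
                 edges = edges,
                 thresholds = list(r_min = r_min, alpha = alpha, B = B)),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network [%s]: %d nodes, %d edges (|r| > %g, p < %g, B = %d)\n",
              x$condition, length(x$nodes), nrow(x$edges),
              x$thresholds$r_min, x$thresholds$alpha, x$thresholds$B))
  invisible(x)
}

corr_network_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(
      g, rbind(match(net$edges$feature_a, net$nodes),
               match(net$edges$feature_b, net$nodes)),
      weight = net$edges$r)
  g
}

#' Cytoscape-style topology summary of a correlation network
#'
#' Metrics follow the conventions of Cytoscape's network analyzer as used
#' for the published networks: `avg_degree` (the "average node neighborhood")
#' is the mean degree over connected nodes (degree >= 1);
#' `clustering_coefficient` is the mean local clustering coefficient over
#' connected nodes, with degree-1 nodes contributing 0; `density` is
#' realized over possible edges among connected nodes. An empty edge set
#' gives all metrics 0.
#'
#' @param net a `corr_network` (or any list with `nodes` and an `edges`
#'   data.frame with columns `feature_a`, `feature_b`).
#' @return a `topology_summary` list: `n_connected_nodes`, `n_edges`,
#'   `avg_degree`, `clustering_coefficient`, `density`.
#' @export
topology_summary <- function(net) {
  g <- corr_network_igraph(net)
  deg <- igraph::degree(g)
  conn <- deg >= 1
  n_c <- sum(conn)
  n_e <- igraph::ecount(g)
  if (n_e == 0)
    return(structure(list(n_connected_nodes = 0L, n_edges = 0L,
                          avg_degree = 0, clustering_coefficient = 0,
                          density = 0), class = "topology_summary"))
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  structure(list(
    n_connected_nodes = as.integer(n_c),
    n_edges = as.integer(n_e),
    avg_degree = mean(deg[conn]),
    clustering_coefficient = mean(local_cc[conn]),
    density = if (n_c >= 2) 2 * n_e / (n_c * (n_c - 1)) else 0),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("topology: %d connected nodes, %d edges, avg degree %.3f, ",
                     "clustering %.3f, density %.3f\n"),
              x$n_connected_nodes, x$n_edges, x$avg_degree,
              x$clustering_coefficient, x$density))
  invisible(x)
}

edge_keys <- function(edges) {
  if (!nrow(edges)) return(character())
  paste(pmin(edges$feature_a, edges$feature_b),
        pmax(edges$feature_a, edges$feature_b), sep = "|")
}

#' Compare the control and deficit networks
#'
#' Topology summaries for both conditions, their differences (D minus C),
#' and the decomposition of the edge sets into shared and condition-unique
#' edges.
#'
#' @param net_c,net_d `corr_network` objects over the same node universe.
#' @return a `network_comparison` list: `summary_c`, `summary_d`,
#'   `difference` (named numeric, D - C), `shared_edges`, `unique_to_c`,
#'   `unique_to_d` (edge key character vectors).
#' @export
compare_conditions <- function(net_c, net_d) {
  if (!setequal(net_c$nodes, net_d$nodes))
    stop("networks must share the same node universe")
  s_c <- topology_summary(net_c)
  s_d <- topology_summary(net_d)
  k_c <- edge_keys(net_c$edges)
  k_d <- edge_keys(net_d$edges)
  metrics <- c("n_connected_nodes", "n_edges", "avg_degree",
               "clustering_coefficient", "density")
  structure(list(
    summary_c = s_c, summary_d = s_d,
    difference = stats::setNames(
      vapply(metrics, function(m) as.numeric(s_d[[m]]) - as.numeric(s_c[[m]]),
             numeric(1)), metrics),
    shared_edges = sort(intersect(k_c, k_d)),
    unique_to_c = sort(setdiff(k_c, k_d)),
    unique_to_d = sort(setdiff(k_d, k_c))),
    class = "network_comparison")
}

#' Write a network edge list as SIF and TSV
#'
#' SIF rows are `feature_a<TAB>pcc_pos|pcc_neg<TAB>feature_b`; the TSV keeps
#' the full edge record (`feature_a`, `feature_b`, `r`, `p`, `sign`).
#'
#' @param net a `corr_network`.
#' @param sif_path,tsv_path output paths (either may be `NULL` to skip).
#' @return written paths, invisibly.
#' @export
write_network <- function(net, sif_path = NULL, tsv_path = NULL) {
  if (!is.null(sif_path)) {
    rel <- ifelse(net$edges$sign == "positive", "pcc_pos", "pcc_neg")
    writeLines(if (nrow(net$edges))
      paste(net$edges$feature_a, rel, net$edges$feature_b, sep = "\t")
      else character(), sif_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(sif_path, tsv_path))
}
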