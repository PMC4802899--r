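# Shared fixtures and independent oracles used across the test files.

# -- small synthetic configurations -----------------------------------------

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_metabolites = 12, n_genes = 30,
               regulon_size = 10, promoter_length = 120,
               modules = list(module_spec("m1", 4, 0.9, "both", 2)))
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# -- brute-force graph topology oracle ---------------------------------------

# Plain-loop degree / local-clustering / density computation from an edge
# list, independent of igraph.
brute_topology <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$feature_a[i], edges$feature_b[i]] <- TRUE
    adj[edges$feature_b[i], edges$feature_a[i]] <- TRUE
  }
  deg <- rowSums(adj)
  conn <- deg >= 1
  if (!any(conn))
    return(list(n_connected_nodes = 0L, n_edges = 0L, avg_degree = 0,
                clustering_coefficient = 0, density = 0))
  local_cc <- vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    links <- sum(vapply(seq_len(ncol(pairs)), function(j)
      adj[pairs[1, j], pairs[2, j]], logical(1)))
    links / ncol(pairs)
  }, numeric(1))
  n_c <- sum(conn)
  list(n_connected_nodes = n_c, n_edges = nrow(edges),
       avg_degree = mean(deg[conn]),
       clustering_coefficient = mean(local_cc[conn]),
       density = if (n_c >= 2) 2 * nrow(edges) / (n_c * (n_c - 1)) else 0)
}

random_graph_edges <- function(n_nodes, p = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < p
  list(nodes = nodes,
       edges = data.frame(feature_a = prs[1, keep], feature_b = prs[2, keep],
                          stringsAsFactors = FALSE))
}

as_net <- function(nodes, edges) {
  structure(list(condition = "X", nodes = nodes, edges = edges,
                 thresholds = list(r_min = 0, alpha = 1, B = 1)),
            class = "corr_network")
}

# -- exact hypergeometric upper tail by combinatorial enumeration ------------

brute_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# -- step-up BH reference implementation -------------------------------------

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# -- IUPAC regex scanning oracle ---------------------------------------------

iupac_regex <- function(consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           M = "[AC]", K = "[GT]", S = "[CG]", W = "[AT]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(toupper(consensus), "")[[1]]], collapse = "")
}

# overlapping-match count via lookahead-free sliding regex
regex_count <- function(seq, consensus) {
  w <- nchar(consensus)
  windows <- substring(seq, seq_len(nchar(seq) - w + 1),
                       seq_len(nchar(seq) - w + 1) + w - 1)
  sum(grepl(paste0("^", iupac_regex(consensus), "$"), windows))
}

revcomp_str <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# -- consensus containment (IUPAC-aware, either strand) ----------------------

# Two consensi are related when the shorter one can match inside the longer
# under IUPAC ambiguity on either strand; such motifs share planted sites
# (as with asterisked consensus-sharing elements on published heatmaps) and
# are therefore not decoys.
consensus_related <- function(a, b) {
  if (identical(a, b)) return(TRUE)
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  subj <- Biostrings::DNAString(long)
  n <- Biostrings::countPattern(short, subj, fixed = FALSE) +
    Biostrings::countPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(short))),
      subj, fixed = FALSE)
  n > 0
}

# -- misc ---------------------------------------------------------------------

edge_key_set <- function(edges) {
  if (!nrow(edges)) return(character())
  paste(pmin(edges$feature_a, edges$feature_b),
        pmax(edges$feature_a, edges$feature_b), sep = "|")
}

planted_keys <- function(truth, condition) {
  pe <- truth$planted_edges
  pe <- pe[pe$condition == condition, , drop = FALSE]
  paste(pmin(pe$feature_a, pe$feature_b),
        pmax(pe$feature_a, pe$feature_b), sep = "|")
}
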