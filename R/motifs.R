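IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_bases <- function(ch) {
  out <- IUPAC_CODES[[ch]]
  if (is.null(out)) stop(sprintf("invalid IUPAC code '%s'", ch))
  out
}

#' A degenerate IUPAC consensus motif
#'
#' @param motif_id motif label (e.g. a PLACE identifier).
#' @param consensus consensus string over the 15-letter IUPAC DNA alphabet.
#' @param source catalogue label (default `"PLACE"`).
#' @return an `iupac_motif` list; errors on an invalid consensus character.
#' @export
iupac_motif <- function(motif_id, consensus, source = "PLACE") {
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  chars <- strsplit(consensus, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' in motif %s", bad[1], motif_id))
  structure(list(motif_id = motif_id, consensus = consensus, source = source),
            class = "iupac_motif")
}

#' Count degenerate motif matches in one promoter
#'
#' Matches the consensus under IUPAC degeneracy on the forward strand and,
#' with `both_strands = TRUE` (the default: cis-elements are taken to be
#' functional on either strand), adds matches of the reverse complement of
#' the consensus. The promoter sequence is read literally: an `N` in the
#' sequence is matched only by an `N` in the motif.
#'
#' @param sequence promoter DNA string (A/C/G/T, N allowed) or
#'   [Biostrings::DNAString].
#' @param motif an [iupac_motif()] (or consensus string).
#' @param both_strands scan both strands (default `TRUE`).
#' @return integer match count (overlapping matches all count).
#' @export
scan_promoter <- function(sequence, motif, both_strands = TRUE) {
  if (is.character(motif)) motif <- iupac_motif("motif", motif)
  subject <- if (inherits(sequence, "DNAString")) sequence
             else Biostrings::DNAString(toupper(sequence))
  if (length(subject) < nchar(motif$consensus))
    stop("sequence shorter than motif consensus")
  n <- Biostrings::countPattern(motif$consensus, subject, fixed = "subject")
  if (both_strands)
    n <- n + Biostrings::countPattern(revcomp_chr(motif$consensus), subject,
                                      fixed = "subject")
  n
}

#' Index which promoters contain each motif
#'
#' For every motif, the set of genes whose promoter carries at least one
#' match ("associated" promoters); presence/absence is what feeds the
#' enrichment test, so match multiplicity is not recorded here.
#'
#' @param promoters named [Biostrings::DNAStringSet] (or named character
#'   vector), one promoter per gene.
#' @param motifs list of [iupac_motif()] objects, or a data.frame with
#'   columns `motif_id` and `consensus`.
#' @param both_strands scan both strands (default `TRUE`).
#' @return a `motif_hit_index`: list with `hits` (named list, motif ->
#'   character vector of gene IDs) and `background_size`.
#' @export
build_hit_index <- function(promoters, motifs, both_strands = TRUE) {
  if (is.character(promoters)) promoters <- Biostrings::DNAStringSet(promoters)
  if (!length(promoters)) stop("promoter set is empty")
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop("promoters must have unique gene names")
  if (is.data.frame(motifs))
    motifs <- mapply(iupac_motif, motifs$motif_id, motifs$consensus,
                     if ("source" %in% names(motifs)) motifs$source else "PLACE",
                     SIMPLIFY = FALSE)
  hits <- list()
  for (m in motifs) {
    cnt <- Biostrings::vcountPattern(m$consensus, promoters, fixed = "subject")
    if (both_strands)
      cnt <- cnt + Biostrings::vcountPattern(revcomp_chr(m$consensus),
                                             promoters, fixed = "subject")
    hits[[m$motif_id]] <- names(promoters)[cnt > 0]
  }
  structure(list(hits = hits, background_size = length(promoters),
                 background = names(promoters)),
            class = "motif_hit_index")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes when drawing `n` genes without
#' replacement from a universe of `N` genes of which `K` are annotated.
#'
#' @param k observed annotated genes in the set.
#' @param K annotated genes in the background.
#' @param n gene-set size.
#' @param N background size.
#' @return the upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric bounds: need 0 <= k <= min(K, n), K,n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input and capped at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Motif enrichment in a gene set
#'
#' Hypergeometric upper-tail test of each motif's associated promoters in
#' the gene set against the full promoter background. Following the study's
#' rule, a motif is significant when its raw p-value is below `alpha`
#' (default 0.01) and at least `min_promoters` (default 10) gene-set
#' promoters carry the motif; no FDR correction is applied at this stage.
#' The enrichment score is `-log10(p)` (score 2 at p = 0.01, 4 at
#' p = 0.0001).
#'
#' @param gene_set character vector of gene IDs, a subset of the background.
#' @param hit_index a `motif_hit_index` from [build_hit_index()].
#' @param alpha raw p-value threshold (default 0.01).
#' @param min_promoters minimum associated promoters in the gene set
#'   (default 10).
#' @return data.frame `id`, `k`, `K`, `n`, `N`, `p`, `p_adjusted` (`NA`
#'   here), `score`, `significant`, sorted by p then id.
#' @export
motif_enrichment <- function(gene_set, hit_index, alpha = 0.01,
                             min_promoters = 10) {
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, hit_index$background)
  if (length(missing))
    stop(sprintf("gene(s) not in promoter background: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  N <- hit_index$background_size
  n <- length(gene_set)
  out <- do.call(rbind, lapply(names(hit_index$hits), function(id) {
    K <- length(hit_index$hits[[id]])
    k <- length(intersect(hit_index$hits[[id]], gene_set))
    p <- hypergeometric_upper_tail(k, K, n, N)
    data.frame(id = id, k = k, K = K, n = n, N = N, p = p,
               p_adjusted = NA_real_, score = -log10(p),
               significant = p < alpha && k >= min_promoters,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO-slim term enrichment in a gene set
#'
#' Hypergeometric upper-tail test per term with Benjamini-Hochberg FDR
#' control across terms; a term is significant when its adjusted p-value is
#' below `fdr` (default 0.05). Term gene sets are intersected with the
#' background before testing.
#'
#' @param gene_set character vector of gene IDs, a subset of `background`.
#' @param background character vector: the gene universe.
#' @param term_map named list, term -> character vector of annotated genes.
#' @param fdr adjusted-p threshold (default 0.05).
#' @return data.frame as in [motif_enrichment()], with `p_adjusted` filled
#'   and `significant = p_adjusted < fdr`, sorted by p then id.
#' @export
go_slim_enrichment <- function(gene_set, background, term_map, fdr = 0.05) {
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, background)
  if (length(missing))
    stop(sprintf("gene(s) not in background: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  if (!length(term_map)) {
    warning("empty term map; no enrichment computed")
    return(data.frame(id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adjusted = numeric(), score = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  N <- length(unique(background))
  n <- length(gene_set)
  out <- do.call(rbind, lapply(names(term_map), function(tm) {
    ann <- intersect(unique(term_map[[tm]]), background)
    K <- length(ann)
    k <- length(intersect(ann, gene_set))
    p <- hypergeometric_upper_tail(k, K, n, N)
    data.frame(id = tm, k = k, K = K, n = n, N = N, p = p,
               p_adjusted = NA_real_, score = -log10(p), significant = NA,
               stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted < fdr
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a motif table / promoter FASTA / term map
#'
#' `read_motif_tsv()` expects columns `motif_id` and `consensus` (optional
#' `source`); `read_promoters()` reads a FASTA with gene IDs as record
#' names; `read_term_map()` expects columns `term` and `gene_id`.
#'
#' @param path input file path.
#' @return motifs as a list of [iupac_motif()]; promoters as a named
#'   [Biostrings::DNAStringSet]; the term map as a named list.
#' @export
read_motif_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  mapply(iupac_motif, df$motif_id, df$consensus,
         if ("source" %in% names(df)) df$source else "PLACE",
         SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' @rdname read_motif_tsv
#' @export
read_promoters <- function(path) {
  ps <- Biostrings::readDNAStringSet(path)
  names(ps) <- sub("\\s.*$", "", names(ps))
  ps
}

#' @rdname read_motif_tsv
#' @export
read_term_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  split(df$gene_id, df$term)
}

#' Heatmap-ready motif score matrix
#'
#' Motif x gene-set matrix of enrichment scores (`-log10 p`), with
#' non-significant cells set to `NA` — the tabular analogue of the
#' enrichment heatmap.
#'
#' @param enrichments named list of [motif_enrichment()] results, one per
#'   gene set.
#' @return numeric matrix, motifs in rows, gene sets in columns.
#' @export
enrichment_score_matrix <- function(enrichments) {
  ids <- sort(unique(unlist(lapply(enrichments, `[[`, "id"))))
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(enrichments),
                dimnames = list(ids, names(enrichments)))
  for (set in names(enrichments)) {
    e <- enrichments[[set]]
    sig <- e[e$significant, , drop = FALSE]
    out[sig$id, set] <- sig$score
  }
  out
}
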