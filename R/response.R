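#' Log2 fold change of group means (D over C)
#'
#' The heatmap statistic of the stage-wise treatment comparison:
#' `log2(mean(values_D) / mean(values_C))`, on raw concentrations.
#'
#' @param values_C,values_D positive concentration values of the control and
#'   deficit groups at one stage.
#' @return the log2 fold change (numeric scalar).
#' @export
log2_fold_change <- function(values_C, values_D) {
  if (!length(values_C) || !length(values_D))
    stop("both groups must be non-empty")
  m_c <- mean(values_C); m_d <- mean(values_D)
  if (!is.finite(m_c) || !is.finite(m_d) || m_c <= 0 || m_d <= 0)
    stop("group means must be positive")
  log2(m_d / m_c)
}

#' Two-group one-way ANOVA
#'
#' The fixed-effects F test with (1, n_a + n_b - 2) degrees of freedom used
#' for the per-stage treatment comparison. With two groups F equals the
#' square of the pooled-variance t statistic. Degenerate inputs (zero pooled
#' within-group variance) are flagged: equal means give F = 0, p = 1;
#' unequal means give infinite F and p = 0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `f`, `p`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(group_a, group_b) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2)
    stop("each group needs at least 2 values")
  df2 <- n_a + n_b - 2L
  ssw <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  if (ssw <= 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(f = 0, p = 1, df1 = 1L, df2 = df2, degenerate = TRUE))
    return(list(f = Inf, p = 0, df1 = 1L, df2 = df2, degenerate = TRUE))
  }
  fit <- stats::oneway.test(
    value ~ group,
    data = data.frame(value = c(group_a, group_b),
                      group = rep(c("a", "b"), c(n_a, n_b))),
    var.equal = TRUE)
  list(f = unname(fit$statistic), p = fit$p.value,
       df1 = as.integer(fit$parameter[1]), df2 = as.integer(fit$parameter[2]),
       degenerate = FALSE)
}

#' Stage-wise treatment response table
#'
#' For every (feature, stage), the group means under C and D, the log2 fold
#' change D/C, and the one-way ANOVA F and p comparing the treatments at
#' that sampling point, with `significant = p < alpha`. No multiple-testing
#' correction is applied across features or stages (each sampling point is
#' tested at the nominal level).
#'
#' @param x an [omics_matrix()] with both treatments present.
#' @param alpha per-test significance level (default 0.05).
#' @return data.frame with one row per (feature, stage): `feature_id`,
#'   `stage_daa`, `mean_C`, `mean_D`, `log2fc`, `f_statistic`, `p_value`,
#'   `significant`, `degenerate`. Stages present in only one treatment yield
#'   `NA` statistics and `significant = NA`.
#' @export
response_table <- function(x, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  md <- x$metadata
  stages <- sort(unique(md$stage_daa))
  feats <- rownames(x$values)
  out <- vector("list", length(feats) * length(stages))
  i <- 0L
  for (f in feats) {
    for (st in stages) {
      v_c <- x$values[f, md$sample_id[md$treatment == "C" & md$stage_daa == st]]
      v_d <- x$values[f, md$sample_id[md$treatment == "D" & md$stage_daa == st]]
      i <- i + 1L
      if (length(v_c) < 2 || length(v_d) < 2) {
        out[[i]] <- data.frame(
          feature_id = f, stage_daa = st,
          mean_C = if (length(v_c)) mean(v_c) else NA_real_,
          mean_D = if (length(v_d)) mean(v_d) else NA_real_,
          log2fc = NA_real_, f_statistic = NA_real_, p_value = NA_real_,
          significant = NA, degenerate = NA, stringsAsFactors = FALSE)
        next
      }
      an <- one_way_anova(v_c, v_d)
      out[[i]] <- data.frame(
        feature_id = f, stage_daa = st, mean_C = mean(v_c), mean_D = mean(v_d),
        log2fc = log2_fold_change(v_c, v_d), f_statistic = an$f,
        p_value = an$p, significant = an$p < alpha, degenerate = an$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
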