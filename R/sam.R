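#' SAM moderated statistic for two-class differential expression
#'
#' For each gene, `d = (mean_poor - mean_good) / (s + s0)` where `s` is the
#' pooled standard error of the group-mean difference and the fudge factor
#' `s0` damps the statistic for genes with tiny variance. `s0` is taken as a
#' quantile (default the median) of the gene-wise standard errors.
#'
#' @param expr Genes-by-samples log2 matrix.
#' @param labels Character vector over samples, values `"good"` / `"poor"`.
#' @param s0_quantile Quantile of `{s_i}` used as the fudge factor.
#' @return List with `d` (named vector, positive = higher in poor
#'   prognosis), `s0`, and `se` (gene-wise pooled standard errors).
#' @export
sam_statistic <- function(expr, labels, s0_quantile = 0.5) {
  expr <- validate_expression(expr)
  stats_de <- de_group_stats(expr, labels)
  se <- stats_de$se
  if (all(se == 0)) stop("zero variance in every gene; cannot form SAM statistic")
  s0 <- stats::quantile(se, s0_quantile, names = FALSE)
  d <- stats_de$diff / (se + s0)
  list(d = stats::setNames(d, rownames(expr)), s0 = s0,
       se = stats::setNames(se, rownames(expr)))
}

## mean difference (poor - good) and pooled SE per gene
de_group_stats <- function(expr, labels) {
  if (length(labels) != ncol(expr)) stop("one label per sample required")
  if (!all(labels %in% c("good", "poor"))) stop("labels must be 'good' or 'poor'")
  g <- labels == "good"; p <- labels == "poor"
  n1 <- sum(g); n2 <- sum(p)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per class")
  m_g <- rowMeans(expr[, g, drop = FALSE])
  m_p <- rowMeans(expr[, p, drop = FALSE])
  ss_g <- rowSums((expr[, g, drop = FALSE] - m_g)^2)
  ss_p <- rowSums((expr[, p, drop = FALSE] - m_p)^2)
  pooled <- (ss_g + ss_p) / (n1 + n2 - 2)
  list(diff = m_p - m_g, se = sqrt((1 / n1 + 1 / n2) * pooled))
}

#' Signed fold change between prognosis groups
#'
#' On log2 data the ratio is `2^(mean_poor - mean_good)`, reported with the
#' signed convention of microarray tables: a ratio below 1 becomes its
#' negative reciprocal, so `-1.5` means 1.5-fold lower in poor-prognosis
#' patients. Values are in `(-Inf, -1] U [1, Inf)`.
#'
#' @inheritParams sam_statistic
#' @return Named numeric vector of signed fold changes.
#' @export
fold_change <- function(expr, labels) {
  expr <- validate_expression(expr)
  if (!all(labels %in% c("good", "poor"))) stop("labels must be 'good' or 'poor'")
  g <- labels == "good"; p <- labels == "poor"
  if (!any(g) || !any(p)) stop("need >= 1 sample per class")
  ratio <- 2^(rowMeans(expr[, p, drop = FALSE]) - rowMeans(expr[, g, drop = FALSE]))
  stats::setNames(ifelse(ratio >= 1, ratio, -1 / ratio), rownames(expr))
}

#' Permutation false discovery rates for the SAM statistic
#'
#' Estimates, for each gene, the FDR (in percent) of calling significant all
#' genes at least as extreme: the median over label permutations of the
#' number of null `|d|` values exceeding the gene's `|d|`, divided by the
#' number of genes actually called at that cut. Estimates are monotonised so
#' FDR never decreases as `|d|` shrinks. When the number of distinct label
#' assignments is at most `n_perm` the full set is enumerated, making the
#' estimate exact; otherwise `n_perm` random permutations are drawn under
#' `seed`.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed for the permutation draw.
#' @return List of class `sam_result`: `d`, `fc`, `fdr_pct`, `s0`,
#'   `n_perm` (permutations actually used), `exact` (full enumeration?),
#'   `seed`.
#' @export
permutation_fdr <- function(expr, labels, n_perm = 200, seed = 1,
                            s0_quantile = 0.5) {
  expr <- validate_expression(expr)
  obs <- sam_statistic(expr, labels, s0_quantile)
  fc <- fold_change(expr, labels)
  n <- ncol(expr)
  n_poor <- sum(labels == "poor")
  total_perm <- choose(n, n_poor)

  if (total_perm <= n_perm) {
    poor_sets <- utils::combn(n, n_poor, simplify = FALSE)
  } else {
    set.seed(as.integer(seed))
    poor_sets <- replicate(n_perm, sample.int(n, n_poor), simplify = FALSE)
  }
  abs_obs <- abs(obs$d)
  ord <- order(abs_obs, decreasing = TRUE)
  cuts <- abs_obs[ord]                       # descending
  called <- seq_along(cuts)                  # genes called at each gene's cut

  ## per permutation: how many null |d| reach each cut
  all_null <- numeric(0)
  null_counts <- vapply(poor_sets, function(idx) {
    perm_labels <- rep("good", n)
    perm_labels[idx] <- "poor"
    d_null <- sam_statistic(expr, perm_labels, s0_quantile)$d
    all_null <<- c(all_null, d_null)
    d_abs <- sort(abs(d_null))
    length(d_abs) - findInterval(cuts, d_abs, left.open = TRUE)
  }, numeric(length(cuts)))
  if (is.null(dim(null_counts))) null_counts <- matrix(null_counts, nrow = length(cuts))
  med_false <- apply(null_counts, 1L, stats::median)

  ## pi0: fraction of genes that look null, estimated from the share of
  ## observed statistics inside the interquartile range of the null
  q <- stats::quantile(all_null, c(0.25, 0.75))
  pi0 <- min(1, sum(obs$d >= q[1] & obs$d <= q[2]) / (0.5 * length(obs$d)))

  fdr <- pmin(100, 100 * pi0 * med_false / called)
  fdr <- cummax(fdr)                         # monotone: non-increasing in |d|
  fdr_pct <- numeric(length(fdr))
  fdr_pct[ord] <- fdr
  names(fdr_pct) <- names(obs$d)

  structure(list(d = obs$d, fc = fc, fdr_pct = fdr_pct, s0 = obs$s0,
                 n_perm = length(poor_sets), exact = total_perm <= n_perm,
                 seed = as.integer(seed)),
            class = "sam_result")
}

#' Select differentially expressed genes from a SAM result
#'
#' Applies the joint criterion: absolute fold change above `fc_min` and
#' permutation FDR below `fdr_max_pct` percent.
#'
#' @param sam A `sam_result` from [permutation_fdr()].
#' @param fc_min Minimum absolute fold change (default 1.5).
#' @param fdr_max_pct Maximum FDR in percent (default 2).
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(sam, fc_min = 1.5, fdr_max_pct = 2.0) {
  stopifnot(inherits(sam, "sam_result"))
  names(sam$d)[abs(sam$fc) > fc_min & sam$fdr_pct < fdr_max_pct]
}
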