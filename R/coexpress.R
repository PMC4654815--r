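#' Configuration for co-expression network construction
#'
#' @param candidate_powers Integer soft-threshold powers to scan.
#' @param scale_free_r2_target Scale-free topology fit R-squared required to
#'   accept a power.
#' @param min_module_size Smallest cluster retained as a module; smaller
#'   clusters fall into the unassigned ("grey") pool.
#' @param merge_cut_height Eigengene dissimilarity (1 - cor) below which two
#'   detected modules are merged.
#' @param cut_height Static dendrogram cut height on the 1 - TOM tree, as a
#'   fraction of the maximum merge height.
#' @param n_bins Connectivity bins for the scale-free fit.
#' @return An object of class `network_config`.
#' @export
network_config <- function(candidate_powers = 1:20,
                           scale_free_r2_target = 0.8,
                           min_module_size = 30,
                           merge_cut_height = 0.25,
                           cut_height = 0.99,
                           n_bins = 10) {
  if (any(candidate_powers < 1)) stop("powers must be >= 1")
  if (scale_free_r2_target < 0 || scale_free_r2_target > 1)
    stop("scale_free_r2_target must be in [0, 1]")
  structure(list(candidate_powers = candidate_powers,
                 scale_free_r2_target = scale_free_r2_target,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = cut_height,
                 n_bins = n_bins),
            class = "network_config")
}

## Scale-free fit: regress log10 p(k) on log10 k over equal-width
## connectivity bins (the network-analysis convention). Returns the signed
## R^2 -- negative when the slope is positive, i.e. the degree distribution
## is not scale-free-like. Fewer than 3 populated bins means the degree
## distribution is (near-)degenerate and any power law fits it perfectly,
## so the fit is reported as 1.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3 || max(k) - min(k) <= 1e-8 * max(k)) return(1)
  breaks <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  if (length(breaks) < 4) return(1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(ok) < 3) return(1)
  fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Choose the soft-threshold power for the adjacency transform
#'
#' Scans `cfg$candidate_powers` and returns the smallest power whose signed
#' scale-free topology fit reaches `cfg$scale_free_r2_target`. If none does,
#' the power with maximal fit is returned with a warning.
#'
#' @param expr Genes-by-samples log2 matrix (>= 20 genes, >= 10 samples).
#' @param cfg A [network_config()].
#' @return Integer power with attributes `fit_r2` (per candidate) and
#'   `criterion_met`.
#' @export
pick_soft_threshold <- function(expr, cfg = network_config()) {
  expr <- validate_expression(expr)
  if (nrow(expr) < 20 || ncol(expr) < 10)
    stop("need >= 20 genes and >= 10 samples to estimate scale-free fit")
  cmat <- abs(safe_cor(t(expr)))
  diag(cmat) <- 0
  r2 <- vapply(cfg$candidate_powers, function(p) {
    scale_free_fit(rowSums(cmat^p), cfg$n_bins)
  }, numeric(1))
  ## target 0 is vacuous by definition (signed fits can be negative)
  hit <- if (cfg$scale_free_r2_target == 0) seq_along(r2) else
    which(r2 >= cfg$scale_free_r2_target)
  if (length(hit)) {
    power <- cfg$candidate_powers[hit[1L]]
    met <- TRUE
  } else {
    warning("no candidate power reached the scale-free fit target; returning argmax")
    power <- cfg$candidate_powers[which.max(r2)]
    met <- FALSE
  }
  structure(as.integer(power),
            fit_r2 = stats::setNames(r2, cfg$candidate_powers),
            criterion_met = met)
}

## Pearson correlation that errors on constant rows instead of returning NA.
safe_cor <- function(x) {
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("constant gene expression row; filter before network construction")
  stats::cor(x)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power`, unit diagonal.
#'
#' @param expr Genes-by-samples matrix.
#' @param power Soft-threshold power (>= 1).
#' @return Symmetric gene-by-gene matrix with entries in the unit interval.
#' @export
adjacency <- function(expr, power) {
  if (power < 1) stop("power must be >= 1")
  expr <- validate_expression(expr)
  a <- abs(safe_cor(t(expr)))^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Genes sharing the
#' same neighbourhood get overlap 1 even when their direct adjacency is
#' moderate, which is what makes module detection robust to single noisy
#' correlations.
#'
#' @param adj Symmetric adjacency with unit diagonal.
#' @return Symmetric TOM matrix with entries in the unit interval.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a               # sum_u a_iu a_uj (diag zeroed) + a_ij
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2        # symmetrise numerical noise
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering of the 1 - TOM dissimilarity,
#' cut at `cfg$cut_height` times the maximum merge height. Clusters smaller
#' than `cfg$min_module_size` are pooled into the reserved "grey" label.
#' Detected modules whose eigengenes correlate above
#' `1 - cfg$merge_cut_height` are then merged. Labels are `"M1", "M2", ...`
#' in decreasing module size (ties broken by first gene position), so
#' naming is deterministic.
#'
#' @param tom TOM similarity matrix from [tom_similarity()].
#' @param cfg A [network_config()].
#' @param expr Optional genes-by-samples matrix; required for the eigengene
#'   merge step (skipped, with a message, when absent).
#' @return List of class `module_partition`: `assignment` (named character
#'   vector, gene -> label) and `module_sizes`.
#' @export
cluster_modules <- function(tom, cfg = network_config(), expr = NULL) {
  diss <- stats::as.dist(1 - tom)
  hc <- stats::hclust(diss, method = "average")
  h <- cfg$cut_height * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  small <- names(sizes)[sizes < cfg$min_module_size]
  lab <- as.character(cl)
  lab[lab %in% small] <- "grey"

  if (!is.null(expr) && cfg$merge_cut_height > 0) {
    lab <- merge_close_modules(lab, expr, cfg$merge_cut_height)
  }
  assignment <- stats::setNames(relabel_modules(lab), rownames(tom))
  structure(list(assignment = assignment,
                 module_sizes = table(assignment)),
            class = "module_partition")
}

## Merge modules whose eigengenes are closer than `cut` in 1 - cor distance,
## iterating until no pair qualifies.
merge_close_modules <- function(lab, expr, cut) {
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2) return(lab)
    me <- sapply(mods, function(m) {
      eigengene_of(expr[lab == m, , drop = FALSE])$scores
    })
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= cut) return(lab)
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    lab[lab == mods[idx[2L]]] <- mods[idx[1L]]
  }
}

## Deterministic names: M1, M2, ... by decreasing size, grey preserved.
relabel_modules <- function(lab) {
  mods <- setdiff(unique(lab), "grey")
  if (!length(mods)) return(lab)
  sizes <- table(factor(lab, levels = mods))
  first <- vapply(mods, function(m) which(lab == m)[1L], integer(1))
  ord <- order(-as.vector(sizes), first)
  map <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
  out <- lab
  out[lab != "grey"] <- map[lab[lab != "grey"]]
  out
}

## First principal component of a standardized module submatrix
## (genes x samples), scores sign-oriented to correlate positively with the
## module's mean standardized expression, unit variance.
eigengene_of <- function(mod_expr) {
  z <- t(scale(t(mod_expr)))          # standardize each gene
  if (nrow(mod_expr) == 1L) {
    scores <- as.vector(z)
    ev <- 1
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    scores <- pc$x[, 1L]
    ev <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  }
  if (stats::cor(scores, colMeans(z)) < 0) scores <- -scores
  scores <- as.vector(scale(scores))
  list(scores = scores, explained_variance = ev)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix: one unit-variance summary profile per
#' module, sign-oriented so it correlates positively with the module's mean
#' expression. The grey (unassigned) pool gets no eigengene.
#'
#' @param expr Genes-by-samples matrix covering the partition's genes.
#' @param partition A `module_partition` from [cluster_modules()].
#' @return List of class `module_eigengenes`: `eigengene` (samples x
#'   modules matrix) and `explained_variance` (named vector).
#' @export
module_eigengene <- function(expr, partition) {
  expr <- validate_expression(expr)
  mods <- setdiff(names(partition$module_sizes), "grey")
  if (!length(mods)) stop("no non-grey module in partition")
  res <- lapply(mods, function(m) {
    genes <- names(partition$assignment)[partition$assignment == m]
    eigengene_of(expr[genes, , drop = FALSE])
  })
  me <- sapply(res, `[[`, "scores")
  dimnames(me) <- list(colnames(expr), mods)
  structure(list(eigengene = me,
                 explained_variance = stats::setNames(
                   vapply(res, `[[`, numeric(1), "explained_variance"), mods)),
            class = "module_eigengenes")
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation of each eigengene with each trait; two-sided p-value
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`. Binary traits
#' must be pre-encoded 0/1 (the package convention: male = 1, white = 1).
#' Missing trait values are dropped pairwise and the n used is recorded.
#'
#' @param eigengenes A `module_eigengenes`.
#' @param clinical Data frame with `sample_id` and trait columns, rows
#'   matching the eigengene samples.
#' @param traits Character vector of trait column names.
#' @return List of class `module_trait_matrix` with matrices `r`, `p`, `n`
#'   (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, clinical, traits) {
  me <- eigengenes$eigengene
  ord <- match(rownames(me), clinical$sample_id)
  if (anyNA(ord)) stop("clinical table missing eigengene samples")
  clin <- clinical[ord, , drop = FALSE]
  mods <- colnames(me)
  r <- p <- nmat <- matrix(NA_real_, length(mods), length(traits),
                           dimnames = list(mods, traits))
  for (tr in traits) {
    x <- trait_numeric(clin[[tr]], tr)
    for (m in mods) {
      ok <- !is.na(x)
      n <- sum(ok)
      if (n < 3) stop("fewer than 3 complete pairs for trait ", tr)
      if (stats::sd(x[ok]) == 0) stop("zero-variance trait: ", tr)
      rr <- stats::cor(me[ok, m], x[ok])
      tt <- rr * sqrt((n - 2) / max(1 - rr^2, .Machine$double.eps))
      r[m, tr] <- rr
      p[m, tr] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
      nmat[m, tr] <- n
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "module_trait_matrix")
}

## Encode traits numerically; binary factors get the documented 0/1 coding.
trait_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  x <- as.character(x)
  if (all(x %in% c("male", "female", NA))) return(as.numeric(x == "male"))
  if (all(x %in% c("white", "nonwhite", NA))) return(as.numeric(x == "white"))
  stop("trait ", name, " is neither numeric nor a recognised binary coding")
}

#' Select modules correlated with clinical traits of interest
#'
#' A module qualifies when its eigengene correlates with at least one of the
#' traits of interest at `p < alpha`. The grey pool never qualifies.
#'
#' @param mt A `module_trait_matrix`.
#' @param traits_of_interest Trait columns to consider (default the
#'   pulmonary-function set: FVC, DLCO and CPI).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of selected module labels.
#' @export
select_trait_modules <- function(mt, traits_of_interest = c("fvc_pct", "dlco_pct", "cpi"),
                                 alpha = 0.05) {
  if (!length(mt$p)) stop("empty module-trait matrix")
  traits <- intersect(traits_of_interest, colnames(mt$p))
  if (!length(traits)) stop("none of the traits of interest were tested")
  pm <- mt$p[, traits, drop = FALSE]
  mods <- rownames(pm)[apply(pm < alpha, 1L, any)]
  setdiff(mods, "grey")
}

#' Conventional soft-threshold default by sample size
#'
#' The fallback powers recommended for unsigned networks when the
#' scale-free criterion is inconclusive: 9 below 20 samples, 8 below 30,
#' 7 below 40, 6 otherwise.
#'
#' @param n_samples Number of samples.
#' @return Integer power.
#' @export
conventional_power <- function(n_samples) {
  if (n_samples < 20) 9L else if (n_samples < 30) 8L else if (n_samples < 40) 7L else 6L
}

#' Automatic soft-threshold choice for the pipeline
#'
#' Applies [pick_soft_threshold()] and caps the result at the
#' sample-size-based conventional default: the scale-free criterion tends
#' to select extreme powers on small cohorts, where noise correlations
#' dominate the connectivity distribution, and powering past the
#' conventional default collapses within-module adjacency faster than it
#' suppresses noise. When the criterion is not met at any candidate, the
#' conventional default is used directly.
#'
#' @inheritParams pick_soft_threshold
#' @return Integer power.
#' @export
choose_power <- function(expr, cfg = network_config()) {
  cap <- conventional_power(ncol(expr))
  p <- suppressWarnings(pick_soft_threshold(expr, cfg))
  if (attr(p, "criterion_met")) min(as.integer(p), cap) else cap
}
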