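#' Compile the prognostic predictor gene set
#'
#' Intersects the three selection criteria: membership in a trait-correlated
#' co-expression module, differential expression between observed good and
#' poor prognosis, and univariate Cox association with mortality. The order
#' of the returned set is deterministic: decreasing absolute fold change
#' (when a SAM result is supplied), then gene id.
#'
#' @param trait_modules Module labels selected by [select_trait_modules()].
#' @param partition A `module_partition`.
#' @param de_genes Genes passing the SAM criterion ([select_de_genes()]).
#' @param cox_genes Genes passing the Cox screen.
#' @param sam Optional `sam_result` used for ordering and provenance.
#' @param cox_table Optional Cox screen table for provenance.
#' @return List of class `predictor_gene_set`: `genes` (ordered ids) and
#'   `provenance` (data frame gene, module, fc, fdr_pct, cox_p).
#' @export
compile_predictor_genes <- function(trait_modules, partition, de_genes, cox_genes,
                                    sam = NULL, cox_table = NULL) {
  module_genes <- names(partition$assignment)[partition$assignment %in% trait_modules]
  genes <- intersect(intersect(module_genes, de_genes), cox_genes)
  if (length(genes) == 0L)
    stop("the three criteria have an empty intersection; relax thresholds ",
         "(alpha, fc_min, fdr_max_pct) or check that all stages ran on the ",
         "same filtered gene universe")
  fc <- if (!is.null(sam)) sam$fc[genes] else stats::setNames(rep(NA_real_, length(genes)), genes)
  ord <- order(-abs(fc), genes, na.last = TRUE)
  genes <- genes[ord]
  prov <- data.frame(
    gene = genes,
    module = unname(partition$assignment[genes]),
    fc = unname(fc[genes]),
    fdr_pct = if (!is.null(sam)) unname(sam$fdr_pct[genes]) else NA_real_,
    cox_p = if (!is.null(cox_table)) cox_table$p[match(genes, cox_table$gene)] else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(genes = genes, provenance = prov), class = "predictor_gene_set")
}

#' Fit the supervised-PCA prognostic model
#'
#' Standardizes each predictor gene by its training mean and SD, extracts
#' the first `n_components` principal components of the standardized
#' matrix, fits a cause-specific Cox model of mortality on the component
#' scores, and folds loadings, Cox coefficients and standardization into
#' per-gene weights on the raw log2 scale:
#' `W_i = sum_j beta_j v_ij / sd_i`. The prognostic index of a patient is
#' then the reporting-friendly linear score `PI = sum_i W_i X_i + c` — the
#' component-space linear predictor up to a constant shift, so risk ranking
#' is unchanged.
#'
#' @param expr_subset Genes-by-samples matrix restricted to the predictor
#'   genes.
#' @param survival_df Survival data frame for the training samples.
#' @param n_components Number of supervised principal components (default
#'   2).
#' @param offset The additive constant `c` of the prognostic index
#'   (default 13.5). It shifts every PI equally and never affects risk
#'   classes.
#' @param risk_split Percent of patients assigned low/high risk
#'   (default `c(66.7, 33.3)`, the upper-tertile convention).
#' @return List of class `prognostic_model`: `genes`, `weights`, `offset`,
#'   `n_components`, `standardization` (data frame gene, mean, sd),
#'   `risk_split`, `cox` (component-space fit summary), `threshold_pi`
#'   and `training_pi`.
#' @export
fit_supervised_pca <- function(expr_subset, survival_df, n_components = 2,
                               offset = 13.5, risk_split = c(66.7, 33.3)) {
  expr_subset <- validate_expression(expr_subset)
  sv <- match_survival(survival_df, colnames(expr_subset))
  if (sum(sv$event == 1) < 1) stop("need >= 1 death event to supervise the components")
  n_components <- as.integer(n_components)
  max_nc <- min(nrow(expr_subset), ncol(expr_subset) - 1L)
  if (n_components < 1L || n_components > max_nc)
    stop("n_components must be in [1, ", max_nc, "]")

  mu <- rowMeans(expr_subset)
  sdv <- apply(expr_subset, 1L, stats::sd)
  if (any(sdv == 0)) stop("zero-variance predictor gene; filter before fitting")
  z <- t((expr_subset - mu) / sdv)              # samples x genes, standardized
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  v <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- z %*% v

  y <- survival::Surv(sv$time_months, sv$event == 1)
  fit <- survival::coxph(y ~ scores, ties = "efron")
  if (any(!is.finite(fit$coefficients)))
    stop("Cox fit on component scores did not converge")
  beta <- as.vector(fit$coefficients)
  weights <- as.vector(v %*% beta) / sdv

  model <- structure(list(
    genes = rownames(expr_subset),
    weights = stats::setNames(weights, rownames(expr_subset)),
    offset = offset,
    n_components = n_components,
    standardization = data.frame(gene = rownames(expr_subset), mean = mu,
                                 sd = sdv, row.names = NULL,
                                 stringsAsFactors = FALSE),
    risk_split = risk_split,
    cox = cox_fit_summary(fit)),
    class = "prognostic_model")
  model$training_pi <- prognostic_index(model, expr_subset)
  model$threshold_pi <- assign_risk(model$training_pi, risk_split)$threshold_pi
  model
}

#' Prognostic index of each patient
#'
#' `PI = sum_i W_i * X_i + c` over the model genes present in the cohort
#' (missing classifier genes are dropped, as in cross-platform transfer).
#'
#' @param model A `prognostic_model`.
#' @param expr Genes-by-samples log2 matrix.
#' @return Named numeric vector of PI scores per sample.
#' @export
prognostic_index <- function(model, expr) {
  expr <- validate_expression(expr)
  al <- align_cohorts(model$genes, expr)
  w <- model$weights[rownames(al$expr)]
  pis <- as.vector(crossprod(al$expr, w)) + model$offset
  stats::setNames(pis, colnames(al$expr))
}

#' Assign low/high risk by the upper-tertile rule
#'
#' The `round(n * high_pct / 100)` patients with the largest PI are high
#' risk; the recorded threshold is the smallest high-risk PI. Ties at the
#' boundary are resolved by stable ascending sample-id order, so the split
#' is deterministic. If all PIs are identical everyone is low risk, with a
#' warning.
#'
#' @param pis Named numeric vector of prognostic indices.
#' @param split `c(low_pct, high_pct)` summing to 100 (default 66.7/33.3).
#' @return List of class `risk_assignment`: `pi`, `risk` (named
#'   `"low"`/`"high"`), `threshold_pi`, `split`.
#' @export
assign_risk <- function(pis, split = c(66.7, 33.3)) {
  if (length(pis) < 3) stop("need >= 3 samples to form tertiles")
  if (abs(sum(split) - 100) > 1e-8) stop("risk split must sum to 100")
  if (is.null(names(pis))) names(pis) <- sprintf("s%03d", seq_along(pis))
  risk <- stats::setNames(rep("low", length(pis)), names(pis))
  if (stats::sd(pis) == 0) {
    warning("all prognostic indices identical; everyone assigned low risk")
    threshold <- Inf
  } else {
    n_high <- round(length(pis) * split[2] / 100)
    ord <- order(-pis, names(pis))            # ties: ascending sample id
    high <- names(pis)[ord[seq_len(n_high)]]
    risk[high] <- "high"
    threshold <- if (n_high > 0) min(pis[high]) else Inf
  }
  structure(list(pi = pis, risk = risk, threshold_pi = threshold, split = split),
            class = "risk_assignment")
}

#' Percentile-ranking k-fold cross-validation of the prognostic model
#'
#' Repeats the classical survival-signature validation loop: each fold is held out, the
#' supervised-PCA model is refit on the remainder (the gene set itself is
#' fixed, as in the original procedure), each held-out patient's PI is
#' percentile-ranked against the retained patients' PIs, and risk is
#' assigned by whether that percentile falls in the upper `high_pct`
#' percent. The misclassification rate is
#' `(predicted-high & observed-good + predicted-low & observed-poor) / total`
#' over patients with a determinate good/poor label. Fresh random
#' partitions are drawn for each repeat; a partition leaving any training
#' fold without a death event is redrawn (bounded retries).
#'
#' @param expr_subset Predictor-gene expression matrix (genes x samples).
#' @param survival_df Survival data frame.
#' @param observed_labels Named character vector, sample -> `"good"` /
#'   `"poor"` (other values are excluded from the rate).
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated CV runs (default 1).
#' @param seed Integer seed.
#' @param n_components,risk_split Passed to [fit_supervised_pca()].
#' @return List of class `cv_report`: `fold_assignments` and
#'   `predicted_risk` (first repeat), `observed`,
#'   `misclassification_rate` (mean over repeats), `repeats` (per-repeat
#'   rates), `range`.
#' @export
cross_validate <- function(expr_subset, survival_df, observed_labels,
                           k = 10, repeats = 1, seed = 1,
                           n_components = 2, risk_split = c(66.7, 33.3)) {
  expr_subset <- validate_expression(expr_subset)
  n <- ncol(expr_subset)
  if (k > n) stop("k must be <= number of samples")
  sv <- match_survival(survival_df, colnames(expr_subset))
  obs <- observed_labels[colnames(expr_subset)]
  set.seed(as.integer(seed))

  rates <- numeric(repeats)
  first <- NULL
  for (rep_i in seq_len(repeats)) {
    folds <- draw_folds(n, k, sv$event)
    predicted <- stats::setNames(rep(NA_character_, n), colnames(expr_subset))
    for (f in seq_len(k)) {
      hold <- folds == f
      model <- fit_supervised_pca(expr_subset[, !hold, drop = FALSE],
                                  sv[!hold, , drop = FALSE],
                                  n_components = n_components,
                                  risk_split = risk_split)
      ref_pi <- model$training_pi
      out_pi <- prognostic_index(model, expr_subset[, hold, drop = FALSE])
      pct <- vapply(out_pi, function(x) {
        100 * (sum(ref_pi < x) + 0.5 * sum(ref_pi == x)) / length(ref_pi)
      }, numeric(1))
      predicted[hold] <- ifelse(pct > risk_split[1], "high", "low")
    }
    det <- obs %in% c("good", "poor")
    mis <- (predicted == "high" & obs == "good") |
           (predicted == "low" & obs == "poor")
    rates[rep_i] <- sum(mis[det]) / sum(det)
    if (rep_i == 1L) {
      first <- list(fold_assignments = stats::setNames(folds, colnames(expr_subset)),
                    predicted_risk = predicted)
    }
  }
  structure(list(fold_assignments = first$fold_assignments,
                 predicted_risk = first$predicted_risk,
                 observed = obs,
                 misclassification_rate = mean(rates),
                 repeats = rates,
                 range = range(rates)),
            class = "cv_report")
}

## random k-fold partition whose every training complement has >= 1 death
draw_folds <- function(n, k, event, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    folds <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(f) sum(event[folds != f] == 1) >= 1,
                     logical(1)))
    if (ok) return(folds)
  }
  stop("could not draw a fold partition keeping a death event in every training set")
}
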