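#' Transfer a trained prognostic model to an independent cohort
#'
#' Keeps the training weights unchanged, drops classifier genes the target
#' platform lacks, computes each patient's PI, re-derives the upper-tertile
#' threshold within the validation cohort (the default;
#' `threshold = "training"` instead carries the training cut), and runs the
#' survival analyses: log-rank between risk groups, univariate Fine-Gray
#' regression on PI, and the CPI-adjusted competing-risk fit when CPI is
#' available.
#'
#' @param model A `prognostic_model`.
#' @param expr Validation genes-by-samples matrix.
#' @param survival_df Validation survival data frame.
#' @param clinical Optional validation clinical data frame (for `cpi`).
#' @param cohort_id Label stored in the report.
#' @param threshold `"cohort"` (re-derive tertile, default) or
#'   `"training"`.
#' @return List of class `validation_report`: `cohort_id`,
#'   `n_classifiers_used`, `missing_genes`, `risk` (a `risk_assignment`),
#'   `logrank`, `univariate` (Fine-Gray on PI), `cpi_adjusted` (or NULL).
#' @export
transfer_and_validate <- function(model, expr, survival_df, clinical = NULL,
                                  cohort_id = "validation",
                                  threshold = c("cohort", "training")) {
  threshold <- match.arg(threshold)
  al <- align_cohorts(model$genes, expr)
  pis <- prognostic_index(model, expr)
  if (threshold == "cohort") {
    risk <- assign_risk(pis, model$risk_split)
  } else {
    rk <- ifelse(pis >= model$threshold_pi, "high", "low")
    risk <- structure(list(pi = pis, risk = stats::setNames(rk, names(pis)),
                           threshold_pi = model$threshold_pi,
                           split = model$risk_split),
                      class = "risk_assignment")
  }
  sv <- match_survival(survival_df, names(pis))
  logrank <- km_logrank(risk$risk, sv)
  univariate <- fine_gray_fit(data.frame(pi = unname(pis)), sv, term = "pi")
  cpi_adj <- NULL
  if (!is.null(clinical) && "cpi" %in% names(clinical)) {
    cpi <- clinical$cpi[match(names(pis), clinical$sample_id)]
    if (!anyNA(cpi)) cpi_adj <- cox_adjusted(unname(pis), cpi, sv, "fine_gray")
  }
  structure(list(cohort_id = cohort_id,
                 n_classifiers_used = nrow(al$expr),
                 missing_genes = al$missing,
                 risk = risk, logrank = logrank,
                 univariate = univariate, cpi_adjusted = cpi_adj),
            class = "validation_report")
}

#' Fold-change concordance between cohorts
#'
#' For every shared model gene, computes the signed fold change between
#' predicted low- and high-risk patients separately in each cohort, then
#' correlates the two fold-change profiles across genes (Pearson). High
#' concordance indicates the classifier contrasts transfer across
#' platforms.
#'
#' @param model_genes Classifier gene ids.
#' @param expr_train,risk_train Training expression and its
#'   `risk_assignment` (or named low/high vector).
#' @param expr_valid,risk_valid Validation cohort counterparts.
#' @return List: `r`, `p`, `n_genes`, `fc` (data frame gene, fc_train,
#'   fc_valid).
#' @export
fc_concordance <- function(model_genes, expr_train, risk_train,
                           expr_valid, risk_valid) {
  fc_of <- function(expr, risk) {
    if (inherits(risk, "risk_assignment")) risk <- risk$risk
    expr <- expr[intersect(model_genes, rownames(expr)), names(risk), drop = FALSE]
    if (length(unique(risk)) < 2) stop("need both risk classes in each cohort")
    ## low risk plays the "good" role, high risk the "poor" role
    fold_change(expr, ifelse(risk == "low", "good", "poor"))
  }
  fc1 <- fc_of(expr_train, risk_train)
  fc2 <- fc_of(expr_valid, risk_valid)
  shared <- intersect(names(fc1), names(fc2))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  if (stats::sd(fc1[shared]) == 0 || stats::sd(fc2[shared]) == 0)
    stop("degenerate fold-change vector")
  ct <- stats::cor.test(fc1[shared], fc2[shared])
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = length(shared),
       fc = data.frame(gene = shared, fc_train = unname(fc1[shared]),
                       fc_valid = unname(fc2[shared]), stringsAsFactors = FALSE))
}

#' ROC curve and AUC of the prognostic index as a diagnostic score
#'
#' Empirical ROC over all score thresholds, with cases (`"IPF"`) expected
#' to score higher than controls. The trapezoid AUC equals the
#' Mann-Whitney concordance probability. Sensitivity is also interpolated
#' at a fixed false-positive rate (default 10%).
#'
#' @param pis Numeric scores.
#' @param labels Character vector, `"IPF"` (case) / `"control"`.
#' @param at_fpr False-positive rate at which to report sensitivity.
#' @return List of class `roc_result`: `fpr`, `tpr` (monotone step
#'   coordinates), `auc`, `sens_at_fpr`.
#' @export
roc_of_pi <- function(pis, labels, at_fpr = 0.10) {
  if (length(unique(labels)) < 2) stop("both classes required")
  case <- labels == "IPF"
  ## sweep thresholds from +Inf down: each step adds the samples at one score
  ord <- order(pis, decreasing = TRUE)
  tp <- cumsum(case[ord]); fp <- cumsum(!case[ord])
  ## collapse ties so the curve has one point per distinct score
  keep <- which(!duplicated(pis[ord], fromLast = TRUE))
  tpr <- c(0, tp[keep] / sum(case))
  fpr <- c(0, fp[keep] / sum(!case))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  sens <- stats::approx(fpr, tpr, xout = at_fpr, method = "constant",
                        ties = max, rule = 2)$y
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 sens_at_fpr = stats::setNames(sens, at_fpr)),
            class = "roc_result")
}

#' Correlate the prognostic index with clinical variables
#'
#' Continuous variables get a Pearson correlation test; binary variables
#' (sex, race) a Welch two-sample t-test of PI location between the two
#' levels.
#'
#' @param pis Named numeric vector of PI scores.
#' @param clinical Clinical data frame with `sample_id`.
#' @param variables Clinical column names to test.
#' @return Data frame: variable, type, statistic (r or t), p.
#' @export
correlate_pi_clinical <- function(pis, clinical,
                                  variables = c("cpi", "age", "sex", "race")) {
  clin <- clinical[match(names(pis), clinical$sample_id), , drop = FALSE]
  rows <- lapply(variables, function(v) {
    x <- clin[[v]]
    if (is.null(x)) return(NULL)
    if (is.numeric(x)) {
      if (stats::sd(x, na.rm = TRUE) == 0) stop("zero-variance variable: ", v)
      ct <- stats::cor.test(pis, x)
      data.frame(variable = v, type = "pearson",
                 statistic = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    } else {
      lv <- unique(stats::na.omit(x))
      if (length(lv) != 2) stop("binary variable expected: ", v)
      tt <- stats::t.test(pis[x == lv[1]], pis[x == lv[2]])
      data.frame(variable = v, type = "welch_t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' One-way ANOVA from group summary statistics
#'
#' Recovers the exact F test from per-group means, standard deviations and
#' sizes: between-group sum of squares from the means, within-group sum of
#' squares as `sum((n_g - 1) * sd_g^2)`. Identical to ANOVA on any raw data
#' matching those summaries.
#'
#' @param means,sds,ns Numeric vectors, one entry per group (all `ns >= 2`,
#'   `sds > 0`).
#' @return List: `F`, `df` (c(between, within)), `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  G <- length(means)
  if (G < 2 || length(sds) != G || length(ns) != G) stop("need >= 2 groups with matching means/sds/ns")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("sds must be >= 0")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) stop("zero within-group variance")
  Fstat <- (ssb / (G - 1)) / (ssw / (N - G))
  list(F = Fstat, df = c(G - 1, N - G),
       p = stats::pf(Fstat, G - 1, N - G, lower.tail = FALSE))
}

#' Compare categorical counts across cohorts
#'
#' Pearson chi-square test (without continuity correction, the convention
#' that clinical cohort tables conventionally report) or Fisher's exact test.
#' Under `method = "auto"` the exact test is used whenever any expected
#' cell count falls below 5.
#'
#' @param counts Matrix of non-negative integer counts, groups x
#'   categories, at least 2 x 2.
#' @param method `"auto"` (default), `"chi_square"` or `"fisher"`.
#' @return List: `p`, `method` (test actually used), `statistic`
#'   (chi-square value or NA for the exact test).
#' @export
categorical_test <- function(counts, method = c("auto", "chi_square", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) stop("zero-margin row or column")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "auto") method <- if (any(expected < 5)) "fisher" else "chi_square"
  if (method == "chi_square") {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(p = ct$p.value, method = "chi_square", statistic = unname(ct$statistic))
  } else {
    ft <- stats::fisher.test(counts)
    list(p = ft$p.value, method = "fisher", statistic = NA_real_)
  }
}
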