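#' @importFrom survival coxph Surv survfit survdiff finegray cox.zph strata
NULL

## Assemble the package's standard fit summary from a coxph object.
## `term` selects the covariate of interest when the model has several.
cox_fit_summary <- function(fit, term = 1L, model_kind = "cause_specific") {
  s <- summary(fit)
  co <- s$coefficients
  i <- if (is.character(term)) match(term, rownames(co)) else term
  beta <- co[i, "coef"]
  se <- co[i, "se(coef)"]
  ph_p <- tryCatch({
    z <- survival::cox.zph(fit)
    unname(z$table[min(i, nrow(z$table) - (nrow(z$table) > 1)), "p"])
  }, error = function(e) NA_real_)
  list(coefficient = unname(beta),
       hazard_ratio = unname(exp(beta)),
       ci95 = unname(exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)),
       se = unname(se),
       p = unname(co[i, "Pr(>|z|)"]),
       n_events = unname(fit$nevent),
       ph_p = ph_p,
       model_kind = model_kind)
}

#' Univariate Cox screening of genes against mortality
#'
#' Fits, for each gene, a proportional-hazards model with the gene's log2
#' expression as the sole covariate; death is the event and transplant is
#' treated as censoring (the competing-risk treatment is reserved for the
#' prognostic-index-level analyses). Ties use the Efron approximation.
#' Genes whose fit fails (constant expression, non-convergence) are
#' excluded and flagged.
#'
#' @param expr Genes-by-samples log2 matrix.
#' @param survival_df Data frame with `sample_id`, `time_months`, `event`
#'   (0/1/2), rows covering the expression samples.
#' @param alpha Wald p-value threshold for the selected set (default 0.05).
#' @param ph_check Also run the scaled-Schoenfeld proportional-hazards test
#'   per gene (column `ph_p`); default TRUE.
#' @return List with `selected` (gene ids with p < alpha), `table` (data
#'   frame gene, coef, hr, ci_low, ci_high, p, ph_p) and `failed` (flagged
#'   gene ids).
#' @export
cox_univariate_screen <- function(expr, survival_df, alpha = 0.05, ph_check = TRUE) {
  expr <- validate_expression(expr)
  sv <- match_survival(survival_df, colnames(expr))
  if (sum(sv$event == 1) < 10)
    warning("fewer than 10 death events; univariate Cox screen will be unstable")
  y <- survival::Surv(sv$time_months, sv$event == 1)
  rows <- vector("list", nrow(expr))
  failed <- character()
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    g <- rownames(expr)[i]
    if (stats::sd(x) == 0) { failed <- c(failed, g); next }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients) || abs(fit$coefficients) > 50) {
      failed <- c(failed, g); next
    }
    fs <- cox_fit_summary(fit)
    if (!ph_check) fs$ph_p <- NA_real_
    rows[[i]] <- data.frame(gene = g, coef = fs$coefficient, hr = fs$hazard_ratio,
                            ci_low = fs$ci95[1], ci_high = fs$ci95[2],
                            p = fs$p, ph_p = fs$ph_p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) stop("no gene could be fit in the Cox screen")
  rownames(tab) <- NULL
  list(selected = tab$gene[tab$p < alpha], table = tab, failed = failed)
}

## align a survival data frame to a vector of sample ids
match_survival <- function(survival_df, sample_ids) {
  ord <- match(sample_ids, survival_df$sample_id)
  if (anyNA(ord)) stop("survival records missing for some samples")
  survival_df[ord, , drop = FALSE]
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' @param groups Named character vector, sample id -> group label (e.g.
#'   `"low"` / `"high"`).
#' @param survival_df Survival data frame (`sample_id`, `time_months`,
#'   `event`); death (code 1) is the event, transplant and loss to
#'   follow-up are censored.
#' @return List with `curves` (per group: `times`, `survival_prob`,
#'   `at_risk`, `median_survival`), `chisq`, `df` and `p`.
#' @export
km_logrank <- function(groups, survival_df) {
  sv <- match_survival(survival_df, names(groups))
  grp <- factor(unname(groups))
  if (nlevels(grp) < 2) stop("need >= 2 groups")
  if (any(table(grp) == 0)) stop("empty group")
  if (sum(sv$event == 1) < 1) stop("no death events")
  y <- survival::Surv(sv$time_months, sv$event == 1)
  sd_fit <- survival::survdiff(y ~ grp)
  df <- nlevels(grp) - 1L
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)

  sf <- survival::survfit(y ~ grp)
  med <- summary(sf)$table
  if (is.null(dim(med))) med <- matrix(med, nrow = 1, dimnames = list(levels(grp), names(med)))
  strata_id <- rep(seq_len(nlevels(grp)),
                   if (is.null(sf$strata)) length(sf$time) else sf$strata)
  curves <- lapply(seq_len(nlevels(grp)), function(k) {
    sel <- strata_id == k
    list(times = sf$time[sel], survival_prob = sf$surv[sel],
         at_risk = sf$n.risk[sel],
         median_survival = unname(med[k, "median"]))
  })
  names(curves) <- levels(grp)
  list(curves = curves, chisq = unname(sd_fit$chisq), df = df, p = p)
}

#' Fine-Gray subdistribution-hazard regression with transplant competing
#'
#' Fits the subdistribution hazard of death treating transplant (event code
#' 2) as a competing event, via inverse-probability-of-censoring weighting:
#' the data are expanded with [survival::finegray()] and a weighted Cox
#' model is fit on the result. With zero competing events the expansion is
#' the identity and the fit coincides with cause-specific Cox regression.
#'
#' @param covariates Data frame (or named numeric vector for a single
#'   covariate) of per-sample covariates, rows in `survival_df` sample
#'   order or carrying `sample_id` rownames/names.
#' @param survival_df Survival data frame (`sample_id`, `time_months`,
#'   `event` coded 0/1/2).
#' @param term Covariate whose effect to report (default the first).
#' @return A fit summary list (standard fit-summary fields): coefficient,
#'   `hazard_ratio` (the SHR), `ci95`, Wald `p`, `n_events`, `ph_p`,
#'   `model_kind = "fine_gray"`.
#' @export
fine_gray_fit <- function(covariates, survival_df, term = 1L) {
  if (is.numeric(covariates) && is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  if (nrow(covariates) != nrow(survival_df))
    stop("covariates and survival records must cover the same samples")
  if (sum(survival_df$event == 1) == 0) stop("no death events")
  etype <- factor(survival_df$event, levels = 0:2,
                  labels = c("censor", "death", "transplant"))
  dat <- cbind(survival_df[c("time_months")], etype = etype, covariates)
  fg <- survival::finegray(survival::Surv(time_months, etype) ~ ., data = dat,
                           etype = "death")
  fml <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~",
    paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = fg, weights = fg$fgwt, ties = "efron")
  out <- cox_fit_summary(fit, term = term, model_kind = "fine_gray")
  out$n_events <- sum(survival_df$event == 1)
  out
}

#' Cause-specific Cox fit for one or more covariates
#'
#' Death is the event; transplant and loss to follow-up are censored. Ties
#' use the Efron approximation.
#'
#' @inheritParams fine_gray_fit
#' @return A fit summary list with `model_kind = "cause_specific"`.
#' @export
cause_specific_fit <- function(covariates, survival_df, term = 1L) {
  if (is.numeric(covariates) && is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  if (sum(survival_df$event == 1) == 0) stop("no death events")
  dat <- cbind(survival_df[c("time_months", "event")], covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event == 1) ~",
    paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  cox_fit_summary(fit, term = term, model_kind = "cause_specific")
}

#' Prognostic-index effect adjusted for baseline CPI
#'
#' Two-covariate survival regression of mortality on the prognostic index
#' and the composite physiologic index, reporting the PI coefficient.
#' `model_kind` selects cause-specific Cox or the Fine-Gray competing-risk
#' model (transplant competing).
#'
#' @param pi_scores,cpi_values Numeric vectors in `survival_df` sample
#'   order.
#' @param survival_df Survival data frame.
#' @param model_kind `"fine_gray"` (default) or `"cause_specific"`.
#' @return Fit summary for the PI term.
#' @export
cox_adjusted <- function(pi_scores, cpi_values, survival_df,
                         model_kind = c("fine_gray", "cause_specific")) {
  model_kind <- match.arg(model_kind)
  if (anyNA(pi_scores) || anyNA(cpi_values)) stop("PI and CPI must be complete")
  if (stats::sd(cpi_values) > 0 &&
      abs(stats::cor(pi_scores, cpi_values)) > 0.999)
    stop("PI and CPI are collinear")
  covs <- data.frame(pi = pi_scores, cpi = cpi_values)
  if (stats::sd(cpi_values) == 0) covs <- covs["pi"]  # degenerate adjustment
  f <- if (model_kind == "fine_gray") fine_gray_fit else cause_specific_fit
  f(covs, survival_df, term = "pi")
}
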