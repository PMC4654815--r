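#' Read a genes-by-samples expression matrix from delimited text
#'
#' The expected layout is the field-standard one: a header row of sample
#' identifiers, a first column of gene (or probe) identifiers, and log2
#' intensities in the body. Both tab- and comma-delimited files are accepted.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `"\t"` (default) or `","`. Use `sep = NULL`
#'   to sniff from the header line.
#' @param duplicate_genes What to do when a gene identifier appears on more
#'   than one row: `"error"` (default) or `"collapse"` (keep the row with
#'   maximal mean intensity, as [collapse_probes()] would).
#' @return A numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames; no missing values.
#' @seealso [write_expression()], [collapse_probes()]
#' @export
read_expression <- function(path, sep = "\t", duplicate_genes = c("error", "collapse")) {
  duplicate_genes <- match.arg(duplicate_genes)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("malformed expression file: need gene-id column plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(names(df)[-1L])) stop("duplicate sample id in header")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    suppressWarnings(storage.mode(mat) <- "double")
  }
  if (anyNA(mat)) stop("non-numeric or missing cell in expression body")
  sample_ids <- colnames(mat)
  if (anyDuplicated(sample_ids)) stop("duplicate sample id in header")
  rownames(mat) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    if (duplicate_genes == "error") {
      stop("duplicate gene ids in expression file (set duplicate_genes = \"collapse\" to resolve)")
    }
    mat <- collapse_probes(mat, data.frame(probe = gene_ids, gene = gene_ids,
                                           stringsAsFactors = FALSE))
  }
  validate_expression(mat)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]: header row of sample ids, first column of
#' gene ids.
#'
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  expr <- validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Shared gatekeeper for every operation taking an expression matrix.
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (anyNA(expr)) stop("missing values in expression matrix")
  expr
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray platforms carry redundant probes per gene. The collapse rule is
#' deterministic: for each gene keep the probe with the largest mean
#' intensity across samples (`rule = "max_mean"`), or average all its probes
#' (`rule = "mean"`).
#'
#' @param expr Probes-by-samples numeric matrix (rownames are probe ids).
#' @param mapping Data frame with columns `probe` and `gene`.
#' @param rule `"max_mean"` (default) or `"mean"`.
#' @param unmapped `"drop"` (default) or `"error"` for probes absent from the
#'   mapping.
#' @return Genes-by-samples matrix with one row per gene.
#' @export
collapse_probes <- function(expr, mapping, rule = c("max_mean", "mean"),
                            unmapped = c("drop", "error")) {
  rule <- match.arg(rule)
  unmapped <- match.arg(unmapped)
  if (!all(c("probe", "gene") %in% names(mapping)) || nrow(mapping) == 0L)
    stop("mapping must be a nonempty data frame with columns probe, gene")
  probes <- rownames(expr)
  hit <- match(probes, mapping$probe)
  if (all(is.na(hit))) stop("no probe in the expression matrix maps to a gene")
  if (unmapped == "error" && anyNA(hit)) stop("unmapped probes present")
  keep <- !is.na(hit)
  expr <- expr[keep, , drop = FALSE]
  gene <- as.character(mapping$gene[hit[keep]])

  if (rule == "mean") {
    out <- rowsum(expr, group = gene) / as.vector(table(gene)[sort(unique(gene))])
    out <- out[unique(gene)[order(match(unique(gene), gene))], , drop = FALSE]
  } else {
    means <- rowMeans(expr)
    ## per gene, index of the probe with maximal mean (first wins on ties)
    pick <- tapply(seq_along(gene), gene, function(ii) ii[which.max(means[ii])])
    pick <- pick[unique(gene)]  # keep first-appearance gene order
    out <- expr[as.integer(pick), , drop = FALSE]
    rownames(out) <- names(pick)
  }
  validate_expression(out)
}

#' Filter genes by coefficient of variation
#'
#' Removes genes whose coefficient of variation (sd/mean) across all samples
#' falls below `cv_min`. By default the CV is computed on linear-scale
#' intensities (`2^x` of the stored log2 values), the conventional scale for
#' array variation filters; `scale = "log"` computes it on the stored values
#' directly.
#'
#' @param expr Genes-by-samples log2 matrix.
#' @param cv_min Minimum CV to retain a gene (default 0.3).
#' @param scale `"linear"` (default) or `"log"`.
#' @return The matrix restricted to retained genes, in their original order.
#'   Genes with non-positive mean on the chosen scale are dropped with a
#'   warning.
#' @export
filter_by_cv <- function(expr, cv_min = 0.3, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  expr <- validate_expression(expr)
  if (cv_min < 0) stop("cv_min must be >= 0")
  vals <- if (scale == "linear") 2^expr else expr
  mu <- rowMeans(vals)
  bad <- mu <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive mean dropped from CV filter")
  }
  sdv <- apply(vals, 1L, stats::sd)
  cv <- ifelse(bad, NA_real_, sdv / mu)
  keep <- !bad & cv >= cv_min
  expr[keep, , drop = FALSE]
}

#' Composite physiologic index from pulmonary function tests
#'
#' CPI combines percent-predicted FVC, DLCO and FEV1 into a single extent
#' measure of fibrotic disease:
#' `91.0 - 0.65 * DLCO - 0.53 * FVC + 0.34 * FEV1`.
#'
#' @param fvc_pct,dlco_pct,fev1_pct Percent-predicted values, all > 0.
#'   Vectorised.
#' @return Numeric CPI value(s).
#' @export
compute_cpi <- function(fvc_pct, dlco_pct, fev1_pct) {
  if (any(is.na(fvc_pct)) || any(is.na(dlco_pct)) || any(is.na(fev1_pct)))
    stop("compute_cpi requires fvc_pct, dlco_pct and fev1_pct; supply cpi directly if FEV1 is unavailable")
  if (any(fvc_pct <= 0) || any(dlco_pct <= 0) || any(fev1_pct <= 0))
    stop("percent-predicted values must be > 0")
  91.0 - 0.65 * dlco_pct - 0.53 * fvc_pct + 0.34 * fev1_pct
}

#' Dichotomise observed prognosis at a follow-up horizon
#'
#' A patient is `poor` if they died at or before `horizon_months`, `good` if
#' known alive at (or beyond) the horizon. Patients censored or transplanted
#' before the horizon are indeterminate; `indeterminate_as` controls whether
#' they are labelled `"good"` (default, optimistic convention),
#' `"indeterminate"` (excluded downstream) or `"poor"`.
#'
#' @param time_months Follow-up time(s), months, >= 0.
#' @param event Event code(s): 0 censored, 1 death, 2 transplant.
#' @param horizon_months Label horizon (default 36, i.e. 3 years).
#' @param indeterminate_as Fallback label for indeterminate patients.
#' @return Character vector in `{good, poor, indeterminate}` with attribute
#'   `indeterminate` marking which entries were rule-indeterminate before the
#'   fallback was applied.
#' @export
derive_prognosis_label <- function(time_months, event, horizon_months = 36,
                                   indeterminate_as = c("good", "indeterminate", "poor")) {
  indeterminate_as <- match.arg(indeterminate_as)
  if (any(time_months < 0)) stop("negative survival time")
  if (!all(event %in% 0:2)) stop("event codes must be 0 (censored), 1 (death), 2 (transplant)")
  lab <- ifelse(event == 1 & time_months <= horizon_months, "poor",
         ifelse(time_months >= horizon_months, "good", "indeterminate"))
  indet <- lab == "indeterminate"
  if (indeterminate_as != "indeterminate") lab[indet] <- indeterminate_as
  attr(lab, "indeterminate") <- indet
  lab
}

#' Read a clinical + survival table
#'
#' Expects a CSV with columns `sample_id, age, sex, race, fvc_pct, dlco_pct,
#' fev1_pct, cpi, diagnosis, time_months, event, prognosis` (fev1_pct, cpi
#' and prognosis may be empty; cpi is filled in from the Wells formula when
#' absent and fev1 is available, prognosis from [derive_prognosis_label()]).
#' Event encoding is fixed: 0 censored, 1 death, 2 transplant.
#'
#' @param path CSV path.
#' @param horizon_months Horizon for prognosis labelling when the column is
#'   absent.
#' @return A data frame keyed by `sample_id`.
#' @export
read_clinical <- function(path, horizon_months = 36) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "race", "fvc_pct", "dlco_pct",
            "diagnosis", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (is.null(df$cpi) || anyNA(df$cpi)) {
    if (!is.null(df$fev1_pct) && !anyNA(df$fev1_pct)) {
      fill <- if (is.null(df$cpi)) rep(TRUE, nrow(df)) else is.na(df$cpi)
      cpi <- compute_cpi(df$fvc_pct, df$dlco_pct, df$fev1_pct)
      if (is.null(df$cpi)) df$cpi <- cpi else df$cpi[fill] <- cpi[fill]
    } else if (is.null(df$cpi)) {
      stop("cpi column absent and fev1_pct unavailable to compute it")
    }
  }
  if (is.null(df$prognosis) || all(is.na(df$prognosis))) {
    df$prognosis <- as.character(derive_prognosis_label(df$time_months, df$event,
                                                        horizon_months))
  }
  df
}

#' Restrict a cohort's expression matrix to a model's gene space
#'
#' Transfers a trained classifier to another platform: keeps the genes shared
#' with `model_genes`, in model order, and reports the classifier genes the
#' target platform is missing.
#'
#' @param model_genes Ordered character vector of classifier gene ids.
#' @param target Genes-by-samples matrix of the target cohort.
#' @return List with `expr` (restricted matrix, model gene order) and
#'   `missing` (character vector of absent model genes).
#' @export
align_cohorts <- function(model_genes, target) {
  target <- validate_expression(target)
  present <- model_genes[model_genes %in% rownames(target)]
  if (length(present) == 0L) stop("no model gene present in target cohort")
  list(expr = target[present, , drop = FALSE],
       missing = setdiff(model_genes, present))
}
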