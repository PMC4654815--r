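#' Pipeline configuration
#'
#' Collects every stage parameter with its field-standard default, plus
#' input locations and the output directory. Inputs may be in-memory
#' objects (expression matrix, clinical data frame) or file paths in the
#' package's standard formats.
#'
#' @param expression Genes-by-samples matrix or path for
#'   [read_expression()].
#' @param clinical Clinical+survival data frame or CSV path for
#'   [read_clinical()].
#' @param out_dir Output directory for stage files and the manifest
#'   (`NULL` = no files written).
#' @param cv_min Coefficient-of-variation filter threshold.
#' @param network [network_config()] for the co-expression stage.
#' @param traits_of_interest Traits defining criterion 1.
#' @param trait_alpha Module-trait significance threshold.
#' @param n_perm,fc_min,fdr_max_pct SAM stage parameters.
#' @param cox_alpha Univariate Cox screen threshold.
#' @param n_components,offset,risk_split Prognostic model parameters.
#' @param k_folds,cv_repeats Cross-validation parameters.
#' @param seed Single master seed; each stochastic stage derives its own
#'   seed from it deterministically.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, out_dir = NULL,
                            cv_min = 0.3,
                            network = network_config(),
                            traits_of_interest = c("fvc_pct", "dlco_pct", "cpi"),
                            trait_alpha = 0.05,
                            n_perm = 200, fc_min = 1.5, fdr_max_pct = 2.0,
                            cox_alpha = 0.05,
                            n_components = 2, offset = 13.5,
                            risk_split = c(66.7, 33.3),
                            k_folds = 10, cv_repeats = 1,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

## one master seed fans out to per-stage seeds via a stable name hash
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full prognosis pipeline
#'
#' Executes preprocess (CV filter) -> network (soft threshold, TOM,
#' modules, eigengenes, module-trait correlation) -> SAM differential
#' expression -> univariate Cox screen -> three-criteria gene selection ->
#' supervised-PCA fit -> tertile risk assignment + training log-rank ->
#' k-fold cross-validation, recording per-stage row counts, seeds and
#' parameters in a manifest. Any stage failure aborts with an error naming
#' the stage and its cause.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result` with every stage output and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  res <- list()
  manifest <- list(seed = cfg$seed,
                   parameters = cfg[!(names(cfg) %in% c("expression", "clinical", "network"))],
                   network = unclass(cfg$network),
                   stages = list())
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out
  }

  ## -- preprocess ----------------------------------------------------
  expr <- if (is.character(cfg$expression)) read_expression(cfg$expression) else
    validate_expression(cfg$expression)
  clinical <- if (is.character(cfg$clinical)) read_clinical(cfg$clinical) else cfg$clinical
  res$filtered <- run_stage("preprocess", function() filter_by_cv(expr, cfg$cv_min))
  manifest$stages$preprocess <- list(n_genes_in = nrow(expr),
                                     n_genes_out = nrow(res$filtered))

  ## -- co-expression network ----------------------------------------
  res$power <- run_stage("network", function() choose_power(res$filtered, cfg$network))
  res$partition <- run_stage("network", function() {
    tom <- tom_similarity(adjacency(res$filtered, res$power))
    cluster_modules(tom, cfg$network, expr = res$filtered)
  })
  res$eigengenes <- run_stage("network", function() module_eigengene(res$filtered, res$partition))
  res$module_trait <- run_stage("network", function() {
    traits <- unique(c(cfg$traits_of_interest, "age", "sex", "race"))
    traits <- intersect(traits, names(clinical))
    module_trait_correlation(res$eigengenes, clinical, traits)
  })
  res$trait_modules <- run_stage("select_modules", function()
    select_trait_modules(res$module_trait, cfg$traits_of_interest, cfg$trait_alpha))
  manifest$stages$network <- list(power = as.integer(res$power),
                                  module_sizes = as.list(res$partition$module_sizes),
                                  trait_modules = res$trait_modules)

  ## -- SAM differential expression ----------------------------------
  labels <- stats::setNames(clinical$prognosis, clinical$sample_id)[colnames(res$filtered)]
  res$sam <- run_stage("de", function()
    permutation_fdr(res$filtered, unname(labels), n_perm = cfg$n_perm,
                    seed = stage_seed(cfg$seed, "de")))
  res$de_genes <- select_de_genes(res$sam, cfg$fc_min, cfg$fdr_max_pct)
  manifest$stages$de <- list(n_de = length(res$de_genes), s0 = res$sam$s0,
                             n_perm = res$sam$n_perm, seed = res$sam$seed)

  ## -- univariate Cox screen ----------------------------------------
  res$cox_screen <- run_stage("coxscreen", function()
    cox_univariate_screen(res$filtered, clinical, alpha = cfg$cox_alpha,
                          ph_check = FALSE))
  manifest$stages$coxscreen <- list(n_selected = length(res$cox_screen$selected),
                                    n_failed = length(res$cox_screen$failed))

  ## -- three-criteria selection, model fit, CV ----------------------
  res$predictor <- run_stage("select", function()
    compile_predictor_genes(res$trait_modules, res$partition, res$de_genes,
                            res$cox_screen$selected, sam = res$sam,
                            cox_table = res$cox_screen$table))
  manifest$stages$select <- list(n_predictor_genes = length(res$predictor$genes))

  expr_sub <- res$filtered[res$predictor$genes, , drop = FALSE]
  res$model <- run_stage("fit", function()
    fit_supervised_pca(expr_sub, clinical, n_components = cfg$n_components,
                       offset = cfg$offset, risk_split = cfg$risk_split))
  res$risk <- assign_risk(res$model$training_pi, cfg$risk_split)
  res$logrank <- run_stage("fit", function() km_logrank(res$risk$risk, clinical))
  manifest$stages$fit <- list(n_genes = length(res$model$genes),
                              n_high = sum(res$risk$risk == "high"),
                              n_low = sum(res$risk$risk == "low"),
                              logrank_p = res$logrank$p)

  res$cv <- run_stage("cv", function()
    cross_validate(expr_sub, clinical, labels, k = cfg$k_folds,
                   repeats = cfg$cv_repeats,
                   seed = stage_seed(cfg$seed, "cv"),
                   n_components = cfg$n_components,
                   risk_split = cfg$risk_split))
  manifest$stages$cv <- list(misclassification_rate = res$cv$misclassification_rate,
                             repeats = res$cv$repeats,
                             seed = stage_seed(cfg$seed, "cv"))

  res$manifest <- manifest
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  structure(res, class = "pipeline_result")
}

## stage outputs in the package's standard delimited formats + JSON manifest
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(gene = names(res$partition$assignment),
                              module = unname(res$partition$assignment)),
                   file.path(dir, "modules.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(res$eigengenes$eigengene),
                              res$eigengenes$eigengene, check.names = FALSE),
                   file.path(dir, "eigengenes.csv"), row.names = FALSE)
  mt <- res$module_trait
  utils::write.csv(data.frame(module = rep(rownames(mt$r), ncol(mt$r)),
                              trait = rep(colnames(mt$r), each = nrow(mt$r)),
                              r = as.vector(mt$r), p = as.vector(mt$p),
                              n = as.vector(mt$n)),
                   file.path(dir, "module_trait.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = names(res$sam$d), d = unname(res$sam$d),
                              fc = unname(res$sam$fc),
                              fdr_pct = unname(res$sam$fdr_pct)),
                   file.path(dir, "sam.csv"), row.names = FALSE)
  utils::write.csv(res$cox_screen$table, file.path(dir, "cox_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(res$predictor$provenance, file.path(dir, "predictor_genes.csv"),
                   row.names = FALSE)
  model <- res$model
  jsonlite::write_json(list(genes = model$genes,
                            weights = as.list(model$weights),
                            offset = model$offset,
                            n_components = model$n_components,
                            standardization = model$standardization,
                            risk_split = model$risk_split,
                            threshold_pi = model$threshold_pi),
                       file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(sample_id = names(res$risk$pi),
                              pi = unname(res$risk$pi),
                              risk = unname(res$risk$risk),
                              predicted_cv = unname(res$cv$predicted_risk),
                              observed = unname(res$cv$observed)),
                   file.path(dir, "risk.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones. Used to score module recovery against simulation ground truth.
#'
#' @param a,b Vectors of cluster labels (same length).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
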