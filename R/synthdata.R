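#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' latent factor per co-expression module, clinical traits linearly coupled
#' to those factors, and survival driven by the signature module's factor
#' through an exponential proportional-hazards law, with independent
#' censoring and transplant as a competing exponential clock.
#'
#' Defaults mirror a single-centre IPF blood cohort: 45 patients, roughly
#' 40% three-year mortality, rare transplant, follow-up truncated around
#' five years.
#'
#' @param n_genes Total genes simulated (background genes are iid noise).
#' @param n_samples Patients in the cohort.
#' @param module_sizes Genes per planted module; sum must be <= `n_genes`.
#' @param within_module_cor Target pairwise Pearson correlation inside each
#'   module (single value or one per module), each in [0, 1).
#' @param trait_coupling Numeric matrix (modules x traits) of linear
#'   coefficients from module factors to the continuous traits
#'   `fvc_pct, dlco_pct, fev1_pct` and the binary trait `sex` (on the latent
#'   scale). Default couples the signature module to lung function.
#' @param signature_module Index of the module whose factor drives hazard.
#' @param beta_signature Log-hazard per SD of the signature factor.
#' @param baseline_hazard Death hazard (events/month) at factor 0.
#' @param censor_rate Independent censoring hazard (events/month).
#' @param transplant_rate Competing transplant hazard (events/month).
#' @param horizon_months Administrative end of follow-up.
#' @param platform_dropout Fraction of genes unmappable on a second platform
#'   (used by [generate_validation_cohort()]).
#' @param scale_shift Multiplicative linear-intensity factor of the second
#'   platform.
#' @param mean_log2 Range of per-gene baseline log2 intensities.
#' @param sd_log2 Per-gene residual SD on the log2 scale.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600,
                       n_samples = 45,
                       module_sizes = c(100, 70, 50),
                       within_module_cor = 0.7,
                       trait_coupling = NULL,
                       signature_module = 1L,
                       beta_signature = 1.0,
                       baseline_hazard = 0.015,
                       censor_rate = 0.02,
                       transplant_rate = 0.002,
                       horizon_months = 60,
                       platform_dropout = 0.1,
                       scale_shift = 1.0,
                       mean_log2 = c(6, 12),
                       sd_log2 = 1.0,
                       seed = 1L) {
  if (sum(module_sizes) > n_genes) stop("sum(module_sizes) must be <= n_genes")
  if (any(within_module_cor < 0) || any(within_module_cor >= 1))
    stop("within_module_cor must be in [0, 1)")
  if (any(c(baseline_hazard, censor_rate, transplant_rate) < 0)) stop("rates must be >= 0")
  if (platform_dropout < 0 || platform_dropout >= 1) stop("platform_dropout must be in [0, 1)")
  if (signature_module < 1L || signature_module > length(module_sizes))
    stop("signature_module out of range")
  m <- length(module_sizes)
  within_module_cor <- rep_len(within_module_cor, m)
  if (is.null(trait_coupling)) {
    ## traits: fvc_pct, dlco_pct, fev1_pct, sex (latent); lung function loads
    ## on the signature module with a physiologically plausible magnitude
    trait_coupling <- matrix(0, nrow = m, ncol = 4,
                             dimnames = list(NULL, c("fvc_pct", "dlco_pct", "fev1_pct", "sex")))
    trait_coupling[signature_module, c("fvc_pct", "dlco_pct")] <- c(-8, -8)
    trait_coupling[signature_module, "sex"] <- 0.5
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_sizes = module_sizes,
                 within_module_cor = within_module_cor,
                 trait_coupling = trait_coupling,
                 signature_module = as.integer(signature_module),
                 beta_signature = beta_signature,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 transplant_rate = transplant_rate,
                 horizon_months = horizon_months,
                 platform_dropout = platform_dropout,
                 scale_shift = scale_shift,
                 mean_log2 = mean_log2, sd_log2 = sd_log2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Draw one cohort's worth of data under the generative law described in
## sim_config; `sample_prefix` keeps ids distinct across cohorts.
simulate_from_law <- function(cfg, n, gene_meta, sample_prefix) {
  m <- length(cfg$module_sizes)
  sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n))

  ## latent module factors, one per module, iid standard normal per sample
  factors <- matrix(stats::rnorm(n * m), nrow = m,
                    dimnames = list(paste0("M", seq_len(m)), sample_ids))

  ## expression: x_g = mu_g + sd_g * (sqrt(r)*loading_sign*f_m + sqrt(1-r)*eps)
  ## so within-module pairwise correlation is r in expectation
  expr <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
                 dimnames = list(gene_meta$gene_id, sample_ids))
  for (k in seq_len(m)) {
    idx <- which(gene_meta$module == k)
    r <- cfg$within_module_cor[k]
    load <- sqrt(r) * gene_meta$loading_sign[idx]
    expr[idx, ] <- load %o% factors[k, ] + sqrt(1 - r) * expr[idx, , drop = FALSE]
  }
  expr <- gene_meta$mu + gene_meta$sd * expr

  ## continuous traits = baseline + coupling %*% factors + noise
  tc <- cfg$trait_coupling
  base <- c(fvc_pct = 62, dlco_pct = 45, fev1_pct = 70)
  traits <- sapply(names(base), function(tr) {
    base[[tr]] + as.vector(crossprod(tc[, tr, drop = FALSE], factors)) +
      stats::rnorm(n, sd = 6)
  })
  traits <- pmax(traits, 10)  # percent-predicted values stay positive
  sex_lat <- as.vector(crossprod(tc[, "sex", drop = FALSE], factors)) + stats::rnorm(n)
  sex <- ifelse(sex_lat > stats::qnorm(0.25), "male", "female")  # ~75% male, as in IPF
  clinical <- data.frame(
    sample_id = sample_ids,
    age = round(stats::rnorm(n, 67, 8), 1),
    sex = sex,
    race = sample(c("white", "nonwhite"), n, replace = TRUE, prob = c(0.85, 0.15)),
    fvc_pct = round(traits[, "fvc_pct"], 1),
    dlco_pct = round(traits[, "dlco_pct"], 1),
    fev1_pct = round(traits[, "fev1_pct"], 1),
    diagnosis = "IPF",
    stringsAsFactors = FALSE)
  clinical$cpi <- compute_cpi(clinical$fvc_pct, clinical$dlco_pct, clinical$fev1_pct)

  ## competing exponential clocks on the signature factor
  f_sig <- factors[cfg$signature_module, ]
  t_death <- stats::rexp(n, rate = cfg$baseline_hazard * exp(cfg$beta_signature * f_sig))
  t_txp <- if (cfg$transplant_rate > 0) stats::rexp(n, cfg$transplant_rate) else rep(Inf, n)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, cfg$horizon_months)
  time <- pmin(t_death, t_txp, t_cens)
  event <- ifelse(time == t_death, 1L, ifelse(time == t_txp, 2L, 0L))
  survival <- data.frame(sample_id = sample_ids,
                         time_months = time, event = event,
                         stringsAsFactors = FALSE)
  survival$prognosis <- as.character(derive_prognosis_label(time, event))

  list(expr = expr, clinical = clinical, survival = survival, factors = factors)
}

#' Generate a synthetic cohort with known ground truth
#'
#' See [sim_config()] for the generative law. The returned truth element
#' records module membership, the latent factor scores, the signature
#' module's gene ids (the "true" prognostic genes) and the hazard
#' coefficient, so downstream recovery can be scored.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `expr`
#'   (genes x samples log2 matrix), `clinical` and `survival` data frames,
#'   and `truth`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- length(cfg$module_sizes)
  module <- rep(0L, cfg$n_genes)
  module[seq_len(sum(cfg$module_sizes))] <- rep(seq_len(m), cfg$module_sizes)
  gene_meta <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    module = module,
    mu = stats::runif(cfg$n_genes, cfg$mean_log2[1], cfg$mean_log2[2]),
    sd = rep(cfg$sd_log2, cfg$n_genes),
    ## half the module genes anti-correlate with the factor, as in real
    ## modules containing both directions of regulation
    loading_sign = sample(c(-1, 1), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  drawn <- simulate_from_law(cfg, cfg$n_samples, gene_meta, "S")
  truth <- list(module = stats::setNames(gene_meta$module, gene_meta$gene_id),
                loading_sign = stats::setNames(gene_meta$loading_sign, gene_meta$gene_id),
                factors = drawn$factors,
                signature_genes = gene_meta$gene_id[gene_meta$module == cfg$signature_module],
                beta_signature = cfg$beta_signature,
                gene_meta = gene_meta)
  structure(list(expr = drawn$expr, clinical = drawn$clinical,
                 survival = drawn$survival, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Generate an independent validation cohort on a second platform
#'
#' Draws new patients from the same generative law as `cohort`, then applies
#' two platform effects: a fraction `platform_dropout` of genes becomes
#' unmappable (removed), and all linear intensities are multiplied by
#' `scale_shift` (a constant `log2(scale_shift)` shift of the stored log2
#' values). Ground truth carries over.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param n_samples Patients in the validation cohort.
#' @param platform_dropout,scale_shift Override the source config.
#' @param protect_genes Genes never dropped (e.g. to keep a fixed number of
#'   classifiers mappable); dropping an entire signature module is an error.
#' @param seed Seed for the new cohort (default: source seed + 1).
#' @return A `synthetic_cohort` for the validation platform.
#' @export
generate_validation_cohort <- function(cohort, n_samples = 75,
                                       platform_dropout = NULL,
                                       scale_shift = NULL,
                                       protect_genes = character(),
                                       seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  if (is.null(platform_dropout)) platform_dropout <- cfg$platform_dropout
  if (is.null(scale_shift)) scale_shift <- cfg$scale_shift
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(as.integer(seed))
  gene_meta <- cohort$truth$gene_meta
  drawn <- simulate_from_law(cfg, n_samples, gene_meta, "V")

  n_drop <- floor(platform_dropout * nrow(gene_meta))
  droppable <- setdiff(gene_meta$gene_id, protect_genes)
  dropped <- if (n_drop > 0) sample(droppable, min(n_drop, length(droppable))) else character()
  sig <- cohort$truth$signature_genes
  if (length(sig) && all(sig %in% dropped))
    stop("platform dropout removed the entire signature module")
  keep <- !(gene_meta$gene_id %in% dropped)
  expr <- drawn$expr[keep, , drop = FALSE] + log2(scale_shift)

  structure(list(expr = expr, clinical = drawn$clinical,
                 survival = drawn$survival,
                 truth = c(cohort$truth, list(dropped_genes = dropped,
                                              factors_validation = drawn$factors)),
                 config = cfg),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to the package's standard file formats
#'
#' Expression goes to a tab-delimited genes-by-samples matrix, clinical and
#' survival to a single CSV, and generator metadata (including the seed) to
#' a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expr, paths[["expression"]])
  clin <- merge(cohort$clinical, cohort$survival, by = "sample_id", sort = FALSE)
  utils::write.csv(clin, paths[["clinical"]], row.names = FALSE)
  meta <- list(seed = cohort$config$seed,
               n_genes = cohort$config$n_genes,
               module_sizes = cohort$config$module_sizes,
               beta_signature = cohort$config$beta_signature,
               module = as.list(cohort$truth$module))
  jsonlite::write_json(meta, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Merge a cohort's clinical and survival records into one table
#'
#' The pipeline and the survival functions expect a single data frame
#' carrying clinical columns alongside `time_months`, `event` and
#' `prognosis`; this joins the two cohort components on `sample_id`.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with one row per sample.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  merge(cohort$clinical, cohort$survival, by = "sample_id", sort = FALSE)
}
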