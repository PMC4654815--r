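# small deterministic fixtures shared across test files

toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression matrix of independent N(mu, sd) genes
noise_expr <- function(n_genes, n_samples, mu = 8, sd = 1, seed = 1) {
  set.seed(seed)
  toy_expr(matrix(stats::rnorm(n_genes * n_samples, mu, sd), n_genes))
}

# survival table from raw vectors
surv_df <- function(time, event, ids = NULL) {
  ids <- ids %||% sprintf("s%d", seq_along(time))
  data.frame(sample_id = ids, time_months = time, event = event,
             stringsAsFactors = FALSE)
}

# exponential survival driven by a covariate: hazard = l0 * exp(beta * x)
sim_surv <- function(x, beta, l0 = 0.02, censor = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_death <- stats::rexp(length(x), rate = l0 * exp(beta * x))
  time <- pmin(t_death, censor)
  surv_df(time, as.integer(t_death <= censor))
}

# two planted blocks with zero cross-correlation plus optional noise genes
block_expr <- function(block_sizes = c(40, 40), n_noise = 0, n = 60,
                       r = 0.8, seed = 1) {
  set.seed(seed)
  total <- sum(block_sizes) + n_noise
  mat <- matrix(stats::rnorm(total * n), total)
  start <- 0
  for (b in seq_along(block_sizes)) {
    f <- stats::rnorm(n)
    idx <- start + seq_len(block_sizes[b])
    mat[idx, ] <- sqrt(r) * rep(1, block_sizes[b]) %o% f +
      sqrt(1 - r) * mat[idx, , drop = FALSE]
    start <- start + block_sizes[b]
  }
  expr <- toy_expr(8 + mat)
  attr(expr, "truth") <- rep(c(seq_along(block_sizes), 0),
                             c(block_sizes, n_noise))
  expr
}
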