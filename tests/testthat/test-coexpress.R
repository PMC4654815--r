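test_that("adjacency is |cor|^power with unit diagonal and symmetry", {
  expr <- noise_expr(15, 25, seed = 21)
  a <- adjacency(expr, 6)
  brute <- abs(cor(t(expr)))^6
  diag(brute) <- 1
  expect_equal(a, brute, tolerance = 1e-12)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))

  # perfectly (anti-)correlated pair has adjacency 1 at any power
  pair <- toy_expr(rbind(1:10, -(1:10), rnorm(10)))
  for (p in c(1, 6, 12)) expect_equal(adjacency(pair, p)["g1", "g2"], 1)

  expect_error(adjacency(toy_expr(rbind(rep(1, 5), rnorm(5))), 6), "constant")
  expect_error(adjacency(expr, 0.5), ">= 1")
})

test_that("topological overlap matches its defining formula", {
  # 2-gene network: TOM_12 reduces to a_12
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a2)["x", "y"], 0.4)

  # fully adjacent genes with identical neighbourhoods reach overlap 1
  a_id <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0.3), c(0, 0, 0.3, 1))
  dimnames(a_id) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(tom_similarity(a_id)["g1", "g2"], 1)

  # 5-gene random adjacency vs brute-force triple loop
  set.seed(5)
  r <- abs(cor(matrix(rnorm(80), 16, 5)))
  dimnames(r) <- list(letters[1:5], letters[1:5])
  tom <- tom_similarity(r)
  k <- rowSums(r) - 1
  for (i in 1:5) for (j in 1:5) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    num <- sum(sapply(setdiff(1:5, c(i, j)), function(u) r[i, u] * r[u, j])) + r[i, j]
    expect_equal(tom[i, j], num / (min(k[i], k[j]) + 1 - r[i, j]), tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("soft-threshold selection honours the scale-free criterion", {
  # single perfectly correlated block: criterion met at the smallest power
  set.seed(7)
  f <- rnorm(30)
  block <- toy_expr(8 + seq(0.5, 2, length.out = 40) %o% f)
  p <- pick_soft_threshold(block, network_config(candidate_powers = 2:10))
  expect_equal(as.integer(p), 2L)
  expect_true(attr(p, "criterion_met"))

  # vacuous target returns the smallest candidate
  expr <- noise_expr(60, 20, seed = 2)
  p0 <- pick_soft_threshold(expr, network_config(candidate_powers = 3:8,
                                                 scale_free_r2_target = 0))
  expect_equal(as.integer(p0), 3L)

  # noise with an unreachable target walks the warning path and returns argmax
  cfgw <- network_config(candidate_powers = 1:6, scale_free_r2_target = 0.999)
  expect_warning(pw <- pick_soft_threshold(expr, cfgw), "argmax")
  r2 <- attr(pw, "fit_r2")
  expect_equal(as.integer(pw), as.integer(names(r2)[which.max(r2)]))
})

test_that("planted blocks are recovered as modules and noise stays grey", {
  expr <- block_expr(c(40, 40), n_noise = 20, n = 60, r = 0.8, seed = 13)
  truth <- attr(expr, "truth")
  part <- cluster_modules(tom_similarity(adjacency(expr, 6)),
                          network_config(min_module_size = 20), expr = expr)
  mods <- part$assignment
  expect_equal(sum(names(part$module_sizes) != "grey"), 2)
  expect_equal(adjusted_rand_index(mods[truth != 0], truth[truth != 0]), 1)

  # iid noise: majority grey
  noise <- noise_expr(100, 40, seed = 17)
  pnoise <- cluster_modules(tom_similarity(adjacency(noise, 6)),
                            network_config(min_module_size = 30), expr = noise)
  expect_gt(mean(pnoise$assignment == "grey"), 0.5)
})

test_that("module detection is invariant to gene order", {
  expr <- block_expr(c(30, 30), n_noise = 10, n = 50, seed = 23)
  part1 <- cluster_modules(tom_similarity(adjacency(expr, 6)),
                           network_config(min_module_size = 20), expr = expr)
  set.seed(1)
  perm <- sample(nrow(expr))
  expr2 <- expr[perm, ]
  part2 <- cluster_modules(tom_similarity(adjacency(expr2, 6)),
                           network_config(min_module_size = 20), expr = expr2)
  common <- rownames(expr)
  expect_equal(adjusted_rand_index(part1$assignment[common], part2$assignment[common]), 1)
})

test_that("eigengenes summarise modules with the documented orientation", {
  # module of identical genes: eigengene equals the standardized common profile
  set.seed(31)
  profile <- rnorm(20)
  expr <- toy_expr(matrix(rep(profile, each = 5), 5, byrow = FALSE) +
                     0 * rnorm(100))
  part <- structure(list(assignment = setNames(rep("M1", 5), rownames(expr)),
                         module_sizes = table(rep("M1", 5))),
                    class = "module_partition")
  me <- module_eigengene(expr, part)
  expect_equal(unname(me$eigengene[, "M1"]), as.vector(scale(profile)),
               tolerance = 1e-8)
  expect_equal(unname(me$explained_variance["M1"]), 1)

  # sign rule: negating every module gene leaves the eigengene direction tied
  # to the module mean, and a rank-1 + small-noise module is well explained
  expr2 <- block_expr(60, n_noise = 0, n = 30, r = 0.95, seed = 32)
  part2 <- structure(list(assignment = setNames(rep("M1", 60), rownames(expr2)),
                          module_sizes = table(rep("M1", 60))),
                     class = "module_partition")
  me2 <- module_eigengene(expr2, part2)
  expect_gt(me2$explained_variance["M1"], 0.9)
  me2n <- module_eigengene(-expr2, part2)
  expect_gt(cor(me2$eigengene[, 1], -me2n$eigengene[, 1]), 0.999)
  # orientation: positive correlation with module mean of standardized genes
  z <- t(scale(t(expr2)))
  expect_gt(cor(me2$eigengene[, 1], colMeans(z)), 0)
  # unit variance, zero mean
  expect_equal(mean(me2$eigengene[, 1]), 0, tolerance = 1e-10)
  expect_equal(sd(me2$eigengene[, 1]), 1, tolerance = 1e-10)
})

test_that("module-trait correlation reproduces the t-transform p-value", {
  expr <- block_expr(30, n_noise = 0, n = 45, r = 0.9, seed = 41)
  part <- structure(list(assignment = setNames(rep("M1", 30), rownames(expr)),
                         module_sizes = table(rep("M1", 30))),
                    class = "module_partition")
  me <- module_eigengene(expr, part)
  e <- me$eigengene[, "M1"]

  # trait identical (and opposite) to the eigengene
  clin <- data.frame(sample_id = rownames(me$eigengene),
                     same = e, flip = -e, stringsAsFactors = FALSE)
  mt <- module_trait_correlation(me, clin, c("same", "flip"))
  expect_equal(unname(mt$r["M1", "same"]), 1, tolerance = 1e-10)
  expect_equal(unname(mt$r["M1", "flip"]), -1, tolerance = 1e-10)
  expect_lt(mt$p["M1", "same"], 1e-10)

  # arbitrary trait: p matches the closed-form t CDF and cor.test
  set.seed(42)
  clin$mix <- 0.5 * e + rnorm(45)
  mt2 <- module_trait_correlation(me, clin, "mix")
  ct <- cor.test(e, clin$mix)
  expect_equal(unname(mt2$r["M1", "mix"]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(unname(mt2$p["M1", "mix"]), ct$p.value, tolerance = 1e-12)
  expect_equal(unname(mt2$n["M1", "mix"]), 45)
})

test_that("module-trait p-values agree with a permutation null on small n", {
  set.seed(43)
  n <- 14
  e <- rnorm(n)
  x <- rnorm(n)
  r_obs <- cor(e, x)
  t_p <- 2 * pt(abs(r_obs) * sqrt((n - 2) / (1 - r_obs^2)), n - 2, lower.tail = FALSE)
  perm <- replicate(4000, abs(cor(e, sample(x))) >= abs(r_obs) - 1e-12)
  p_perm <- mean(perm)
  expect_lt(abs(t_p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("trait-correlated modules are selected and null ones are not", {
  co <- generate_cohort(sim_config(n_genes = 250, module_sizes = c(60, 60),
                                   within_module_cor = 0.8, n_samples = 60,
                                   seed = 51))
  part <- cluster_modules(tom_similarity(adjacency(co$expr, 6)),
                          network_config(), expr = co$expr)
  me <- module_eigengene(co$expr, part)
  mt <- module_trait_correlation(me, co$clinical, c("fvc_pct", "dlco_pct", "cpi"))
  sel <- select_trait_modules(mt)
  # the signature module's factor drives lung function; find its label
  sig_genes <- co$truth$signature_genes
  lab <- names(which.max(table(part$assignment[sig_genes])))
  expect_true(lab %in% sel)

  # alpha = 1 selects every non-grey module; uniform p selects none
  expect_setequal(select_trait_modules(mt, alpha = 1),
                  setdiff(rownames(mt$p), "grey"))
  mt_null <- mt
  mt_null$p[] <- 0.5
  expect_length(select_trait_modules(mt_null), 0)
})

test_that("the package's adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(61)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(letters[1:5], 2)),
               mclust::adjustedRandIndex(1:10, rep(letters[1:5], 2)))
})
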