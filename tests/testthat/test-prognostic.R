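test_that("three-criteria compilation is exact set algebra with provenance", {
  genes <- sprintf("g%03d", 1:120)
  part <- structure(list(
    assignment = setNames(rep(c("M1", "M2", "grey"), c(60, 30, 30)), genes),
    module_sizes = table(rep(c("M1", "M2", "grey"), c(60, 30, 30)))),
    class = "module_partition")
  in_modules <- genes[1:90]
  de <- genes[c(1:40, 61:70, 100:110)]
  cox <- genes[c(1:50, 61:65, 111:120)]
  got <- compile_predictor_genes(c("M1", "M2"), part, de, cox)
  truth <- intersect(intersect(in_modules, de), cox)   # g001..g040, g061..g065
  expect_setequal(got$genes, truth)
  expect_length(got$genes, 45)
  expect_identical(got$provenance$gene, got$genes)
  expect_true(all(got$provenance$module %in% c("M1", "M2")))

  # identical criterion sets: idempotent intersection
  same <- compile_predictor_genes("M1", part, genes[1:60], genes[1:60])
  expect_setequal(same$genes, genes[1:60])

  # disjoint sets: actionable error
  expect_error(compile_predictor_genes("M1", part, genes[61:70], genes[61:70]),
               "empty intersection")
})

test_that("predictor ordering follows |fold change| then gene id", {
  genes <- c("b", "a", "c")
  part <- structure(list(assignment = setNames(rep("M1", 3), genes),
                         module_sizes = table(rep("M1", 3))),
                    class = "module_partition")
  sam <- structure(list(d = setNames(c(1, 1, 1), genes),
                        fc = setNames(c(1.7, -1.7, 2.5), genes),
                        fdr_pct = setNames(c(1, 1, 1), genes),
                        s0 = 0.1, n_perm = 10, exact = TRUE, seed = 1L),
                   class = "sam_result")
  got <- compile_predictor_genes("M1", part, genes, genes, sam = sam)
  expect_identical(got$genes, c("c", "a", "b"))  # 2.5, then |−1.7| tie by id
})

test_that("a single-gene model ranks patients by that gene with the Cox sign", {
  set.seed(31)
  x <- rnorm(50)
  sv <- sim_surv(x, beta = 1.2, seed = 31)
  expr <- matrix(8 + x, 1, dimnames = list("g1", sv$sample_id))
  model <- fit_supervised_pca(expr, sv, n_components = 1)
  pis <- prognostic_index(model, expr)
  # higher expression -> higher hazard -> higher PI
  expect_equal(order(pis), order(expr[1, ]))
  expect_gt(model$weights[["g1"]], 0)
  expect_error(fit_supervised_pca(expr, sv, n_components = 0), "n_components")
})

test_that("the PI equals the component-space linear predictor up to a constant", {
  co <- generate_cohort(sim_config(n_genes = 80, module_sizes = 40,
                                   n_samples = 40, seed = 32))
  genes <- co$truth$signature_genes[1:20]
  expr <- co$expr[genes, ]
  model <- fit_supervised_pca(expr, co$survival, n_components = 2)
  pis <- prognostic_index(model, expr)
  # recompute the component-space linear predictor directly
  st <- model$standardization
  z <- t((expr - st$mean) / st$sd)
  pc <- prcomp(z, center = FALSE)
  v <- pc$rotation[, 1:2]
  # weights live in the same 2-dim subspace: lp and pi differ by a constant
  lp <- as.vector(z %*% (v %*% solve(crossprod(v), crossprod(v, st$sd * model$weights))))
  expect_equal(diff(range((pis - model$offset) -
                            as.vector(crossprod(expr, model$weights)))), 0,
               tolerance = 1e-10)
  shifts <- pis - lp
  expect_lt(diff(range(shifts)), 1e-8)
})

test_that("risk ranking is invariant to a global intensity rescaling", {
  co <- generate_cohort(sim_config(n_genes = 60, module_sizes = 30,
                                   n_samples = 45, seed = 33))
  genes <- co$truth$signature_genes[1:15]
  m1 <- fit_supervised_pca(co$expr[genes, ], co$survival)
  m2 <- fit_supervised_pca(co$expr[genes, ] * 2, co$survival)
  r1 <- rank(prognostic_index(m1, co$expr[genes, ]))
  r2 <- rank(prognostic_index(m2, co$expr[genes, ] * 2))
  expect_true(identical(r1, r2) || identical(r1, rank(-prognostic_index(m2, co$expr[genes, ] * 2))))
  a1 <- assign_risk(prognostic_index(m1, co$expr[genes, ]))
  a2 <- assign_risk(prognostic_index(m2, co$expr[genes, ] * 2))
  expect_identical(a1$risk, a2$risk)
})

test_that("the prognostic index is the documented affine form", {
  model <- structure(list(genes = c("a", "b", "c"),
                          weights = c(a = 0.5, b = -1, c = 2),
                          offset = 13.5, n_components = 1,
                          standardization = NULL, risk_split = c(66.7, 33.3)),
                     class = "prognostic_model")
  expr <- toy_expr(matrix(c(2, 1, 0.25), 3), genes = c("a", "b", "c"),
                   samples = "p1")
  expect_equal(unname(prognostic_index(model, expr)), 0.5 * 2 - 1 * 1 + 2 * 0.25 + 13.5)
  expect_equal(unname(prognostic_index(model, expr)), 14.0)

  # zero weights: offset only
  model$weights[] <- 0
  multi <- toy_expr(matrix(rnorm(9), 3), genes = c("a", "b", "c"))
  expect_equal(unname(prognostic_index(model, multi)), rep(13.5, 3))

  # single gene arithmetic
  m1 <- structure(list(genes = "a", weights = c(a = 1), offset = 13.5),
                  class = "prognostic_model")
  e1 <- toy_expr(matrix(2, 1), genes = "a", samples = "s")
  expect_equal(unname(prognostic_index(m1, e1)), 15.5)

  # affinity: adding delta to one gene moves PI by W_i * delta
  m2 <- structure(list(genes = c("a", "b"), weights = c(a = 0.7, b = -0.2),
                       offset = 13.5), class = "prognostic_model")
  e2 <- toy_expr(matrix(c(1, 2), 2), genes = c("a", "b"), samples = "s")
  e2b <- e2; e2b["a", ] <- e2b["a", ] + 3
  expect_equal(unname(prognostic_index(m2, e2b) - prognostic_index(m2, e2)),
               0.7 * 3)
})

test_that("tertile assignment yields the documented counts and tie handling", {
  set.seed(41)
  pis <- setNames(sample(seq(0.01, 5, length.out = 45)), sprintf("p%02d", 1:45))
  ra <- assign_risk(pis)
  expect_equal(sum(ra$risk == "high"), 15)
  expect_equal(sum(ra$risk == "low"), 30)
  expect_equal(ra$threshold_pi, min(pis[ra$risk == "high"]))
  expect_true(all(pis[ra$risk == "high"] >= max(pis[ra$risk == "low"])))

  # tertile by construction
  ra9 <- assign_risk(setNames(1:9, paste0("s", 1:9)))
  expect_setequal(names(which(ra9$risk == "high")), paste0("s", 7:9))

  # two-way tie straddling the cut: stable ascending sample-id order wins
  tied <- setNames(c(1, 2, 3, 3, 2, 1), c("f", "e", "d", "c", "b", "a"))
  rat <- assign_risk(tied)   # n_high = 2; PI 3 held by "c" and "d"
  expect_setequal(names(which(rat$risk == "high")), c("c", "d"))
  tied2 <- setNames(c(3, 2, 2, 1), letters[1:4])  # n_high = 1... rounds to 1
  rat2 <- assign_risk(tied2)
  expect_identical(names(which(rat2$risk == "high")), "a")

  # rank invariance: any strictly monotone transform keeps the classes
  expect_identical(assign_risk(exp(pis))$risk, ra$risk)
  expect_warning(flat <- assign_risk(setNames(rep(1, 5), letters[1:5])), "identical")
  expect_true(all(flat$risk == "low"))
})

test_that("cross-validation is deterministic and its rate matches the formula", {
  co <- generate_cohort(sim_config(n_genes = 80, module_sizes = 40,
                                   n_samples = 45, seed = 51))
  genes <- co$truth$signature_genes[1:20]
  labels <- setNames(co$survival$prognosis, co$survival$sample_id)
  cv1 <- cross_validate(co$expr[genes, ], co$survival, labels, k = 5, seed = 9)
  cv2 <- cross_validate(co$expr[genes, ], co$survival, labels, k = 5, seed = 9)
  expect_identical(cv1, cv2)

  # the reported rate is (pred high & good + pred low & poor) / total
  obs <- cv1$observed
  pred <- cv1$predicted_risk
  k_n <- sum(pred == "high" & obs == "good") + sum(pred == "low" & obs == "poor")
  expect_equal(cv1$misclassification_rate, k_n / length(obs))
  expect_length(cv1$repeats, 1)

  cv3 <- cross_validate(co$expr[genes, ], co$survival, labels, k = 5,
                        repeats = 3, seed = 9)
  expect_length(cv3$repeats, 3)
  expect_equal(cv3$range, range(cv3$repeats))
})

test_that("under independence the CV rate approaches its closed form", {
  # expression carries no outcome signal: predicted high risk is an
  # independent 1/3 coin, so E[rate] = (1/3) P(good) + (2/3) P(poor)
  rates <- sapply(1:3, function(s) {
    set.seed(s * 100)
    n <- 90
    expr <- noise_expr(25, n, seed = s * 100)
    sv <- surv_df(rexp(n, 0.03), rbinom(n, 1, 0.8), ids = colnames(expr))
    labels <- setNames(derive_prognosis_label(sv$time_months, sv$event),
                       sv$sample_id)
    q <- mean(labels == "poor")
    cv <- cross_validate(expr, sv, labels, k = 5, seed = s)
    cv$misclassification_rate - ((1 / 3) * (1 - q) + (2 / 3) * q)
  })
  expect_lt(abs(mean(rates)), 0.12)
})
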