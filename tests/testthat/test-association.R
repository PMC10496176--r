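test_that("IRLS logistic agrees with Newton oracle and glm to 1e-6", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    d <- rbinom(n, 2, 0.3)
    covar <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n, 80, 8))
    y <- rbinom(n, 1, plogis(-0.2 + 0.5 * d + 0.3 * covar[, 1]))
    if (length(unique(y)) < 2 || length(unique(d)) < 2) next
    fit <- fit_logistic(y, d, covar)
    X <- cbind(1, d, covar)
    ora <- oracle_logistic(X, y)
    expect_equal(fit$beta, ora$beta[2], tolerance = 1e-6)
    expect_equal(fit$se, ora$se[2], tolerance = 1e-6)
    gl <- glm(y ~ d + covar, family = binomial())
    expect_equal(fit$beta, unname(coef(gl)["d"]), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(diag(vcov(gl)))["d"]), tolerance = 1e-6)
  }
})

test_that("a genotype-count table fit matches the closed-form solution", {
  # 2 x 3 table expanded to observations: the 6-cell likelihood solved by
  # the independent Newton oracle on aggregated counts
  counts <- rbind(case = c(30, 45, 25), control = c(55, 35, 10))
  y <- rep(c(1, 0), rowSums(counts))
  d <- c(rep(0:2, counts["case", ]), rep(0:2, counts["control", ]))
  fit <- fit_logistic(y, d)
  ora <- oracle_logistic(cbind(1, 0:2)[rep(1:3, colSums(counts)), ],
                         unlist(lapply(0:2, function(g) {
                           rep(c(1, 0), counts[, g + 1])
                         })))
  expect_equal(fit$beta, ora$beta[2], tolerance = 1e-6)
  expect_equal(fit$se, ora$se[2], tolerance = 1e-6)
})

test_that("result invariants: OR/CI consistency, allele flip, age shift", {
  set.seed(33)
  n <- 300
  d <- rbinom(n, 2, 0.25)
  covar <- cbind(age = rnorm(n, 80, 8))
  y <- rbinom(n, 1, plogis(0.6 * d - 0.1))
  fit <- fit_logistic(y, d, covar)
  expect_equal(fit$or_, exp(fit$beta))
  expect_equal(fit$ci95, exp(fit$beta + c(-1.96, 1.96) * fit$se))
  expect_gt(fit$p, 0)

  flipped <- fit_logistic(y, 2 - d, covar)
  expect_equal(flipped$beta, -fit$beta, tolerance = 1e-8)
  expect_equal(flipped$p, fit$p, tolerance = 1e-8)
  expect_equal(flipped$eaf, 1 - fit$eaf)

  shifted <- fit_logistic(y, d, covar + 100)
  expect_equal(shifted$beta, fit$beta, tolerance = 1e-6)
})

test_that("Firth engages on separation and stays off on balanced data", {
  d <- c(rep(0, 20), rep(2, 20))
  y <- c(rep(0, 20), rep(1, 20))      # perfect separation
  fit <- fit_logistic(y, d)
  expect_true(fit$firth_used)
  expect_true(is.finite(fit$beta) && is.finite(fit$se))
  expect_lt(abs(fit$beta), 10)

  set.seed(44)
  for (rep in 1:10) {
    n <- 400
    dd <- rbinom(n, 2, 0.4)
    yy <- rbinom(n, 1, plogis(0.3 * dd))
    expect_false(fit_logistic(yy, dd)$firth_used)
  }
})

test_that("null p-values are uniform (KS over replicate fits)", {
  set.seed(55)
  ps <- vapply(1:500, function(i) {
    d <- rbinom(2000, 2, 0.3)
    y <- rbinom(2000, 1, 0.4)
    fit_logistic(y, d)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("degenerate designs raise typed errors", {
  expect_error(fit_logistic(rep(1, 10), rbinom(10, 2, 0.5)),
               class = "copath_design")
  expect_error(fit_logistic(rbinom(10, 1, 0.5), rep(1, 10)),
               class = "copath_monomorphic")
  expect_error(contrast_spec("AD_vs_everything"), class = "copath_contrast")
})

test_that("principal components recover planted structure", {
  co <- generate_cohort(simulation_config(
    n_per_site = c(250, 250), n_variants = 200L, pop_divergence_fst = 0.1,
    genotype_missing_rate = 0.02, duplicate_rate = 0, first_degree_rate = 0,
    seed = 77
  ))
  pcs <- compute_pcs(co$genotypes, k = 10)
  r <- cor(pcs[, 1], co$truth$subpop)
  expect_gt(abs(r), 0.9)
  # permutation equivariance
  perm <- sample(ncol(co$genotypes$dosages))
  ids <- colnames(co$genotypes$dosages)[perm]
  pcs_p <- compute_pcs(co$genotypes, individuals = ids, k = 10)
  expect_equal(pcs_p, pcs[ids, ], tolerance = 1e-8)
})

test_that("a rank-one dosage matrix reproduces its generating vector", {
  v <- c(0.2, 0.5, 1.1, 1.9, 0.8, 1.4)
  dos <- outer(rep(1, 4), v)   # four identical variants
  g <- make_genotypes(dos)
  pcs <- compute_pcs(g, k = 1)
  std <- (v - mean(v)) / sd(v)
  expect_equal(abs(cor(pcs[, 1], std)), 1, tolerance = 1e-10)
})

test_that("run_site_gwas wires classification, QC and covariates together", {
  co <- generate_cohort(simulation_config(n_per_site = c(900, 100),
                                          n_variants = 20L, seed = 19))
  ph <- co$pathology
  res <- run_site_gwas(ph[ph$site == "site1", ], co$genotypes,
                       "AD_vs_ctrl", "current", n_pcs = 4)
  expect_true(all(c("beta", "se", "p", "chrom", "pos", "effect_allele",
                    "n_cases", "n_controls") %in% names(res)))
  expect_true(co$truth$causal_id %in% res$variant)
  causal <- res[res$variant == co$truth$causal_id, ]
  expect_lt(causal$p, 1e-4)
  expect_s3_class(attr(res, "dropped"), "data.frame")

  # a site with no sole-LB cases is infeasible for that contrast
  ph_nolb <- ph[ph$site == "site1", ]
  ph_nolb$lewy_dist[ph_nolb$lewy_dist %in% c("limbic", "neocortical")] <- "none"
  expect_error(
    run_site_gwas(ph_nolb, co$genotypes, "LB_vs_ctrl", "current"),
    class = "copath_contrast_infeasible"
  )
})

test_that("allele-count helper reproduces published-table arithmetic", {
  st <- allele_count_stats(744, 2144, 249, 2526)
  expect_equal(st$case_freq_pct, 34.7, tolerance = 0.05)
  expect_equal(st$ctrl_freq_pct, 9.9, tolerance = 0.05)
  expect_equal(st$allelic_or, (744 * 2277) / (1400 * 249), tolerance = 1e-12)
})
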