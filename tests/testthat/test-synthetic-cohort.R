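# The generator runs at reduced size in most of these tests; the full-size
# parameter-recovery experiments live in test-acceptance.R.

small_config <- function(...) {
  simulation_config(n_per_site = c(600L, 300L), n_variants = 20L, ...)
}

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- generate_cohort(small_config(seed = 42))
  b <- generate_cohort(small_config(seed = 42))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- generate_cohort(small_config(seed = 43))
  expect_false(identical(a$genotypes$dosages, c_$genotypes$dosages))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simulation_config(n_variants = 1), "n_variants")
  expect_error(simulation_config(causal_ad_variant_index = 99), "causal_ad_variant_index")
  expect_error(simulation_config(lb_base_rate = 1.2), "lb_base_rate")
  expect_error(simulation_config(duplicate_rate = -0.1), "duplicate_rate")
  expect_error(simulation_config(allele_freq_range = c(0.001, 0.5)),
               "allele_freq_range")
})

test_that("zero relative rates yield an empty kinship table", {
  co <- generate_cohort(small_config(duplicate_rate = 0, first_degree_rate = 0,
                                     seed = 5))
  expect_equal(nrow(co$kinship), 0L)
})

test_that("planted relatives carry the declared kinship coefficients", {
  co <- generate_cohort(small_config(duplicate_rate = 0.05,
                                     first_degree_rate = 0.05, seed = 5))
  expect_true(all(co$kinship$kinship %in% c(0.5, 0.25)))
  dups <- co$kinship[co$kinship$kinship == 0.5, ]
  expect_gt(nrow(dups), 0)
  for (k in seq_len(nrow(dups))) {
    a <- co$genotypes$dosages[, dups$id1[k]]
    b <- co$genotypes$dosages[, dups$id2[k]]
    ok <- !is.na(a) & !is.na(b)   # missingness is masked after copying
    expect_identical(round(a[ok]), round(b[ok]))
    expect_gt(sum(ok), 0)
  }
})

test_that("at default settings ~60% of AD+ individuals carry limbic or worse LB", {
  co <- generate_cohort(simulation_config(seed = 2024))
  tab <- tabulate_categories(co$pathology, "current")
  frac <- tab[["AD+LB+"]] / (tab[["AD+LB+"]] + tab[["AD+LB-"]])
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.7)
})

test_that("LB status is independent of causal dosage within liability strata", {
  co <- generate_cohort(simulation_config(n_per_site = c(4000, 2000),
                                          genotype_missing_rate = 0, seed = 9))
  dose <- co$genotypes$dosages[co$truth$causal_id, ]
  lbpos <- as.integer(co$truth$lb_stage >= 2)
  decile <- cut(co$truth$liability,
                quantile(co$truth$liability, 0:10 / 10),
                include.lowest = TRUE, labels = FALSE)
  X <- cbind(1, model.matrix(~ factor(decile))[, -1], dose = dose)
  fit <- oracle_logistic(X, lbpos)
  slope <- fit$beta[ncol(X)]
  se <- fit$se[ncol(X)]
  expect_lt(abs(slope), 1.96 * se)
})

test_that("stronger planted effects raise the AD+ fraction among carriers", {
  fracs <- vapply(c(0, log(2), log(4)), function(b) {
    co <- generate_cohort(simulation_config(n_per_site = c(4000, 2000),
                                            causal_ad_log_or = b, seed = 31))
    ph <- classify_cohort(co$pathology, "current")
    carrier <- co$genotypes$dosages[co$truth$causal_id, ph$id] >= 1
    carrier[is.na(carrier)] <- FALSE
    mean(ph$category[carrier] %in% c("AD+LB+", "AD+LB-"))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("a null generator yields nominal CI coverage for the causal variant", {
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(simulation_config(
      n_per_site = c(600, 300), n_variants = 5L, causal_ad_log_or = 0,
      genotype_missing_rate = 0, duplicate_rate = 0, first_degree_rate = 0,
      seed = 5000 + s
    ))
    ph <- classify_cohort(co$pathology, "current")
    sel <- ph$category %in% c("AD+LB-", "AD-LB-")
    y <- as.integer(ph$category[sel] == "AD+LB-")
    d <- co$genotypes$dosages[co$truth$causal_id, ph$id[sel]]
    cov <- cbind(sex = as.integer(ph$sex[sel] == "F"), age = ph$age_at_death[sel])
    fit <- fit_logistic(y, d, cov)
    abs(fit$beta) <= 1.96 * fit$se
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("misclassification experiment demands a non-empty scheme list", {
  expect_error(misclassification_experiment(small_config(), list()),
               class = "copath_config")
})
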