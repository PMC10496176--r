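# Per-site logistic-regression association, implemented from first
# principles: IRLS maximum likelihood with a Firth bias-reduced fallback
# under (quasi-)separation, Wald tests from the observed information.

#' The four case-control contrasts
#'
#' @param name one of `ADLB_vs_ctrl` (AD+LB+ vs AD-LB-), `AD_vs_ctrl`
#'   (AD+LB- vs AD-LB-), `LB_vs_ctrl` (AD-LB+ vs AD-LB-), `ADLB_vs_AD`
#'   (AD+LB+ vs AD+LB-).
#' @return list with `name`, `case_category`, `control_category`.
#' @export
contrast_spec <- function(name) {
  defs <- list(
    ADLB_vs_ctrl = c("AD+LB+", "AD-LB-"),
    AD_vs_ctrl   = c("AD+LB-", "AD-LB-"),
    LB_vs_ctrl   = c("AD-LB+", "AD-LB-"),
    ADLB_vs_AD   = c("AD+LB+", "AD+LB-")
  )
  if (!name %in% names(defs)) {
    stop_copath("contrast", sprintf(
      "unknown contrast '%s'; available: %s", name,
      paste(names(defs), collapse = ", ")
    ))
  }
  list(name = name, case_category = defs[[name]][1],
       control_category = defs[[name]][2])
}

#' Principal components of a dosage matrix
#'
#' Computes the top `k` principal components of the individuals x variants
#' dosage matrix after per-variant mean imputation of missing entries,
#' centering and variance standardization. Deterministic up to sign; signs
#' are fixed by making each component's largest-magnitude variant loading
#' positive.
#'
#' @param genotypes a [genotype_matrix()].
#' @param individuals ids to compute PCs for (default: all columns).
#' @param k number of components.
#' @return numeric matrix (individuals x k) with columns `pc1..pck` and
#'   rownames the individual ids.
#' @export
compute_pcs <- function(genotypes, individuals = NULL, k = 10) {
  dos <- genotypes$dosages
  if (!is.null(individuals)) dos <- dos[, individuals, drop = FALSE]
  X <- t(dos)
  n <- nrow(X)
  if (n < k + 1L) stop_copath("pca", "need at least k + 1 individuals")
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    mu <- mean(xj, na.rm = TRUE)
    xj[is.na(xj)] <- mu
    s <- sd(xj)
    X[, j] <- if (s > 0) (xj - mu) / s else 0
  }
  keep <- apply(X, 2, function(x) any(x != 0))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) stop_copath("pca", "degenerate (constant) dosage matrix")
  k <- min(k, ncol(X), n - 1L)
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(X), paste0("pc", seq_len(k)))
  scores
}

# Core IRLS maximum-likelihood logistic fit. Returns beta, the inverse
# observed information, convergence flag and the final log-likelihood.
irls_logistic <- function(X, y, max_iter = 25L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    ll <- sum(y * eta - log1p(exp(eta)))
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-8)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  p <- plogis(drop(X %*% beta))
  w <- pmax(p * (1 - p), 1e-12)
  info <- t(X * w) %*% X
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, vcov = vcov, converged = converged, loglik = ll_old)
}

# Firth bias-reduced logistic regression: IRLS on the modified score
# U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij, with h the hat diagonal.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(inv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  p <- plogis(drop(X %*% beta))
  w <- pmax(p * (1 - p), 1e-12)
  info <- t(X * w) %*% X
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, vcov = vcov, converged = converged)
}

#' Logistic-regression association of case status with dosage
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood (IRLS). If the
#' fit fails to converge, drifts to an extreme estimate (|beta| > 10, a
#' quasi-separation signature) or yields a singular information matrix, the
#' model is refit with Firth's bias-reduced likelihood and `firth_used` is
#' set. The dosage effect is per alt-allele; tests are two-sided Wald.
#'
#' @param case_status binary vector (1 = case).
#' @param dosage numeric dosage vector in `[0, 2]`; individuals with missing
#'   dosage are dropped from the fit.
#' @param covariates optional numeric matrix/data frame of covariates (no
#'   missing values among modeled individuals).
#' @param variant_id label carried into the result.
#' @param firth `"fallback"` (default), `"never"`, or `"always"`.
#' @return one-row data frame: `variant, beta, se, or_, ci_low, ci_high, p,
#'   n_cases, n_controls, eaf, converged, firth_used`.
#' @export
fit_logistic <- function(case_status, dosage, covariates = NULL,
                         variant_id = NA_character_, firth = "fallback") {
  y <- as.numeric(case_status)
  if (!all(y %in% c(0, 1))) stop_copath("design", "case_status must be binary")
  keep <- !is.na(dosage) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & !apply(covariates, 1, anyNA)
  }
  y <- y[keep]
  d <- dosage[keep]
  if (sum(y) == 0 || sum(1 - y) == 0) {
    stop_copath("design", "need at least one case and one control")
  }
  if (length(unique(d)) < 2L) {
    stop_copath("monomorphic", "dosage is constant; no association estimable")
  }
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (!is.null(covariates)) X <- cbind(X, covariates[keep, , drop = FALSE])

  fit <- irls_logistic(X, y)
  firth_used <- FALSE
  bad <- !fit$converged || !all(is.finite(fit$vcov)) || abs(fit$beta[2]) > 10
  if (firth == "always" || (firth == "fallback" && bad)) {
    fit <- firth_logistic(X, y)
    firth_used <- TRUE
  }
  beta <- fit$beta[2]
  se <- sqrt(fit$vcov[2, 2])
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  structure(
    data.frame(
      variant = variant_id, beta = beta, se = se, or_ = exp(beta),
      ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
      p = max(p, 1e-320), n_cases = sum(y), n_controls = sum(1 - y),
      eaf = sum(d) / (2 * length(d)), converged = fit$converged,
      firth_used = firth_used, stringsAsFactors = FALSE
    ),
    class = c("association_result", "data.frame")
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "OR = %.3f, 95%% CI = %.3f-%.3f, P = %.3g (beta %.4f, se %.4f)%s\n",
    x$or_, x$ci_low, x$ci_high, x$p, x$beta, x$se,
    if (x$firth_used) " [Firth]" else ""
  ))
  invisible(x)
}

# ci95 accessor used in documentation/tests: exp(beta +/- 1.96 se).
#' @export
`$.association_result` <- function(x, name) {
  if (identical(name, "ci95")) return(c(x[["ci_low"]], x[["ci_high"]]))
  NextMethod()
}

#' Crude allelic association from allele counts
#'
#' Allele-count arithmetic for published tables: effect-allele frequencies
#' and the unadjusted allelic odds ratio from a 2 x 2 allele table.
#'
#' @param case_alt,case_total effect-allele count and total allele count in
#'   cases.
#' @param ctrl_alt,ctrl_total the same in controls.
#' @return list with `case_freq_pct`, `ctrl_freq_pct` (percentages) and
#'   `allelic_or`.
#' @export
allele_count_stats <- function(case_alt, case_total, ctrl_alt, ctrl_total) {
  stopifnot(case_alt <= case_total, ctrl_alt <= ctrl_total)
  list(
    case_freq_pct = 100 * case_alt / case_total,
    ctrl_freq_pct = 100 * ctrl_alt / ctrl_total,
    allelic_or = (case_alt * (ctrl_total - ctrl_alt)) /
      ((case_total - case_alt) * ctrl_alt)
  )
}

#' Run a one-site, one-contrast GWAS
#'
#' Classifies the site's individuals under `scheme`, selects the contrast's
#' case/control groups, applies variant QC on that subset (HWE in controls
#' only by default), computes site-level principal components on the
#' post-QC variants, and fits every surviving variant with sex,
#' age-at-death and the top `n_pcs` PCs as covariates.
#'
#' @param pathology pathology records for one site (columns `id, sex,
#'   age_at_death, braak, cerad, lewy_dist`).
#' @param genotypes a [genotype_matrix()] covering those individuals.
#' @param contrast a contrast name or [contrast_spec()].
#' @param scheme a scheme or built-in name.
#' @param n_pcs number of principal-component covariates.
#' @param variant_ids optional subset of variants to fit (QC still runs on
#'   all variants; PCs use the full post-QC set).
#' @param hwe_controls_only logical; test HWE in controls only (default).
#' @param maf_min,hwe_p_min,miss_max,r2_min QC thresholds, see
#'   [apply_variant_filters()].
#' @param firth passed to [fit_logistic()].
#' @return data frame of per-variant association results with variant
#'   metadata columns (`chrom, pos, effect_allele, other_allele`) attached;
#'   attribute `dropped` holds the QC drop report.
#' @export
run_site_gwas <- function(pathology, genotypes, contrast, scheme,
                          n_pcs = 10, variant_ids = NULL,
                          hwe_controls_only = TRUE,
                          maf_min = 0.01, hwe_p_min = 1e-5,
                          miss_max = 0.20, r2_min = 0.8,
                          firth = "fallback") {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  ph <- classify_cohort(pathology, scheme)
  cases <- ph$id[ph$category == contrast$case_category]
  controls <- ph$id[ph$category == contrast$control_category]
  if (length(cases) == 0L || length(controls) == 0L) {
    stop_copath("contrast_infeasible", sprintf(
      "contrast %s infeasible: %d cases (%s), %d controls (%s)",
      contrast$name, length(cases), contrast$case_category,
      length(controls), contrast$control_category
    ))
  }
  subset_ids <- c(cases, controls)
  qc <- apply_variant_filters(
    genotypes, individuals = subset_ids,
    maf_min = maf_min, hwe_p_min = hwe_p_min, miss_max = miss_max,
    r2_min = r2_min,
    hwe_ids = if (hwe_controls_only) controls else NULL
  )
  if (length(qc$kept) == 0L) {
    stop_copath("variant_qc", "no variants survive QC in this subset")
  }
  gsub_ <- subset_genotypes(genotypes, qc$kept, subset_ids)
  pcs <- compute_pcs(gsub_, k = n_pcs)
  ph <- ph[match(subset_ids, ph$id), ]
  covar <- cbind(sex = as.integer(ph$sex == "F"),
                 age_at_death = ph$age_at_death,
                 pcs[subset_ids, , drop = FALSE])
  y <- as.integer(subset_ids %in% cases)

  fit_ids <- if (is.null(variant_ids)) qc$kept else intersect(variant_ids, qc$kept)
  vmeta <- gsub_$variants
  rows <- lapply(fit_ids, function(vid) {
    i <- match(vid, vmeta$id)
    res <- fit_logistic(y, gsub_$dosages[i, ], covar, variant_id = vid,
                        firth = firth)
    res$chrom <- vmeta$chrom[i]
    res$pos <- vmeta$pos[i]
    res$effect_allele <- vmeta$alt[i]
    res$other_allele <- vmeta$ref[i]
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- qc$dropped
  attr(out, "contrast") <- contrast$name
  out
}
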