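# Independent oracles and fixture builders shared across test files.

# Newton-Raphson logistic maximum likelihood, written independently of the
# package's IRLS engine (explicit gradient/Hessian, no weighted least
# squares). Returns coefficients and Wald standard errors.
oracle_logistic <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- drop(t(X) %*% (y - p))
    hess <- -t(X) %*% (X * (p * (1 - p)))
    beta <- beta - solve(hess, grad)
  }
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  se <- sqrt(diag(solve(t(X) %*% (X * (p * (1 - p))))))
  list(beta = unname(beta), se = unname(se))
}

# Exact conditional HWE p-value by direct enumeration using binomial
# coefficients (a formulation independent of the package's log-space
# recurrence): P(h | n, nr) proportional to C(n, hom_r) C(n - hom_r, h) 2^h.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  hs <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  pr <- vapply(hs, function(h) {
    hom_r <- (nr - h) / 2
    choose(n, hom_r) * choose(n - hom_r, h) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# The current-study classification rules, re-stated as independent
# predicates over (braak 0-6, cerad 0-3, lb in {"LB-","LB+"}) straight from
# their textual definition; used to cross-check the shipped decision table.
oracle_current_ad <- function(braak, cerad, lb) {
  if (braak >= 4 && cerad >= 2) return("AD+")
  if (lb == "LB+" && ((braak >= 3 && cerad == 1) ||
                      (braak == 3 && cerad >= 2))) return("AD+")
  if (braak >= 5 && cerad == 0) return("unclassified")
  if (lb == "LB-" && braak >= 5 && cerad == 1) return("unclassified")
  if (lb == "LB-" && braak == 3 && cerad == 3) return("unclassified")
  if (braak <= 2) return("AD-")
  if (braak %in% c(3, 4) && cerad == 0) return("AD-")
  if (lb == "LB-" && ((braak == 3 && cerad %in% c(1, 2)) ||
                      (braak == 4 && cerad == 1))) return("AD-")
  "AD-"
}

# A tiny hand-built pathology table with one exemplar per quadrant.
quadrant_records <- function() {
  data.frame(
    id = c("q1", "q2", "q3", "q4"),
    site = "site1", sex = "F", age_at_death = c(80, 82, 84, 86),
    braak = c(5, 5, 1, 0), cerad = c(3, 3, 0, 0),
    lewy_dist = c("neocortical", "none", "limbic", "none"),
    stringsAsFactors = FALSE
  )
}

# All 56 (braak, cerad, LB-stratum) cells as records, one per cell, using a
# representative Lewy distribution per stratum.
cell_records <- function() {
  grid <- expand.grid(braak = 0:6, cerad = 0:3, lb = c("LB-", "LB+"),
                      stringsAsFactors = FALSE)
  data.frame(
    id = sprintf("c%02d", seq_len(nrow(grid))),
    site = "site1", sex = "M", age_at_death = 80,
    braak = grid$braak, cerad = grid$cerad,
    lewy_dist = ifelse(grid$lb == "LB+", "limbic", "none"),
    lb = grid$lb, stringsAsFactors = FALSE
  )
}

# Small genotype fixture: m variants x n individuals with given dosages.
make_genotypes <- function(dosages, r2 = NA_real_) {
  m <- nrow(dosages)
  dimnames(dosages) <- list(sprintf("v%03d", seq_len(m)),
                            sprintf("i%03d", seq_len(ncol(dosages))))
  genotype_matrix(dosages, data.frame(
    id = rownames(dosages), chrom = as.character(rep(1:22, length.out = m)),
    pos = seq_len(m) * 1000L, ref = "A", alt = "G",
    r2 = rep_len(r2, m), stringsAsFactors = FALSE
  ))
}
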