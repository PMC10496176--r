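# Two-site synthetic cohort generator. The generative model:
#
#   liability  S = beta * dosage(causal) + 0.03 * (age - 85) + Logistic(0, 1)
#   Braak      = ordinal cut of S + N(0, 0.15) at fixed thresholds
#   CERAD      = ordinal cut of S + N(0, 0.15) at fixed thresholds
#   LB stage   = ordinal cut of coupling * f(S) + Logistic(0, 1), where f(S)
#                counts AD-stage boundaries crossed (0 below the early-AD
#                cut, 1 between early and established AD, 1.3 above), so LB
#                risk rises with AD severity and then saturates.
#
# Logistic liability noise makes the per-allele log-odds of crossing any
# liability threshold exactly `beta`, so a logistic regression of an
# AD-defined case group on the causal dosage recovers the planted effect.
# LB stage is a function of S plus independent noise, hence conditionally
# independent of the causal allele given liability: the generator encodes
# the null that the allele does not drive LB emergence beyond AD severity.
# Population structure is Balding-Nichols with two subpopulations mixed in
# different proportions at the two sites; the causal variant is kept
# undifferentiated so the planted effect is not confounded with structure.

# Emission thresholds (liability scale). The early-AD cut (-1.2) is where
# Braak crosses into III and CERAD into sparse; the established-AD cut
# (-0.2) is where Braak crosses into IV and CERAD into moderate. These
# anchor the decision-table boundaries of the built-in schemes.
BRAAK_THRESH <- c(-3.2, -2.2, -1.2, -0.2, 1.4, 2.8)
CERAD_THRESH <- c(-1.2, -0.2, 1.2)
AD_STAGE_CUTS <- c(-1.2, -0.2)
AD_STAGE_SCORE <- c(0, 0.5, 1.1)
LB_STAGE_OFFSETS <- c(-1.5, 0, 1.8)   # brainstem / limbic / neocortical cuts
EMISSION_NOISE_SD <- 0.15
AGE_LIABILITY_COEF <- 0.03

#' Configuration for the synthetic two-site cohort
#'
#' Defaults emulate a two-site autopsy cohort: a large site and a smaller,
#' older site; a planted per-allele effect of `log(4)` on AD liability at a
#' causal variant of frequency 0.2 (an APOE-e4-like effect); Lewy-body risk
#' that rises with AD severity but, given severity, is independent of the
#' causal allele; mild two-population structure; a sprinkling of duplicates
#' and first-degree relatives; and sporadic missing genotypes.
#'
#' @param n_per_site integer vector of length 2, individuals per site.
#' @param n_variants number of variants (>= 2).
#' @param causal_ad_variant_index index of the causal variant.
#' @param causal_ad_log_or per-allele log odds ratio on AD liability.
#' @param causal_allele_freq allele frequency of the causal variant (shared
#'   by both subpopulations).
#' @param lb_base_rate probability of limbic-or-worse Lewy bodies in an
#'   individual with no AD-stage pathology.
#' @param lb_ad_coupling increase in the log-odds of Lewy-body progression
#'   per unit of AD-stage score (>= 0).
#' @param allele_freq_range range the non-causal ancestral allele
#'   frequencies are drawn from; within (0.01, 0.5).
#' @param pop_divergence_fst Balding-Nichols divergence between the two
#'   subpopulations, in `[0, 0.2]`.
#' @param duplicate_rate,first_degree_rate fraction of individuals planted
#'   as one member of a duplicate / first-degree pair.
#' @param genotype_missing_rate per-entry probability a dosage is missing.
#' @param seed integer seed; all randomness flows from it through named
#'   per-component substreams.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_per_site = c(3600L, 1400L),
                              n_variants = 50L,
                              causal_ad_variant_index = 1L,
                              causal_ad_log_or = log(4),
                              causal_allele_freq = 0.2,
                              lb_base_rate = 0.08,
                              lb_ad_coupling = 2.4,
                              allele_freq_range = c(0.05, 0.5),
                              pop_divergence_fst = 0.05,
                              duplicate_rate = 0.01,
                              first_degree_rate = 0.02,
                              genotype_missing_rate = 0.01,
                              seed = 1L) {
  cfg <- list(
    n_per_site = as.integer(n_per_site), n_variants = as.integer(n_variants),
    causal_ad_variant_index = as.integer(causal_ad_variant_index),
    causal_ad_log_or = causal_ad_log_or,
    causal_allele_freq = causal_allele_freq,
    lb_base_rate = lb_base_rate, lb_ad_coupling = lb_ad_coupling,
    allele_freq_range = allele_freq_range,
    pop_divergence_fst = pop_divergence_fst,
    duplicate_rate = duplicate_rate, first_degree_rate = first_degree_rate,
    genotype_missing_rate = genotype_missing_rate, seed = as.integer(seed)
  )
  chk <- function(ok, field) {
    if (!isTRUE(ok)) {
      stop_copath("config", sprintf("invalid simulation_config field: %s", field))
    }
  }
  chk(length(cfg$n_per_site) == 2L && all(cfg$n_per_site >= 1L), "n_per_site")
  chk(length(cfg$n_variants) == 1L && cfg$n_variants >= 2L, "n_variants")
  chk(cfg$causal_ad_variant_index >= 1L &&
        cfg$causal_ad_variant_index <= cfg$n_variants,
      "causal_ad_variant_index")
  chk(is.finite(cfg$causal_ad_log_or), "causal_ad_log_or")
  chk(cfg$causal_allele_freq > 0 && cfg$causal_allele_freq < 1,
      "causal_allele_freq")
  chk(cfg$lb_base_rate >= 0 && cfg$lb_base_rate <= 1, "lb_base_rate")
  chk(cfg$lb_ad_coupling >= 0, "lb_ad_coupling")
  chk(length(cfg$allele_freq_range) == 2L &&
        cfg$allele_freq_range[1] > 0.01 && cfg$allele_freq_range[2] <= 0.5 &&
        cfg$allele_freq_range[1] <= cfg$allele_freq_range[2],
      "allele_freq_range")
  chk(cfg$pop_divergence_fst >= 0 && cfg$pop_divergence_fst <= 0.2,
      "pop_divergence_fst")
  for (f in c("duplicate_rate", "first_degree_rate", "genotype_missing_rate")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed")
  structure(cfg, class = "simulation_config")
}

# Named substreams: each component reseeds from the base seed plus a fixed
# offset so inserting draws in one component never perturbs another.
substream <- function(seed, component) {
  offsets <- c(freq = 101L, genotype = 211L, demographics = 307L,
               relatives = 401L, liability = 503L, emission = 601L,
               lewy = 701L, missing = 811L)
  set.seed((seed %% 2147480000L) + offsets[[component]])
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a synthetic two-site cohort
#'
#' @param config a [simulation_config()].
#' @return list of class `copath_cohort` with elements
#'   * `pathology`: data frame `id, site, sex, age_at_death, braak, cerad,
#'     lewy_dist`,
#'   * `genotypes`: a `genotype_matrix` (variants x individuals dosages plus
#'     per-variant metadata),
#'   * `kinship`: data frame `id1, id2, kinship` of planted relative pairs,
#'   * `truth`: latent liability, latent LB stage, subpopulation labels and
#'     the planted log odds ratio.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  m <- config$n_variants
  n <- sum(config$n_per_site)
  causal <- config$causal_ad_variant_index
  fst <- config$pop_divergence_fst

  # Ancestral and subpopulation allele frequencies (Balding-Nichols).
  substream(config$seed, "freq")
  p0 <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  p0[causal] <- config$causal_allele_freq
  psub <- if (fst > 0) {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    cbind(rbeta(m, a, b), rbeta(m, a, b))
  } else {
    cbind(p0, p0)
  }
  psub <- pmin(pmax(psub, 0.005), 0.995)
  psub[causal, ] <- config$causal_allele_freq

  site <- rep(c("site1", "site2"), config$n_per_site)
  # The two sites sample the two subpopulations in different proportions, so
  # genetic structure is confounded with site.
  substream(config$seed, "demographics")
  subpop <- ifelse(runif(n) < ifelse(site == "site1", 0.7, 0.4), 1L, 2L)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  age <- ifelse(site == "site1",
                rtruncnorm1(n, 82, 9, 50, 110),
                rtruncnorm1(n, 90, 6, 50, 110))
  id <- sprintf("ind%05d", seq_len(n))

  substream(config$seed, "genotype")
  geno <- matrix(rbinom(m * n, 2L, psub[, subpop]), nrow = m, ncol = n)

  # Planted relatives: duplicates copy the source genotype; first-degree
  # relatives inherit one allele per variant from the source and draw the
  # other from their own subpopulation. Kinship is emitted directly.
  substream(config$seed, "relatives")
  n_dup <- round(config$duplicate_rate * n / 2)
  n_fd <- round(config$first_degree_rate * n / 2)
  kin <- data.frame(id1 = character(0), id2 = character(0),
                    kinship = numeric(0), stringsAsFactors = FALSE)
  if (n_dup + n_fd > 0) {
    picks <- sample.int(n, 2L * (n_dup + n_fd))
    src <- picks[seq_len(n_dup + n_fd)]
    dst <- picks[(n_dup + n_fd) + seq_len(n_dup + n_fd)]
    if (n_dup > 0) {
      for (k in seq_len(n_dup)) geno[, dst[k]] <- geno[, src[k]]
    }
    if (n_fd > 0) {
      for (k in n_dup + seq_len(n_fd)) {
        transmitted <- rbinom(m, 1L, geno[, src[k]] / 2)
        own <- rbinom(m, 1L, psub[, subpop[dst[k]]])
        geno[, dst[k]] <- transmitted + own
      }
    }
    kin <- data.frame(
      id1 = id[src], id2 = id[dst],
      kinship = rep(c(0.5, 0.25), c(n_dup, n_fd)),
      stringsAsFactors = FALSE
    )
  }

  dose_causal <- geno[causal, ]
  substream(config$seed, "liability")
  liability <- config$causal_ad_log_or * dose_causal +
    AGE_LIABILITY_COEF * (age - 85) + rlogis(n)

  substream(config$seed, "emission")
  braak <- findInterval(liability + rnorm(n, 0, EMISSION_NOISE_SD), BRAAK_THRESH)
  cerad <- findInterval(liability + rnorm(n, 0, EMISSION_NOISE_SD), CERAD_THRESH)

  substream(config$seed, "lewy")
  ad_score <- AD_STAGE_SCORE[findInterval(liability, AD_STAGE_CUTS) + 1L]
  lb_latent <- config$lb_ad_coupling * ad_score + rlogis(n)
  lb_cuts <- -qlogis(config$lb_base_rate) + LB_STAGE_OFFSETS
  lb_stage <- findInterval(lb_latent, lb_cuts)
  lewy <- c("none", "brainstem", "limbic", "neocortical")[lb_stage + 1L]

  dosages <- geno * 1.0
  substream(config$seed, "missing")
  if (config$genotype_missing_rate > 0) {
    dosages[runif(m * n) < config$genotype_missing_rate] <- NA_real_
  }
  dimnames(dosages) <- list(sprintf("var%04d", seq_len(m)), id)

  chrom <- rep(1:22, length.out = m)[order(rep(1:22, length.out = m))]
  pos <- integer(m)
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    pos[k] <- seq_len(length(k)) * 100000L + 1000000L
  }
  alleles <- c("A", "C", "G", "T")
  substream(config$seed, "freq")  # reuse stream; alleles are cosmetic
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  r2 <- runif(m, 0.75, 1.0)
  r2[causal] <- 0.99
  variants <- data.frame(
    id = rownames(dosages), chrom = as.character(chrom), pos = pos,
    ref = ref, alt = alt, r2 = r2, stringsAsFactors = FALSE, row.names = NULL
  )

  pathology <- data.frame(
    id = id, site = site, sex = sex, age_at_death = round(age, 1),
    braak = braak, cerad = cerad, lewy_dist = lewy,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pathology = pathology,
      genotypes = genotype_matrix(dosages, variants),
      kinship = kin,
      truth = list(liability = liability, lb_stage = lb_stage,
                   subpop = subpop,
                   planted_log_or = config$causal_ad_log_or,
                   causal_id = variants$id[causal])
    ),
    class = "copath_cohort"
  )
}

#' Compare schemes on the sole-LB contrast of one simulated cohort
#'
#' Generates a cohort with a planted effect on AD liability only, then, for
#' each scheme, classifies the cohort, prunes relatives, and fits the causal
#' variant for the AD-LB+ vs AD-LB- contrast (logistic regression with sex,
#' age-at-death and site as covariates, both sites pooled). Because stricter
#' schemes leave early-AD individuals inside the "sole LB" case group, the
#' recovered odds ratio is expected to exceed the one under the relaxed
#' scheme even though the allele has no effect on LB emergence.
#'
#' @param config a [simulation_config()] with `lb_ad_coupling > 0` and
#'   `causal_ad_log_or > 0`.
#' @param schemes non-empty list of schemes or built-in names.
#' @return data frame with one row per scheme: `scheme, or, ci_low, ci_high,
#'   p, n_cases, n_controls, firth_used`.
#' @export
misclassification_experiment <- function(config, schemes) {
  if (length(schemes) == 0L) {
    stop_copath("config", "schemes list must be non-empty")
  }
  cohort <- generate_cohort(config)
  dose <- cohort$genotypes$dosages[config$causal_ad_variant_index, ]
  out <- lapply(schemes, function(sc) {
    scheme <- if (is.character(sc)) builtin_scheme(sc) else sc
    ph <- classify_cohort(cohort$pathology, scheme)
    keep <- prune_relatives(ph, cohort$kinship,
                            setNames(ph$category, ph$id))
    ph <- ph[ph$id %in% keep, ]
    sel <- ph$category %in% c("AD-LB+", "AD-LB-")
    ph <- ph[sel, ]
    y <- as.integer(ph$category == "AD-LB+")
    d <- dose[ph$id]
    covar <- cbind(sex = as.integer(ph$sex == "F"),
                   age_at_death = ph$age_at_death,
                   site2 = as.integer(ph$site == "site2"))
    fit <- fit_logistic(y, d, covar)
    data.frame(scheme = scheme$name, or = fit$or_, ci_low = fit$ci95[1],
               ci_high = fit$ci95[2], p = fit$p, n_cases = fit$n_cases,
               n_controls = fit$n_controls, firth_used = fit$firth_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
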