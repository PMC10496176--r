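# Per-variant quality control: minor allele frequency, exact
# Hardy-Weinberg test, missingness, imputation quality.

#' Genotype dosage container
#'
#' A light container for a variants x individuals dosage matrix plus
#' per-variant metadata. Dosages are alt-allele doses in `[0, 2]`, possibly
#' missing; `variants` must carry `id, chrom, pos, ref, alt` and may carry
#' `r2` (imputation quality; `NA` means directly genotyped).
#'
#' @param dosages numeric matrix, variants in rows, individuals in columns;
#'   both dimensions named.
#' @param variants data frame of per-variant metadata, rows aligned with
#'   `dosages`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  if (!is.matrix(dosages) || is.null(rownames(dosages)) ||
      is.null(colnames(dosages))) {
    stop_copath("genotypes", "dosages must be a matrix with row and column names")
  }
  if (nrow(variants) != nrow(dosages) ||
      !all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    stop_copath("genotypes",
                "variants must align with dosage rows and carry id, chrom, pos, ref, alt")
  }
  if (!identical(as.character(variants$id), rownames(dosages))) {
    stop_copath("genotypes", "variant ids must match dosage rownames")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop_copath("genotypes", "dosages must lie in [0, 2]")
  }
  if (any(variants$ref == variants$alt)) {
    stop_copath("genotypes", "ref and alt alleles must differ")
  }
  if (is.null(variants$r2)) variants$r2 <- NA_real_
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d variants x %d individuals>\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Minor allele frequency from dosages
#'
#' `MAF = min(p, 1 - p)` with `p = sum(dosages) / (2 * n_nonmissing)`;
#' invariant to swapping ref/alt (dosage `d -> 2 - d`).
#'
#' @param dosages numeric vector of dosages in `[0, 2]`, `NA` allowed.
#' @return minor allele frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) {
    stop_copath("monomorphic", "all dosages missing; MAF undefined")
  }
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: given the allele counts, the
#' p-value is the total probability of heterozygote counts that are no more
#' probable than the observed one. Probabilities follow the standard
#' recurrence over heterozygote counts (the same conditional distribution
#' used by the common SNP-HWE implementations); computed in log space for
#' stability at large n.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_copath("hwe", "genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1L) stop_copath("hwe", "at least one genotype required")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  # All heterozygote counts compatible with the allele counts share the
  # parity of n_rare and cannot exceed min(n_rare, 2n - n_rare).
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  if (length(hets) == 1L) return(1.0)
  # log P(het = h | n, n_rare) up to a shared constant
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[hets == n_Aa]
  min(1.0, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# Best-guess genotype counts from dosages (rounded), for the HWE test on
# imputed data; mirrors how hard-call-based tools behave.
dosage_genotype_counts <- function(dosages) {
  g <- round(dosages[!is.na(dosages)])
  c(n_AA = sum(g == 0), n_Aa = sum(g == 1), n_aa = sum(g == 2))
}

#' Apply per-variant filters
#'
#' A variant is dropped iff `MAF < maf_min`, HWE exact `p < hwe_p_min`,
#' missing fraction `> miss_max`, or it is imputed with `R2 <= r2_min` (all
#' boundaries strict, matching "below 0.01", "above 20%", "R2 > 0.8").
#' Filters are evaluated on the supplied individual subset; the HWE test
#' runs on `hwe_ids` when given (e.g. controls only), otherwise on the
#' subset.
#'
#' @param genotypes a [genotype_matrix()].
#' @param individuals individual ids defining the evaluation subset;
#'   defaults to all.
#' @param maf_min,hwe_p_min,miss_max,r2_min thresholds.
#' @param hwe_ids optional ids (subset of `individuals`) the HWE test is
#'   restricted to.
#' @return list with `kept` (variant ids) and `dropped` (data frame
#'   `id, reason, value`; a variant failing several filters reports the
#'   first of maf/hwe/missingness/low_r2).
#' @export
apply_variant_filters <- function(genotypes, individuals = NULL,
                                  maf_min = 0.01, hwe_p_min = 1e-5,
                                  miss_max = 0.20, r2_min = 0.8,
                                  hwe_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  if (!is.null(individuals)) dos <- dos[, individuals, drop = FALSE]
  hwe_dos <- if (is.null(hwe_ids)) dos else
    genotypes$dosages[, hwe_ids, drop = FALSE]
  v <- genotypes$variants
  reason <- rep(NA_character_, nrow(v))
  value <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    di <- dos[i, ]
    miss <- mean(is.na(di))
    if (all(is.na(di))) {
      reason[i] <- "missingness"; value[i] <- 1; next
    }
    maf <- minor_allele_frequency(di)
    cnt <- dosage_genotype_counts(hwe_dos[i, ])
    hwe_p <- if (sum(cnt) >= 1) do.call(hwe_exact_test, as.list(cnt)) else 1.0
    r2 <- v$r2[i]
    if (maf < maf_min) {
      reason[i] <- "maf"; value[i] <- maf
    } else if (hwe_p < hwe_p_min) {
      reason[i] <- "hwe"; value[i] <- hwe_p
    } else if (miss > miss_max) {
      reason[i] <- "missingness"; value[i] <- miss
    } else if (!is.na(r2) && r2 <= r2_min) {
      reason[i] <- "low_r2"; value[i] <- r2
    }
  }
  drop <- !is.na(reason)
  list(
    kept = v$id[!drop],
    dropped = data.frame(id = v$id[drop], reason = reason[drop],
                         value = value[drop], stringsAsFactors = FALSE)
  )
}

#' Subset a genotype matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @param variant_ids,individual_ids ids to retain (NULL keeps all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(genotypes, variant_ids = NULL,
                             individual_ids = NULL) {
  dos <- genotypes$dosages
  v <- genotypes$variants
  if (!is.null(variant_ids)) {
    keep <- match(variant_ids, v$id)
    if (anyNA(keep)) stop_copath("genotypes", "unknown variant id in subset")
    dos <- dos[keep, , drop = FALSE]
    v <- v[keep, , drop = FALSE]
  }
  if (!is.null(individual_ids)) {
    if (!all(individual_ids %in% colnames(dos))) {
      stop_copath("genotypes", "unknown individual id in subset")
    }
    dos <- dos[, individual_ids, drop = FALSE]
  }
  rownames(v) <- NULL
  genotype_matrix(dos, v)
}
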