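# Fixed-effect inverse-variance-weighted meta-analysis across sites,
# significance flagging and Manhattan-plot data preparation.

#' Inverse-variance-weighted fixed-effect combination
#'
#' `w_i = 1/se_i^2`, `beta = sum(w b) / sum(w)`, `se = sum(w)^(-1/2)`,
#' two-sided normal p from `z = beta/se`.
#'
#' @param betas,ses numeric vectors of per-study effects and standard
#'   errors (alleles already harmonized).
#' @return list `beta_meta, se_meta, z, p_meta, n_studies, direction`
#'   (direction is a `"+-"`-style string, one character per study).
#' @export
ivw_meta <- function(betas, ses) {
  ok <- is.finite(betas) & is.finite(ses)
  betas <- betas[ok]; ses <- ses[ok]
  if (length(betas) == 0L) stop_copath("meta", "no studies with finite estimates")
  if (any(ses <= 0)) stop_copath("meta", "standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta_meta = beta, se_meta = se, z = z,
       p_meta = max(2 * pnorm(-abs(z)), 1e-320),
       n_studies = length(betas),
       direction = paste(ifelse(betas >= 0, "+", "-"), collapse = ""))
}

# Harmonize one study's rows to reference alleles: returns beta multiplied
# by +1 (match), -1 (swap) or NA (irreconcilable / strand-ambiguous flip).
harmonize_beta <- function(beta, ea, oa, ref_ea, ref_oa) {
  flip <- function(a) chartr("ACGT", "TGCA", a)
  ambiguous <- ea == flip(oa)   # A/T or C/G pairs
  out <- rep(NA_real_, length(beta))
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  out[same] <- beta[same]
  out[swap] <- -beta[swap]
  strand_same <- !ambiguous & flip(ea) == ref_ea & flip(oa) == ref_oa
  strand_swap <- !ambiguous & flip(ea) == ref_oa & flip(oa) == ref_ea
  out[strand_same & is.na(out)] <- beta[strand_same & is.na(out)]
  out[strand_swap & is.na(out)] <- -beta[strand_swap & is.na(out)]
  out
}

#' Meta-analyze per-site association results
#'
#' Matches variants across sites on `chrom:pos`, harmonizes effect alleles
#' to the first site carrying the variant (swapped alleles flip the beta
#' sign; strand flips are resolved except for A/T and C/G ambiguous pairs,
#' which are dropped with a warning), and combines with [ivw_meta()].
#' Variants present in a single site are reported with `n_studies = 1`.
#'
#' @param site_results list of data frames from [run_site_gwas()].
#' @return data frame: `variant, chrom, pos, effect_allele, other_allele,
#'   eaf, beta, se, p, n_studies, direction, n_cases, n_controls`.
#' @export
meta_analyze <- function(site_results) {
  stopifnot(length(site_results) >= 1L)
  all_keys <- unique(unlist(lapply(site_results, function(d) paste(d$chrom, d$pos))))
  rows <- lapply(all_keys, function(key) {
    per <- lapply(site_results, function(d) d[paste(d$chrom, d$pos) == key, , drop = FALSE])
    per <- per[vapply(per, nrow, integer(1)) > 0L]
    ref <- per[[1]]
    betas <- ses <- numeric(0)
    ncase <- nctrl <- 0L
    eaf_num <- eaf_den <- 0
    for (d in per) {
      b <- harmonize_beta(d$beta, d$effect_allele, d$other_allele,
                          ref$effect_allele, ref$other_allele)
      if (is.na(b)) {
        warning(sprintf("dropping study with irreconcilable alleles at %s", key))
        next
      }
      betas <- c(betas, b); ses <- c(ses, d$se)
      ncase <- ncase + d$n_cases; nctrl <- nctrl + d$n_controls
      n2 <- 2 * (d$n_cases + d$n_controls)
      eaf_num <- eaf_num + (if (b == d$beta) d$eaf else 1 - d$eaf) * n2
      eaf_den <- eaf_den + n2
    }
    mr <- ivw_meta(betas, ses)
    data.frame(
      variant = ref$variant, chrom = ref$chrom, pos = ref$pos,
      effect_allele = ref$effect_allele, other_allele = ref$other_allele,
      eaf = eaf_num / eaf_den, beta = mr$beta_meta, se = mr$se_meta,
      p = mr$p_meta, n_studies = mr$n_studies, direction = mr$direction,
      n_cases = ncase, n_controls = nctrl, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(as.integer(out$chrom), out$pos), , drop = FALSE]
}

#' Flag significance levels
#'
#' Adds strict-inequality flags `genome_wide` (`p < gw_threshold`) and
#' `nominal` (`p < nominal`).
#'
#' @param results data frame with a `p` column.
#' @param gw_threshold genome-wide threshold (default `5e-8`).
#' @param nominal nominal threshold (default `0.05`).
#' @return `results` with logical columns `genome_wide` and `nominal`.
#' @export
flag_significance <- function(results, gw_threshold = 5e-8, nominal = 0.05) {
  results$genome_wide <- results$p < gw_threshold
  results$nominal <- results$p < nominal
  results
}

#' Manhattan-plot data preparation
#'
#' Cumulative genome coordinates (chromosomes 1..22 laid end to end),
#' `-log10(p)` (p floored at 1e-320) and chromosome parity for alternating
#' colors. Rendering itself is left to the caller.
#'
#' @param results data frame with `chrom, pos, p`.
#' @return data frame `variant (if present), chrom, pos, cum_pos,
#'   neg_log10_p, chrom_parity`.
#' @export
manhattan_data <- function(results) {
  chrom <- as.integer(results$chrom)
  ord <- order(chrom, results$pos)
  r <- results[ord, , drop = FALSE]
  chrom <- chrom[ord]
  offset <- 0
  cum <- numeric(nrow(r))
  for (ch in sort(unique(chrom))) {
    k <- which(chrom == ch)
    cum[k] <- offset + r$pos[k]
    offset <- offset + max(r$pos[k])
  }
  data.frame(
    variant = r$variant %||% NA_character_, chrom = chrom, pos = r$pos,
    cum_pos = cum, neg_log10_p = -log10(pmax(r$p, 1e-320)),
    chrom_parity = chrom %% 2L, stringsAsFactors = FALSE
  )
}
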