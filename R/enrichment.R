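# Known-risk-locus survey: direction concordance with literature effects,
# nominal-significance hits and an exact binomial enrichment test against
# the analytic chance level.

#' Match literature loci to meta-analysis results
#'
#' Matches on `chrom:pos` with allele reconciliation: when the literature
#' effect allele equals the pipeline's other allele, the pipeline beta is
#' flipped for comparison. Loci absent from the results are reported as
#' unmatched (never silently dropped); loci whose allele sets cannot be
#' reconciled are flagged `mismatch` and excluded from `n_tested`.
#'
#' @param loci data frame with `rsid, chrom, pos, effect_allele,
#'   other_allele, direction` (`"+"` or `"-"`), and optionally `source`,
#'   `label`.
#' @param results meta-analysis data frame (see [meta_analyze()]).
#' @return data frame with one row per locus: the locus columns plus
#'   `matched, mismatch, beta, se, p` (pipeline effect re-expressed on the
#'   literature effect allele).
#' @export
harmonize_and_match <- function(loci, results) {
  key_r <- paste(results$chrom, results$pos)
  out <- loci
  out$matched <- FALSE
  out$mismatch <- FALSE
  out$beta <- out$se <- out$p <- NA_real_
  for (i in seq_len(nrow(loci))) {
    j <- match(paste(loci$chrom[i], loci$pos[i]), key_r)
    if (is.na(j)) next
    b <- harmonize_beta(results$beta[j], results$effect_allele[j],
                        results$other_allele[j],
                        loci$effect_allele[i], loci$other_allele[i])
    if (is.na(b)) {
      out$mismatch[i] <- TRUE
      next
    }
    out$matched[i] <- TRUE
    out$beta[i] <- b
    out$se[i] <- results$se[j]
    out$p[i] <- results$p[j]
  }
  out
}

#' Is a matched locus a concordant nominal hit?
#'
#' TRUE iff the pipeline p-value is strictly below `alpha` and the sign of
#' the (harmonized) pipeline beta agrees with the literature direction.
#'
#' @param row one matched row from [harmonize_and_match()] (or a data frame
#'   of rows; vectorized).
#' @param alpha nominal significance level.
#' @return logical vector.
#' @export
concordant_hit <- function(row, alpha = 0.05) {
  lit_sign <- ifelse(as.character(row$direction) == "+", 1, -1)
  row$matched & !is.na(row$p) & row$p < alpha &
    sign(row$beta) == lit_sign
}

#' Enrichment of concordant nominal hits over chance
#'
#' The chance level is `alpha / 2`: nominal two-sided significance times a
#' coin-flip direction agreement. The enrichment p-value is the exact
#' binomial upper-tail probability of at least `n_hits` successes in
#' `n_tested` trials at the chance level.
#'
#' @param matched data frame from [harmonize_and_match()].
#' @param alpha nominal significance level.
#' @param contrast optional contrast label carried into the summary.
#' @return data frame: `contrast, n_tested, n_hits, fraction_pct,
#'   chance_level_pct, binomial_p`.
#' @export
enrichment_summary <- function(matched, alpha = 0.05, contrast = NA_character_) {
  tested <- matched[matched$matched & !matched$mismatch, , drop = FALSE]
  n_tested <- nrow(tested)
  if (n_tested == 0L) stop_copath("enrichment", "no testable loci after matching")
  hits <- concordant_hit(tested, alpha = alpha)
  n_hits <- sum(hits)
  chance <- alpha / 2
  data.frame(
    contrast = contrast, n_tested = n_tested, n_hits = n_hits,
    fraction_pct = 100 * n_hits / n_tested,
    chance_level_pct = 100 * chance,
    binomial_p = pbinom(n_hits - 1L, n_tested, chance, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}
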