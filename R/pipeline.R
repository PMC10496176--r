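# End-to-end orchestration: exclude -> classify -> prune -> per-site
# (variant QC, PCs, association per contrast) -> meta -> enrichment, with a
# JSON run manifest recording counts at every stage.

#' Pipeline configuration
#'
#' @param phenotypes path to the phenotype TSV ([read_phenotypes()]).
#' @param genotypes path to a dosage TSV or VCF (`.vcf` suffix).
#' @param kinship optional path to a kinship TSV; `NULL` skips pruning.
#' @param loci optional path to a literature-locus TSV; `NULL` skips the
#'   enrichment survey.
#' @param scheme built-in scheme name or path to a scheme JSON file.
#' @param contrasts contrast names to run (see [contrast_spec()]).
#' @param out_dir output directory (created if needed).
#' @param maf_min,hwe_p_min,miss_max,r2_min variant QC thresholds.
#' @param gw_threshold,nominal_alpha significance thresholds.
#' @param dup_threshold,first_degree_threshold kinship cutoffs.
#' @param n_pcs number of principal-component covariates.
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(phenotypes, genotypes, kinship = NULL,
                            loci = NULL, scheme = "current",
                            contrasts = c("ADLB_vs_ctrl", "AD_vs_ctrl",
                                          "LB_vs_ctrl", "ADLB_vs_AD"),
                            out_dir = "copath_out",
                            maf_min = 0.01, hwe_p_min = 1e-5,
                            miss_max = 0.20, r2_min = 0.8,
                            gw_threshold = 5e-8, nominal_alpha = 0.05,
                            dup_threshold = 0.354,
                            first_degree_threshold = 0.177,
                            n_pcs = 10, seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("phenotypes", "genotypes")) {
    if (!file.exists(cfg[[p]])) {
      stop_copath("config", sprintf("%s path does not exist: %s", p, cfg[[p]]))
    }
  }
  for (p in c("kinship", "loci")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop_copath("config", sprintf("%s path does not exist: %s", p, cfg[[p]]))
    }
  }
  vapply(contrasts, function(x) contrast_spec(x)$name, character(1))
  structure(cfg, class = "pipeline_config")
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "copath_scheme")) return(scheme)
  if (file.exists(scheme)) read_scheme(scheme) else builtin_scheme(scheme)
}

#' Run the full pipeline
#'
#' Executes exclusion, classification, kinship pruning, per-site variant QC
#' and association for every requested contrast, inverse-variance
#' meta-analysis, Manhattan-plot data preparation and (if loci are given)
#' the known-locus enrichment survey. Per-stage TSVs, the category-count
#' table, and a JSON manifest with counts at every stage are written to
#' `config$out_dir`. A contrast that is infeasible at one site (no cases or
#' no controls there) continues on the remaining site(s) and is recorded in
#' the manifest; a contrast infeasible everywhere is skipped with a record.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  scheme <- resolve_scheme(config$scheme)

  pheno <- read_phenotypes(config$phenotypes)
  genotypes <- if (grepl("\\.vcf$", config$genotypes)) {
    read_vcf_dosages(config$genotypes)
  } else {
    read_dosage_matrix(config$genotypes)
  }
  n_input <- nrow(pheno)

  # Stage 1: cohort-level exclusions.
  excl <- exclude_ineligible(pheno)
  write.table(excl$excluded, out("excluded.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # Stage 2: classification.
  ph <- classify_cohort(excl$kept, scheme)
  counts <- tabulate_categories(ph)
  write.table(data.frame(category = names(counts), n = as.integer(counts)),
              out("category_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # Only the four analysis categories move forward; unclassified and
  # excluded individuals are counted and set aside.
  ph <- ph[!ph$category %in% c("unclassified", "excluded"), , drop = FALSE]

  # Stage 3: kinship pruning (optional).
  pruned_n <- 0L
  if (!is.null(config$kinship)) {
    kin <- read_kinship(config$kinship)
    kin <- kin[kin$id1 %in% ph$id & kin$id2 %in% ph$id, , drop = FALSE]
    keep_ids <- prune_relatives(ph, kin, setNames(ph$category, ph$id),
                                dup_threshold = config$dup_threshold,
                                first_degree_threshold = config$first_degree_threshold)
    pruned_n <- nrow(ph) - length(keep_ids)
    ph <- ph[ph$id %in% keep_ids, ]
  } else {
    message("no kinship table supplied; relative pruning skipped")
  }

  sites <- unique(ph$site)
  manifest_contrasts <- list()
  meta_results <- list()
  for (ct in config$contrasts) {
    site_res <- list()
    infeasible <- character(0)
    for (s in sites) {
      ph_s <- ph[ph$site == s, ]
      res <- tryCatch(
        run_site_gwas(ph_s, genotypes, ct, scheme, n_pcs = config$n_pcs,
                      maf_min = config$maf_min, hwe_p_min = config$hwe_p_min,
                      miss_max = config$miss_max, r2_min = config$r2_min),
        copath_contrast_infeasible = function(e) NULL
      )
      if (is.null(res)) {
        infeasible <- c(infeasible, s)
        next
      }
      write_summary_stats(res, out(sprintf("site_%s_%s.tsv", s, ct)))
      write.table(attr(res, "dropped"),
                  out(sprintf("variant_qc_%s_%s.tsv", s, ct)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      site_res[[s]] <- res
    }
    entry <- list(contrast = ct, n_sites = length(site_res),
                  infeasible_sites = infeasible)
    if (length(site_res) > 0L) {
      meta <- flag_significance(meta_analyze(site_res),
                                gw_threshold = config$gw_threshold,
                                nominal = config$nominal_alpha)
      write_summary_stats(meta, out(sprintf("meta_%s.tsv", ct)))
      write.table(manhattan_data(meta), out(sprintf("manhattan_%s.tsv", ct)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      meta_results[[ct]] <- meta
      entry$n_variants <- nrow(meta)
      entry$n_genome_wide <- sum(meta$genome_wide)
    } else {
      message(sprintf("contrast %s infeasible at every site; skipped", ct))
    }
    manifest_contrasts[[ct]] <- entry
  }

  enrich <- NULL
  if (!is.null(config$loci) && length(meta_results) > 0L) {
    loci <- read_loci(config$loci)
    enrich <- do.call(rbind, lapply(names(meta_results), function(ct) {
      matched <- harmonize_and_match(loci, meta_results[[ct]])
      if (!any(matched$matched)) return(NULL)
      enrichment_summary(matched, alpha = config$nominal_alpha, contrast = ct)
    }))
    if (!is.null(enrich)) {
      write.table(enrich, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }

  # Bookkeeping invariant: input = ineligible + scheme-excluded +
  # unclassified + pruned + analyzed.
  analyzed <- nrow(ph)
  manifest <- list(
    package_version = as.character(utils::packageVersion("copath")),
    seed = config$seed,
    scheme = scheme$name,
    thresholds = config[c("maf_min", "hwe_p_min", "miss_max", "r2_min",
                          "gw_threshold", "nominal_alpha", "dup_threshold",
                          "first_degree_threshold", "n_pcs")],
    counts = list(
      input = n_input,
      excluded_ineligible = nrow(excl$excluded),
      classified = as.list(setNames(as.integer(counts), names(counts))),
      pruned_relatives = pruned_n,
      analyzed = analyzed
    ),
    contrasts = manifest_contrasts,
    pruning_skipped = is.null(config$kinship)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
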