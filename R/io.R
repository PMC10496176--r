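# Readers and writers for the plain-text formats the pipeline touches.
# Every writer round-trips through its reader.

#' Read / write a pathology phenotype table
#'
#' TSV with columns `id, site, sex, age_at_death, braak, cerad, lewy_dist`.
#' Braak accepts integers or Roman numerals, CERAD words or 0-3 codes, and
#' the Lewy-body column words or NACC-style 0-4 codes (4 = olfactory bulb /
#' unspecified region). Unparseable staging values are collected into a
#' `parse_errors` attribute (data frame `id, field, value`) and left `NA`,
#' never silently coerced.
#'
#' @param path TSV path.
#' @return data frame of typed records with attribute `parse_errors`.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  need <- c("id", "site", "sex", "age_at_death", "braak", "cerad", "lewy_dist")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_copath("schema", paste("phenotype TSV missing column(s):",
                                paste(miss, collapse = ", ")))
  }
  errs <- list()
  note <- function(field, raw, parsed) {
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad)) {
      errs[[field]] <<- data.frame(id = df$id[bad], field = field,
                                   value = raw[bad], stringsAsFactors = FALSE)
    }
    parsed
  }
  out <- data.frame(
    id = df$id, site = df$site, sex = df$sex,
    age_at_death = suppressWarnings(as.numeric(df$age_at_death)),
    braak = note("braak", df$braak, parse_braak(df$braak)),
    cerad = note("cerad", df$cerad, parse_cerad(df$cerad)),
    lewy_dist = note("lewy_dist", df$lewy_dist, parse_lewy(df$lewy_dist)),
    stringsAsFactors = FALSE
  )
  attr(out, "parse_errors") <-
    if (length(errs)) do.call(rbind, c(errs, make.row.names = FALSE))
    else data.frame(id = character(0), field = character(0),
                    value = character(0), stringsAsFactors = FALSE)
  out
}

#' @rdname read_phenotypes
#' @param records pathology data frame.
#' @export
write_phenotypes <- function(records, path) {
  cols <- c("id", "site", "sex", "age_at_death", "braak", "cerad", "lewy_dist")
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a kinship table
#'
#' TSV with columns `id1, id2, kinship` (pairwise kinship coefficients).
#'
#' @param path TSV path.
#' @export
read_kinship <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id1", "id2", "kinship")
  if (!all(need %in% names(df))) {
    stop_copath("schema", "kinship TSV must have columns id1, id2, kinship")
  }
  df$kinship <- as.numeric(df$kinship)
  if (any(df$kinship < 0 | df$kinship > 0.5, na.rm = TRUE)) {
    stop_copath("kinship", "kinship coefficients must lie in [0, 0.5]")
  }
  df[, need]
}

#' @rdname read_kinship
#' @param kinship kinship data frame.
#' @export
write_kinship <- function(kinship, path) {
  write.table(kinship, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dosage matrix TSV
#'
#' Wide TSV: metadata columns `id, chrom, pos, ref, alt, r2` followed by one
#' numeric dosage column per individual. `r2 = NA` marks a directly
#' genotyped variant.
#'
#' @param path TSV path.
#' @return a [genotype_matrix()].
#' @export
read_dosage_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "r2")
  if (!all(meta_cols %in% names(df))) {
    stop_copath("schema", paste("dosage TSV missing column(s):",
                                paste(setdiff(meta_cols, names(df)), collapse = ", ")))
  }
  ind <- setdiff(names(df), meta_cols)
  dos <- as.matrix(df[, ind, drop = FALSE])
  mode(dos) <- "numeric"
  rownames(dos) <- df$id
  v <- df[, meta_cols]
  v$chrom <- as.character(v$chrom)
  genotype_matrix(dos, v)
}

#' @rdname read_dosage_matrix
#' @param genotypes a [genotype_matrix()].
#' @export
write_dosage_matrix <- function(genotypes, path) {
  df <- cbind(genotypes$variants[, c("id", "chrom", "pos", "ref", "alt", "r2")],
              as.data.frame(genotypes$dosages, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genotypes as VCF
#'
#' Minimal VCFv4.2 support for the fields this pipeline uses: bi-allelic
#' sites with `INFO/R2` (imputation quality; absent for genotyped sites)
#' and per-sample `GT:DS`. The writer derives GT from rounded dosages; the
#' reader uses DS and falls back to GT when DS is absent.
#'
#' @param path VCF path (uncompressed).
#' @return `read_vcf_dosages` returns a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop_copath("schema", "not a VCF: no #CHROM header line")
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  m <- length(rows)
  dos <- matrix(NA_real_, m, length(samples))
  v <- data.frame(id = character(m), chrom = character(m), pos = integer(m),
                  ref = character(m), alt = character(m), r2 = NA_real_,
                  stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    f <- rows[[i]]
    if (grepl(",", f[5], fixed = TRUE)) {
      stop_copath("schema", sprintf("multi-allelic site at %s:%s; split first",
                                    f[1], f[2]))
    }
    v$chrom[i] <- sub("^chr", "", f[1])
    v$pos[i] <- as.integer(f[2])
    v$id[i] <- f[3]
    v$ref[i] <- f[4]
    v$alt[i] <- f[5]
    r2m <- regmatches(f[8], regexpr("(?:^|;)R2=([0-9.eE+-]+)", f[8]))
    if (length(r2m)) v$r2[i] <- as.numeric(sub(".*R2=", "", r2m))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_k <- match("DS", fmt)
    gt_k <- match("GT", fmt)
    parts <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    dos[i, ] <- vapply(parts, function(p) {
      if (!is.na(ds_k) && length(p) >= ds_k && p[ds_k] != ".") {
        as.numeric(p[ds_k])
      } else if (!is.na(gt_k) && length(p) >= gt_k) {
        gt <- p[gt_k]
        if (grepl("\\.", gt)) NA_real_
        else sum(as.integer(strsplit(gt, "[/|]")[[1]]))
      } else NA_real_
    }, numeric(1))
  }
  dimnames(dos) <- list(v$id, samples)
  genotype_matrix(dos, v)
}

#' @rdname read_vcf_dosages
#' @param genotypes a [genotype_matrix()].
#' @export
write_vcf_dosages <- function(genotypes, path) {
  v <- genotypes$variants
  dos <- genotypes$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t")
  ), con)
  gt_of <- function(d) {
    ifelse(is.na(d), "./.",
           c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1])
  }
  for (i in seq_len(nrow(v))) {
    d <- dos[i, ]
    sample_f <- paste(gt_of(d),
                      ifelse(is.na(d), ".", format(d, trim = TRUE)),
                      sep = ":")
    info <- if (is.na(v$r2[i])) "." else sprintf("R2=%g", v$r2[i])
    writeLines(paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i],
                       ".", "PASS", info, "GT:DS", sample_f),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a literature risk-locus table
#'
#' TSV with columns `rsid, chrom, pos, effect_allele, other_allele,
#' direction` (`+`/`-`, relative to the effect allele) and optionally
#' `source` (`AD_gwas`/`PD_gwas`) and `label` (gene name).
#'
#' @param path TSV path.
#' @export
read_loci <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "effect_allele", "other_allele", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_copath("schema", paste("locus TSV missing column(s):",
                                paste(miss, collapse = ", ")))
  }
  if (!all(df$direction %in% c("+", "-"))) {
    stop_copath("schema", "locus direction must be '+' or '-'")
  }
  df$chrom <- as.character(df$chrom)
  df
}

#' Write summary statistics
#'
#' GWAS-Catalog-style headers: `variant_id, chromosome, base_pair_location,
#' effect_allele, other_allele, effect_allele_frequency, beta,
#' standard_error, p_value` plus the per-site counts.
#'
#' @param results data frame from [meta_analyze()] or [run_site_gwas()].
#' @param path output TSV path.
#' @export
write_summary_stats <- function(results, path) {
  out <- data.frame(
    variant_id = results$variant,
    chromosome = results$chrom,
    base_pair_location = results$pos,
    effect_allele = results$effect_allele,
    other_allele = results$other_allele,
    effect_allele_frequency = results$eaf,
    beta = results$beta,
    standard_error = results$se,
    p_value = results$p,
    stringsAsFactors = FALSE
  )
  for (extra in c("n_cases", "n_controls", "n_studies", "direction")) {
    if (!is.null(results[[extra]])) out[[extra]] <- results[[extra]]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
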