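# Classification schemes are data, not code: a scheme is a named pair of
# exhaustive lookup tables (5 Lewy-body cells, 7 x 4 x 2 AD cells) validated
# for totality at construction, so users can override individual cells and
# still get a checked object.

AD_LABELS <- c("AD+", "AD-", "unclassified")
LB_LABELS <- c("LB+", "LB-", "excluded")
LB_STRATA <- c("LB-", "LB+")

#' Construct a pathology classification scheme
#'
#' @param name scheme name.
#' @param lb_rule named character vector over all five Lewy-body distribution
#'   values ([LEWY_LEVELS]), each mapped to `"LB+"`, `"LB-"` or `"excluded"`.
#' @param ad_rule character array of dimension `c(7, 4, 2)` (Braak 0..VI x
#'   CERAD absent..frequent x LB stratum `"LB-"`, `"LB+"`), each cell one of
#'   `"AD+"`, `"AD-"`, `"unclassified"`.
#' @return an object of class `copath_scheme`.
#' @seealso [builtin_scheme()] for the shipped schemes.
#' @export
new_scheme <- function(name, lb_rule, ad_rule) {
  scheme <- structure(
    list(name = name, lb_rule = lb_rule, ad_rule = ad_rule),
    class = "copath_scheme"
  )
  validate_scheme(scheme)
  scheme
}

#' Validate a classification scheme for totality
#'
#' Checks that the Lewy-body rule covers all five distribution values and the
#' AD rule covers all 56 (Braak, CERAD, LB-stratum) cells with recognized
#' labels. Called automatically by [new_scheme()] and [read_scheme()].
#'
#' @param scheme a `copath_scheme`.
#' @return the scheme, invisibly; errors if any cell is missing or invalid.
#' @export
validate_scheme <- function(scheme) {
  if (!is.character(scheme$name) || length(scheme$name) != 1L) {
    stop_copath("scheme", "scheme name must be a single string")
  }
  lb <- scheme$lb_rule
  if (!setequal(names(lb), LEWY_LEVELS) || length(lb) != 5L) {
    stop_copath("scheme", sprintf(
      "lb_rule must cover exactly the Lewy distributions: %s",
      paste(LEWY_LEVELS, collapse = ", ")
    ))
  }
  if (!all(lb %in% LB_LABELS)) {
    stop_copath("scheme", "lb_rule values must be LB+, LB- or excluded")
  }
  ad <- scheme$ad_rule
  if (!is.array(ad) || !identical(dim(ad), c(7L, 4L, 2L))) {
    stop_copath("scheme", "ad_rule must be a 7 x 4 x 2 array")
  }
  if (anyNA(ad) || !all(ad %in% AD_LABELS)) {
    bad <- which(is.na(ad) | !(ad %in% AD_LABELS), arr.ind = TRUE)
    stop_copath("scheme", sprintf(
      "ad_rule has %d invalid/missing cell(s), first at Braak %s, CERAD %s, %s",
      nrow(bad), BRAAK_ROMAN[bad[1, 1]], CERAD_LEVELS[bad[1, 2]],
      LB_STRATA[bad[1, 3]]
    ))
  }
  invisible(scheme)
}

empty_ad_rule <- function() {
  array(NA_character_, dim = c(7L, 4L, 2L),
        dimnames = list(braak = BRAAK_ROMAN, cerad = CERAD_LEVELS,
                        lb = LB_STRATA))
}

# Braak value b (0..6) lives at index b + 1; CERAD value c (0..3) at c + 1.
# "Braak >= IV" is therefore rows 5:7, "CERAD >= moderate" columns 3:4.

build_current_scheme <- function() {
  ad <- empty_ad_rule()
  # LB- stratum: AD+ only for established pathology; three gray zones.
  ad[, , "LB-"] <- "AD-"
  ad[5:7, 3:4, "LB-"] <- "AD+"            # Braak >= IV & CERAD >= moderate
  ad[6:7, 1:2, "LB-"] <- "unclassified"   # Braak V/VI & CERAD absent/sparse
  ad[4, 4, "LB-"] <- "unclassified"       # Braak III & CERAD frequent
  # LB+ stratum: threshold lowered to Braak III + sparse; one gray zone.
  ad[, , "LB+"] <- "AD-"
  ad[4:7, 2:4, "LB+"] <- "AD+"            # Braak >= III & CERAD >= sparse
  ad[6:7, 1, "LB+"] <- "unclassified"     # Braak V/VI & CERAD absent
  new_scheme(
    "current",
    c(none = "LB-", brainstem = "LB-", limbic = "LB+", neocortical = "LB+",
      olfactory_or_unspecified = "excluded"),
    ad
  )
}

build_tsuang_scheme <- function() {
  ad <- empty_ad_rule()
  # Single stringent AD threshold for both strata, everything else AD-;
  # brainstem-limited Lewy bodies are excluded rather than counted as LB-.
  ad[, , ] <- "AD-"
  ad[5:7, 3:4, ] <- "AD+"
  new_scheme(
    "tsuang",
    c(none = "LB-", brainstem = "excluded", limbic = "LB+",
      neocortical = "LB+", olfactory_or_unspecified = "excluded"),
    ad
  )
}

build_kaivola_scheme <- function() {
  ad <- empty_ad_rule()
  # Less stringent AD threshold (Braak >= III & CERAD >= sparse) in both
  # strata; brainstem-limited Lewy bodies count as LB-; no gray zones.
  ad[, , ] <- "AD-"
  ad[4:7, 2:4, ] <- "AD+"
  new_scheme(
    "kaivola",
    c(none = "LB-", brainstem = "LB-", limbic = "LB+", neocortical = "LB+",
      olfactory_or_unspecified = "excluded"),
    ad
  )
}

#' Built-in classification schemes
#'
#' Returns one of the three shipped decision-table schemes:
#'
#' * `current`: Lewy bodies in the limbic system or cortex define LB+, none
#'   or brainstem-limited define LB-. AD+ requires Braak IV+ and CERAD
#'   moderate/frequent, relaxed to Braak III+ with at least sparse CERAD in
#'   LB+ individuals. Three gray zones are left unclassified (Braak V/VI with
#'   absent CERAD in either stratum; Braak V/VI with sparse CERAD in LB-;
#'   Braak III with frequent CERAD in LB-).
#' * `tsuang`: same stringent AD+ threshold in both strata (Braak IV+ and
#'   CERAD moderate/frequent, everything else AD-) and brainstem-limited
#'   Lewy bodies excluded from both LB strata.
#' * `kaivola`: the permissive AD+ threshold (Braak III+ and at least sparse
#'   CERAD) in both strata, LB- includes brainstem-limited Lewy bodies, and
#'   no gray zones.
#'
#' All three exclude individuals with Lewy bodies confined to the olfactory
#' bulb or an unspecified region.
#'
#' @param name one of `"current"`, `"tsuang"`, `"kaivola"`.
#' @return a `copath_scheme`.
#' @export
builtin_scheme <- function(name) {
  builders <- list(current = build_current_scheme,
                   tsuang = build_tsuang_scheme,
                   kaivola = build_kaivola_scheme)
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(builders)))) {
    stop_copath("scheme", sprintf(
      "unknown scheme '%s'; built-ins are: %s",
      as.character(name)[1], paste(names(builders), collapse = ", ")
    ))
  }
  builders[[name]]()
}

#' Classify staging triples into pathology categories
#'
#' Applies a scheme's Lewy-body rule, then its AD rule, to vectors of staging
#' values. Individuals whose Lewy-body distribution the scheme excludes
#' (always the olfactory/unspecified group) are `excluded` regardless of
#' Braak/CERAD; gray-zone cells are `unclassified`.
#'
#' @param braak Braak stages; anything [parse_braak()] accepts.
#' @param cerad CERAD scores; anything [parse_cerad()] accepts.
#' @param lewy Lewy-body distributions; anything [parse_lewy()] accepts.
#' @param scheme a `copath_scheme` or a built-in scheme name.
#' @param id optional ids used in error messages.
#' @return factor with levels [PATHOLOGY_CATEGORIES].
#' @examples
#' classify("V", "frequent", "neocortical", "current")   # AD+LB+
#' classify(3, "sparse", "limbic", "current")            # AD+LB+
#' classify("V", "absent", "none", "current")            # unclassified
#' @export
classify <- function(braak, cerad, lewy, scheme, id = NULL) {
  if (is.character(scheme)) scheme <- builtin_scheme(scheme)
  validate_scheme(scheme)
  b <- parse_braak(braak)
  ce <- parse_cerad(cerad)
  lw <- parse_lewy(lewy)
  n <- max(length(b), length(ce), length(lw))
  b <- rep_len(b, n); ce <- rep_len(ce, n); lw <- rep_len(lw, n)
  id <- if (is.null(id)) as.character(seq_len(n)) else rep_len(as.character(id), n)
  for (fld in c("braak", "cerad", "lewy")) {
    v <- switch(fld, braak = b, cerad = ce, lewy = lw)
    if (anyNA(v)) {
      stop_copath("missing_staging", sprintf(
        "missing or unparseable %s for record(s): %s",
        fld, paste(head(id[is.na(v)], 5L), collapse = ", ")
      ))
    }
  }
  lb <- unname(scheme$lb_rule[lw])
  out <- rep(NA_character_, n)
  out[lb == "excluded"] <- "excluded"
  ok <- lb != "excluded"
  if (any(ok)) {
    ad <- scheme$ad_rule[cbind(b[ok] + 1L, ce[ok] + 1L, match(lb[ok], LB_STRATA))]
    out[ok] <- ifelse(ad == "unclassified", "unclassified",
                      paste0(ad, ifelse(lb[ok] == "LB+", "LB+", "LB-")))
  }
  factor(out, levels = PATHOLOGY_CATEGORIES)
}

#' Classify a pathology table
#'
#' Convenience wrapper around [classify()] for a phenotype data frame with
#' columns `braak`, `cerad`, `lewy_dist` and (optionally) `id`; appends a
#' `category` column.
#'
#' @param records data frame of pathology records.
#' @param scheme a `copath_scheme` or built-in name.
#' @return `records` with a `category` factor column added.
#' @export
classify_cohort <- function(records, scheme) {
  need <- c("braak", "cerad", "lewy_dist")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_copath("schema", paste("missing pathology column(s):",
                                paste(miss, collapse = ", ")))
  }
  records$category <- classify(records$braak, records$cerad,
                               records$lewy_dist, scheme,
                               id = records$id %||% NULL)
  records
}

#' Tabulate pathology categories
#'
#' @param records data frame with a `category` column, or one classifiable by
#'   [classify_cohort()] when `scheme` is given.
#' @param scheme optional scheme used to classify first.
#' @return named integer vector over [PATHOLOGY_CATEGORIES]; sums to
#'   `nrow(records)`.
#' @export
tabulate_categories <- function(records, scheme = NULL) {
  if (!is.null(scheme)) records <- classify_cohort(records, scheme)
  if (is.null(records$category)) {
    stop_copath("schema", "records have no category column; supply a scheme")
  }
  table(factor(records$category, levels = PATHOLOGY_CATEGORIES))
}

#' Cross-tabulate category assignments under two schemes
#'
#' @param records pathology records (see [classify_cohort()]).
#' @param scheme_a,scheme_b schemes or built-in names.
#' @return a 6 x 6 contingency table (rows: `scheme_a` category, columns:
#'   `scheme_b` category) whose margins equal the per-scheme tabulations.
#' @export
scheme_concordance <- function(records, scheme_a, scheme_b) {
  a <- classify_cohort(records, scheme_a)$category
  b <- classify_cohort(records, scheme_b)$category
  table(a, b, dnn = c(
    if (is.character(scheme_a)) scheme_a else scheme_a$name,
    if (is.character(scheme_b)) scheme_b else scheme_b$name
  ))
}

#' Read / write scheme decision tables
#'
#' Schemes serialize to JSON: the name, the five Lewy-body cells, and all 56
#' AD cells keyed `braak|cerad|stratum`. Files are validated for totality on
#' read.
#'
#' @param path file path.
#' @param scheme a `copath_scheme`.
#' @return `read_scheme` returns a validated `copath_scheme`; `write_scheme`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ad <- empty_ad_rule()
  cells <- obj$ad_rule
  key <- strsplit(names(cells), "|", fixed = TRUE)
  for (i in seq_along(cells)) {
    k <- key[[i]]
    ad[k[1], k[2], k[3]] <- cells[[i]]
  }
  new_scheme(obj$name, unlist(obj$lb_rule), ad)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  idx <- expand.grid(braak = BRAAK_ROMAN, cerad = CERAD_LEVELS,
                     lb = LB_STRATA, stringsAsFactors = FALSE)
  cells <- scheme$ad_rule[as.matrix(idx)]
  names(cells) <- paste(idx$braak, idx$cerad, idx$lb, sep = "|")
  jsonlite::write_json(
    list(name = scheme$name, lb_rule = as.list(scheme$lb_rule),
         ad_rule = as.list(cells)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.copath_scheme <- function(x, ...) {
  cat(sprintf("<copath scheme '%s'>\n", x$name))
  cat("Lewy-body rule:\n")
  print(x$lb_rule)
  for (s in LB_STRATA) {
    cat(sprintf("AD rule (%s stratum):\n", s))
    print(x$ad_rule[, , s])
  }
  invisible(x)
}
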