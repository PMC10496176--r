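# Cohort-level exclusions and kinship-based pruning.

#' Exclude ineligible individuals
#'
#' Drops individuals with Lewy bodies confined to the olfactory bulb or an
#' unspecified region (NACC code 4) and individuals missing sex or
#' age-at-death, each with a machine-readable reason code.
#'
#' @param records pathology data frame with columns `id, sex, age_at_death,
#'   lewy_dist`.
#' @return list with `kept` (data frame) and `excluded` (data frame
#'   `id, reason`, reasons in `NACCLEWY4`, `missing_sex`, `missing_aad`).
#' @export
exclude_ineligible <- function(records) {
  lewy <- parse_lewy(records$lewy_dist)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$age_at_death)] <- "missing_aad"
  reason[is.na(records$sex) | records$sex == ""] <- "missing_sex"
  reason[!is.na(lewy) & lewy == "olfactory_or_unspecified"] <- "NACCLEWY4"
  drop <- !is.na(reason)
  list(
    kept = records[!drop, , drop = FALSE],
    excluded = data.frame(id = records$id[drop], reason = reason[drop],
                          stringsAsFactors = FALSE)
  )
}

# Minimal union-find (no path compression; kinship graphs are tiny).
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Prune duplicates and relatives
#'
#' Builds a graph over pairs at or above `first_degree_threshold` and keeps
#' exactly one individual per connected component: among pathology cases
#' (any of AD+LB+, AD+LB-, AD-LB+) the one with the youngest age-at-death;
#' in components with no cases, the control (AD-LB-) with the oldest
#' age-at-death, falling back to the oldest member; ties broken by
#' lexicographic id. The keep-rule mirrors preferential retention of the
#' younger-deceased relative among cases and the oldest control otherwise.
#'
#' @param records pathology data frame with `id` and `age_at_death`.
#' @param kinship data frame `id1, id2, kinship`.
#' @param category named vector/factor of pathology categories per id
#'   (names = ids). Unclassified/excluded members are treated like
#'   non-controls without case priority.
#' @param dup_threshold,first_degree_threshold kinship cutoffs; defaults are
#'   the usual KING conventions (0.354 duplicate, 0.177 first degree).
#' @return character vector of retained ids (input order preserved).
#' @export
prune_relatives <- function(records, kinship, category,
                            dup_threshold = 0.354,
                            first_degree_threshold = 0.177) {
  ids <- records$id
  if (is.null(kinship) || nrow(kinship) == 0L) return(ids)
  unknown <- setdiff(c(kinship$id1, kinship$id2), ids)
  if (length(unknown)) {
    stop_copath("kinship", sprintf(
      "kinship table references unknown id(s): %s",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  rel <- kinship[kinship$kinship >= first_degree_threshold, , drop = FALSE]
  if (nrow(rel) == 0L) return(ids)

  parent <- seq_along(ids)
  i1 <- match(rel$id1, ids)
  i2 <- match(rel$id2, ids)
  for (k in seq_along(i1)) {
    r1 <- uf_find(parent, i1[k])
    r2 <- uf_find(parent, i2[k])
    if (r1 != r2) parent[r2] <- r1
  }
  root <- vapply(seq_along(ids), function(i) uf_find(parent, i), integer(1))

  age <- records$age_at_death
  cat_ <- as.character(category[ids])
  is_case <- cat_ %in% c("AD+LB+", "AD+LB-", "AD-LB+")
  is_control <- cat_ %in% "AD-LB-"

  keep <- rep(TRUE, length(ids))
  for (r in unique(root[duplicated(root) | root != seq_along(ids)])) {
    comp <- which(root == r)
    if (length(comp) < 2L) next
    pick_from <- if (any(is_case[comp])) comp[is_case[comp]] else comp
    if (any(is_case[comp])) {
      # youngest age-at-death among cases
      ord <- order(age[pick_from], ids[pick_from])
    } else {
      if (any(is_control[comp])) pick_from <- comp[is_control[comp]]
      # oldest control (or oldest member if no control)
      ord <- order(-age[pick_from], ids[pick_from])
    }
    chosen <- pick_from[ord[1]]
    keep[comp] <- FALSE
    keep[chosen] <- TRUE
  }
  ids[keep]
}
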