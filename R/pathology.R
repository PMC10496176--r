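# Parsers for neuropathological staging values. All parsers are vectorized,
# return NA for unparseable input, and never error: callers that need strict
# behaviour (classification, the TSV reader) collect NAs into error reports.

#' Parse Braak neurofibrillary-tangle stages
#'
#' Accepts integers 0-6 (as numbers or strings) and Roman numerals 0, I-VI,
#' case-insensitively. Returns an integer vector in 0..6 with `NA` for
#' unparseable values.
#'
#' @param x vector of Braak stage codes.
#' @return integer vector, values in `0:6` or `NA`.
#' @examples
#' parse_braak(c("IV", "2", "vi", "VII"))
#' @export
parse_braak <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- match(x, BRAAK_ROMAN) - 1L
  num <- suppressWarnings(as.integer(x))
  use_num <- is.na(out) & !is.na(num) & num >= 0L & num <= 6L &
    x == as.character(num)
  out[use_num] <- num[use_num]
  out
}

#' Parse CERAD neuritic-plaque scores
#'
#' Accepts the words absent/sparse/moderate/frequent (any case, "none" is a
#' synonym for absent) and integer codes 0-3 in the same order. Returns an
#' integer vector in 0..3 (0 = absent .. 3 = frequent) with `NA` for
#' unparseable values.
#'
#' @param x vector of CERAD codes.
#' @return integer vector, values in `0:3` or `NA`.
#' @export
parse_cerad <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x == "none"] <- "absent"
  out <- match(x, CERAD_LEVELS) - 1L
  num <- suppressWarnings(as.integer(x))
  use_num <- is.na(out) & !is.na(num) & num >= 0L & num <= 3L &
    x == as.character(num)
  out[use_num] <- num[use_num]
  out
}

#' Parse Lewy-body distribution codes
#'
#' Accepts the words none/brainstem/limbic/neocortical/
#' olfactory_or_unspecified and NACC-style integer codes 0-4, where 4 denotes
#' Lewy bodies in the olfactory bulb or an unspecified region (the
#' NACCLEWY = 4 group that is excluded from analysis). "transitional" is
#' accepted as a synonym for limbic and "diffuse" for neocortical.
#'
#' @param x vector of Lewy-body distribution codes.
#' @return character vector with levels [LEWY_LEVELS] or `NA`.
#' @export
parse_lewy <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x == "transitional"] <- "limbic"
  x[x == "diffuse"] <- "neocortical"
  x[x == "olfactory"] <- "olfactory_or_unspecified"
  x[x == "unspecified"] <- "olfactory_or_unspecified"
  idx <- match(x, LEWY_LEVELS)
  num <- suppressWarnings(as.integer(x))
  use_num <- is.na(idx) & !is.na(num) & num >= 0L & num <= 4L &
    x == as.character(num)
  idx[use_num] <- num[use_num] + 1L
  LEWY_LEVELS[idx]
}
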