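test_that("staging parsers accept field encodings and reject junk", {
  expect_equal(parse_braak(c("IV", "2", "vi", "0")), c(4L, 2L, 6L, 0L))
  expect_true(is.na(parse_braak("VII")))
  expect_equal(parse_cerad(c("absent", "Sparse", "2", "frequent", "none")),
               c(0L, 1L, 2L, 3L, 0L))
  expect_true(is.na(parse_cerad("5")))
  expect_equal(parse_lewy(c("4", "brainstem", "transitional", "diffuse")),
               c("olfactory_or_unspecified", "brainstem", "limbic",
                 "neocortical"))
  expect_true(is.na(parse_lewy("cortical?")))
})

test_that("every built-in scheme is total over the 7 x 4 x 5 staging space", {
  grid <- expand.grid(braak = 0:6, cerad = 0:3, lewy = LEWY_LEVELS,
                      stringsAsFactors = FALSE)
  for (nm in c("current", "tsuang", "kaivola")) {
    cats <- classify(grid$braak, grid$cerad, grid$lewy, nm)
    expect_false(anyNA(cats), info = nm)
    expect_true(all(cats %in% PATHOLOGY_CATEGORIES), info = nm)
    # olfactory/unspecified always forces exclusion
    expect_true(all(cats[grid$lewy == "olfactory_or_unspecified"] == "excluded"),
                info = nm)
  }
})

test_that("the current scheme matches its textual rules cell by cell", {
  cells <- cell_records()
  got <- classify(cells$braak, cells$cerad, cells$lewy_dist, "current")
  want <- mapply(function(b, c, lb) {
    ad <- oracle_current_ad(b, c, lb)
    if (ad == "unclassified") "unclassified" else paste0(ad, lb)
  }, cells$braak, cells$cerad, cells$lb)
  expect_equal(as.character(got), unname(want))
  # enumerated gray zones: exactly these cells, no others
  grays <- cells[want == "unclassified", c("braak", "cerad", "lb")]
  expect_equal(sum(want == "unclassified"), 7L)
  expect_setequal(
    paste(grays$braak, grays$cerad, grays$lb),
    c("5 0 LB-", "6 0 LB-", "5 0 LB+", "6 0 LB+",
      "5 1 LB-", "6 1 LB-", "3 3 LB-")
  )
})

test_that("worked staging examples classify as published criteria dictate", {
  expect_equal(as.character(classify("V", "frequent", "neocortical", "current")),
               "AD+LB+")
  expect_equal(as.character(classify("III", "sparse", "limbic", "current")),
               "AD+LB+")
  expect_equal(as.character(classify("V", "absent", "none", "current")),
               "unclassified")
  expect_equal(as.character(classify(0, "absent", "none", "current")),
               "AD-LB-")
  expect_equal(as.character(classify("III", "frequent", "brainstem", "current")),
               "unclassified")
  expect_equal(as.character(classify("IV", "sparse", "none", "current")),
               "AD-LB-")
})

test_that("AD+ cells nest: current's LB+ rule strictly relaxes tsuang's", {
  cur <- builtin_scheme("current")$ad_rule[, , "LB+"]
  tsu <- builtin_scheme("tsuang")$ad_rule[, , "LB+"]
  expect_true(all(which(tsu == "AD+") %in% which(cur == "AD+")))
  expect_gt(sum(cur == "AD+"), sum(tsu == "AD+"))
})

test_that("AD+ is monotone in Braak and CERAD within each LB stratum", {
  sch <- builtin_scheme("current")
  for (lb in c("LB-", "LB+")) {
    tab <- sch$ad_rule[, , lb]
    for (b in 1:7) for (ce in 1:4) {
      if (tab[b, ce] != "AD+") next
      worse <- tab[b:7, ce:4]
      expect_true(all(worse %in% c("AD+", "unclassified")),
                  info = sprintf("%s braak %d cerad %d", lb, b - 1, ce - 1))
    }
  }
})

test_that("tabulate_categories counts every record exactly once", {
  tab <- tabulate_categories(quadrant_records(), "current")
  expect_equal(as.integer(tab[c("AD+LB+", "AD+LB-", "AD-LB+", "AD-LB-")]),
               rep(1L, 4))
  expect_equal(sum(tab), 4L)
  empty <- quadrant_records()[0, ]
  expect_equal(sum(tabulate_categories(empty, "current")), 0L)
  # LB+ stratum of the full enumeration: no AD- cell with CERAD >= sparse
  # and Braak >= III under the current criteria
  cells <- cell_records()
  lbp <- cells[cells$lb == "LB+" & cells$braak >= 3 & cells$cerad >= 1, ]
  cats <- classify(lbp$braak, lbp$cerad, lbp$lewy_dist, "current")
  expect_false(any(cats == "AD-LB+"))
})

test_that("scheme concordance cross-tabulates with consistent margins", {
  cells <- cell_records()
  xt <- scheme_concordance(cells, "current", "current")
  expect_true(all(xt[row(xt) != col(xt)] == 0))

  xt2 <- scheme_concordance(cells, "current", "tsuang")
  expect_equal(rowSums(xt2), unclass(tabulate_categories(cells, "current")),
               ignore_attr = TRUE)
  expect_equal(colSums(xt2), unclass(tabulate_categories(cells, "tsuang")),
               ignore_attr = TRUE)

  expect_equal(as.character(classify(3, 1, "limbic", "tsuang")), "AD-LB+")
  expect_equal(as.character(classify(2, 0, "brainstem", "tsuang")), "excluded")
  expect_equal(as.character(classify(2, 0, "brainstem", "current")), "AD-LB-")
  # kaivola applies the permissive threshold in the LB- stratum too
  expect_equal(as.character(classify(3, 1, "none", "kaivola")), "AD+LB-")
  expect_equal(as.character(classify(3, 1, "none", "current")), "AD-LB-")
})

test_that("schemes serialize, validate and reject malformed tables", {
  sch <- builtin_scheme("current")
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_equal(back$ad_rule, sch$ad_rule)
  expect_equal(back$lb_rule, sch$lb_rule)

  broken <- sch
  broken$ad_rule[3, 2, 1] <- NA_character_
  expect_error(validate_scheme(broken), class = "copath_scheme")
  broken2 <- sch
  broken2$lb_rule <- broken2$lb_rule[-1]
  expect_error(validate_scheme(broken2), class = "copath_scheme")
  expect_error(builtin_scheme("nacc"), "built-ins")
  expect_error(classify(NA, 1, "none", "current"), class = "copath_missing_staging")
})
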