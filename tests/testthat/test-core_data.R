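test_that("half-life tables are read, grouped and round-tripped", {
  df <- data.frame(
    compound_id = c("A", "A", "A", "B", "B", "C"),
    smiles = c("CCO", "OCC", "CCO", "C[C@H](O)CC", "CC(O)CC", "c1ccccc1O"),
    dt50_days = c("10", "100", "1000", "5", ">40", "<1"),
    censor = c("", "", "", "=", "", "<"),
    stringsAsFactors = FALSE)
  path <- write_obs_csv(df)
  recs <- read_halflife_table(path)

  expect_length(recs, 3)  # CCO/OCC merge; stereo variants of butanol merge
  a <- recs[[1]]
  expect_equal(nrow(a$observations), 3)
  expect_equal(a$observations$log_value, c(1, 2, 3))  # log10 of 10/100/1000
  b <- recs[[2]]
  expect_equal(b$smiles, standardize_structure("CC(O)CC"))
  expect_equal(b$observations$censor, c("exact", "right"))
  cc <- recs[[3]]
  expect_equal(cc$observations$censor, "left")
  expect_equal(cc$observations$log_value, 0)
  expect_equal(nrow(attr(recs, "rejects")), 0)

  # round trip preserves compound count, observation count, censor flags
  out <- tempfile(fileext = ".csv")
  write_halflife_table(recs, out)
  back <- read_halflife_table(out)
  expect_length(back, length(recs))
  expect_equal(
    lapply(back, function(r) r$observations[c("value_days", "censor")]),
    lapply(recs, function(r) r$observations[c("value_days", "censor")]))

  # grouping is order-independent
  shuf <- df[c(4, 6, 1, 5, 3, 2), ]
  recs2 <- read_halflife_table(write_obs_csv(shuf))
  key <- function(rs) {
    x <- lapply(rs, function(r) {
      o <- r$observations[order(r$observations$value_days), ]
      list(r$smiles, o$value_days, o$censor)
    })
    x[order(vapply(rs, `[[`, character(1), "smiles"))]
  }
  expect_equal(key(recs2), key(recs))
})

test_that("bad rows are rejected with reasons, bad files error", {
  df <- data.frame(compound_id = c("A", "B", "C"),
                   smiles = c("CCO", "not_a_smiles", "CC"),
                   dt50_days = c("10", "5", "-3"))
  recs <- read_halflife_table(write_obs_csv(df))
  expect_length(recs, 1)
  rej <- attr(recs, "rejects")
  expect_equal(nrow(rej), 2)
  expect_match(rej$reason[rej$smiles == "not_a_smiles"], "unparsable")

  # missing mandatory column is a configuration error
  bad <- write_obs_csv(data.frame(compound_id = "A", dt50_days = "1"))
  expect_error(read_halflife_table(bad), "mandatory column")

  # empty table warns and returns an empty list
  empty <- write_obs_csv(df[0, ])
  expect_warning(out <- read_halflife_table(empty), "empty")
  expect_length(out, 0)
})

test_that("standardization strips stereo, keeps isotopes, is idempotent", {
  expect_equal(standardize_structure("C[C@H](O)CC"),
               standardize_structure("CC(O)CC"))
  expect_equal(standardize_structure("c1ccccc1O"),
               standardize_structure("Oc1ccccc1"))
  once <- standardize_structure("C[C@@H](N)C(=O)O")
  expect_equal(standardize_structure(once), once)
  expect_false(grepl("@", once))
  # isotopomers stay distinct
  expect_false(standardize_structure("[13CH4]") == standardize_structure("C"))
  expect_error(standardize_structure("xyzzy("), "xyzzy")
})

test_that("applicability domain gate reports all violated rules", {
  ad <- check_applicability_domain(c("[Na+].[Cl-]", "CCO", "[Si]([O-])([O-])=O"))
  expect_false(ad$in_domain[1])
  expect_setequal(ad$reasons[[1]], c("multi_fragment", "inorganic"))
  expect_true(ad$in_domain[2])
  expect_length(ad$reasons[[2]], 0)
  expect_true("inorganic" %in% ad$reasons[[3]])

  # 90-carbon alkane, MW about 1264 Da
  alkane <- paste(rep("C", 90), collapse = "")
  expect_equal(check_applicability_domain(alkane)$reasons[[1]], "too_heavy")

  expect_equal(check_applicability_domain("][")$reasons[[1]], "parse_failure")

  # gate is pure: identical answers across calls
  expect_identical(check_applicability_domain(c("CCO", alkane)),
                   check_applicability_domain(c("CCO", alkane)))
})
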