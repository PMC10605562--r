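test_that("each gate produces its label and order is fixed", {
  cb <- default_codebook()
  base <- list(year = 2017, drg = "O01G", icd_codes = "", chop_codes = "")
  expect_identical(classify_record(base, cb), "NMI_CS")
  expect_identical(
    classify_record(modifyList(base, list(drg = "O60D")), cb), "SVB"
  )
  expect_identical(
    classify_record(modifyList(base, list(drg = "O01E")), cb),
    "EXCLUDED_NON_TARGET_DRG"
  )
  expect_identical(
    classify_record(modifyList(base, list(icd_codes = "O32.1")), cb),
    "EXCLUDED_DIAGNOSIS"
  )
  expect_identical(
    classify_record(modifyList(base, list(chop_codes = "74.99.10")), cb),
    "EXCLUDED_EMERGENCY"
  )
  # diagnosis gate precedes emergency gate when both would fire
  expect_identical(
    classify_record(
      modifyList(base, list(icd_codes = "O64.1", chop_codes = "74.99.10")), cb
    ),
    "EXCLUDED_DIAGNOSIS"
  )
  # year-aware candidate: O01H is non-target in 2017, target in 2018
  expect_identical(
    classify_record(modifyList(base, list(drg = "O01H")), cb),
    "EXCLUDED_NON_TARGET_DRG"
  )
  expect_identical(
    classify_record(list(
      year = 2018, drg = "O01H", icd_codes = "", chop_codes = ""
    ), cb),
    "NMI_CS"
  )
  expect_error(
    classify_record(modifyList(base, list(year = 2013)), cb), "year"
  )
})

test_that("vectorized classification agrees with the naive oracle on random records", {
  cb <- default_codebook()
  recs <- random_records(10000, seed = 99)
  sel <- build_cohort(recs, cb)
  oracle <- vapply(
    seq_len(nrow(recs)),
    function(i) naive_classify(as.list(recs[i, ]), cb),
    character(1)
  )
  expect_identical(sel$records$label, oracle)
  # labels partition the input
  expect_identical(sum(sel$tally), nrow(recs))
  expect_setequal(names(sel$tally), cohort_labels())
  expect_gt(min(sel$tally), 0) # the random pool hits every gate
})

test_that("permuting a record's code lists never changes its label", {
  cb <- default_codebook()
  rec <- list(
    year = 2016, drg = "O01F",
    icd_codes = "Z37.0;O44.1;O30.0", chop_codes = "89.26;74.99.10"
  )
  l0 <- classify_record(rec, cb)
  set.seed(1)
  for (i in 1:20) {
    icd <- paste(sample(strsplit(rec$icd_codes, ";")[[1]]), collapse = ";")
    chop <- paste(sample(strsplit(rec$chop_codes, ";")[[1]]), collapse = ";")
    expect_identical(
      classify_record(
        modifyList(rec, list(icd_codes = icd, chop_codes = chop)), cb
      ),
      l0
    )
  }
})

test_that("build_cohort rejects duplicates and empty input", {
  recs <- random_records(5, seed = 1)
  expect_error(build_cohort(recs[0, ]), "non-empty")
  recs$record_id[2] <- recs$record_id[1]
  expect_error(build_cohort(recs), "duplicate")
})

test_that("annual summary counts are shuffle-invariant and internally consistent", {
  cb <- default_codebook()
  cfg <- generator_config(
    n_records = 20000, seed = 12,
    contamination = c(emergency = 0.05, diagnosis = 0.05, other_drg = 0.1)
  )
  sim <- generate_cohort(cfg, cb)
  sel <- build_cohort(sim$records, cb)
  s1 <- annual_summary(sel$records, cb)
  set.seed(3)
  s2 <- annual_summary(sel$records[sample(nrow(sel$records)), ], cb)
  expect_identical(s1, s2)
  annual <- s1[s1$year %in% as.character(2014:2018), ]
  total <- s1[s1$year == "Total", ]
  expect_true(all(annual$n_nmi_cs <= annual$n_cs))
  expect_true(all(annual$n_cs <= annual$n_births))
  expect_equal(sum(annual$n_births), total$n_births)
  expect_equal(sum(annual$n_nmi_cs), total$n_nmi_cs)
  pcts <- unlist(annual[grep("^pct_", names(annual))])
  expect_true(all(pcts >= 0 & pcts <= 100))
  # CS denominator counts every O01x DRG, not only the candidate
  n_cs_direct <- sum(startsWith(sim$records$drg, "O01"))
  expect_equal(total$n_cs, n_cs_direct)
})

test_that("exclusion tallies track the contamination fractions", {
  cb <- default_codebook()
  cfg <- generator_config(
    n_records = 50000, seed = 21,
    contamination = c(emergency = 0.1, diagnosis = 0, other_drg = 0)
  )
  sel <- build_cohort(generate_cohort(cfg, cb)$records, cb)
  expect_lt(
    abs(sel$tally[["EXCLUDED_EMERGENCY"]] - 5000),
    3 * sqrt(50000 * 0.1 * 0.9)
  )
  expect_identical(sel$tally[["EXCLUDED_DIAGNOSIS"]], 0L)
  expect_identical(sel$tally[["EXCLUDED_NON_TARGET_DRG"]], 0L)
})

test_that("a zero-birth year yields undefined ratios, not an error", {
  counts <- tibble::tibble(
    year = 2014:2018,
    n_births = c(10L, 0L, 10L, 10L, 10L),
    n_cs = c(5L, 0L, 5L, 5L, 5L),
    n_nmi_cs = c(1L, 0L, 1L, 1L, 1L),
    n_svb = c(4L, 0L, 4L, 4L, 4L)
  )
  s <- summarize_annual_counts(counts)
  expect_true(is.na(s$pct_cs_of_births[s$year == "2015"]))
  expect_identical(s$n_births[s$year == "Total"], 40)
})

test_that("half-up rounding matches the printed convention", {
  expect_identical(round_half_up(41.098, 2), 41.10)
  expect_identical(round_half_up(0.125, 2), 0.13) # banker's would give 0.12
  expect_identical(round_half_up(2.675, 2), 2.68)
  expect_identical(round_half_up(-0.125, 2), -0.13)
  expect_identical(round_half_up(7.872, 2), 7.87)
})
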