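test_that("generation is deterministic in (config, seed)", {
  cfg <- small_config(n = 2000, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$contexts, b$contexts)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(small_config(n = 2000, seed = 124))
  expect_false(identical(a$records, c2$records))
})

test_that("degenerate dispersions give constant contexts; LLN holds otherwise", {
  cfg0 <- small_config(context_sds = c(midwives = 0, staff = 0, income = 0))
  ctx0 <- generate_contexts(cfg0)
  expect_true(all(ctx0$midwives_per_1000_births == 37.7))
  expect_true(all(ctx0$nursing_staff_per_bed == 3.65))
  expect_true(all(ctx0$income_per_capita_chf == 37200))
  expect_identical(nrow(ctx0), 26L * 5L)

  cfg <- generator_config(n_cantons = 2000, seed = 5)
  ctx <- generate_contexts(cfg)
  n <- nrow(ctx)
  expect_identical(n, 2000L * 5L)
  expect_lt(
    abs(mean(ctx$midwives_per_1000_births) - 37.7), 3 * 8 / sqrt(n)
  )
  expect_lt(abs(mean(ctx$income_per_capita_chf) - 37200), 3 * 6000 / sqrt(n))
  expect_true(all(ctx$midwives_per_1000_births >= 0))
  expect_error(
    generator_config(context_sds = c(midwives = -1, staff = 0.5, income = 10)),
    "non-negative"
  )
})

test_that("zero-signal model yields a fair coin; clean cohorts carry no exclusion codes", {
  cfg <- generator_config(
    n_records = 10000, seed = 9, true_model = zero_model()
  )
  sim <- generate_cohort(cfg)
  expect_true(all(sim$truth$channel %in% c("nmi_cs", "svb")))
  expect_true(all(sim$records$icd_codes == ""))
  expect_true(all(sim$records$chop_codes == ""))
  share <- mean(sim$truth$channel == "nmi_cs")
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("empirical marginals converge to the configured distributions", {
  cfg <- generator_config(n_records = 50000, seed = 31)
  sim <- generate_cohort(cfg)
  for (v in c("age_category", "urbanity", "living_region")) {
    probs <- cfg[[switch(v,
      age_category = "age_category_probs",
      insurance = "insurance_probs",
      urbanity = "urbanity_probs",
      living_region = "region_probs"
    )]]
    obs <- table(factor(sim$records[[v]], levels = names(probs)))
    gof <- suppressWarnings(
      stats::chisq.test(obs, p = probs / sum(probs))
    )
    expect_gt(gof$p.value, 0.001)
  }
  # insurance marginal: exact multinomial behaviour with the income link
  # off; with the link on the draws are canton-correlated, so only a
  # cluster-noise-tolerant absolute check applies
  cfg0 <- generator_config(
    n_records = 50000, seed = 31, income_insurance_rho = 0
  )
  sim0 <- generate_cohort(cfg0)
  p_ins <- cfg0$insurance_probs
  emp0 <- prop.table(table(factor(sim0$records$insurance, names(p_ins))))
  se <- sqrt(p_ins * (1 - p_ins) / 50000)
  expect_true(all(abs(emp0 - p_ins) < 3 * se + 1e-12))
  emp <- prop.table(table(factor(sim$records$insurance, names(p_ins))))
  expect_true(all(abs(emp - p_ins) < 0.01))
})

test_that("age in years always lies inside its category bounds", {
  sim <- generate_cohort(small_config(n = 20000, seed = 2))
  lo <- as.integer(substr(sim$records$age_category, 1, 2))
  expect_true(all(sim$records$age_years >= lo))
  expect_true(all(sim$records$age_years <= lo + 4))
  # all five years represented and in range
  expect_true(all(sim$records$year %in% 2014:2018))
})

test_that("intercept calibration hits the target prevalence", {
  p_star <- 0.059
  cfg <- generator_config(
    n_records = 20000, seed = 17, intercept_calibration = p_star
  )
  sim <- generate_cohort(cfg)
  prev <- mean(sim$truth$channel == "nmi_cs")
  expect_lt(abs(prev - p_star), 3 * sqrt(p_star * (1 - p_star) / 20000))
})

test_that("contamination channels carry the constructed code signatures", {
  cb <- default_codebook()
  cfg <- generator_config(
    n_records = 20000, seed = 77,
    contamination = c(emergency = 0.1, diagnosis = 0.05, other_drg = 0.1)
  )
  sim <- generate_cohort(cfg, cb)
  tr <- sim$truth$channel
  rec <- sim$records
  cand <- unname(cb$cs_candidate_drg_by_year[as.character(rec$year)])
  expect_true(all(rec$drg[tr == "emergency"] == cand[tr == "emergency"]))
  expect_true(all(nzchar(rec$chop_codes[tr == "emergency"])))
  expect_true(all(rec$drg[tr == "diagnosis"] == cand[tr == "diagnosis"]))
  expect_true(all(nzchar(rec$icd_codes[tr == "diagnosis"])))
  od <- tr == "other_drg"
  expect_true(all(startsWith(rec$drg[od], "O01")))
  expect_true(all(rec$drg[od] != cand[od]))
  # channel frequencies within 3 binomial SEs
  for (ch in c("emergency", "other_drg")) {
    expect_lt(
      abs(mean(tr == ch) - 0.1), 3 * sqrt(0.1 * 0.9 / 20000)
    )
  }
})

test_that("every generated record classifies back to its generating channel", {
  # the central round-trip property of the pipeline
  cb <- default_codebook()
  cfg <- generator_config(
    n_records = 30000, seed = 4,
    contamination = c(emergency = 0.08, diagnosis = 0.04, other_drg = 0.12)
  )
  sim <- generate_cohort(cfg, cb)
  sel <- build_cohort(sim$records, cb)
  expected <- c(
    nmi_cs = "NMI_CS", svb = "SVB", emergency = "EXCLUDED_EMERGENCY",
    diagnosis = "EXCLUDED_DIAGNOSIS", other_drg = "EXCLUDED_NON_TARGET_DRG"
  )
  expect_identical(
    sel$records$label,
    unname(expected[sim$truth$channel])
  )
})

test_that("generator configs are validated", {
  expect_error(generator_config(n_records = 0), "positive")
  expect_error(
    generator_config(insurance_probs = c(mandatory = 0.5, `semi-private` = 0.2, private = 0.2)),
    "summing to 1"
  )
  expect_error(
    generator_config(contamination = c(emergency = 0.6, diagnosis = 0.6, other_drg = 0)),
    "sum to at most 1"
  )
  expect_error(generator_config(intercept_calibration = 1.2), "strictly")
  expect_error(
    true_model(
      intercept = 0,
      beta_age = setNames(rep(1, 7), names(published_birthmode_model()$beta_age)),
      beta_insurance = c(mandatory = 0, `semi-private` = 0, private = 0),
      beta_urbanity = c(urban = 0, suburban = 0, rural = 0),
      beta_midwives = 0, beta_staff = 0, beta_income = 0
    ),
    "reference"
  )
})
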