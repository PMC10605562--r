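test_that("build_design encodes references, units and dimensions as documented", {
  dat <- tibble::tibble(
    label = c("NMI_CS", "SVB", "SVB"),
    age_category = c("30-34", "45-49", "15-19"),
    insurance = c("private", "mandatory", "semi-private"),
    urbanity = c("rural", "urban", "suburban"),
    midwives_per_1000_births = c(30, 40, 37),
    nursing_staff_per_bed = c(3.5, 3.7, 3.6),
    income_per_capita_chf = c(38273, 40000, 35000)
  )
  d <- build_design(dat)
  expect_identical(dim(d$X), c(3L, 14L))
  expect_identical(colnames(d$X), model_terms())
  expect_identical(d$y, c(1L, 0L, 0L))
  # reference absorption: private + rural woman has all-zero insurance
  # and urbanity indicators
  expect_true(all(d$X[1, c(
    "insurance_mandatory", "insurance_semi-private",
    "urbanity_urban", "urbanity_suburban"
  )] == 0))
  expect_equal(unname(d$X[1, "age_30-34"]), 1)
  # 45-49 is the absorbed age reference
  expect_true(all(d$X[2, paste0("age_", c(
    "15-19", "20-24", "25-29", "30-34", "35-39", "40-44"
  ))] == 0))
  # income scaled to CHF 10,000 units
  expect_equal(unname(d$X[1, "income_chf_10k"]), 3.8273)
  expect_error(
    build_design(dplyr::mutate(dat, age_category = "50-54")), "unseen"
  )
  expect_error(
    build_design(dplyr::mutate(dat, label = "EXCLUDED_EMERGENCY")),
    "restricted"
  )
  expect_error(
    build_design(dat[, setdiff(names(dat), "nursing_staff_per_bed")]),
    "join"
  )
})

test_that("the IRLS slope matches the closed-form 2x2 log odds ratio", {
  # cells: exposed-case 10, exposed-control 20, unexposed-case 30,
  # unexposed-control 40
  x <- c(rep(1, 30), rep(0, 70))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  X <- cbind(intercept = 1, exposure = x)
  fit <- fit_logistic(X, y)
  slope <- fit$coefficients$estimate[fit$coefficients$term == "exposure"]
  expect_equal(slope, log((10 * 40) / (20 * 30)), tolerance = 1e-6)
  expect_equal(
    fit$coefficients$estimate[1], log(30 / 40),
    tolerance = 1e-6
  )
  expect_true(fit$converged)
})

test_that("IRLS agrees with the reference optimizer on random designs", {
  set.seed(13)
  n <- 2000
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4), runif(n))
  colnames(X) <- c("intercept", "x1", "x2", "x3")
  eta <- -0.5 + 0.8 * X[, 2] - 0.6 * X[, 3] + 0.3 * X[, 4]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  ref <- stats::glm(y ~ X[, -1], family = stats::binomial())
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(
    fit$coefficients$estimate, unname(stats::coef(ref)),
    tolerance = 1e-6
  )
  expect_equal(
    fit$coefficients$se,
    unname(sqrt(diag(stats::vcov(ref)))),
    tolerance = 1e-4
  )
  # Wald CIs bracket the estimate with the 1.959964 critical value
  expect_equal(
    fit$coefficients$ci_high - fit$coefficients$estimate,
    1.959964 * fit$coefficients$se,
    tolerance = 1e-6
  )
})

test_that("rescaling a continuous column divides its coefficient by the factor", {
  set.seed(23)
  n <- 3000
  inc <- rnorm(n, 37200, 6000)
  X <- cbind(intercept = 1, income = inc / 10000)
  y <- rbinom(n, 1, plogis(-1 + 0.17 * X[, 2]))
  f1 <- fit_logistic(X, y)
  X2 <- X
  X2[, 2] <- inc # raw CHF
  f2 <- fit_logistic(X2, y)
  expect_equal(
    f2$coefficients$estimate[2] * 10000,
    f1$coefficients$estimate[2],
    tolerance = 1e-6
  )
})

test_that("degenerate fits fail loudly", {
  X <- cbind(intercept = 1, a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_logistic(X, c(0, 1, 0, 1)), "collinear.*b")
  X2 <- cbind(intercept = 1, x = rnorm(10))
  expect_error(fit_logistic(X2, rep(1, 10)), "both outcome classes")
  # complete separation is detected
  xs <- c(-(5:1), 1:5)
  expect_error(
    fit_logistic(cbind(1, xs), as.integer(xs > 0)),
    "separation"
  )
})

test_that("roc_auc equals exhaustive pair enumeration, with midrank ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4)), 0.5)
  s <- c(0.1, 0.4, 0.4, 0.8, 0.2, 0.9)
  o <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_auc(s, o), auc_bruteforce(s, o))
  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    o <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(roc_auc(s, o), auc_bruteforce(s, o), tolerance = 1e-12)
    # invariance under strictly increasing transform
    expect_equal(roc_auc(exp(3 * s), o), roc_auc(s, o), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both")
})

test_that("roc_auc agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- round(rnorm(500), 1) # plenty of ties
  o <- rbinom(500, 1, plogis(s))
  expect_equal(
    roc_auc(s, o),
    as.numeric(pROC::auc(pROC::roc(o, s, quiet = TRUE, direction = "<"))),
    tolerance = 1e-12
  )
})

test_that("Wald intervals achieve nominal coverage over replicate fits", {
  set.seed(314)
  truth <- 0.8
  n <- 400
  covered <- logical(200)
  for (r in seq_len(200)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + truth * x))
    fit <- fit_logistic(cbind(intercept = 1, x = x), y)
    ci <- fit$coefficients[fit$coefficients$term == "x", ]
    covered[r] <- ci$ci_low <= truth && truth <= ci$ci_high
  }
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("zero-signal truth yields chance-level AUC; seeds vary estimates, not truth", {
  cfg <- generator_config(
    n_records = 10000, seed = 5, true_model = zero_model()
  )
  rec <- recovery_experiment(cfg)
  expect_lt(abs(rec$auc - 0.5), 0.02)
  r1 <- recovery_experiment(small_config(n = 20000, seed = 51))
  r2 <- recovery_experiment(small_config(n = 20000, seed = 52))
  expect_identical(r1$comparison$truth, r2$comparison$truth)
  expect_false(identical(r1$comparison$estimate, r2$comparison$estimate))
  expect_true(all(abs(r1$comparison$z_vs_truth) < 4))
  expect_true(all(abs(r2$comparison$z_vs_truth) < 4))
})
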