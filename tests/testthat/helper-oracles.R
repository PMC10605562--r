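# Independent oracles, written directly from first principles and kept
# free of the package's implementation paths.

# naive pattern matcher: double loop over (code, pattern) pairs
naive_matches_any <- function(codes, patterns) {
  codes <- toupper(trimws(codes))
  codes <- codes[nzchar(codes)]
  for (code in codes) {
    for (p in toupper(trimws(patterns))) {
      prefix <- grepl("\\*$", p) || !grepl("\\.", sub("\\*$", "", p))
      body <- sub("\\*$", "", p)
      hit <- if (prefix) substr(code, 1, nchar(body)) == body else code == body
      if (hit) return(TRUE)
    }
  }
  FALSE
}

# naive gate-by-gate classifier with direct set-membership checks
naive_classify <- function(rec, cb) {
  split1 <- function(s) {
    out <- strsplit(toupper(trimws(s)), ";", fixed = TRUE)[[1]]
    out[nzchar(out)]
  }
  yr <- as.character(rec$year)
  if (toupper(trimws(rec$drg)) == cb$svb_drg_by_year[[yr]]) {
    return("SVB")
  }
  if (toupper(trimws(rec$drg)) != cb$cs_candidate_drg_by_year[[yr]]) {
    return("EXCLUDED_NON_TARGET_DRG")
  }
  if (naive_matches_any(split1(rec$icd_codes), cb$icd_exclusions)) {
    return("EXCLUDED_DIAGNOSIS")
  }
  if (naive_matches_any(split1(rec$chop_codes), cb$chop_emergency)) {
    return("EXCLUDED_EMERGENCY")
  }
  "NMI_CS"
}

# textbook Welch statistic (direct formulas)
welch_formula <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Spearman by explicit midranks (sorting-based), then Pearson formula
spearman_bruteforce <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# AUC by exhaustive case-control pair enumeration, ties as 1/2
auc_bruteforce <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  tot <- 0
  for (s1 in cases) {
    for (s0 in controls) {
      tot <- tot + (s1 > s0) + 0.5 * (s1 == s0)
    }
  }
  tot / (length(cases) * length(controls))
}

# random discharge records exercising every gate
random_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    record_id = sprintf("X%06d", seq_len(n)),
    year = sample(2014:2018, n, replace = TRUE),
    drg = sample(
      c("O01F", "O01G", "O01H", "O60D", "O01E", "O65A", "o01f ", "P67D"),
      n,
      replace = TRUE
    ),
    icd_codes = sample(
      c(
        "", "O32.1", "O64.0", "Z37.0", "O80", "O44.1;Z37.0",
        "Z37.0;O66.5", "O30.0", "o32.9"
      ),
      n,
      replace = TRUE
    ),
    chop_codes = sample(
      c("", "74.1", "74.99.10", "74.99", "89.26", "74.1;74.99.11"),
      n,
      replace = TRUE
    ),
    age_years = sample(15:49, n, replace = TRUE),
    age_category = "30-34",
    insurance = "mandatory",
    living_region = "Zurich",
    canton_id = "C01",
    urbanity = "urban",
    cost_weight = NA_real_
  )
}

# small generator config for fast stochastic tests
small_config <- function(n = 5000, seed = 7, ...) {
  generator_config(n_records = n, seed = seed, ...)
}

zero_model <- function() {
  true_model(
    intercept = 0,
    beta_age = setNames(rep(0, 7), names(published_birthmode_model()$beta_age)),
    beta_insurance = c(mandatory = 0, `semi-private` = 0, private = 0),
    beta_urbanity = c(urban = 0, suburban = 0, rural = 0),
    beta_midwives = 0, beta_staff = 0, beta_income = 0
  )
}
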