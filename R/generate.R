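#' Construct the true (generating) birth-mode model
#'
#' The data-generating model for the synthetic cohort, on the log-odds
#' scale: probability of a non-medically indicated CS (vs spontaneous
#' vaginal birth) given maternal age category, insurance class, urbanity
#' level and the cantonal covariates. Reference categories (age 45-49,
#' private insurance, rural) must carry exactly 0.
#'
#' @param intercept intercept on the log-odds scale.
#' @param beta_age named log-odds per age category (reference "45-49" = 0).
#' @param beta_insurance named log-odds per insurance class
#'   (reference "private" = 0).
#' @param beta_urbanity named log-odds per urbanity level
#'   (reference "rural" = 0).
#' @param beta_midwives log-odds per practicing midwife per 1,000 births.
#' @param beta_staff log-odds per nursing staff member per hospital bed.
#' @param beta_income log-odds per CHF 10,000 annual income per capita.
#' @return a list of class `true_model`.
#' @export
true_model <- function(intercept, beta_age, beta_insurance, beta_urbanity,
                       beta_midwives, beta_staff, beta_income) {
  m <- list(
    intercept = intercept,
    beta_age = beta_age[age_category_levels()],
    beta_insurance = beta_insurance[insurance_levels()],
    beta_urbanity = beta_urbanity[urbanity_levels()],
    beta_midwives = beta_midwives,
    beta_staff = beta_staff,
    beta_income = beta_income
  )
  vals <- unlist(m)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("true_model: all coefficients must be finite and cover all levels",
      call. = FALSE
    )
  }
  refs <- c(
    m$beta_age[["45-49"]], m$beta_insurance[["private"]],
    m$beta_urbanity[["rural"]]
  )
  if (any(refs != 0)) {
    stop("true_model: reference levels (45-49, private, rural) must be 0",
      call. = FALSE
    )
  }
  class(m) <- "true_model"
  m
}

#' Configuration for the synthetic discharge-record generator
#'
#' Defaults emulate the published study conditions: year weights
#' proportional to the printed annual birth totals, categorical marginals
#' equal to the pooled printed group profiles, canton-year covariate
#' means at the pooled printed person-level means (midwives 37.7 per
#' 1,000 births, 3.65 nursing staff per bed, CHF 37,200 income per
#' capita), generating coefficients equal to the published fitted model,
#' and an income-insurance Spearman rank correlation of 0.155. The
#' cantonal covariate dispersions are free parameters of the generator
#' (the study reports none); defaults are chosen as realistic Swiss
#' cantonal variation and documented in the methods vignette.
#'
#' @param n_records number of discharge records to generate.
#' @param year_weights named distribution over 2014-2018.
#' @param age_category_probs,insurance_probs,urbanity_probs,region_probs
#'   named categorical distributions (normalised if needed).
#' @param n_cantons number of cantons (default 26).
#' @param context_means,context_sds named numeric vectors with entries
#'   `midwives`, `staff`, `income` giving the mean/SD of the canton-year
#'   covariates (normal, truncated at 0).
#' @param true_model generating model, see [true_model()].
#' @param income_insurance_rho target Spearman rank correlation between
#'   person-level income and ordinal insurance class (0 disables the
#'   dependency).
#' @param contamination named fractions (`emergency`, `diagnosis`,
#'   `other_drg`) of records routed through the contamination channels
#'   that exist to exercise the selection classifier; default all 0.
#' @param intercept_calibration optional target prevalence of nmi CS
#'   among clean (nmi CS or SVB) records; when set, the intercept is
#'   shifted so the mean generating probability equals this target
#'   before outcomes are drawn.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_records = 10000,
                             year_weights = NULL,
                             age_category_probs = NULL,
                             insurance_probs = NULL,
                             urbanity_probs = NULL,
                             region_probs = NULL,
                             n_cantons = 26,
                             context_means = c(
                               midwives = 37.7, staff = 3.65, income = 37200
                             ),
                             context_sds = c(
                               midwives = 8, staff = 0.5, income = 6000
                             ),
                             true_model = published_birthmode_model(),
                             income_insurance_rho = 0.155,
                             contamination = c(
                               emergency = 0, diagnosis = 0, other_drg = 0
                             ),
                             intercept_calibration = NULL,
                             seed = 1L) {
  if (is.null(year_weights)) {
    ab <- swiss_annual_births()
    year_weights <- setNames(ab$n_births / sum(ab$n_births), ab$year)
  }
  if (is.null(age_category_probs)) {
    age_category_probs <- pooled_profile_probs("age_category")
  }
  if (is.null(insurance_probs)) {
    insurance_probs <- pooled_profile_probs("insurance")
  }
  if (is.null(urbanity_probs)) urbanity_probs <- pooled_profile_probs("urbanity")
  if (is.null(region_probs)) region_probs <- pooled_profile_probs("living_region")
  cfg <- list(
    n_records = n_records,
    year_weights = year_weights,
    age_category_probs = age_category_probs,
    insurance_probs = insurance_probs,
    urbanity_probs = urbanity_probs,
    region_probs = region_probs,
    n_cantons = n_cantons,
    context_means = context_means,
    context_sds = context_sds,
    true_model = true_model,
    income_insurance_rho = income_insurance_rho,
    contamination = contamination,
    intercept_calibration = intercept_calibration,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_records) || length(cfg$n_records) != 1 ||
    is.na(cfg$n_records) || cfg$n_records < 1) {
    stop("n_records must be a positive integer", call. = FALSE)
  }
  probs <- list(
    year_weights = cfg$year_weights,
    age_category_probs = cfg$age_category_probs,
    insurance_probs = cfg$insurance_probs,
    urbanity_probs = cfg$urbanity_probs,
    region_probs = cfg$region_probs
  )
  levels <- list(
    year_weights = as.character(STUDY_YEARS),
    age_category_probs = age_category_levels(),
    insurance_probs = insurance_levels(),
    urbanity_probs = urbanity_levels(),
    region_probs = region_levels()
  )
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!setequal(names(p), levels[[nm]])) {
      stop(nm, " must be named over: ", paste(levels[[nm]], collapse = ", "),
        call. = FALSE
      )
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  for (f in c("context_means", "context_sds")) {
    v <- cfg[[f]]
    if (!all(c("midwives", "staff", "income") %in% names(v))) {
      stop(f, " must name midwives, staff and income", call. = FALSE)
    }
  }
  if (any(cfg$context_sds < 0)) {
    stop("context_sds must be non-negative", call. = FALSE)
  }
  ctm <- cfg$contamination
  if (!all(c("emergency", "diagnosis", "other_drg") %in% names(ctm)) ||
    any(ctm < 0) || any(ctm > 1) || sum(ctm) > 1) {
    stop("contamination fractions must lie in [0,1] and sum to at most 1",
      call. = FALSE
    )
  }
  if (!is.null(cfg$intercept_calibration)) {
    p <- cfg$intercept_calibration
    if (p <= 0 || p >= 1) {
      stop("intercept_calibration must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  if (!inherits(cfg$true_model, "true_model")) {
    stop("true_model must be constructed with true_model()", call. = FALSE)
  }
  cfg
}

# Stream splitting: sub-streams derive deterministically from the single
# top-level seed (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Generate canton-year covariate contexts
#'
#' One row per (canton, year): practicing midwives per 1,000 births,
#' nursing staff per hospital bed, and annual income per capita (CHF),
#' each drawn from a normal distribution with the configured mean and SD,
#' truncated at 0 by resampling. Identical (cfg, seed) gives identical
#' output.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return a tibble with columns `canton_id`, `year`,
#'   `midwives_per_1000_births`, `nursing_staff_per_bed`,
#'   `income_per_capita_chf`.
#' @export
generate_contexts <- function(cfg, seed = cfg$seed) {
  cfg <- validate_generator_config(cfg)
  grid <- expand.grid(
    canton_id = paste0("C", sprintf("%02d", seq_len(cfg$n_cantons))),
    year = STUDY_YEARS,
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  draw <- function(mean, sd) {
    if (sd == 0) {
      return(rep(mean, n))
    }
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  withr_seed <- derive_seed(seed, 0L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  tibble::tibble(
    canton_id = grid$canton_id,
    year = grid$year,
    midwives_per_1000_births = draw(
      cfg$context_means[["midwives"]], cfg$context_sds[["midwives"]]
    ),
    nursing_staff_per_bed = draw(
      cfg$context_means[["staff"]], cfg$context_sds[["staff"]]
    ),
    income_per_capita_chf = draw(
      cfg$context_means[["income"]], cfg$context_sds[["income"]]
    )
  )
}

# Population Spearman grade correlation between a N(0,1) score and an
# ordinal variable generated from it by a Gaussian latent-threshold model
# with latent correlation r. Midrank grades: continuous -> Phi(z),
# ordinal level k -> cum_{k-1} + p_k / 2.
latent_ordinal_spearman <- function(r, probs) {
  probs <- probs / sum(probs)
  cum <- cumsum(probs)
  thr <- qnorm(c(0, cum))
  m <- c(0, head(cum, -1)) + probs / 2
  s <- sqrt(1 - r^2)
  e_u_k <- vapply(seq_along(probs), function(k) {
    integrate(
      function(z) {
        dnorm(z) * pnorm(z) *
          (pnorm((thr[k + 1] - r * z) / s) - pnorm((thr[k] - r * z) / s))
      },
      -8, 8,
      rel.tol = 1e-10
    )$value
  }, numeric(1))
  cov_um <- sum(m * e_u_k) - 0.5 * sum(m * probs)
  var_m <- sum(probs * m^2) - sum(probs * m)^2
  cov_um / sqrt(var_m / 12)
}

# Latent correlation achieving a target Spearman between income and the
# ordinal insurance class; solved once per generation by 1-D root finding.
solve_latent_corr <- function(target_rho, probs) {
  if (target_rho == 0) {
    return(0)
  }
  if (abs(target_rho) >= 0.99) {
    stop("income_insurance_rho must lie in (-0.99, 0.99)", call. = FALSE)
  }
  uniroot(
    function(r) latent_ordinal_spearman(r, probs) - target_rho,
    interval = c(-0.995, 0.995), tol = 1e-9
  )$root
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# A concrete code matching a pattern: the pattern body itself (an exact
# pattern matches itself; a prefix is a prefix of itself).
exemplar_code <- function(patterns) {
  sub("\\*$", "", canonicalize_code(patterns))
}

other_cs_drg <- function(prefixes, candidate) {
  for (letter in c("A", "B", "C", "D", "E")) {
    code <- paste0(prefixes[[1]], letter)
    if (!code %in% candidate) {
      return(code)
    }
  }
  stop("cannot construct a non-candidate CS DRG", call. = FALSE)
}

#' Generate a synthetic claims cohort
#'
#' Draws `cfg$n_records` discharge records. For clean records, covariates
#' are sampled independently from the configured marginals (except the
#' optional income-insurance rank dependency), the canton is assigned
#' uniformly, the linear predictor of the generating model is evaluated
#' on the record's canton-year context, and the birth mode is drawn
#' Bernoulli on the logistic scale: outcome 1 receives the year's
#' low-complexity CS DRG, outcome 0 the SVB DRG, and no exclusion codes.
#' Contaminant records instead receive, per channel: `emergency` - the CS
#' candidate DRG plus one emergency procedure code; `diagnosis` - the CS
#' candidate DRG plus one excluded diagnosis code; `other_drg` - a CS DRG
#' matching the CS prefix set but not the candidate code. The generating
#' channel of every record is recorded in `truth`.
#'
#' @param cfg a [generator_config()].
#' @param cb codebook used for code assignment (default
#'   [default_codebook()]); use the same codebook downstream for the
#'   selection round trip.
#' @return a list with elements `records` (tibble of discharge records;
#'   code lists are ";"-separated strings), `contexts` (canton-year
#'   covariates) and `truth` (tibble `record_id`, `channel` with levels
#'   nmi_cs / svb / emergency / diagnosis / other_drg).
#' @export
generate_cohort <- function(cfg, cb = default_codebook()) {
  cfg <- validate_generator_config(cfg)
  cb <- validate_codebook(cb)
  contexts <- generate_contexts(cfg, cfg$seed)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(cfg$seed, 1L))

  n <- as.integer(cfg$n_records)
  year <- as.integer(sample_levels(n, cfg$year_weights))
  canton_id <- sample(unique(contexts$canton_id), n, replace = TRUE)
  ctx_key <- paste(canton_id, year)
  ctx_idx <- match(ctx_key, paste(contexts$canton_id, contexts$year))
  midwives <- contexts$midwives_per_1000_births[ctx_idx]
  staff <- contexts$nursing_staff_per_bed[ctx_idx]
  income <- contexts$income_per_capita_chf[ctx_idx]

  age_category <- sample_levels(n, cfg$age_category_probs)
  bounds <- age_category_bounds()
  b_idx <- match(age_category, bounds$age_category)
  age_years <- bounds$lo[b_idx] +
    as.integer(floor(runif(n) * (bounds$hi[b_idx] - bounds$lo[b_idx] + 1)))

  # insurance: Gaussian latent-threshold draw tied to the income score so
  # the (income, ordinal insurance) Spearman correlation hits the target;
  # marginal insurance probabilities are preserved by construction
  ins_probs <- cfg$insurance_probs[insurance_levels()]
  r <- solve_latent_corr(cfg$income_insurance_rho, ins_probs)
  z_income <- (income - cfg$context_means[["income"]]) /
    max(cfg$context_sds[["income"]], .Machine$double.eps)
  z_lat <- r * z_income + sqrt(1 - r^2) * rnorm(n)
  thr <- qnorm(cumsum(ins_probs / sum(ins_probs)))
  insurance <- insurance_levels()[
    1L + findInterval(z_lat, head(thr, -1), left.open = TRUE)
  ]

  urbanity <- sample_levels(n, cfg$urbanity_probs)
  living_region <- sample_levels(n, cfg$region_probs)

  tm <- cfg$true_model
  eta <- tm$intercept +
    unname(tm$beta_age[age_category]) +
    unname(tm$beta_insurance[insurance]) +
    unname(tm$beta_urbanity[urbanity]) +
    tm$beta_midwives * midwives +
    tm$beta_staff * staff +
    tm$beta_income * (income / 10000)
  if (!is.null(cfg$intercept_calibration)) {
    p_star <- cfg$intercept_calibration
    delta <- uniroot(
      function(d) mean(plogis(eta + d)) - p_star,
      interval = c(-50, 50), tol = 1e-12
    )$root
    eta <- eta + delta
  }
  outcome <- rbinom(n, 1L, plogis(eta))

  channel <- rep("clean", n)
  ctm <- cfg$contamination
  u <- runif(n)
  cuts <- cumsum(c(ctm[["emergency"]], ctm[["diagnosis"]], ctm[["other_drg"]]))
  channel[u < cuts[1]] <- "emergency"
  channel[u >= cuts[1] & u < cuts[2]] <- "diagnosis"
  channel[u >= cuts[2] & u < cuts[3]] <- "other_drg"

  cand <- unname(cb$cs_candidate_drg_by_year[as.character(year)])
  svb <- unname(cb$svb_drg_by_year[as.character(year)])
  drg <- ifelse(outcome == 1L, cand, svb)
  icd_codes <- rep("", n)
  chop_codes <- rep("", n)

  is_em <- channel == "emergency"
  is_dx <- channel == "diagnosis"
  is_od <- channel == "other_drg"
  if (any(is_em)) {
    drg[is_em] <- cand[is_em]
    chop_codes[is_em] <- sample(
      exemplar_code(cb$chop_emergency), sum(is_em),
      replace = TRUE
    )
  }
  if (any(is_dx)) {
    drg[is_dx] <- cand[is_dx]
    icd_codes[is_dx] <- sample(
      exemplar_code(cb$icd_exclusions), sum(is_dx),
      replace = TRUE
    )
  }
  if (any(is_od)) {
    drg[is_od] <- vapply(
      cand[is_od],
      function(cc) other_cs_drg(cb$cs_all_drg_prefixes, cc),
      character(1), USE.NAMES = FALSE
    )
  }
  channel[channel == "clean"] <- ifelse(
    outcome[channel == "clean"] == 1L, "nmi_cs", "svb"
  )

  record_id <- sprintf("R%07d", seq_len(n))
  records <- tibble::tibble(
    record_id = record_id,
    year = year,
    drg = drg,
    icd_codes = icd_codes,
    chop_codes = chop_codes,
    age_years = age_years,
    age_category = age_category,
    insurance = insurance,
    living_region = living_region,
    canton_id = canton_id,
    urbanity = urbanity,
    cost_weight = NA_real_
  )
  list(
    records = records,
    contexts = contexts,
    truth = tibble::tibble(record_id = record_id, channel = channel)
  )
}
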