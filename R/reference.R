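#' Published annual birth counts, Switzerland 2014-2018
#'
#' The printed annual counts from the national hospital discharge study:
#' total in-hospital births, caesarean sections (any O01x DRG),
#' non-medically indicated CS (the year's low-complexity CS DRG after
#' diagnosis and emergency exclusions) and uncomplicated spontaneous
#' vaginal births (DRG O60D). These counts serve as arithmetic inputs for
#' [summarize_annual_counts()] and as year weights for the synthetic
#' generator; they are not produced by this package.
#'
#' @return a tibble with columns `year`, `n_births`, `n_cs`, `n_nmi_cs`,
#'   `n_svb`.
#' @export
swiss_annual_births <- function() {
  tibble::tibble(
    year = 2014:2018,
    n_births = c(84438L, 85847L, 87255L, 86501L, 86879L),
    n_cs = c(28324L, 28473L, 28768L, 27801L, 27773L),
    n_nmi_cs = c(2206L, 2340L, 2331L, 2145L, 2090L),
    n_svb = c(39654L, 39941L, 33662L, 32701L, 30950L)
  )
}

#' Published covariate counts by birth-mode group
#'
#' Printed categorical counts for the two analysis groups (non-medically
#' indicated CS, n = 11,112; spontaneous vaginal birth, n = 176,908):
#' maternal age category, living region, insurance class and urbanity
#' score. Used as arithmetic inputs for the descriptive tables and,
#' pooled across groups, as the synthetic generator's default marginal
#' distributions. (The printed urbanity and age columns do not sum
#' exactly to the group totals; proportions are normalised when used as
#' sampling distributions.)
#'
#' @return a tibble with columns `variable`, `level`, `nmi_cs`, `svb`.
#' @export
swiss_group_profile <- function() {
  tibble::tribble(
    ~variable, ~level, ~nmi_cs, ~svb,
    "age_category", "15-19", 89L, 1355L,
    "age_category", "20-24", 654L, 14849L,
    "age_category", "25-29", 2236L, 47374L,
    "age_category", "30-34", 3754L, 69238L,
    "age_category", "35-39", 3176L, 37453L,
    "age_category", "40-44", 1060L, 6422L,
    "age_category", "45-49", 128L, 199L,
    "living_region", "Eastern Switzerland", 1115L, 22296L,
    "living_region", "Central Switzerland", 1009L, 16519L,
    "living_region", "North-Western Switzerland", 1805L, 21544L,
    "living_region", "Ticino", 324L, 6626L,
    "living_region", "Zurich", 2871L, 29409L,
    "living_region", "Western Switzerland", 1616L, 38837L,
    "living_region", "Espace Mittelland", 2058L, 38014L,
    "living_region", "Other Countries", 314L, 3663L,
    "insurance", "mandatory", 8431L, 151295L,
    "insurance", "semi-private", 1702L, 18429L,
    "insurance", "private", 979L, 7184L,
    "urbanity", "urban", 6896L, 102431L,
    "urbanity", "suburban", 1733L, 27706L,
    "urbanity", "rural", 1529L, 30963L
  )
}

#' Published fitted birth-mode model (log-odds scale)
#'
#' The point estimates of the published logistic regression of
#' non-medically indicated CS (vs spontaneous vaginal birth) on maternal
#' and cantonal factors, on the log-odds scale. Reference categories
#' carry 0: age 45-49, private insurance, rural urbanity. The income
#' coefficient is per CHF 10,000 of annual per-capita income. These are
#' the synthetic generator's default true coefficients.
#'
#' @return a `true_model` list; see [true_model()].
#' @export
published_birthmode_model <- function() {
  true_model(
    intercept = 0.800,
    beta_age = c(
      "15-19" = -2.172, "20-24" = -2.533, "25-29" = -2.500,
      "30-34" = -2.413, "35-39" = -2.020, "40-44" = -1.373,
      "45-49" = 0
    ),
    beta_insurance = c(
      "mandatory" = -0.713, "semi-private" = -0.360, "private" = 0
    ),
    beta_urbanity = c("urban" = 0.152, "suburban" = 0.176, "rural" = 0),
    beta_midwives = -0.019,
    beta_staff = 0.243,
    beta_income = 0.168
  )
}

# closed level sets ---------------------------------------------------------

age_category_levels <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

age_category_bounds <- function() {
  lo <- seq(15, 45, by = 5)
  tibble::tibble(age_category = age_category_levels(), lo = lo, hi = lo + 4)
}

insurance_levels <- function() c("mandatory", "semi-private", "private")

urbanity_levels <- function() c("urban", "suburban", "rural")

region_levels <- function() {
  unique(swiss_group_profile()$level[
    swiss_group_profile()$variable == "living_region"
  ])
}

pooled_profile_probs <- function(variable) {
  p <- swiss_group_profile()
  p <- p[p$variable == variable, ]
  n <- p$nmi_cs + p$svb
  setNames(n / sum(n), p$level)
}
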