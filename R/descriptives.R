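#' Categorical group-comparison table
#'
#' Counts and within-group percentages of the requested categorical
#' variables across the two analysis groups (non-medically indicated CS
#' vs spontaneous vaginal birth). Percentages use the group total as
#' denominator and are rounded half-up to 1 decimal, matching the
#' printed convention.
#'
#' @param labelled labelled records restricted (or restrictable) to
#'   labels NMI_CS and SVB; other labels are dropped with a message.
#' @param variables character vector of record columns to tabulate
#'   (default: age category, living region, insurance, urbanity).
#' @return tibble with columns `variable`, `level`, `n_nmi_cs`,
#'   `pct_nmi_cs`, `n_svb`, `pct_svb`.
#' @export
categorical_table <- function(labelled,
                              variables = c(
                                "age_category", "living_region",
                                "insurance", "urbanity"
                              )) {
  unknown <- setdiff(variables, names(labelled))
  if (length(unknown) > 0) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  dat <- dplyr::filter(labelled, .data$label %in% c("NMI_CS", "SVB"))
  n_nmi <- sum(dat$label == "NMI_CS")
  n_svb <- sum(dat$label == "SVB")
  if (n_nmi == 0 || n_svb == 0) {
    stop("both groups (NMI_CS, SVB) must be non-empty", call. = FALSE)
  }
  out <- lapply(variables, function(v) {
    tab <- dat |>
      dplyr::count(level = as.character(.data[[v]]), .data$label) |>
      tidyr::pivot_wider(
        names_from = "label", values_from = "n", values_fill = 0L
      )
    for (g in c("NMI_CS", "SVB")) if (!g %in% names(tab)) tab[[g]] <- 0L
    tibble::tibble(
      variable = v, level = tab$level,
      n_nmi_cs = tab$NMI_CS, n_svb = tab$SVB
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      pct_nmi_cs = round_half_up(100 * .data$n_nmi_cs / .env$n_nmi, 1),
      pct_svb = round_half_up(100 * .data$n_svb / .env$n_svb, 1)
    ) |>
    dplyr::select(
      "variable", "level", "n_nmi_cs", "pct_nmi_cs", "n_svb", "pct_svb"
    )
}

#' Within-group percentages from raw counts
#'
#' @param counts integer counts of the levels of one variable in one
#'   group.
#' @return percentages of `sum(counts)`, rounded half-up to 1 decimal.
#' @export
group_percentages <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("group total must be positive", call. = FALSE)
  round_half_up(100 * counts / total, 1)
}

#' Independent-samples t-test (Welch by default)
#'
#' Compares two sample means; by default Welch's unequal-variance
#' statistic with Welch-Satterthwaite degrees of freedom (delegating to
#' [stats::t.test()]); `pooled = TRUE` gives the classical equal-variance
#' test.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values and
#'   nonzero variance each.
#' @param pooled use the pooled-variance (equal-variance) statistic.
#' @return list with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(sample_a, sample_b, pooled = FALSE) {
  for (s in list(sample_a, sample_b)) {
    if (length(s) < 2 || !is.numeric(s) || anyNA(s)) {
      stop("each sample needs >= 2 non-missing numeric values", call. = FALSE)
    }
    if (var(s) == 0) {
      stop("each sample must have nonzero variance", call. = FALSE)
    }
  }
  fit <- stats::t.test(sample_a, sample_b, var.equal = pooled)
  list(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = unname(fit$p.value),
    mean_a = mean(sample_a),
    mean_b = mean(sample_b)
  )
}

#' Spearman rank correlation with midranks and t-approximation p-value
#'
#' The Pearson correlation of midranks (ties receive their average
#' rank), with a two-sided p-value from the t approximation
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r_s` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3 || anyNA(x) || anyNA(y)) {
    stop("need >= 3 complete pairs", call. = FALSE)
  }
  r_s <- cor(rank(x), rank(y))
  p <- if (abs(r_s) >= 1 - 1e-15) {
    0
  } else {
    tt <- r_s * sqrt((n - 2) / (1 - r_s^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r_s = r_s, p = p)
}

#' Metric group-comparison table on canton-level covariates
#'
#' Joins each woman's canton-year covariates to her record (the printed
#' table reports person-level means of cantonal quantities) and compares
#' the NMI_CS and SVB groups by independent-samples t-test.
#'
#' @param labelled labelled records (NMI_CS / SVB rows are used).
#' @param contexts canton-year covariate table.
#' @param pooled passed to [welch_t_test()].
#' @return tibble with `variable`, `mean_nmi_cs`, `mean_svb`, `t`, `df`,
#'   `p`.
#' @export
metric_table <- function(labelled, contexts, pooled = FALSE) {
  dat <- labelled |>
    dplyr::filter(.data$label %in% c("NMI_CS", "SVB")) |>
    dplyr::inner_join(contexts, by = c("canton_id", "year"))
  if (nrow(dat) == 0) {
    stop("no NMI_CS/SVB records with a matching canton-year context",
      call. = FALSE
    )
  }
  vars <- c(
    midwives_per_1000_births = "midwives_per_1000_births",
    nursing_staff_per_bed = "nursing_staff_per_bed",
    income_per_capita_chf = "income_per_capita_chf"
  )
  rows <- lapply(names(vars), function(v) {
    a <- dat[[v]][dat$label == "NMI_CS"]
    b <- dat[[v]][dat$label == "SVB"]
    tt <- welch_t_test(a, b, pooled = pooled)
    tibble::tibble(
      variable = v, mean_nmi_cs = tt$mean_a, mean_svb = tt$mean_b,
      t = tt$t, df = tt$df, p = tt$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Income-insurance rank correlation in a labelled cohort
#'
#' Spearman rank correlation between person-level annual income per
#' capita (the woman's canton-year value) and ordinal insurance class
#' (mandatory = 0, semi-private = 1, private = 2), over NMI_CS and SVB
#' records.
#'
#' @inheritParams metric_table
#' @return list with `r_s` and `p` (see [spearman_cor()]).
#' @export
income_insurance_correlation <- function(labelled, contexts) {
  dat <- labelled |>
    dplyr::filter(.data$label %in% c("NMI_CS", "SVB")) |>
    dplyr::inner_join(contexts, by = c("canton_id", "year"))
  code <- match(dat$insurance, insurance_levels()) - 1L
  spearman_cor(dat$income_per_capita_chf, code)
}
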