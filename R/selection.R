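#' Cohort label values
#'
#' The closed set of classification outcomes of the selection algorithm:
#' `NMI_CS` (non-medically indicated caesarean section), `SVB`
#' (uncomplicated spontaneous vaginal birth), and the three exclusion
#' reasons in gate order.
#'
#' @return character vector of the five labels.
#' @export
cohort_labels <- function() {
  c(
    "SVB", "EXCLUDED_NON_TARGET_DRG", "EXCLUDED_DIAGNOSIS",
    "EXCLUDED_EMERGENCY", "NMI_CS"
  )
}

split_codes <- function(field) {
  if (length(field) == 1) {
    out <- strsplit(canonicalize_code(field), ";", fixed = TRUE)[[1]]
    return(out[nzchar(out)])
  }
  lapply(strsplit(canonicalize_code(field), ";", fixed = TRUE), function(x) {
    x[nzchar(x)]
  })
}

#' Classify one discharge record
#'
#' Applies the selection gates in fixed order: (1) the year's SVB DRG
#' gives `SVB`; (2) any DRG other than the year's low-complexity CS
#' candidate gives `EXCLUDED_NON_TARGET_DRG`; (3) any coded diagnosis
#' (principal or secondary) matching the diagnosis exclusion patterns
#' gives `EXCLUDED_DIAGNOSIS`; (4) any procedure matching the emergency
#' patterns gives `EXCLUDED_EMERGENCY`; (5) otherwise `NMI_CS`. The first
#' failing gate wins, so exclusion reasons are mutually exclusive.
#'
#' @param rec a single discharge record: a list or one-row data frame
#'   with at least `year`, `drg`, `icd_codes`, `chop_codes` (code fields
#'   may be character vectors or ";"-separated strings).
#' @param cb codebook (default [default_codebook()]).
#' @return one of [cohort_labels()].
#' @export
classify_record <- function(rec, cb = default_codebook()) {
  year <- as.integer(rec$year[[1]])
  check_year(year)
  drg <- canonicalize_code(rec$drg[[1]])
  if (drg == unname(cb$svb_drg_by_year[as.character(year)])) {
    return("SVB")
  }
  if (drg != unname(cb$cs_candidate_drg_by_year[as.character(year)])) {
    return("EXCLUDED_NON_TARGET_DRG")
  }
  icd <- unlist(split_codes(paste(unlist(rec$icd_codes), collapse = ";")))
  if (matches_any(icd, cb$icd_exclusions)) {
    return("EXCLUDED_DIAGNOSIS")
  }
  chop <- unlist(split_codes(paste(unlist(rec$chop_codes), collapse = ";")))
  if (matches_any(chop, cb$chop_emergency)) {
    return("EXCLUDED_EMERGENCY")
  }
  "NMI_CS"
}

# Vectorized gate cascade; semantically identical to classify_record()
# applied row-wise (enforced by an oracle test).
classify_cohort <- function(records, cb) {
  check_year(records$year)
  yr <- as.character(records$year)
  drg <- canonicalize_code(records$drg)
  svb <- unname(cb$svb_drg_by_year[yr])
  cand <- unname(cb$cs_candidate_drg_by_year[yr])
  label <- rep("NMI_CS", nrow(records))
  dx <- match_field(records$icd_codes, cb$icd_exclusions)
  em <- match_field(records$chop_codes, cb$chop_emergency)
  label[em] <- "EXCLUDED_EMERGENCY"
  label[dx] <- "EXCLUDED_DIAGNOSIS"
  label[drg != cand] <- "EXCLUDED_NON_TARGET_DRG"
  label[drg == svb] <- "SVB"
  label
}

#' Label a batch of discharge records
#'
#' Applies [classify_record()] to every record and tallies the labels.
#' No record is dropped: the tally covers all five labels and sums to
#' the number of records.
#'
#' @param records tibble of discharge records (columns `record_id`,
#'   `year`, `drg`, `icd_codes`, `chop_codes`, ...).
#' @param cb codebook.
#' @return a list with `records` (input plus a `label` column) and
#'   `tally` (named integer vector over [cohort_labels()]).
#' @export
build_cohort <- function(records, cb = default_codebook()) {
  if (nrow(records) == 0) {
    stop("records must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record_id in input", call. = FALSE)
  }
  cb <- validate_codebook(cb)
  labelled <- dplyr::mutate(records, label = classify_cohort(records, cb))
  tally <- vapply(
    cohort_labels(), function(l) sum(labelled$label == l), integer(1)
  )
  list(records = labelled, tally = tally)
}

#' Round half away from zero at a given number of decimals
#'
#' The printed tables round half-up (5 rounds away from zero), unlike
#' R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Annual summary arithmetic from per-year counts
#'
#' Computes, per year, the caesarean share of births, the
#' non-medically-indicated share of CS and of births, and the SVB share
#' of births, as percentages rounded half-up to 2 decimals; appends an
#' `Average` row (count columns: floor of total/number of years;
#' percentage columns: arithmetic mean of the annual percentages, rounded
#' half-up to 2 decimals) and a `Total` row (column sums, percentage
#' columns NA). Years with zero births get NA ratios.
#'
#' @param counts tibble with columns `year`, `n_births`, `n_cs`,
#'   `n_nmi_cs`, `n_svb` (e.g. [swiss_annual_births()]).
#' @return a tibble with character `year` ("2014", ..., "Average",
#'   "Total") and columns `n_births`, `n_cs`, `n_nmi_cs`, `n_svb`,
#'   `pct_cs_of_births`, `pct_nmi_of_cs`, `pct_nmi_of_births`,
#'   `pct_svb_of_births`.
#' @export
summarize_annual_counts <- function(counts) {
  need <- c("year", "n_births", "n_cs", "n_nmi_cs", "n_svb")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- dplyr::arrange(counts, .data$year)
  bad <- counts$n_nmi_cs > counts$n_cs | counts$n_cs > counts$n_births
  if (any(bad, na.rm = TRUE)) {
    stop("count invariant violated: need n_nmi_cs <= n_cs <= n_births",
      call. = FALSE
    )
  }
  pct <- function(num, den) {
    ifelse(den > 0, round_half_up(100 * num / den, 2), NA_real_)
  }
  annual <- dplyr::mutate(
    counts,
    year = as.character(.data$year),
    pct_cs_of_births = pct(.data$n_cs, .data$n_births),
    pct_nmi_of_cs = pct(.data$n_nmi_cs, .data$n_cs),
    pct_nmi_of_births = pct(.data$n_nmi_cs, .data$n_births),
    pct_svb_of_births = pct(.data$n_svb, .data$n_births)
  )
  n_years <- nrow(annual)
  cnt_cols <- c("n_births", "n_cs", "n_nmi_cs", "n_svb")
  pct_cols <- grep("^pct_", names(annual), value = TRUE)
  totals <- vapply(annual[cnt_cols], sum, numeric(1))
  avg <- c(
    list(year = "Average"),
    as.list(floor(totals / n_years)),
    lapply(annual[pct_cols], function(p) round_half_up(mean(p), 2))
  )
  tot <- c(
    list(year = "Total"),
    as.list(totals),
    setNames(rep(list(NA_real_), length(pct_cols)), pct_cols)
  )
  dplyr::bind_rows(annual, tibble::as_tibble(avg), tibble::as_tibble(tot))
}

#' Annual summary of a labelled cohort
#'
#' Counts, per year: all records (`n_births`), records whose DRG matches
#' the CS prefix set (`n_cs`), records labelled `NMI_CS` and `SVB`; then
#' applies the ratio/average arithmetic of [summarize_annual_counts()].
#'
#' @param labelled labelled records from [build_cohort()].
#' @param cb codebook.
#' @return see [summarize_annual_counts()].
#' @export
annual_summary <- function(labelled, cb = default_codebook()) {
  if (!"label" %in% names(labelled)) {
    stop("labelled must carry a 'label' column (see build_cohort())",
      call. = FALSE
    )
  }
  cb <- validate_codebook(cb)
  is_cs <- match_field(labelled$drg, paste0(cb$cs_all_drg_prefixes, "*"))
  counts <- labelled |>
    dplyr::mutate(is_cs = is_cs) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_births = dplyr::n(),
      n_cs = sum(.data$is_cs),
      n_nmi_cs = sum(.data$label == "NMI_CS"),
      n_svb = sum(.data$label == "SVB"),
      .groups = "drop"
    )
  summarize_annual_counts(counts)
}
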