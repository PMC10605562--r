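# djb2-style rolling hash (mod 2^31-1), used to stamp outputs with a
# short config fingerprint; not cryptographic.
config_hash <- function(x) {
  s <- yaml::as.yaml(x)
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(seed, hash) {
  c(
    paste0("# nmics ", as.character(utils::packageVersion("nmics"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", hash)
  )
}

#' Write a table as CSV with a provenance header
#'
#' Prepends comment lines carrying the package version, the run seed and
#' a short config hash, so two runs with identical configuration produce
#' byte-identical files.
#'
#' @param df data frame.
#' @param path destination path.
#' @param seed run seed recorded in the header.
#' @param hash config hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, seed, hash) {
  lines <- c(
    output_header(seed, hash),
    sub("\n$", "", readr::format_csv(df))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a CSV written by [write_output_csv()]
#'
#' @param path file path.
#' @return a tibble (header comment lines are skipped).
#' @export
read_output_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Assemble a run configuration
#'
#' @param generator a [generator_config()] (used by [run_simulate()] and
#'   by [run_all()] when simulating).
#' @param codebook a codebook or a path to a codebook file.
#' @param seed top-level seed; overrides the generator's.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       codebook = default_codebook(),
                       seed = generator$seed) {
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  generator$seed <- as.integer(seed)
  structure(
    list(
      generator = validate_generator_config(generator),
      codebook = validate_codebook(codebook),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Simulate a cohort and write it to disk
#'
#' Writes `records.csv`, `contexts.csv`, `truth.csv` and a
#' `manifest.yaml` (seed, config hash, record count, package version)
#' into `out_dir`. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list returned by [generate_cohort()].
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "run_config")) {
    stop("config must be a run_config()", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  hash <- config_hash(list(
    generator = unclass(config$generator), codebook = unclass(config$codebook)
  ))
  sim <- generate_cohort(config$generator, config$codebook)
  write_output_csv(
    sim$records, file.path(out_dir, "records.csv"), config$seed, hash
  )
  write_output_csv(
    sim$contexts, file.path(out_dir, "contexts.csv"), config$seed, hash
  )
  write_output_csv(
    sim$truth, file.path(out_dir, "truth.csv"), config$seed, hash
  )
  manifest <- list(
    package = "nmics",
    version = as.character(utils::packageVersion("nmics")),
    seed = config$seed,
    config_hash = hash,
    n_records = nrow(sim$records)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(sim)
}

#' Run the full analysis pipeline and write every stage's table
#'
#' Selection (labelled cohort + exclusion tally), the annual summary,
#' the categorical and metric descriptive tables, the income-insurance
#' correlation, and the logistic birth-mode fit report (coefficients on
#' the log-odds scale with Wald 95% intervals, plus an AUC line) are
#' written as headered CSVs into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param records,contexts either in-memory tables or paths to CSVs
#'   written by [run_simulate()]; when `NULL`, a fresh simulation is run
#'   from `config$generator`.
#' @return invisibly, a list with all stage results (`selection`,
#'   `annual`, `categorical`, `metric`, `correlation`, `fit`).
#' @export
run_all <- function(config, out_dir, records = NULL, contexts = NULL) {
  if (!inherits(config, "run_config")) {
    stop("config must be a run_config()", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(records)) records <- read_output_csv(records)
  if (is.character(contexts)) contexts <- read_output_csv(contexts)
  if (is.null(records) || is.null(contexts)) {
    sim <- generate_cohort(config$generator, config$codebook)
    records <- sim$records
    contexts <- sim$contexts
  }
  records$icd_codes[is.na(records$icd_codes)] <- ""
  records$chop_codes[is.na(records$chop_codes)] <- ""
  hash <- config_hash(list(
    generator = unclass(config$generator), codebook = unclass(config$codebook)
  ))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sel <- stage("selection", build_cohort(records, config$codebook))
  annual <- stage("annual_summary", annual_summary(sel$records, config$codebook))
  cat_tab <- stage("categorical_table", categorical_table(sel$records))
  met_tab <- stage("metric_table", metric_table(sel$records, contexts))
  corr <- stage(
    "correlation", income_insurance_correlation(sel$records, contexts)
  )
  dat <- sel$records |>
    dplyr::filter(.data$label %in% c("NMI_CS", "SVB")) |>
    dplyr::inner_join(contexts, by = c("canton_id", "year"))
  design <- stage("build_design", build_design(dat))
  fit <- stage("fit_logistic", fit_logistic(design$X, design$y))

  w <- function(df, file) {
    write_output_csv(df, file.path(out_dir, file), config$seed, hash)
  }
  w(
    dplyr::select(sel$records, "record_id", "label"),
    "labelled_cohort.csv"
  )
  w(
    tibble::tibble(label = names(sel$tally), n = unname(sel$tally)),
    "exclusion_tally.csv"
  )
  w(annual, "annual_summary.csv")
  w(cat_tab, "categorical_table.csv")
  w(
    dplyr::mutate(met_tab, p = format(.data$p, digits = 3, scientific = TRUE)),
    "metric_table.csv"
  )
  w(
    tibble::tibble(
      statistic = c("spearman_r_s", "p_value"),
      value = c(corr$r_s, corr$p)
    ),
    "income_insurance_correlation.csv"
  )
  fit_report <- dplyr::bind_rows(
    dplyr::select(
      fit$coefficients, "term", "estimate", "ci_low", "ci_high", "p"
    ),
    tibble::tibble(
      term = "AUC", estimate = fit$auc,
      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_
    )
  )
  w(fit_report, "fit_report.csv")
  log_lines <- c(
    output_header(config$seed, hash),
    paste0("# records: ", nrow(records)),
    paste0("# tally: ", paste(names(sel$tally), sel$tally,
      sep = "=", collapse = " "
    )),
    paste0(
      "# fit: converged=", fit$converged, " iterations=", fit$iterations,
      " auc=", format(fit$auc, digits = 6)
    )
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(
    selection = sel, annual = annual, categorical = cat_tab,
    metric = met_tab, correlation = corr, fit = fit
  ))
}
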