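#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data .env
#' @importFrom stats plogis qlogis qnorm pnorm pt rbinom rnorm runif
#'   setNames uniroot integrate dnorm rank cor sd var
#' @importFrom utils head modifyList
NULL

STUDY_YEARS <- 2014:2018

#' Canonicalize a clinical code
#'
#' Upper-cases and strips surrounding whitespace; dots (ICD-10-GM / CHOP
#' notation) are preserved. Canonicalization is idempotent.
#'
#' @param x character vector of DRG / ICD-10-GM / CHOP codes.
#' @return character vector in canonical form.
#' @export
canonicalize_code <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Default codebook for the 2014-2018 birth-mode selection algorithm
#'
#' Returns the built-in code sets driving cohort selection:
#' the year-specific low-complexity caesarean-section DRG
#' (O01F 2014-2016, O01G 2017, O01H 2018), the uncomplicated
#' spontaneous-vaginal-birth DRG (O60D for all years), the DRG prefix set
#' identifying any caesarean section ("O01"), and the diagnosis/procedure
#' exclusion pattern sets.
#'
#' The shipped exclusion lists are PLACEHOLDERS: a small, clearly
#' documented set of ICD-10-GM categories incompatible with a
#' non-medically indicated CS (malpresentation O32, obstructed labour
#' O64-O66, placenta praevia O44, cephalopelvic disproportion O33) and a
#' placeholder CHOP pattern for emergency-CS procedure features. They are
#' not the study's official exclusion catalogue; real analyses must
#' supply their own lists via [read_codebook()] or by editing the fields.
#'
#' Pattern semantics: an entry suffixed `"*"` or written without a dot is
#' a prefix (ICD category) pattern; a fully dotted entry matches exactly.
#'
#' @return an object of class `nmics_codebook` (a named list with fields
#'   `cs_candidate_drg_by_year`, `svb_drg_by_year`, `cs_all_drg_prefixes`,
#'   `icd_exclusions`, `chop_emergency`).
#' @examples
#' cb <- default_codebook()
#' cb$cs_candidate_drg_by_year[["2017"]]  # "O01G"
#' @export
default_codebook <- function() {
  cb <- list(
    cs_candidate_drg_by_year = c(
      "2014" = "O01F", "2015" = "O01F", "2016" = "O01F",
      "2017" = "O01G", "2018" = "O01H"
    ),
    svb_drg_by_year = c(
      "2014" = "O60D", "2015" = "O60D", "2016" = "O60D",
      "2017" = "O60D", "2018" = "O60D"
    ),
    cs_all_drg_prefixes = "O01",
    # placeholder diagnosis exclusions (categories => prefix semantics)
    icd_exclusions = c("O32", "O33", "O44", "O64", "O65", "O66"),
    # placeholder emergency-CS procedure feature pattern
    chop_emergency = c("74.99*")
  )
  class(cb) <- "nmics_codebook"
  validate_codebook(cb)
}

#' Validate a codebook
#'
#' Checks the structural invariants: the year maps each cover exactly
#' 2014-2018 with one code per year, the CS candidate differs from the
#' SVB code in every year, every CS candidate matches one of the CS DRG
#' prefixes, and all codes are stored canonically.
#'
#' @param cb a codebook list.
#' @return the validated codebook (canonicalized), invisibly classed
#'   `nmics_codebook`.
#' @export
validate_codebook <- function(cb) {
  required <- c(
    "cs_candidate_drg_by_year", "svb_drg_by_year",
    "cs_all_drg_prefixes", "icd_exclusions", "chop_emergency"
  )
  missing <- setdiff(required, names(cb))
  if (length(missing) > 0) {
    stop("codebook is missing field(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in c("cs_candidate_drg_by_year", "svb_drg_by_year")) {
    yrs <- suppressWarnings(as.integer(names(cb[[f]])))
    if (anyNA(yrs) || !setequal(yrs, STUDY_YEARS) ||
      length(yrs) != length(STUDY_YEARS)) {
      stop(
        f, " must map exactly the years ",
        min(STUDY_YEARS), "-", max(STUDY_YEARS),
        " with one code per year",
        call. = FALSE
      )
    }
    cb[[f]] <- setNames(
      canonicalize_code(cb[[f]]),
      as.character(yrs)
    )[as.character(STUDY_YEARS)]
  }
  for (f in c("cs_all_drg_prefixes", "icd_exclusions", "chop_emergency")) {
    cb[[f]] <- canonicalize_code(cb[[f]])
  }
  if (any(cb$cs_candidate_drg_by_year == cb$svb_drg_by_year)) {
    stop("CS candidate code equals SVB code for at least one year",
      call. = FALSE
    )
  }
  cand_ok <- vapply(
    cb$cs_candidate_drg_by_year,
    function(code) matches_any(code, cb$cs_all_drg_prefixes),
    logical(1)
  )
  if (!all(cand_ok)) {
    stop("every CS candidate DRG must match a prefix in cs_all_drg_prefixes",
      call. = FALSE
    )
  }
  class(cb) <- "nmics_codebook"
  cb
}

# Split a pattern set into exact codes and prefixes.
# "*"-suffixed or dot-free entries are prefixes; dotted entries are exact.
compile_patterns <- function(patterns) {
  patterns <- canonicalize_code(patterns)
  starred <- endsWith(patterns, "*")
  body <- sub("\\*$", "", patterns)
  is_prefix <- starred | !grepl(".", body, fixed = TRUE)
  list(exact = body[!is_prefix], prefix = body[is_prefix])
}

#' Test whether any code matches a pattern set
#'
#' Shared matcher for the diagnosis and procedure exclusion gates. A code
#' matches a pattern if it equals it exactly or begins with it when the
#' pattern has prefix semantics (suffixed `"*"`, or written without a dot,
#' i.e. an ICD category). Matching is case-insensitive via
#' [canonicalize_code()].
#'
#' @param codes character vector of clinical codes (may be empty).
#' @param patterns character vector of patterns (may be empty).
#' @return `TRUE` iff some code matches some pattern.
#' @examples
#' matches_any("O32.1", "O32") # TRUE: category prefix
#' matches_any("O80", character(0)) # FALSE
#' @export
matches_any <- function(codes, patterns) {
  codes <- canonicalize_code(codes)
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0 || length(patterns) == 0) {
    return(FALSE)
  }
  pat <- compile_patterns(patterns)
  if (length(pat$exact) > 0 && any(codes %in% pat$exact)) {
    return(TRUE)
  }
  for (p in pat$prefix) {
    if (any(startsWith(codes, p))) {
      return(TRUE)
    }
  }
  FALSE
}

# Regex over ";"-joined code fields, vectorized across records; the
# per-record matches_any() is the reference semantics (kept equivalent by
# an oracle test).
pattern_regex <- function(patterns) {
  pat <- compile_patterns(patterns)
  esc <- function(x) gsub("([^A-Za-z0-9])", "\\\\\\1", x)
  alts <- c(
    if (length(pat$exact) > 0) paste0(esc(pat$exact), "(;|$)"),
    if (length(pat$prefix) > 0) esc(pat$prefix)
  )
  if (length(alts) == 0) {
    return(NA_character_)
  }
  paste0("(^|;)(", paste(alts, collapse = "|"), ")")
}

match_field <- function(field, patterns) {
  rx <- pattern_regex(patterns)
  if (is.na(rx)) {
    return(rep(FALSE, length(field)))
  }
  grepl(rx, canonicalize_code(field))
}

check_year <- function(year) {
  if (any(!year %in% STUDY_YEARS)) {
    stop("year must lie in ", min(STUDY_YEARS), "-", max(STUDY_YEARS),
      call. = FALSE
    )
  }
  invisible(year)
}

#' Is a DRG the year's candidate low-complexity CS code?
#'
#' @param code DRG code (scalar or vector).
#' @param year calendar year in 2014-2018 (recycled against `code`).
#' @param cb codebook, by default [default_codebook()].
#' @return logical vector.
#' @export
is_cs_candidate_drg <- function(code, year, cb = default_codebook()) {
  check_year(year)
  canonicalize_code(code) == unname(cb$cs_candidate_drg_by_year[as.character(year)])
}

#' Is a DRG the year's uncomplicated spontaneous-vaginal-birth code?
#'
#' @inheritParams is_cs_candidate_drg
#' @return logical vector.
#' @export
is_svb_drg <- function(code, year, cb = default_codebook()) {
  check_year(year)
  canonicalize_code(code) == unname(cb$svb_drg_by_year[as.character(year)])
}

#' Read a codebook from a JSON or YAML file
#'
#' The document must provide `cs_candidate_drg_by_year` and
#' `svb_drg_by_year` as year-to-code maps and may provide
#' `cs_all_drg_prefixes`, `icd_exclusions` and `chop_emergency`; missing
#' exclusion sections fall back to the built-in placeholder lists with a
#' warning. Exclusion entries may be suffixed `"*"` for prefix semantics.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated `nmics_codebook`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) {
    stop("codebook file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) {
    stop("codebook file must contain a mapping of fields", call. = FALSE)
  }
  defaults <- default_codebook()
  for (f in c("cs_all_drg_prefixes", "icd_exclusions", "chop_emergency")) {
    if (is.null(raw[[f]])) {
      warning("codebook field '", f, "' missing; using built-in placeholder",
        call. = FALSE
      )
      raw[[f]] <- defaults[[f]]
    }
  }
  for (f in c("cs_candidate_drg_by_year", "svb_drg_by_year")) {
    if (is.null(raw[[f]])) {
      stop("codebook file lacks required field '", f, "'", call. = FALSE)
    }
    raw[[f]] <- unlist(raw[[f]])
  }
  validate_codebook(raw[c(
    "cs_candidate_drg_by_year", "svb_drg_by_year",
    "cs_all_drg_prefixes", "icd_exclusions", "chop_emergency"
  )])
}

#' Write a codebook to a JSON or YAML file
#'
#' @param cb a validated codebook.
#' @param path destination; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  cb <- validate_codebook(cb)
  out <- lapply(unclass(cb), function(x) as.list(x))
  out$cs_all_drg_prefixes <- unlist(out$cs_all_drg_prefixes)
  out$icd_exclusions <- unlist(out$icd_exclusions)
  out$chop_emergency <- unlist(out$chop_emergency)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
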