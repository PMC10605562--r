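# Stage 2: identify non-medically indicated CS and uncomplicated SVB.
#
# The gate cascade mirrors the published selection flowchart: SVB DRG,
# year-specific low-complexity CS DRG, diagnosis exclusions, emergency
# procedure exclusions. The annual summary reports the same ratio and
# average conventions as the published national table.
source("analysis/00_config.R")

cb <- default_codebook()
records <- read_output_csv(file.path(paths$sim, "records.csv"))
records$icd_codes[is.na(records$icd_codes)] <- ""
records$chop_codes[is.na(records$chop_codes)] <- ""

sel <- build_cohort(records, cb)
annual <- annual_summary(sel$records, cb)

dir.create(paths$cohort, recursive = TRUE, showWarnings = FALSE)
hash <- substr(format(study_seed), 1, 8)
write_output_csv(
  dplyr::select(sel$records, record_id, label),
  file.path(paths$cohort, "labelled_cohort.csv"), study_seed, hash
)
write_output_csv(
  annual, file.path(paths$cohort, "annual_summary.csv"), study_seed, hash
)

message("label tally:")
print(sel$tally)
message("annual summary:")
print(as.data.frame(annual), digits = 4)
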