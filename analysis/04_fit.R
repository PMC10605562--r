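# Stage 4: logistic regression of birth mode and parameter recovery.
#
# Fits NMI_CS vs SVB on age category, insurance class, urbanity and the
# cantonal covariates by IRLS, reports log-odds coefficients with Wald
# 95% intervals and the ROC AUC, and compares every estimate with the
# generating (published) coefficient.
source("analysis/00_config.R")

records <- read_output_csv(file.path(paths$sim, "records.csv"))
records$icd_codes[is.na(records$icd_codes)] <- ""
records$chop_codes[is.na(records$chop_codes)] <- ""
contexts <- read_output_csv(file.path(paths$sim, "contexts.csv"))

sel <- build_cohort(records)
dat <- sel$records |>
  dplyr::filter(label %in% c("NMI_CS", "SVB")) |>
  dplyr::inner_join(contexts, by = c("canton_id", "year"))
design <- build_design(dat)
fit <- fit_logistic(design$X, design$y)

truth <- nmics:::true_model_vector(published_birthmode_model())
comparison <- fit$coefficients |>
  dplyr::mutate(
    truth = unname(truth[term]),
    z_vs_truth = (estimate - truth) / se
  ) |>
  dplyr::select(term, truth, estimate, se, ci_low, ci_high, z_vs_truth, p)

dir.create(paths$model, recursive = TRUE, showWarnings = FALSE)
hash <- substr(format(study_seed), 1, 8)
write_output_csv(
  comparison, file.path(paths$model, "fit_vs_truth.csv"), study_seed, hash
)

message("fit on ", nrow(dat), " records; converged: ", fit$converged)
print(as.data.frame(comparison), digits = 3)
message(sprintf("AUC = %.4f", fit$auc))
message(sprintf(
  "max |z vs generating truth| = %.2f",
  max(abs(comparison$z_vs_truth))
))
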