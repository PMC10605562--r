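# Stage 1: draw the synthetic claims cohort.
#
# The generator embeds the published logistic birth-mode model as ground
# truth: every clean record's probability of a non-medically indicated
# CS follows the published log-odds coefficients evaluated on its
# covariates, and its DRG is assigned accordingly. A tenth of records
# are routed through the contamination channels (emergency CS, excluded
# diagnoses, other CS DRGs) so the selection stage has real work to do.
source("analysis/00_config.R")

cfg <- run_config(
  generator = generator_config(
    n_records = study_n, seed = study_seed,
    contamination = c(emergency = 0.04, diagnosis = 0.02, other_drg = 0.04)
  )
)
sim <- run_simulate(cfg, paths$sim)

message("wrote ", nrow(sim$records), " records to ", paths$sim)
message(
  "generating channels: ",
  paste(names(table(sim$truth$channel)), table(sim$truth$channel),
    sep = "=", collapse = "  "
  )
)
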