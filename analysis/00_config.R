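# Shared study configuration for the analysis scripts. One top-level
# seed drives every stage; the cohort size keeps each script in seconds
# while leaving Monte-Carlo error well below the effects of interest.
library(nmics)

study_seed <- 20140101
study_n <- 200000

study_config <- function() {
  run_config(
    generator = generator_config(n_records = study_n, seed = study_seed),
    codebook = default_codebook(),
    seed = study_seed
  )
}

paths <- list(
  sim = "results/simulation",
  cohort = "results/cohort",
  descriptives = "results/descriptives",
  model = "results/model"
)
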