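#!/usr/bin/env Rscript
# Step 4 — prognostic modelling.
#
# On the cohort from step 3: univariate Cox screen of the imaging features,
# backward-selected models for NPI alone, imaging alone, and the compound
# NPI + imaging model; Harrell's C for each; bootstrap CI on the concordance
# gain. Writes results/models.json and results/screen.csv.

suppressMessages(library(vavmri))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/cohort.csv")) {
  stop("run analysis/03_simulate_cohort.R first")
}

rep_out <- prognostic_report("results/cohort.csv",
                             run_config(seed = seed + 2L), n_boot = 200)
write_report_json(rep_out, "results/models.json")
write.csv(rep_out$screen$table, "results/screen.csv", row.names = FALSE)

message("compound model:")
print(rep_out$model_npi_vav)
message(sprintf("Harrell's C: NPI %.1f%%, imaging %.1f%%, compound %.1f%% (gain %.1f%%, 95%% CI %.1f to %.1f)",
                100 * rep_out$concordance["npi"],
                100 * rep_out$concordance["vav"],
                100 * rep_out$concordance["npi_vav"],
                100 * rep_out$delta_c$estimate,
                100 * rep_out$delta_c$ci[1], 100 * rep_out$delta_c$ci[2]))
message("wrote results/models.json and results/screen.csv")
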