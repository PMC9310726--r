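#!/usr/bin/env Rscript

# Step 1: generate the two synthetic datasets the downstream analyses run
# on, and write them (plus a manifest) under results/.
#
# Sleep dataset — signal mode: three cats, three cortices (dorsolateral
# prefrontal, posterior parietal, and a deliberately state-flat
# somatosensory cortex), four vigilance states, 300 s (60 five-second
# epochs) per cell at 1024 Hz. The full chain runs here: synthesis ->
# 0.5-200 Hz band-pass -> segmentation -> artifact screening -> per-epoch
# normalized LZ78 complexity.
#
# Dose dataset — direct-value mode: three "cortices" with different true
# dose-response families (inverted-U, linear, U), five cats, doses
# 0/5/10/15 mg/kg, four sessions per dose, 60 epochs per cell; plus a
# stimulated variant of the inverted-U cortex for the stimulation model.

suppressPackageStartupMessages(library(neurolz))

dir.create("results", showWarnings = FALSE)

## sleep -----------------------------------------------------------------
sleep_cfg <- synth_config("sleep",
                          cortices = c("r_dlPf", "r_Pp", "r_S1"),
                          flat_cortices = "r_S1",
                          seed = 1234L)
message("generating signal-mode sleep dataset (3 cats x 3 cortices x 4 states) ...")
sleep_ds <- gen_sleep_dataset(sleep_cfg)
write.csv(sleep_ds$complexity, "results/sleep_complexity.csv", row.names = FALSE)
write.csv(sleep_ds$rejection_log, "results/sleep_rejection_log.csv",
          row.names = FALSE)
message("  ", nrow(sleep_ds$complexity), " epochs kept, ",
        sum(!sleep_ds$rejection_log$kept), " rejected")

## dose ------------------------------------------------------------------
message("generating direct-value dose datasets ...")
dose_cfg <- synth_config("dose", seed = 1234L)
shapes <- c(r_dlPf = "inverted_u", r_S1 = "linear", r_Pp = "u")
dose_tab <- do.call(rbind, lapply(names(shapes), function(cortex) {
  cfg <- synth_config("dose", seed = 1234L + match(cortex, names(shapes)))
  tab <- gen_dose_dataset(shapes[[cortex]], cfg)
  tab$channel <- cortex
  tab
}))
write.csv(dose_tab, "results/dose_values.csv", row.names = FALSE)

stim_tab <- gen_dose_dataset("inverted_u", dose_cfg, include_stim = TRUE)
stim_tab$channel <- "r_dlPf"
write.csv(stim_tab, "results/dose_stim_values.csv", row.names = FALSE)

jsonlite::write_json(
  list(sleep = unclass(sleep_cfg), dose = unclass(dose_cfg),
       dose_shapes = as.list(shapes)),
  "results/simulation_manifest.json", auto_unbox = TRUE, digits = NA)

message("per-state complexity means (pooled over cortices except r_S1):")
keep <- sleep_ds$complexity$channel != "r_S1"
print(round(tapply(sleep_ds$complexity$C[keep],
                   sleep_ds$complexity$state[keep], mean), 3))
message("done: results/sleep_complexity.csv, results/dose_values.csv, ",
        "results/dose_stim_values.csv")
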