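#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs -- weather, ground-truth
# seasons, NDVI observations, WaPOR-convention phenology dekads and
# reported regional yields -- for 10 regions x 5 grids x 20 pixels over
# 2017-2021, and write them under results/scenario/.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg <- analysis_config()
run_stage("scenario", cfg)

truth <- read.csv(file.path(cfg$outdir, "scenario", "truth.csv"))
cat("Scenario written to", file.path(cfg$outdir, "scenario"), "\n")
cat(sprintf("  %d grid-seasons; true yields %.0f-%.0f kg/ha (mean %.0f)\n",
            nrow(truth), min(truth$true_yield), max(truth$true_yield),
            mean(truth$true_yield)))
cat(sprintf("  true sowing days of year span %d-%d\n",
            min(truth$true_sowing_doy), max(truth$true_sowing_doy)))
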