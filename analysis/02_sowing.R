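#!/usr/bin/env Rscript
# Stage 2: grid-median SOS/MS/EOS dekads from the pixel phenology, then
# sowing-date retrieval (per-pixel harmonic fit, zero-gradient minimum
# before SOS, grid median). Prints recovery accuracy against the truth.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg <- analysis_config()
run_stage("lsp", cfg)
run_stage("sowing", cfg)

est <- read.csv(file.path(cfg$outdir, "sowing_estimates.csv"))
truth <- read.csv(file.path(cfg$outdir, "scenario", "truth.csv"))
m <- merge(est, truth, by.x = c("grid_id", "season_year"),
           by.y = c("grid_id", "year"))
err <- as.numeric(as.Date(m$sowing_date) -
                    (as.Date(sprintf("%d-01-01", m$season_year)) +
                       m$true_sowing_doy - 1))
cat(sprintf("Sowing recovery on %d grid-seasons:\n", nrow(m)))
cat(sprintf("  median |error| %.1f days; %.1f%% within +/-10 days; %.1f%% fallback\n",
            median(abs(err)), 100 * mean(abs(err) <= 10),
            100 * mean(m$method == "fallback")))
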