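#!/usr/bin/env Rscript
# Stage 4: evaluation tables -- peak-season phenology pairs and R^2,
# regional simulated-vs-reported yields, per-grid seasonal ET deviation,
# and the +/-30-day sowing-shift sensitivity table.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg <- analysis_config()
run_stage("evaluate", cfg)

ph <- read.csv(file.path(cfg$outdir, "phenology_pairs.csv"))
cat(sprintf("Peak-season phenology: R^2 = %.3f on %d pairs\n",
            r_squared(ph$sim_doy, ph$ms_doy), nrow(ph)))
yld <- read.csv(file.path(cfg$outdir, "regional_yield.csv"))
cat(sprintf("Regional yield agreement (pooled): r = %.3f on %d region-years\n",
            pearson_r(yld$simulated_yield, yld$observed_yield), nrow(yld)))
ed <- read.csv(file.path(cfg$outdir, "et_deviation.csv"))
cat(sprintf("Seasonal ET deviation: median |dev| %.2f%%; %.1f%% of grids beyond +/-20%%\n",
            median(abs(ed$deviation_pct)),
            100 * mean(abs(ed$deviation_pct) > 20)))
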