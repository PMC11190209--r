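# Shared setup for the analysis drivers: one pipeline configuration, so
# every stage reads and writes under results/ with the same seed.
library(phenosow)

analysis_config <- function(seed = 42, outdir = "results") {
  pipeline_config(outdir = outdir, seed = seed)
}
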