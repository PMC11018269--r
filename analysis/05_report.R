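#!/usr/bin/env Rscript
# Stage 5: trajectory figures (PNG + SVG) for each proxy's groups and the
# JSON manifest tying every table to the run's seed and config hash.
source("analysis/_config.R")
res <- run_pipeline(analysis_config(), stages = "report", resume = TRUE)
cat("manifest:\n")
cat(readLines(res$paths$manifest), sep = "\n")
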