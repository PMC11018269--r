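#!/usr/bin/env Rscript
# Stage 2: derive the analysis columns — standardized reserve proxies,
# sex-stratified ICV z-scores, baseline-BPF z-scores, mid/late-life age
# groups, tertile and education group labels, centered covariates.
source("analysis/_config.R")
run_pipeline(analysis_config(), stages = "preprocess", resume = TRUE)
cat("analysis table written to results/data/analysis.csv\n")
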