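#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic three-visit cohort with informative
# mortality and write it (plus its generating truth) under results/data/.
source("analysis/_config.R")
run_pipeline(analysis_config(), stages = "simulate", resume = TRUE)
cat("cohort written to results/data/cohort.csv\n")
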