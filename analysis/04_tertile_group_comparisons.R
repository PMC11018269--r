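#!/usr/bin/env Rscript
# Stage 4: multiple-group bivariate growth models over the low/mid/high
# tertiles of each reserve proxy (education: its three categories), with
# per-group dB and pairwise Wald equality tests (Table-3 analogue).
source("analysis/_config.R")
res <- run_pipeline(analysis_config(), stages = "compare-groups", resume = TRUE)
print(res$groups$table3, digits = 3)
cat("\nPairwise Wald comparisons:\n")
print(res$groups$wald, digits = 3)
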