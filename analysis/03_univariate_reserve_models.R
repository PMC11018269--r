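#!/usr/bin/env Rscript
# Stage 3: univariate memory growth models per reserve proxy, for the
# overall sample and the mid-life / late-life strata (Table-2 analogue),
# plus the bivariate memory-brain model fitted jointly with the
# discrete-time survival submodel (death-adjusted slopes, dB).
source("analysis/_config.R")
res <- run_pipeline(analysis_config(), stages = "fit", resume = TRUE)
print(res$fit$table2, digits = 3)
cat("\nBivariate joint model (death-adjusted):\n")
print(res$fit$bivariate, digits = 3)
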