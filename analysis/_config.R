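# Shared configuration for the numbered analysis scripts. Run every script
# from the repository root, e.g.  Rscript analysis/01_simulate.R
library(growsurv)

analysis_config <- function() {
  pipeline_config(
    output_dir = "results",
    # default calibrated scenario: three visits (0/4/12 y), memory declining
    # at -.085 SD/y and brain volume at -.137 SD/y, DART effects on the
    # memory intercept (.350) and slope (.008), informative mortality
    scenario = sim_scenario(n_subjects = 1000L),
    proxies = c("dart", "education", "icv", "bpf"),
    strata = c("overall", "mid-life", "late-life"),
    gh_points = 9L,
    seed = 20220905L
  )
}
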