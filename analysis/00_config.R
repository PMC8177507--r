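# Shared configuration for the analysis stages: the study's published
# group/stage methylation proportions and change rates, scaled to 2,000
# loci for a quick desk run. Sourced by the numbered stage scripts.

suppressPackageStartupMessages(library(epistates))

make_config <- function() {
  pipeline_config(
    simulation = default_study_config(n_loci = 2000, seed = 20260920),
    output_dir = "results/run",
    seed = 20260920)
}
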