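#!/usr/bin/env Rscript

# Stage 2: presence-filter the binned counts, collapse to binary
# methylation states, and score per-library methylation proportions,
# within-individual state transitions, and group-level change counts.
# Writes proportions.tsv, transitions.tsv and group_summary.json under
# results/run/.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

cfg <- make_config()
scored <- run_score(cfg)

cat("\nMean methylated proportion by group and stage:\n")
print(round(with(scored$proportions,
                 tapply(proportion, list(dispersal, stage), mean)), 3))
cat("\nMean changed fraction by group and transition:\n")
print(round(with(scored$transitions,
                 tapply(changed_fraction, list(dispersal, transition), mean)),
      3))
cat("\nMost loci are stable between consecutive stages: ",
    round(100 * mean(1 - scored$transitions$changed_fraction)),
    "% on average.\n", sep = "")
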