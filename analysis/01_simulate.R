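#!/usr/bin/env Rscript

# Stage 1: generate the synthetic epiRADseq experiment. Writes the count
# table, metadata, truth table and checksummed manifest under
# results/run/data/.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

cfg <- make_config()
out <- run_simulate(cfg)
ds <- out$dataset

cat("Simulated", length(ds$counts$samples), "libraries over",
    ds$config$n_loci, "loci (seed", cfg$seed, ").\n")
cat("Realized methylated fraction by group and stage:\n")
frac <- rowMeans(ds$truth_states == 0L)
print(round(tapply(frac, list(ds$meta$dispersal, ds$meta$stage), mean), 3))
cat("Files written under results/run/data/:\n")
for (f in out$manifest$files) cat("  ", f$path, "  md5 ", f$md5, "\n", sep = "")
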