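#!/usr/bin/env Rscript

# Stage 4: prior machinery. Prior predictive checks for both models (are
# the implied response ranges plausible before seeing data?) and the
# prior-sensitivity sweep over fixed-effect prior sd multipliers
# {0.25, 0.5, 1, 2, 5} plus a quasi-maximum-likelihood endpoint. Writes
# sensitivity_beta.tsv and sensitivity_binomial.tsv under results/run/.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

cfg <- make_config()

pp_beta <- prior_predictive(cfg$beta_spec, n_draws = 4000,
                            seed = cfg$seed + 2)
cat("Beta-model prior predictive 95% intervals per cell:\n")
print(as.data.frame(pp_beta$summary), digits = 3)

pp_bin <- prior_predictive(cfg$binomial_spec, n_draws = 4000,
                           seed = cfg$seed + 3)
cat("\nBinomial-model prior predictive 95% intervals per cell:\n")
print(as.data.frame(pp_bin$summary), digits = 3)
cat("\nFraction of prior draws with any theta > 1 under the log link:",
    round(pp_bin$frac_theta_gt1, 3),
    "\n(the tally that motivates constraining the sampler to theta <= 1)\n")

scored <- run_score(cfg)
sens <- run_sensitivity(cfg, scored)
cat("\nConvergence gate by multiplier (beta model):\n")
print(unique(sens$beta[, c("multiplier", "rhat_max", "converged")]),
      digits = 3)
ok <- !is.na(sens$beta$cell) & sens$beta$converged
cat("\nBeta-model cell-mean spread across gate-passing multipliers:\n")
print(round(tapply(sens$beta$cell_mean[ok], sens$beta$cell[ok],
                   function(v) diff(range(v))), 4))
cat("\nAt this sample size the likelihood dominates among gate-passing\n",
    "settings: the spread above is small relative to the posterior sds in\n",
    "stage 3. A very restrictive multiplier (0.25) fails the gate: a tight\n",
    "zero-centred prior on the cell coefficients opens a ridge in which the\n",
    "common methylation level migrates into the random intercepts, and the\n",
    "sweep records that row as non-converged rather than reporting it.\n",
    sep = "")
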