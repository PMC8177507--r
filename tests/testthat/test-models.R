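# fits here use reduced schedules where the check does not depend on the
# default four-chains-of-2000 study schedule

short_mcmc <- function(seed) {
  mcmc_config(n_iterations = 600, n_warmup = 300, seed = seed)
}

sim_tables <- function(seed, n_loci = 2000, n_ind = 4) {
  ds <- simulate_experiment(default_study_config(n_loci = n_loci,
                                                 n_individuals_per_group = n_ind,
                                                 seed = seed))
  st <- binarize(ds$counts)
  list(pr = proportion_methylated(st, ds$meta),
       tr = score_transitions(st, ds$meta))
}

test_that("beta GLMM cell means match glmmTMB at quasi-flat priors", {
  skip_if_not_installed("glmmTMB")
  tabs <- sim_tables(71)
  fit <- suppressWarnings(fit_beta_glmm(
    tabs$pr, beta_glmm_spec(prior_sd = 1000, re_scale = 1000),
    mcmc_config(seed = 72)))
  mine <- colMeans(cell_draws(fit))
  pr <- tabs$pr
  pr$cell <- paste(pr$dispersal, pr$stage, sep = ":")
  tm <- glmmTMB::glmmTMB(proportion ~ 0 + cell + (1 | individual_id),
                         family = glmmTMB::beta_family(), data = pr)
  ref <- plogis(glmmTMB::fixef(tm)$cond)
  names(ref) <- sub("^cell", "", names(ref))
  expect_equal(mine[names(ref)], ref, tolerance = 0.01)
})

test_that("binomial GLMM cell rates match a log-link glmer fit", {
  skip_if_not_installed("lme4")
  tabs <- sim_tables(73)
  fit <- suppressWarnings(fit_binomial_glmm(
    tabs$tr, binomial_glmm_spec(prior_sd = 1000, re_scale = 1000),
    mcmc_config(seed = 74)))
  mine <- colMeans(cell_draws(fit))
  tr <- tabs$tr
  tr$cell <- paste(tr$dispersal, tr$transition, sep = ":")
  g <- suppressMessages(lme4::glmer(
    cbind(n_changed, n_total - n_changed) ~ 0 + cell + (1 | individual_id),
    family = binomial(link = "log"), data = tr,
    start = list(fixef = rep(-1.5, 4), theta = 0.1)))
  ref <- exp(lme4::fixef(g))
  names(ref) <- sub("^cell", "", names(ref))
  expect_equal(mine[names(ref)], ref, tolerance = 0.01)
})

test_that("single-cell posterior tracks the analytic beta-likelihood maximum", {
  set.seed(81)
  y <- rbeta(12, 0.7 * 200, 0.3 * 200)
  data <- tibble::tibble(proportion = y,
                         individual_id = paste0("i", 1:12),
                         stage = "fledgling", dispersal = "disperser",
                         n_loci = 1000)
  fit <- suppressWarnings(fit_beta_glmm(data, beta_glmm_spec(),
                                        mcmc_config(seed = 82)))
  cm <- cell_draws(fit)
  phi_hat <- mean(exp(fit$draws[, , "log_phi"]))
  # independent 1-D maximization of the beta likelihood in mu at phi_hat
  ml <- optimise(function(mu)
    -sum(dbeta(y, mu * phi_hat, (1 - mu) * phi_hat, log = TRUE)),
    c(0.01, 0.99))$minimum
  expect_lt(abs(mean(cm) - ml), 2 * sd(cm))
})

test_that("parameter recovery holds at study-table rates", {
  tabs <- sim_tables(83)
  fit <- suppressWarnings(fit_beta_glmm(tabs$pr, beta_glmm_spec(),
                                        mcmc_config(seed = 84)))
  s <- summarize_posterior(fit)$cells
  truth <- c("disperser:hatchling" = 0.75, "disperser:fledgling" = 0.71,
             "disperser:adult" = 0.80, "philopatric:hatchling" = 0.77,
             "philopatric:fledgling" = 0.81, "philopatric:adult" = 0.74)
  expect_true(all(abs(s$mean[match(names(truth), s$cell)] - truth) < 0.03))
  fitb <- suppressWarnings(fit_binomial_glmm(tabs$tr, binomial_glmm_spec(),
                                             mcmc_config(seed = 85)))
  sb <- summarize_posterior(fitb)$cells
  truthb <- c("disperser:hatchling->fledgling" = 0.24,
              "philopatric:hatchling->fledgling" = 0.20)
  expect_true(all(abs(sb$mean[match(names(truthb), sb$cell)] - truthb) < 0.02))
})

test_that("a single all-zero response pins theta near zero (rule of three)", {
  one <- tibble::tibble(n_changed = 0L, n_total = 500L, individual_id = "a",
                        dispersal = "disperser",
                        transition = "hatchling->fledgling")
  fit <- suppressWarnings(fit_binomial_glmm(one, binomial_glmm_spec(),
                                            mcmc_config(seed = 86)))
  theta <- fitted_draws(fit)
  expect_lt(mean(theta), 3 / 500)
  expect_gt(mean(theta < 0.01), 0.9)
})

test_that("boundary proportions are shrunk off {0,1} with a warning", {
  data <- tibble::tibble(proportion = c(0, 0.5, 1, 0.4),
                         individual_id = c("a", "a", "b", "b"),
                         stage = c("hatchling", "fledgling",
                                   "hatchling", "fledgling"),
                         dispersal = "disperser", n_loci = 100L)
  expect_warning(fit_beta_glmm(data, beta_glmm_spec(), short_mcmc(87)),
                 "boundary proportions")
})

test_that("prior predictive draws respect the link constraints", {
  pp <- prior_predictive(beta_glmm_spec(), n_draws = 2000, seed = 91)
  expect_true(all(pp$draws > 0 & pp$draws < 1))
  expect_equal(nrow(pp$summary), 6)
  # shrinking the prior collapses cell means toward inverse-logit(0) = 0.5
  pp0 <- prior_predictive(beta_glmm_spec(prior_sd = 1e-6, re_scale = 1e-6),
                          n_draws = 2000, seed = 92)
  expect_true(all(abs(colMeans(pp0$draws) - 0.5) < 0.05))
  ppb <- prior_predictive(binomial_glmm_spec(), n_draws = 2000, seed = 93)
  # under N(0,1) priors a large share of prior mass breaks theta <= 1 —
  # the tally that motivates constraining the sampler
  expect_gt(ppb$frac_theta_gt1, 0.3)
  expect_true(all(ppb$draws >= 0 & ppb$draws <= 1))
})

test_that("prior sensitivity at multiplier 1 reproduces the base fit exactly", {
  tabs <- sim_tables(95, n_loci = 300, n_ind = 2)
  mc <- short_mcmc(96)
  base <- suppressWarnings(fit_beta_glmm(tabs$pr, beta_glmm_spec(), mc))
  tab <- suppressWarnings(prior_sensitivity(tabs$pr, beta_glmm_spec(), mc,
                                            multipliers = c(1, 2)))
  base_means <- colMeans(cell_draws(base))
  row1 <- tab[tab$multiplier == "1", ]
  expect_identical(setNames(row1$cell_mean, row1$cell), base_means)
  expect_true(all(c("1", "2") %in% tab$multiplier))
})

test_that("the ML endpoint and failure rows are recorded in the sweep", {
  tabs <- sim_tables(97, n_loci = 300, n_ind = 2)
  tab <- suppressWarnings(prior_sensitivity(tabs$pr, beta_glmm_spec(),
                                            short_mcmc(98),
                                            multipliers = c(1, Inf)))
  expect_true("ML" %in% tab$multiplier)
  expect_true(all(is.na(tab$error[tab$multiplier == "ML"])))
  # an unfittable input is recorded, not fatal
  bad <- tabs$pr[1, ]
  tab2 <- suppressWarnings(prior_sensitivity(bad, beta_glmm_spec(),
                                             short_mcmc(99),
                                             multipliers = c(1)))
  expect_false(any(tab2$converged))
  expect_true(any(!is.na(tab2$error)))
})

test_that("posterior sd of cell means shrinks as individuals double", {
  sds <- sapply(c(4, 8), function(n) {
    tabs <- sim_tables(101, n_loci = 500, n_ind = n)
    fit <- suppressWarnings(fit_beta_glmm(tabs$pr, beta_glmm_spec(),
                                          mcmc_config(seed = 102)))
    mean(summarize_posterior(fit)$cells$sd)
  })
  expect_lt(sds[2], sds[1])
})

test_that("the optional sex effect is estimable and near zero when absent", {
  tabs <- sim_tables(103, n_loci = 800, n_ind = 4)
  pr <- tabs$pr
  pr$sex <- rep(c("M", "F"), length.out = nrow(pr))
  fit <- suppressWarnings(fit_beta_glmm(pr, beta_glmm_spec(sex_effect = TRUE),
                                        mcmc_config(seed = 104)))
  b_sex <- fit$draws[, , "b_sex"]
  expect_lt(abs(mean(b_sex)), 0.2)
  expect_true("b_sex" %in% dimnames(fit$draws)[[3]])
})
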