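#' MCMC schedule configuration
#'
#' Defaults follow the study design: four chains of 2000 iterations each,
#' the first 1000 discarded as warmup, and a convergence gate requiring all
#' split R-hat values below 1.1.
#'
#' @param n_chains number of chains (>= 2, needed for R-hat).
#' @param n_iterations iterations per chain, including warmup.
#' @param n_warmup warmup iterations discarded from each chain.
#' @param seed integer RNG seed.
#' @param rhat_threshold convergence gate on split R-hat.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 2000, n_warmup = 1000,
                        seed = 1L, rhat_threshold = 1.1) {
  stopifnot(n_chains >= 2, n_warmup >= 0, n_warmup < n_iterations,
            rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

# Adaptive random-walk Metropolis over a model description.
#
# `model` is a list with:
#   par        named numeric init vector
#   lp(par)    total log posterior
#   scalar_idx indices updated one at a time via full-lp Metropolis
#   unit_idx   indices of conditionally independent unit effects (random
#              intercepts), updated jointly with elementwise accepts
#   unit_lp(par) per-unit log posterior contributions (likelihood rows of
#              that unit plus its own prior); must be the only part of lp
#              through which unit parameters enter
#   n_sweeps   optional updates-per-iteration multiplier (default 1); cheap
#              likelihoods afford extra sweeps to cut autocorrelation
#
# Proposal scales adapt during warmup toward 0.44 acceptance (the scalar
# random-walk optimum), then freeze.
run_mh_chains <- function(model, mcmc) {
  set.seed(mcmc$seed)
  n_par <- length(model$par)
  n_keep <- mcmc$n_iterations - mcmc$n_warmup
  draws <- array(NA_real_, c(n_keep, mcmc$n_chains, n_par),
                 dimnames = list(NULL, NULL, names(model$par)))
  accept <- numeric(n_par)
  for (chain in seq_len(mcmc$n_chains)) {
    par <- model$par + rnorm(n_par, 0, 0.1)  # jittered inits per chain
    if (!is.null(model$unit_idx)) par[model$unit_idx] <- 0
    cur_lp <- model$lp(par)
    if (!is.finite(cur_lp)) {
      par <- model$par
      cur_lp <- model$lp(par)
    }
    if (!is.finite(cur_lp))
      stop("non-finite log-posterior at initialization; parameters: ",
           paste(names(par), signif(par, 3), sep = "=", collapse = ", "))
    step <- rep(0.2, n_par)
    acc_win <- att_win <- numeric(n_par)
    cur_unit <- if (!is.null(model$unit_idx)) model$unit_lp(par)
    n_sweeps <- if (is.null(model$n_sweeps)) 1L else model$n_sweeps
    for (it in seq_len(mcmc$n_iterations)) {
      for (sweep in seq_len(n_sweeps)) {
      for (s in model$scalar_idx) {
        prop <- par
        prop[s] <- par[s] + rnorm(1, 0, step[s])
        prop_lp <- model$lp(prop)
        att_win[s] <- att_win[s] + 1
        if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
          par <- prop; cur_lp <- prop_lp
          acc_win[s] <- acc_win[s] + 1
          cur_unit <- NULL
        }
      }
      if (!is.null(model$unit_idx)) {
        ui <- model$unit_idx
        if (is.null(cur_unit)) cur_unit <- model$unit_lp(par)
        prop <- par
        prop[ui] <- par[ui] + rnorm(length(ui), 0, step[ui])
        prop_unit <- model$unit_lp(prop)
        ok <- is.finite(prop_unit) &
          log(runif(length(ui))) < prop_unit - cur_unit
        att_win[ui] <- att_win[ui] + 1
        if (any(ok)) {
          par[ui[ok]] <- prop[ui[ok]]
          cur_unit[ok] <- prop_unit[ok]
          acc_win[ui[ok]] <- acc_win[ui[ok]] + 1
          cur_lp <- model$lp(par)
        }
      }
      }
      if (it <= mcmc$n_warmup && it %% 25 == 0) {
        rate <- ifelse(att_win > 0, acc_win / att_win, 0.44)
        step <- step * exp(pmax(pmin(rate - 0.44, 0.5), -0.5))
        acc_win[] <- att_win[] <- 0
      }
      if (it > mcmc$n_warmup) draws[it - mcmc$n_warmup, chain, ] <- par
    }
  }
  draws
}

#' Split R-hat convergence diagnostic
#'
#' The potential-scale-reduction statistic computed on split chains: each
#' chain is halved, and R-hat compares between- and within-half variance.
#' Values near 1 indicate the chains have mixed; the conventional gate used
#' throughout this package is R-hat < 1.1. Zero-variance (constant)
#' parameters yield `NaN` with a warning.
#'
#' @param draws a matrix (iterations x chains) for one parameter, or a
#'   3-d array (iterations x chains x parameters).
#' @return A named numeric vector of R-hat values (scalar for a matrix).
#' @export
compute_rhat <- function(draws) {
  if (is.matrix(draws)) return(split_rhat_one(draws))
  stopifnot(length(dim(draws)) == 3)
  out <- vapply(seq_len(dim(draws)[3]),
                function(j) split_rhat_one(draws[, , j, drop = TRUE]),
                numeric(1))
  names(out) <- dimnames(draws)[[3]]
  out
}

split_rhat_one <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat requires at least 2 chains")
  n <- nrow(x)
  if (n < 4) stop("R-hat requires at least 2 post-warmup draws per half chain")
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat undefined (NaN)", call. = FALSE)
    return(NaN)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' A basic autocorrelation-based effective sample size: per-chain
#' autocorrelations are averaged, summed over Geyer's initial positive
#' sequence, and the total draw count is deflated accordingly.
#'
#' @param draws matrix (iterations x chains) or 3-d array as in
#'   [compute_rhat()].
#' @return Numeric ESS (named vector for an array).
#' @export
compute_ess <- function(draws) {
  if (is.matrix(draws)) return(ess_one(draws))
  out <- vapply(seq_len(dim(draws)[3]),
                function(j) ess_one(draws[, , j, drop = TRUE]), numeric(1))
  names(out) <- dimnames(draws)[[3]]
  out
}

ess_one <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (all(apply(x, 2, var) == 0)) return(NaN)
  max_lag <- min(n - 1, 200)
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    v <- x[, ch] - mean(x[, ch])
    ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    if (ac[1] <= 0) rep(0, max_lag + 1) else ac / ac[1]
  }, numeric(max_lag + 1)))
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  while (t + 2 <= max_lag + 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(n * m / tau, 1)
}
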