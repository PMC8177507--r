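#' Configure a synthetic epiRADseq experiment
#'
#' Defines the generative model for a methylation-sensitive restriction
#' enzyme experiment. Each individual carries a binary methylation state per
#' locus; a methylated cut site blocks digestion, so a methylated locus
#' yields no fragments (zero reads) and an unmethylated locus yields at
#' least one fragment, with extra depth drawn negative-binomially. States at
#' the first life stage are Bernoulli draws with the group- and
#' stage-specific methylation probability `pi`; each later stage applies a
#' two-state transition kernel whose total flip probability equals
#' `change_rate` and whose update hits the target marginal `pi` at the next
#' stage (gain and loss rates are solved analytically from those two
#' constraints).
#'
#' @param n_individuals_per_group individuals per dispersal group, each
#'   sampled at every stage.
#' @param n_loci number of genomic bins.
#' @param pi numeric matrix of true methylation probabilities, rows =
#'   dispersal groups, columns = stages, all values in (0, 1).
#' @param change_rate numeric matrix of per-locus state-flip probabilities,
#'   rows = groups, columns = stage transitions, values in [0, 1].
#' @param stages ordered life-stage labels.
#' @param depth_mean expected extra reads beyond the first at a detected
#'   unmethylated locus.
#' @param depth_sigma log-normal standard deviation of the per-sample depth
#'   multiplier.
#' @param nb_dispersion negative-binomial size parameter for extra reads.
#' @param technical_dropout probability an unmethylated locus yields zero
#'   reads anyway (default 0).
#' @param digestion_failure probability a methylated locus yields reads
#'   (default 0).
#' @param null_allele_rate per-individual probability a locus is absent at
#'   every stage — a restriction-site genotype confounder (default 0).
#' @param seed integer RNG seed; identical config and seed give bitwise
#'   identical datasets.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals_per_group = 4,
                              n_loci = 2000,
                              pi,
                              change_rate,
                              stages = epistates::stages(),
                              depth_mean = 5,
                              depth_sigma = 0.3,
                              nb_dispersion = 1,
                              technical_dropout = 0,
                              digestion_failure = 0,
                              null_allele_rate = 0,
                              seed = 1L) {
  groups <- dispersal_groups()
  pi <- as.matrix(pi)
  change_rate <- as.matrix(change_rate)
  transitions <- paste0(stages[-length(stages)], "->", stages[-1])
  if (!identical(sort(rownames(pi)), sort(groups)) ||
      !identical(sort(colnames(pi)), sort(stages)))
    stop("pi must have rows ", paste(groups, collapse = ", "),
         " and columns ", paste(stages, collapse = ", "))
  if (!identical(sort(rownames(change_rate)), sort(groups)) ||
      !identical(sort(colnames(change_rate)), sort(transitions)))
    stop("change_rate must have rows ", paste(groups, collapse = ", "),
         " and columns ", paste(transitions, collapse = ", "))
  pi <- pi[groups, stages, drop = FALSE]
  change_rate <- change_rate[groups, transitions, drop = FALSE]
  if (any(pi <= 0 | pi >= 1)) stop("all pi must lie in the open interval (0, 1)")
  for (v in list(change_rate, technical_dropout, digestion_failure,
                 null_allele_rate))
    if (any(v < 0 | v > 1)) stop("rates must lie in [0, 1]")
  stopifnot(n_individuals_per_group >= 1, n_loci >= 1,
            depth_mean > 0, depth_sigma >= 0, nb_dispersion > 0)
  cfg <- structure(list(
    n_individuals_per_group = as.integer(n_individuals_per_group),
    n_loci = as.integer(n_loci), pi = pi, change_rate = change_rate,
    stages = stages, transitions = transitions,
    depth_mean = depth_mean, depth_sigma = depth_sigma,
    nb_dispersion = nb_dispersion,
    technical_dropout = technical_dropout,
    digestion_failure = digestion_failure,
    null_allele_rate = null_allele_rate,
    seed = as.integer(seed)), class = "simulation_config")
  # feasibility: the kernel's gain/loss rates must be valid probabilities
  for (g in groups) for (k in seq_along(transitions)) {
    transition_kernel(pi[g, k], pi[g, k + 1], change_rate[g, transitions[k]],
                      label = paste0(g, " ", transitions[k]))
  }
  cfg
}

#' Solve the two-state methylation transition kernel
#'
#' Given the methylation probability before (`pi1`) and after (`pi2`) a
#' transition and the total per-locus flip probability `c`, returns the
#' conditional rates `loss` = P(methylated -> unmethylated) and
#' `gain` = P(unmethylated -> methylated) satisfying both the marginal and
#' the flip constraint:
#' `pi2 = pi1 (1 - loss) + (1 - pi1) gain` and
#' `c = pi1 loss + (1 - pi1) gain`.
#' Feasibility requires `|pi2 - pi1| <= c` (and the solved rates to be
#' probabilities); violations raise an error naming the transition.
#'
#' @param pi1,pi2 methylation probabilities in (0, 1).
#' @param c total flip probability in [0, 1].
#' @param label transition label used in error messages.
#' @return Named numeric vector `c(loss = , gain = )`.
#' @export
transition_kernel <- function(pi1, pi2, c, label = "transition") {
  delta <- pi2 - pi1
  if (abs(delta) > c + 1e-12)
    stop("infeasible configuration at ", label, ": |pi(next) - pi(current)| = ",
         signif(abs(delta), 3), " exceeds change_rate = ", signif(c, 3))
  loss <- (c - delta) / (2 * pi1)
  gain <- (c + delta) / (2 * (1 - pi1))
  if (loss > 1 + 1e-12 || gain > 1 + 1e-12)
    stop("infeasible configuration at ", label,
         ": solved loss/gain rate exceeds 1 (loss = ", signif(loss, 3),
         ", gain = ", signif(gain, 3), ")")
  c(loss = min(loss, 1), gain = min(gain, 1))
}

#' Default study-scale simulation configuration
#'
#' Returns a configuration whose true methylation probabilities are the six
#' group-by-stage posterior means reported for the chestnut-crowned babbler
#' study (dispersers 0.75/0.71/0.80 and philopatric 0.77/0.81/0.74 at
#' hatching/fledging/adult) and whose flip probabilities are the reported
#' change fractions (hatchling->fledgling 0.24 dispersers vs 0.20
#' philopatric; fledgling->adult 0.24 vs 0.23), with four individuals per
#' group sampled at all three stages and 40,361 retained 50-bp loci.
#'
#' @param ... overrides passed to [simulation_config()] (e.g. `n_loci`,
#'   `seed`).
#' @return A `simulation_config`.
#' @export
default_study_config <- function(...) {
  pi <- matrix(c(0.75, 0.71, 0.80,
                 0.77, 0.81, 0.74),
               nrow = 2, byrow = TRUE,
               dimnames = list(dispersal_groups(), stages()))
  cr <- matrix(c(0.24, 0.24,
                 0.20, 0.23),
               nrow = 2, byrow = TRUE,
               dimnames = list(dispersal_groups(), stage_transitions()))
  defaults <- list(n_individuals_per_group = 4, n_loci = 40361L,
                   pi = pi, change_rate = cr)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate an epiRADseq experiment with known truth
#'
#' @param config a [simulation_config()].
#' @return A list of class `simulated_dataset` with elements `counts` (a
#'   [count_matrix]), `meta` (a [sample_meta]), `truth_states` (integer
#'   matrix, samples x loci, 0 = methylated / 1 = unmethylated, before any
#'   measurement error), `null_alleles` (logical matrix, individuals x
#'   loci), and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- dispersal_groups()
  stg <- config$stages
  L <- config$n_loci
  n <- config$n_individuals_per_group
  ind_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", substr(g, 1, 1), seq_len(n))))
  ind_group <- rep(groups, each = n)
  n_ind <- length(ind_ids)

  null_alleles <- matrix(
    runif(n_ind * L) < config$null_allele_rate, n_ind, L,
    dimnames = list(ind_ids, NULL))

  sample_ids <- as.vector(t(outer(ind_ids, stg, paste, sep = "_")))
  states <- matrix(NA_integer_, n_ind * length(stg), L,
                   dimnames = list(sample_ids, NULL))
  counts <- matrix(0L, n_ind * length(stg), L,
                   dimnames = list(sample_ids, NULL))

  for (i in seq_len(n_ind)) {
    g <- ind_group[i]
    meth <- runif(L) < config$pi[g, stg[1]]
    row0 <- (i - 1) * length(stg)
    for (k in seq_along(stg)) {
      if (k > 1) {
        kern <- transition_kernel(config$pi[g, stg[k - 1]],
                                  config$pi[g, stg[k]],
                                  config$change_rate[g, config$transitions[k - 1]])
        u <- runif(L)
        meth <- ifelse(meth, u >= kern["loss"], u < kern["gain"])
      }
      states[row0 + k, ] <- as.integer(!meth)  # 1 = unmethylated
      counts[row0 + k, ] <- draw_counts(meth, null_alleles[i, ], config)
    }
  }

  bins <- data.frame(contig = "pseudoref",
                     start = (seq_len(L) - 1L) * 50L, width = 50L)
  cm <- count_matrix(counts, bins, samples = sample_ids)
  meta <- sample_meta(sample_id = sample_ids,
                      individual_id = rep(ind_ids, each = length(stg)),
                      stage = rep(stg, times = n_ind),
                      dispersal = rep(ind_group, each = length(stg)),
                      sex = NA_character_, group_size = NA_real_)
  colnames(states) <- cm$bins$locus_id
  colnames(null_alleles) <- cm$bins$locus_id
  structure(list(counts = cm, meta = meta, truth_states = states,
                 null_alleles = null_alleles, config = config),
            class = "simulated_dataset")
}

# Depth model for one library. A detected fragment locus always yields at
# least one read; extra reads are negative binomial with a per-sample
# log-normal depth multiplier. Methylated or technically-dropped loci yield
# zero; null-allele loci yield zero regardless of state.
draw_counts <- function(meth, null, config) {
  L <- length(meth)
  mult <- exp(rnorm(1, 0, config$depth_sigma))
  detected <- ifelse(meth,
                     runif(L) < config$digestion_failure,
                     runif(L) >= config$technical_dropout)
  detected <- detected & !null
  n_det <- sum(detected)
  out <- integer(L)
  if (n_det > 0)
    out[detected] <- 1L + rnbinom(n_det, size = config$nb_dispersion,
                                  mu = config$depth_mean * mult)
  out
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", length(x$counts$samples), "libraries,",
      x$config$n_loci, "loci, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a featureCounts-dialect count table (`counts.tsv`), a metadata CSV
#' (`meta.csv`), and a long truth table (`truth.tsv`: individual_id, stage,
#' locus_id, state), plus a JSON manifest with MD5 checksums. The count
#' table round-trips losslessly through [read_counts_table()].
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "meta.csv")
  truth_path <- file.path(dir, "truth.tsv")
  write_counts_table(dataset$counts, counts_path, dialect = "featurecounts")
  utils::write.csv(as.data.frame(dataset$meta), meta_path, row.names = FALSE)

  st <- dataset$truth_states
  key <- strsplit(rownames(st), "_(?=[^_]+$)", perl = TRUE)
  truth <- data.frame(
    individual_id = rep(vapply(key, `[`, "", 1), each = ncol(st)),
    stage = rep(vapply(key, `[`, "", 2), each = ncol(st)),
    locus_id = rep(colnames(st), times = nrow(st)),
    state = as.integer(t(st)))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c(counts = counts_path, meta = meta_path, truth = truth_path)
  manifest <- list(
    seed = dataset$config$seed,
    n_loci = dataset$config$n_loci,
    n_samples = length(dataset$counts$samples),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
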