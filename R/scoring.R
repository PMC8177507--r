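#' Collapse fragment counts to binary methylation states
#'
#' A locus with no observed fragments in a library is scored methylated
#' (state 0): the methylation-sensitive enzyme could not cut it. A locus
#' with at least one fragment is scored unmethylated (state 1). The map is
#' idempotent: re-binarizing a 0/1 matrix returns it unchanged.
#'
#' @param x a [count_matrix].
#' @return An object of class `state_matrix` (same structure, binary cells).
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "count_matrix") || inherits(x, "state_matrix"))
  states <- x$counts
  states[] <- as.integer(states > 0L)
  structure(list(counts = states, bins = x$bins, samples = x$samples),
            class = c("state_matrix", "count_matrix"))
}

#' @export
print.state_matrix <- function(x, ...) {
  cat("state_matrix:", length(x$samples), "samples x", nrow(x$bins),
      "loci; mean methylated fraction",
      round(mean(x$counts == 0L), 3), "\n")
  invisible(x)
}

#' Per-sample genome-wide methylation proportion
#'
#' For every library, the fraction of retained loci in the methylated state
#' (state 0), equal to `1 - mean(states)` exactly. This is the response of
#' the beta GLMM.
#'
#' @param states a `state_matrix` from [binarize()].
#' @param meta a [sample_meta]; every sample in `states` must resolve.
#' @return A tibble with columns `sample_id`, `individual_id`, `stage`,
#'   `dispersal`, `sex`, `group_size`, `n_loci`, `n_methylated`,
#'   `proportion`.
#' @export
proportion_methylated <- function(states, meta) {
  stopifnot(inherits(states, "state_matrix"))
  if (nrow(states$counts) == 0 || ncol(states$counts) == 0)
    stop("empty state matrix")
  idx <- match(states$samples, meta$sample_id)
  if (anyNA(idx))
    stop("sample missing from metadata: ",
         paste(states$samples[is.na(idx)], collapse = ", "))
  n_meth <- rowSums(states$counts == 0L)
  out <- tibble::tibble(
    sample_id = states$samples,
    individual_id = meta$individual_id[idx],
    stage = meta$stage[idx],
    dispersal = meta$dispersal[idx],
    sex = meta$sex[idx],
    group_size = meta$group_size[idx],
    n_loci = ncol(states$counts),
    n_methylated = as.integer(unname(n_meth)),
    proportion = unname(n_meth) / ncol(states$counts))
  out
}

#' Within-individual methylation-state transitions
#'
#' For each individual with libraries at both ends of a consecutive
#' stage pair, counts the retained loci that gained methylation (state
#' 1 -> 0), lost it (0 -> 1), or kept their state. By default every
#' retained locus enters the denominator, so a locus unobserved at both
#' stages counts as stably methylated; `drop_joint_missing = TRUE` instead
#' excludes loci with zero reads at both stages for that individual (they
#' are indistinguishable from genotype-driven absence). Individuals lacking
#' a stage are skipped with a warning.
#'
#' @param states a `state_matrix`.
#' @param meta a [sample_meta].
#' @param drop_joint_missing drop per-individual always-zero loci from the
#'   denominator (default `FALSE`).
#' @return A tibble with one row per individual and transition: columns
#'   `individual_id`, `dispersal`, `transition`, `n_total`, `n_gain`,
#'   `n_loss`, `n_stable`, `n_changed`, `changed_fraction`.
#' @export
score_transitions <- function(states, meta, drop_joint_missing = FALSE) {
  stopifnot(inherits(states, "state_matrix"))
  idx <- match(states$samples, meta$sample_id)
  if (anyNA(idx))
    stop("sample missing from metadata: ",
         paste(states$samples[is.na(idx)], collapse = ", "))
  m <- meta[idx, ]
  key <- paste(m$individual_id, m$stage)
  if (anyDuplicated(key))
    stop("duplicate sample for individual x stage: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  stg <- stages()
  rows <- list()
  for (ind in unique(m$individual_id)) {
    for (k in seq_len(length(stg) - 1)) {
      i1 <- which(m$individual_id == ind & m$stage == stg[k])
      i2 <- which(m$individual_id == ind & m$stage == stg[k + 1])
      trans <- paste0(stg[k], "->", stg[k + 1])
      if (!length(i1) || !length(i2)) {
        warning("individual ", ind, " lacks a ", trans,
                " stage pair; skipped", call. = FALSE)
        next
      }
      s1 <- states$counts[i1, ]
      s2 <- states$counts[i2, ]
      use <- rep(TRUE, length(s1))
      if (drop_joint_missing) use <- !(s1 == 0L & s2 == 0L)
      n_gain <- sum(s1[use] == 1L & s2[use] == 0L)
      n_loss <- sum(s1[use] == 0L & s2[use] == 1L)
      n_total <- sum(use)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual_id = ind,
        dispersal = m$dispersal[i1],
        transition = trans,
        n_total = n_total,
        n_gain = n_gain, n_loss = n_loss,
        n_stable = n_total - n_gain - n_loss,
        n_changed = n_gain + n_loss,
        changed_fraction = (n_gain + n_loss) / n_total)
    }
  }
  if (!length(rows)) return(tibble::tibble(
    individual_id = character(), dispersal = character(),
    transition = character(), n_total = integer(), n_gain = integer(),
    n_loss = integer(), n_stable = integer(), n_changed = integer(),
    changed_fraction = double()))
  dplyr::bind_rows(rows)
}

#' Group-level counts of loci changing methylation state
#'
#' Summarizes, per dispersal group and transition, how many loci gained or
#' lost methylation "across all individuals" under two readings:
#' `consensus` counts loci whose change in the same direction occurs in
#' every complete individual of the group; `pooled` sums change events over
#' individuals (a locus changing in two individuals contributes twice).
#'
#' @param states a `state_matrix`.
#' @param meta a [sample_meta].
#' @param mode `"consensus"` or `"pooled"`.
#' @return A tibble with columns `dispersal`, `transition`, `mode`,
#'   `n_individuals`, `n_gain`, `n_loss`. Groups with no complete
#'   individual for a transition yield a zero-count row with a warning.
#' @export
group_change_summary <- function(states, meta,
                                 mode = c("consensus", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(states, "state_matrix"))
  idx <- match(states$samples, meta$sample_id)
  if (anyNA(idx)) stop("sample missing from metadata")
  m <- meta[idx, ]
  stg <- stages()
  rows <- list()
  for (g in dispersal_groups()) {
    for (k in seq_len(length(stg) - 1)) {
      trans <- paste0(stg[k], "->", stg[k + 1])
      inds <- unique(m$individual_id[m$dispersal == g])
      gain_mat <- loss_mat <- NULL
      complete <- character()
      for (ind in inds) {
        i1 <- which(m$individual_id == ind & m$stage == stg[k])
        i2 <- which(m$individual_id == ind & m$stage == stg[k + 1])
        if (!length(i1) || !length(i2)) next
        s1 <- states$counts[i1, ]
        s2 <- states$counts[i2, ]
        gain_mat <- rbind(gain_mat, s1 == 1L & s2 == 0L)
        loss_mat <- rbind(loss_mat, s1 == 0L & s2 == 1L)
        complete <- c(complete, ind)
      }
      if (!length(complete)) {
        warning("group ", g, " has no complete individual for ", trans,
                call. = FALSE)
        n_gain <- n_loss <- 0L
      } else if (mode == "consensus") {
        n_gain <- sum(colSums(gain_mat) == length(complete))
        n_loss <- sum(colSums(loss_mat) == length(complete))
      } else {
        n_gain <- sum(gain_mat)
        n_loss <- sum(loss_mat)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        dispersal = g, transition = trans, mode = mode,
        n_individuals = length(complete),
        n_gain = as.integer(n_gain), n_loss = as.integer(n_loss))
    }
  }
  dplyr::bind_rows(rows)
}
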