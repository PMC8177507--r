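# shared builders for small in-memory fixtures

tiny_counts <- function() {
  counts <- rbind(s1 = c(0L, 1L, 7L, 0L),
                  s2 = c(2L, 0L, 3L, 1L),
                  s3 = c(0L, 0L, 5L, 2L))
  bins <- data.frame(contig = "c1", start = c(0L, 50L, 100L, 150L),
                     width = 50L)
  count_matrix(counts, bins)
}

tiny_meta <- function() {
  sample_meta(sample_id = c("s1", "s2", "s3"),
              individual_id = c("i1", "i1", "i2"),
              stage = c("hatchling", "fledgling", "hatchling"),
              dispersal = c("disperser", "disperser", "philopatric"))
}

# uniform-rate config: every cell at `p`, every transition at `c`
flat_config <- function(p = 0.5, c = 0.2, n_ind = 4, n_loci = 1000,
                        seed = 1, ...) {
  pi <- matrix(p, 2, 3, dimnames = list(dispersal_groups(), stages()))
  cr <- matrix(c, 2, 2,
               dimnames = list(dispersal_groups(), stage_transitions()))
  simulation_config(n_individuals_per_group = n_ind, n_loci = n_loci,
                    pi = pi, change_rate = cr, seed = seed, ...)
}

# paired states -> metadata for two stages of the same individuals
two_stage_states <- function(earlier, later) {
  n <- nrow(earlier)
  counts <- rbind(earlier, later)
  rownames(counts) <- c(paste0("i", 1:n, "_h"), paste0("i", 1:n, "_f"))
  bins <- data.frame(contig = "c1",
                     start = (seq_len(ncol(earlier)) - 1L) * 50L,
                     width = 50L)
  st <- binarize(count_matrix(counts, bins))
  meta <- sample_meta(
    sample_id = rownames(counts),
    individual_id = rep(paste0("i", 1:n), 2),
    stage = rep(c("hatchling", "fledgling"), each = n),
    dispersal = "disperser")
  list(states = st, meta = meta)
}
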