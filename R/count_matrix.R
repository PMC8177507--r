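#' @importFrom stats rnorm rbinom rnbinom rbeta rgamma rcauchy runif quantile
#'   sd var acf dnorm dbeta dbinom dgamma dcauchy plogis qlogis aggregate
#'   setNames
#' @importFrom utils write.table read.table head
NULL

locus_ids <- function(bins) {
  if (nrow(bins) == 0) return(character(0))
  paste0(bins$contig, ":", bins$start, "-", bins$start + bins$width)
}

#' Construct a binned fragment-count matrix
#'
#' The central data container of the package: nonnegative integer fragment
#' counts for a set of sample libraries over genomic bins of fixed width.
#' Bin coordinates are 0-based, half-open `[start, start + width)`; bins tile
#' their contig, so `start` must be divisible by `width`.
#'
#' @param counts integer matrix, samples in rows, bins in columns.
#' @param bins data frame with columns `contig`, `start` (0-based), `width`.
#' @param samples character vector of sample library ids (defaults to
#'   `rownames(counts)`).
#' @return An object of class `count_matrix` with elements `counts`
#'   (integer matrix with sample rownames and `contig:start-end` colnames),
#'   `bins`, and `samples`.
#' @export
count_matrix <- function(counts, bins, samples = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(samples)) stop("sample ids are required (rownames or `samples`)")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (nrow(counts) != length(samples))
    stop("counts has ", nrow(counts), " rows but ", length(samples), " sample ids")
  bins <- as.data.frame(bins)
  stopifnot(all(c("contig", "start", "width") %in% names(bins)))
  if (nrow(bins) != ncol(counts))
    stop("counts has ", ncol(counts), " columns but ", nrow(bins), " bins")
  if (any(bins$start < 0)) stop("bin start must be >= 0")
  if (any(bins$width <= 0)) stop("bin width must be > 0")
  if (any(bins$start %% bins$width != 0))
    stop("bin start must be divisible by bin width (bins tile the contig)")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  ids <- locus_ids(bins)
  if (anyDuplicated(ids))
    stop("duplicate bins: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bins$locus_id <- ids
  rownames(counts) <- samples
  colnames(counts) <- ids
  structure(list(counts = counts, bins = bins, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$samples), "samples x", nrow(x$bins), "bins\n")
  cat("  contigs:", length(unique(x$bins$contig)),
      " bin width:", x$bins$width[1], "bp\n")
  cat("  nonzero cells:", sum(x$counts > 0), "/", length(x$counts), "\n")
  invisible(x)
}

#' Construct a sample metadata table
#'
#' Per-library annotations: the individual each library came from, its life
#' stage, the individual's dispersal phenotype, and optional sex and social
#' group size. Dispersal status describes the individual (first-year
#' movement), so it must be constant across an individual's libraries.
#'
#' @param sample_id,individual_id,stage,dispersal character vectors;
#'   `stage` must be one of `hatchling`, `fledgling`, `adult`; `dispersal`
#'   one of `disperser`, `philopatric`.
#' @param sex,group_size optional per-sample annotations.
#' @return A tibble of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, individual_id, stage, dispersal,
                        sex = NA_character_, group_size = NA_real_) {
  stage <- as.character(stage)
  dispersal <- as.character(dispersal)
  bad <- setdiff(unique(stage), stages())
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(dispersal), dispersal_groups())
  if (length(bad)) stop("unknown dispersal label: ", paste(bad, collapse = ", "))
  meta <- tibble::tibble(sample_id = as.character(sample_id),
                         individual_id = as.character(individual_id),
                         stage = stage, dispersal = dispersal,
                         sex = sex, group_size = group_size)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  nlab <- tapply(meta$dispersal, meta$individual_id, function(d) length(unique(d)))
  if (any(nlab > 1))
    stop("dispersal label varies within individual: ",
         paste(names(nlab)[nlab > 1], collapse = ", "))
  class(meta) <- c("sample_meta", class(meta))
  meta
}

#' Ordered life-stage and dispersal-group labels
#'
#' @return Character vectors of the canonical factor levels.
#' @export
stages <- function() c("hatchling", "fledgling", "adult")

#' @rdname stages
#' @export
dispersal_groups <- function() c("disperser", "philopatric")

#' @rdname stages
#' @export
stage_transitions <- function() {
  s <- stages()
  paste0(s[-length(s)], "->", s[-1])
}

#' Read a binned count table
#'
#' Two on-disk dialects are supported. `featurecounts`: tab-separated with
#' header `Geneid Chr Start End Strand Length` followed by one column per
#' sample library; `#` comment lines are skipped; `Start` is 1-based
#' inclusive and is converted to the package's 0-based convention (the
#' conversion is reported via `message()`). `wide`: tab-separated, first
#' column `locus_id` formatted `contig:start-end` with 0-based half-open
#' coordinates, remaining columns sample counts.
#'
#' @param path file path.
#' @param dialect `"featurecounts"` or `"wide"`.
#' @return A [count_matrix].
#' @export
read_counts_table <- function(path, dialect = c("featurecounts", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "featurecounts") {
    fixed <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
    if (!identical(names(df)[seq_along(fixed)], fixed))
      stop("malformed featureCounts header: expected columns ",
           paste(fixed, collapse = ", "))
    samp_cols <- names(df)[-seq_along(fixed)]
    if (!length(samp_cols)) stop("no sample columns in ", path)
    check_count_cols(df[samp_cols], path)
    width <- df$End - df$Start + 1L
    bins <- data.frame(contig = as.character(df$Chr),
                       start = df$Start - 1L,  # 1-based inclusive -> 0-based
                       width = width)
    message("read_counts_table: converted featureCounts 1-based Start to ",
            "0-based half-open coordinates (", nrow(bins), " bins)")
    counts <- t(as.matrix(df[samp_cols]))
  } else {
    if (names(df)[1] != "locus_id")
      stop("malformed wide header: first column must be locus_id")
    samp_cols <- names(df)[-1]
    if (!length(samp_cols)) stop("no sample columns in ", path)
    check_count_cols(df[samp_cols], path)
    parts <- regmatches(df$locus_id,
                        regexec("^(.+):([0-9]+)-([0-9]+)$", df$locus_id))
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop("malformed locus_id at data row ", bad[1], ": ", df$locus_id[bad[1]])
    start <- as.integer(vapply(parts, `[`, "", 3))
    end <- as.integer(vapply(parts, `[`, "", 4))
    bins <- data.frame(contig = vapply(parts, `[`, "", 2),
                       start = start, width = end - start)
    counts <- t(as.matrix(df[samp_cols]))
  }
  count_matrix(counts, bins, samples = samp_cols)
}

check_count_cols <- function(df, path) {
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.numeric(v))
      stop("non-numeric count in column ", nm, " of ", path)
    bad <- which(v < 0 | v != round(v))
    if (length(bad))
      stop("invalid count ", v[bad[1]], " in column ", nm,
           " at data row ", bad[1])
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts_table()] for both dialects; `write` then `read`
#' is the identity.
#'
#' @param x a [count_matrix].
#' @param path output file path.
#' @param dialect `"featurecounts"` or `"wide"`.
#' @export
write_counts_table <- function(x, path, dialect = c("featurecounts", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "count_matrix"))
  if (dialect == "featurecounts") {
    df <- data.frame(Geneid = x$bins$locus_id,
                     Chr = x$bins$contig,
                     Start = x$bins$start + 1L,  # back to 1-based inclusive
                     End = x$bins$start + x$bins$width,
                     Strand = ".",
                     Length = x$bins$width,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(t(x$counts)))
  } else {
    df <- cbind(data.frame(locus_id = x$bins$locus_id),
                as.data.frame(t(x$counts)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin fragment counts into fixed-width genomic bins
#'
#' Each fragment contributes its count to the bin containing its start
#' position (`floor(start / width)`); bin totals are sums over assigned
#' fragments, so the total count is conserved.
#'
#' @param fragments data frame with columns `contig`, `start` (0-based),
#'   `count`, and optionally `sample_id` (single-sample assumed otherwise).
#' @param width bin width in bases (default 50, the analysis resolution).
#' @return A [count_matrix].
#' @export
bin_fragment_counts <- function(fragments, width = 50) {
  stopifnot(width > 0)
  fragments <- as.data.frame(fragments)
  stopifnot(all(c("contig", "start", "count") %in% names(fragments)))
  if (any(fragments$start < 0)) stop("negative fragment start")
  if (is.null(fragments$sample_id)) fragments$sample_id <- "sample_1"
  bin_start <- (fragments$start %/% width) * width
  key <- paste0(fragments$contig, ":", bin_start)
  tab <- aggregate(fragments$count,
                   by = list(sample = fragments$sample_id, key = key),
                   FUN = sum)
  keys <- sort(unique(key))
  samples <- sort(unique(fragments$sample_id))
  counts <- matrix(0L, nrow = length(samples), ncol = length(keys),
                   dimnames = list(samples, keys))
  counts[cbind(match(tab$sample, samples), match(tab$key, keys))] <-
    as.integer(tab$x)
  parts <- strsplit(keys, ":", fixed = TRUE)
  bins <- data.frame(contig = vapply(parts, `[`, "", 1),
                     start = as.integer(vapply(parts, `[`, "", 2)),
                     width = as.integer(width))
  ord <- order(bins$contig, bins$start)
  count_matrix(counts[, ord, drop = FALSE], bins[ord, , drop = FALSE],
               samples = samples)
}

#' Remove rarely observed loci
#'
#' Drops every bin with a sequenced fragment in less than `min_fraction` of
#' screened units — a strict "less than" rule, so a bin observed in exactly
#' the threshold fraction is retained. The unit is either the sample library
#' (default) or the distinct individual (an individual counts as observed at
#' a bin if any of its libraries has at least one read there). Sample order
#' and retained-bin order are preserved; a filter report is attached as the
#' `"filter_report"` attribute and logged via `message()`.
#'
#' @param x a [count_matrix].
#' @param meta a [sample_meta] (required when `unit = "individual"`).
#' @param min_fraction retention threshold in (0, 1], default 0.10.
#' @param unit `"sample"` or `"individual"`.
#' @return The filtered [count_matrix].
#' @export
presence_filter <- function(x, meta = NULL, min_fraction = 0.10,
                            unit = c("sample", "individual")) {
  unit <- match.arg(unit)
  stopifnot(inherits(x, "count_matrix"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  if (length(x$samples) == 0 || nrow(x$bins) == 0) stop("empty count matrix")
  present <- x$counts > 0
  if (unit == "sample") {
    frac <- colMeans(present)
    n_units <- length(x$samples)
  } else {
    if (is.null(meta)) stop("metadata required for unit = \"individual\"")
    idx <- match(x$samples, meta$sample_id)
    if (anyNA(idx))
      stop("sample missing from metadata: ",
           paste(x$samples[is.na(idx)], collapse = ", "))
    ind <- meta$individual_id[idx]
    by_ind <- rowsum(present + 0L, group = ind) > 0
    frac <- colMeans(by_ind)
    n_units <- nrow(by_ind)
  }
  keep <- frac >= min_fraction
  out <- count_matrix(x$counts[, keep, drop = FALSE],
                      x$bins[keep, , drop = FALSE], samples = x$samples)
  report <- list(unit = unit, n_units = n_units, min_fraction = min_fraction,
                 n_bins_before = nrow(x$bins), n_bins_after = sum(keep))
  message(sprintf(
    "presence_filter: retained %d of %d bins (>= %.0f%% of %d %ss with a fragment)",
    report$n_bins_after, report$n_bins_before, 100 * min_fraction, n_units, unit))
  attr(out, "filter_report") <- report
  out
}
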