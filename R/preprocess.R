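#' Rarefy a count table to even depth
#'
#' Subsamples every sample column to `depth` reads without replacement
#' (multivariate hypergeometric), the standard way of equalising library
#' sizes before diversity and network analysis. Samples whose total is
#' below `depth` are dropped with a warning. Each sample draws from its
#' own RNG substream derived from `(seed, sample id)`, so the result does
#' not depend on sample order.
#'
#' @param table A `feature_table` of integer counts.
#' @param depth Target reads per sample, >= 1.
#' @param seed Integer seed.
#' @return A rarefied `feature_table`; every remaining column sums to
#'   `depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  v <- table$values
  if (any(v != round(v))) stop("rarefy requires integer counts")
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  totals <- colSums(v)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) with fewer than ", depth,
            " reads: ", paste(colnames(v)[drop], collapse = ", "))
    v <- v[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  if (ncol(v) == 0) return(subset_table(table, samples = character(0)))
  out <- v
  for (j in seq_len(ncol(v))) {
    if (totals[j] == depth) next  # full draw: sample unchanged
    out[, j] <- withr_seed(derive_seed(seed, colnames(v)[j]),
                           subsample_without_replacement(v[, j], depth))
  }
  tab <- subset_table(table, samples = colnames(v))
  tab$values <- out
  tab
}

# Draw `depth` reads without replacement from integer counts `x` by
# sampling read indices and mapping them back to features through the
# cumulative counts (no read-level expansion).
subsample_without_replacement <- function(x, depth) {
  total <- sum(x)
  picked <- sample.int(total, depth)
  cuts <- cumsum(x)
  counts <- tabulate(findInterval(picked, cuts + 0.5) + 1L, nbins = length(x))
  stats::setNames(counts, names(x))
}

#' Prevalence filter
#'
#' Retains features observed (nonzero) in at least `min_occurrence`
#' samples of the given sample group; the rest are removed. This is the
#' usual guard against spurious associations driven by features seen in
#' only a handful of samples.
#'
#' @param table A `feature_table`.
#' @param min_occurrence Minimum number of samples with a nonzero value.
#' @param samples Optional sample ids defining the group within which
#'   occurrence is evaluated (e.g. the samples of one depth layer);
#'   default: all samples. The returned table keeps all columns of the
#'   input but only the retained features.
#' @return A filtered `feature_table`.
#' @export
prevalence_filter <- function(table, min_occurrence = 4, samples = NULL) {
  if (min_occurrence < 1) stop("min_occurrence must be >= 1")
  v <- table$values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  occ <- rowSums(v > 0)
  keep <- occ >= min_occurrence
  if (!any(keep)) {
    warning("prevalence filter removed every feature")
  }
  subset_table(table, features = names(keep)[keep])
}

#' Signal-to-noise filter for array probes
#'
#' Computes SNR = (signal - background_mean) / background_sd per probe
#' and retains probes with SNR at or above `threshold` (probes with SNR
#' strictly below the threshold are removed, so the boundary survives).
#'
#' @param records data.frame with columns `probe_id`, `signal`,
#'   `background_mean`, `background_sd`.
#' @param threshold SNR cutoff (default 2).
#' @return The input data.frame with an `snr` column, restricted to
#'   retained probes.
#' @export
snr_filter <- function(records, threshold = 2) {
  if (threshold <= 0) stop("threshold must be positive")
  needed <- c("probe_id", "signal", "background_mean", "background_sd")
  missing <- setdiff(needed, colnames(records))
  if (length(missing)) stop("records missing column(s): ",
                            paste(missing, collapse = ", "))
  bad <- records$background_sd <= 0
  if (any(bad)) {
    stop("non-positive background_sd for probe(s): ",
         paste(records$probe_id[bad], collapse = ", "))
  }
  records$snr <- (records$signal - records$background_mean) /
    records$background_sd
  records[records$snr >= threshold, , drop = FALSE]
}

#' lnMR normalisation of array signal intensities
#'
#' Transforms every value x to ln(x + 1) / M. By default M is the mean
#' over samples of the per-sample total raw intensity (one global
#' scalar), which puts all samples on a common scale; with
#' `per_sample = TRUE`, each sample is divided by its own total instead.
#' Zeros map to zero and within-sample rank order is preserved either
#' way.
#'
#' @param table A `feature_table` of non-negative signal intensities.
#' @param per_sample Use each sample's own total as the divisor.
#' @return A normalised `feature_table`.
#' @export
lnmr_normalize <- function(table, per_sample = FALSE) {
  v <- table$values
  totals <- colSums(v)
  if (all(totals == 0)) stop("all-zero table: lnMR divisor undefined")
  out <- if (per_sample) {
    if (any(totals == 0)) stop("per-sample lnMR undefined for all-zero sample")
    sweep(log1p(v), 2, totals, "/")
  } else {
    log1p(v) / mean(totals)
  }
  tab <- table
  tab$values <- out
  tab
}
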