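#' Synthetic reads per 1000 total reads (observed)
#'
#' Depth-normalised spike share: `1000 * synthetic / total`, in
#' `[0, 1000]`.
#'
#' @param synthetic_reads,total_reads Non-negative counts (vectorised);
#'   `total_reads` must be positive and at least `synthetic_reads`.
#' @return Numeric, synthetic reads per 1000 total.
#' @export
per1000 <- function(synthetic_reads, total_reads) {
  if (any(total_reads <= 0)) stopf("total_reads must be positive")
  if (any(synthetic_reads < 0 | synthetic_reads > total_reads)) {
    stopf("synthetic_reads must lie in [0, total_reads]")
  }
  1000 * synthetic_reads / total_reads
}

#' Flag low-depth samples within groups
#'
#' A sample is flagged iff its total reads fall below `fraction` times the
#' mean total of its sample group (the sample itself included in the mean;
#' set `leave_one_out = TRUE` to exclude it). Single-sample groups are never
#' flagged under the default (mean equals self).
#'
#' @param total_reads Numeric vector of per-sample read totals.
#' @param group Group labels, parallel to `total_reads`.
#' @param fraction Threshold fraction of the group mean (default 0.4).
#' @param leave_one_out Exclude the sample from its group mean.
#' @return Logical flags.
#' @export
#' @examples
#' filter_low_depth(c(100, 100, 30), rep("g", 3))  # FALSE FALSE TRUE
filter_low_depth <- function(total_reads, group, fraction = 0.4,
                             leave_one_out = FALSE) {
  stopifnot(length(total_reads) == length(group))
  ref <- numeric(length(total_reads))
  for (g in unique(group)) {
    sel <- group == g
    if (leave_one_out && sum(sel) > 1L) {
      tot <- sum(total_reads[sel]); n <- sum(sel)
      ref[sel] <- (tot - total_reads[sel]) / (n - 1L)
    } else {
      ref[sel] <- mean(total_reads[sel])
    }
  }
  total_reads < fraction * ref
}

#' Flag samples with an excessive synthetic-to-microbial read ratio
#'
#' A sample is flagged iff its ratio of synthetic to microbial reads is at
#' least `fold` times the mean ratio of its group. Samples with zero
#' microbial reads are flagged unconditionally (the ratio is degenerate).
#'
#' @param synthetic_reads,microbial_reads Per-sample counts.
#' @param group Group labels.
#' @param fold Fold-above-mean threshold (default 2.5).
#' @return Logical flags.
#' @export
#' @examples
#' filter_spike_ratio(c(1, 1, 10), c(10, 10, 10), rep("g", 3))
filter_spike_ratio <- function(synthetic_reads, microbial_reads, group,
                               fold = 2.5) {
  stopifnot(length(synthetic_reads) == length(microbial_reads),
            length(synthetic_reads) == length(group))
  degenerate <- microbial_reads == 0
  ratio <- ifelse(degenerate, NA_real_,
                  synthetic_reads / microbial_reads)
  flags <- degenerate
  for (g in unique(group)) {
    sel <- group == g & !degenerate
    if (!any(sel)) next
    cutoff <- fold * mean(ratio[sel])
    flags[sel] <- ratio[sel] >= cutoff
  }
  flags
}

#' Flag order-of-magnitude outlier replicates
#'
#' A biological replicate is flagged iff its estimate differs from the
#' median of the *other* replicates by at least one order of magnitude
#' (>= 1 in log10).
#'
#' @param estimates Positive abundance estimates of biological replicates
#'   (>= 2 values).
#' @param threshold_log10 Flagging threshold in log10 units (default 1).
#' @return Logical flags.
#' @export
#' @examples
#' filter_magnitude_outlier(c(1e9, 1.2e9, 1.5e10))  # FALSE FALSE TRUE
filter_magnitude_outlier <- function(estimates, threshold_log10 = 1) {
  stopifnot(length(estimates) >= 2L, all(estimates > 0))
  lg <- log10(estimates)
  vapply(seq_along(lg), function(i) {
    abs(lg[i] - stats::median(lg[-i])) >= threshold_log10
  }, logical(1))
}

#' Is an observed spike share inside the acceptance window?
#'
#' Strict bounds by default: `low < sr1000 < high`; set `strict = FALSE`
#' for an inclusive window.
#'
#' @param sr1000_observed Observed synthetic reads per 1000 total.
#' @param low,high Window bounds (defaults 200 and 800).
#' @param strict Use strict inequalities (default `TRUE`).
#' @return Logical.
#' @export
#' @examples
#' flag_window(c(200, 500, 801))  # FALSE TRUE FALSE
flag_window <- function(sr1000_observed, low = 200, high = 800,
                        strict = TRUE) {
  if (strict) sr1000_observed > low & sr1000_observed < high
  else sr1000_observed >= low & sr1000_observed <= high
}

#' Sample-level QC report
#'
#' One row per (sample, family) with read totals, the observed spike share
#' per 1000 reads, and all quality flags: `low_depth` (reads below 40% of
#' the group mean), `spike_ratio_high` (synthetic/microbial ratio >= 2.5x
#' the group mean), `out_of_window` (spike share outside 200-800 per 1000)
#' and `contaminated` (manual manifest annotation). `magnitude_outlier` is
#' computed downstream on abundance estimates (see
#' [quantify()]); here it is initialised `FALSE`.
#'
#' @param counts A [count_table()].
#' @param manifest Manifest `data.frame` (see [read_manifest()]); groups
#'   are taken per (group, family).
#' @param depth_fraction,ratio_fold,window Filter parameters (defaults 0.4,
#'   2.5, `c(200, 800)`).
#' @param strict_window Strict window bounds (default `TRUE`).
#' @return `data.frame` of class `sample_qc`.
#' @export
qc_table <- function(counts, manifest, depth_fraction = 0.4,
                     ratio_fold = 2.5, window = c(200, 800),
                     strict_window = TRUE) {
  fams <- unique(attr(counts, "family"))
  out <- do.call(rbind, lapply(fams, function(f) {
    tot <- family_read_totals(counts, f)
    tot$family <- f
    tot
  }))
  key <- paste(out$sample, out$family)
  mkey <- paste(manifest$sample, manifest$family)
  mi <- match(key, mkey)
  out$group <- manifest$group[mi]
  out$contaminated <- as.logical(manifest$contaminated[mi])
  out$contaminated[is.na(out$contaminated)] <- FALSE
  out$sr1000_observed <- ifelse(out$total_reads > 0,
                                1000 * out$synthetic_reads / out$total_reads,
                                NA_real_)
  gf <- paste(out$group, out$family)
  out$low_depth <- filter_low_depth(out$total_reads, gf,
                                    fraction = depth_fraction)
  out$spike_ratio_high <- filter_spike_ratio(out$synthetic_reads,
                                             out$microbial_reads, gf,
                                             fold = ratio_fold)
  out$out_of_window <- !flag_window(out$sr1000_observed, window[1],
                                    window[2], strict = strict_window)
  out$magnitude_outlier <- FALSE
  out$flagged <- out$low_depth | out$spike_ratio_high | out$out_of_window |
    out$contaminated
  rownames(out) <- NULL
  class(out) <- c("sample_qc", "data.frame")
  out
}

#' @rdname qc_table
#' @param x A `sample_qc` report.
#' @param path TSV path.
#' @export
write_qc_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
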