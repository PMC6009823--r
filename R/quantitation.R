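#' Absolute gene abundance from spike and microbial read counts
#'
#' The ratio estimator at the core of spike-based quantitation:
#' \deqn{\hat{A} = \frac{R_{micro}}{R_{spike}} \times N_{spike}}
#' i.e. gene copies per unit of sample = (microbial-origin reads /
#' synthetic-origin reads) x spike copies added per unit of sample prior to
#' DNA isolation. Microbial-origin reads exclude synthetic and unassigned
#' reads.
#'
#' @param microbial_reads,synthetic_reads Read counts (vectorised);
#'   `synthetic_reads` must be positive — zero synthetic reads means the
#'   spike failed and quantitation is impossible.
#' @param spike_copies Spike copies added per unit of sample (> 0).
#' @return Gene copies per unit of sample.
#' @export
#' @examples
#' absolute_abundance(900, 100, 3.5e7)  # 3.15e8
absolute_abundance <- function(microbial_reads, synthetic_reads,
                               spike_copies) {
  if (any(synthetic_reads <= 0)) {
    stopf("synthetic_reads must be positive (zero spike reads: quantitation impossible)")
  }
  stopifnot(all(spike_copies > 0), all(microbial_reads >= 0))
  spike_copies * microbial_reads / synthetic_reads
}

#' Isolation-loss correction
#'
#' When spikes are added to already-isolated DNA (rather than to the raw
#' sample), the estimate misses DNA lost during column-based isolation and
#' must be scaled by predicted total DNA over the DNA actually mixed with
#' spikes and used for PCR. It must not be applied when spikes were added
#' before isolation — there the loss hits spike and microbial DNA alike and
#' cancels in the ratio.
#'
#' @param estimate Uncorrected copies per unit.
#' @param predicted_total_dna_ng Predicted total DNA in the sample (ng).
#' @param used_dna_ng DNA mixed with spikes and used for PCR (ng, > 0).
#' @param spike_timing `"after"` (the only timing for which the correction
#'   is defined) or `"before"` (raises).
#' @return Corrected copies per unit.
#' @export
#' @examples
#' isolation_correction(1e9, 20, 10)  # 2e9
isolation_correction <- function(estimate, predicted_total_dna_ng,
                                 used_dna_ng, spike_timing = "after") {
  if (any(spike_timing != "after")) {
    stopf("isolation correction applies only to spike-after-isolation samples")
  }
  stopifnot(all(used_dna_ng > 0), all(predicted_total_dna_ng >= 0))
  estimate * predicted_total_dna_ng / used_dna_ng
}

#' Expected marker-gene copies for a counted culture
#'
#' Product of cells per unit (e.g. cfu/ml) and marker-gene operon copies
#' per genome.
#'
#' @param cells_per_unit Colony-forming units per unit (> 0).
#' @param operons_per_genome Operon copies per genome (>= 1).
#' @return Expected gene copies per unit.
#' @export
#' @examples
#' expected_culture_copies(1.11e9, 3)  # 3.33e9
expected_culture_copies <- function(cells_per_unit, operons_per_genome) {
  stopifnot(all(cells_per_unit > 0), all(operons_per_genome >= 1))
  cells_per_unit * operons_per_genome
}

#' Recovery of an expected abundance
#'
#' `mean(estimates) / expected * 100`. Note that recomputing a published
#' recovery from rounded printed estimates can differ from the published
#' figure in the last digit.
#'
#' @param estimates Abundance estimates.
#' @param expected Expected (true) abundance (> 0).
#' @return Percent recovery.
#' @export
#' @examples
#' recovery_percent(c(3.11e9, 3.44e9, 3.38e9), 3.33e9)  # ~99.4
recovery_percent <- function(estimates, expected) {
  stopifnot(expected > 0)
  mean(estimates) / expected * 100
}

#' Scale a taxon count profile to absolute units
#'
#' Each taxon receives the family total times its read fraction among
#' microbial (non-synthetic) reads, so the profile sums to the total.
#'
#' @param taxon_counts Named non-negative read counts for one sample's
#'   microbial categories.
#' @param total_estimate Absolute family total (copies per unit).
#' @return Named numeric vector of per-taxon copies per unit.
#' @export
taxon_absolute <- function(taxon_counts, total_estimate) {
  micro <- sum(taxon_counts)
  if (micro <= 0) stopf("no microbial reads to distribute")
  total_estimate * taxon_counts / micro
}

#' Cross-family (domain) fractions
#'
#' Normalises per-family absolute totals to percentages; invariant to a
#' common rescaling of all totals.
#'
#' @param totals Named non-negative absolute totals (not all zero).
#' @return Named percentages summing to 100.
#' @export
#' @examples
#' domain_fractions(c(`16S` = 9.1e9, `18S` = 9.0e8))
domain_fractions <- function(totals) {
  stopifnot(all(totals >= 0), sum(totals) > 0)
  100 * totals / sum(totals)
}

#' Target fractions from qPCR Ct values
#'
#' Quantities are proportional to `efficiency^(-Ct)`; fractions are
#' normalised to 100%.
#'
#' @param ct Named Ct values per target.
#' @param efficiency Per-cycle amplification factor (> 1; default 2, i.e.
#'   100% efficiency).
#' @return Named percentages summing to 100.
#' @export
#' @examples
#' qpcr_fractions(c(b = 20, e = 21))  # 2:1, ~66.7 / 33.3
qpcr_fractions <- function(ct, efficiency = 2) {
  stopifnot(efficiency > 1)
  q <- efficiency^(-(ct - min(ct)))  # shift for numerical stability
  100 * q / sum(q)
}

#' Quantify absolute abundances for a spiked experiment
#'
#' Applies the ratio estimator per (sample, family), the isolation-loss
#' correction where the manifest calls for it, flags order-of-magnitude
#' outlier replicates within (group, family), and scales taxon profiles to
#' absolute units.
#'
#' @param counts A [count_table()].
#' @param manifest Manifest `data.frame` (see [read_manifest()]) with one
#'   row per (sample, family) carrying `spike_copies` and, for
#'   spike-after-isolation samples, `predicted_total_dna_ng` and
#'   `used_dna_ng`.
#' @param qc Optional `sample_qc` report from [qc_table()]; flagged
#'   (sample, family) pairs are excluded unless `keep_flagged = TRUE`.
#' @param keep_flagged Keep QC-flagged samples (default `FALSE`).
#' @return Object of class `abs_quant`: list with `estimates` (one row per
#'   sample x family: reads, spike copies, `copies_per_unit`, flags) and
#'   `profiles` (named list per family of samples x taxa absolute-abundance
#'   matrices).
#' @export
quantify <- function(counts, manifest, qc = NULL, keep_flagged = FALSE) {
  fams <- unique(attr(counts, "family"))
  syn <- attr(counts, "synthetic")
  famv <- attr(counts, "family")
  mkey <- paste(manifest$sample, manifest$family)
  est <- list(); profiles <- list()
  for (f in fams) {
    tot <- family_read_totals(counts, f)
    mi <- match(paste(tot$sample, f), mkey)
    if (anyNA(mi)) {
      stopf("manifest rows missing for family %s", f)
    }
    man <- manifest[mi, , drop = FALSE]
    keep <- rep(TRUE, nrow(tot))
    if (!is.null(qc) && !keep_flagged) {
      qkey <- paste(qc$sample, qc$family)
      qi <- match(paste(tot$sample, f), qkey)
      keep <- !(qc$flagged[qi] %in% TRUE)
    }
    usable <- keep & tot$synthetic_reads > 0
    e <- data.frame(
      sample = tot$sample, family = f, group = man$group,
      spike_level = if (!is.null(man$spike_level)) man$spike_level else NA,
      spike_copies = man$spike_copies,
      total_reads = tot$total_reads,
      synthetic_reads = tot$synthetic_reads,
      microbial_reads = tot$microbial_reads,
      corrected = FALSE,
      copies_per_unit = NA_real_,
      stringsAsFactors = FALSE
    )
    e$copies_per_unit[usable] <- absolute_abundance(
      tot$microbial_reads[usable], tot$synthetic_reads[usable],
      man$spike_copies[usable])
    after <- usable & man$spike_timing == "after"
    if (any(after)) {
      e$copies_per_unit[after] <- isolation_correction(
        e$copies_per_unit[after], man$predicted_total_dna_ng[after],
        man$used_dna_ng[after])
      e$corrected[after] <- TRUE
    }
    # order-of-magnitude outliers among biological replicates
    e$magnitude_outlier <- FALSE
    for (g in unique(e$group)) {
      sel <- which(e$group == g & !is.na(e$copies_per_unit) &
                     e$copies_per_unit > 0)
      if (length(sel) >= 2L) {
        e$magnitude_outlier[sel] <-
          filter_magnitude_outlier(e$copies_per_unit[sel])
      }
    }
    e$excluded <- !usable
    est[[f]] <- e

    # absolute taxon profiles for usable samples
    taxa <- rownames(counts)[famv == f & !syn]
    ok <- which(usable & tot$microbial_reads > 0)
    if (length(taxa) && length(ok)) {
      prof <- t(vapply(ok, function(i) {
        taxon_absolute(unclass(counts)[taxa, tot$sample[i]],
                       e$copies_per_unit[i])
      }, numeric(length(taxa))))
      rownames(prof) <- tot$sample[ok]
      colnames(prof) <- taxa
      profiles[[f]] <- prof
    }
  }
  structure(list(estimates = do.call(rbind, est), profiles = profiles,
                 families = fams),
            class = "abs_quant")
}

#' @export
print.abs_quant <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("absolute quantitation: %d samples x %d families\n",
              length(unique(e$sample)), length(x$families)))
  for (f in x$families) {
    sel <- e$family == f & !e$excluded
    if (!any(sel)) next
    cat(sprintf("  %s: median %.3g copies/unit (n = %d%s)\n", f,
                stats::median(e$copies_per_unit[sel], na.rm = TRUE),
                sum(sel),
                if (any(e$excluded[e$family == f]))
                  sprintf(", %d excluded", sum(e$excluded[e$family == f]))
                else ""))
  }
  invisible(x)
}

#' @export
summary.abs_quant <- function(object, ...) {
  e <- object$estimates[!object$estimates$excluded, , drop = FALSE]
  agg <- stats::aggregate(copies_per_unit ~ family + group, data = e,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) /
                                                sqrt(length(v)),
                                              n = length(v)))
  out <- data.frame(family = agg$family, group = agg$group,
                    mean = agg$copies_per_unit[, "mean"],
                    sem = agg$copies_per_unit[, "sem"],
                    n = agg$copies_per_unit[, "n"])
  class(out) <- c("summary.abs_quant", "data.frame")
  out
}

#' Relative (proportion) taxon profiles from counts
#'
#' Samples x taxa matrix of microbial read proportions for one family
#' (synthetic reads excluded).
#'
#' @param counts A [count_table()].
#' @param family Family label.
#' @return Matrix, rows = samples, columns = taxa, rows summing to 1.
#' @export
relative_profile <- function(counts, family) {
  famv <- attr(counts, "family"); syn <- attr(counts, "synthetic")
  taxa <- rownames(counts)[famv == family & !syn]
  m <- t(unclass(counts)[taxa, , drop = FALSE])
  tot <- rowSums(m)
  if (any(tot == 0)) {
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  m / tot
}

#' Absolute taxon profiles from a quantitation result
#'
#' @param x An `abs_quant` object.
#' @param family Family label.
#' @return Matrix, rows = samples, columns = taxa (copies per unit).
#' @export
absolute_profile <- function(x, family) {
  stopifnot(inherits(x, "abs_quant"))
  x$profiles[[family]]
}
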