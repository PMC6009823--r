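#' Simulate a multi-family microbial community
#'
#' Taxon abundances are drawn lognormally on the copy scale, normalised and
#' scaled to per-family totals. Defaults emulate a soil community:
#' prokaryotic 16S rRNA around 1e9, eukaryotic 18S rRNA around 1e8 and
#' fungal ITS around 1e7 gene copies per gram.
#'
#' @param n_taxa Named integer vector of taxa per family (default
#'   `c(P = 40, E = 30, F = 20)`).
#' @param family_totals Named numeric, total gene copies per gram per family
#'   (default `c(P = 1e9, E = 1e8, F = 1e7)`).
#' @param dispersion Log-scale (natural log) SD of taxon abundances
#'   (default 1.5; `0` gives equal proportions).
#' @param isolation_efficiency Fraction of DNA surviving isolation, in
#'   `(0, 1]` (default 1).
#' @param seed Integer seed.
#' @return Object of class `truth_record`: list with `taxa` (named copy
#'   vectors per family), `family_totals`, `isolation_efficiency`, `seed`.
#' @export
make_community <- function(n_taxa = c(P = 40L, E = 30L, F = 20L),
                           family_totals = c(P = 1e9, E = 1e8, F = 1e7),
                           dispersion = 1.5, isolation_efficiency = 1,
                           seed = NULL) {
  stopifnot(all(n_taxa >= 1L), all(family_totals > 0),
            dispersion >= 0, isolation_efficiency > 0,
            isolation_efficiency <= 1,
            identical(sort(names(n_taxa)), sort(names(family_totals))))
  taxa <- with_seed(seed, {
    out <- list()
    for (f in names(n_taxa)) {
      k <- n_taxa[[f]]
      w <- if (dispersion == 0) rep(1, k) else
        stats::rlnorm(k, meanlog = 0, sdlog = dispersion)
      v <- family_totals[[f]] * w / sum(w)
      names(v) <- sprintf("%s_taxon_%02d", f, seq_len(k))
      out[[f]] <- v
    }
    out
  })
  structure(list(taxa = taxa, family_totals = family_totals,
                 isolation_efficiency = isolation_efficiency, seed = seed),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("simulated community truth:\n")
  for (f in names(x$taxa)) {
    cat(sprintf("  %s: %d taxa, %.3g copies per unit\n", f,
                length(x$taxa[[f]]), sum(x$taxa[[f]])))
  }
  cat(sprintf("  isolation efficiency %.2f\n", x$isolation_efficiency))
  invisible(x)
}

#' Generate reference amplicon sequences for a simulated community
#'
#' One primer-inclusive amplicon per taxon: concrete forward binding site +
#' random interior + reverse-complemented concrete reverse binding site.
#' Fixed-window families get the target length; wide-window families (ITS)
#' get lengths drawn uniformly from the central part of the window.
#'
#' @param truth A `truth_record` from [make_community()].
#' @param primers Named list of [primer_pair()] covering the truth's
#'   families.
#' @param seed Integer seed.
#' @return Named list per family of named character vectors
#'   (taxon -> amplicon).
#' @export
make_reference_set <- function(truth, primers = default_primer_set(),
                               seed = 1L) {
  with_seed(seed, {
    refs <- list()
    for (f in names(truth$taxa)) {
      pp <- primers[[f]]
      w <- pp$amplicon_length_window
      fixed <- (w[2] - w[1]) <= 4L
      out <- character(length(truth$taxa[[f]]))
      for (i in seq_along(out)) {
        len <- if (fixed) pp$amplicon_length_target else {
          pad <- max(1L, (w[2] - w[1]) %/% 10L)
          sample(seq(w[1] + pad, w[2] - pad), 1L)
        }
        interior <- random_dna(len - nchar(pp$forward) - nchar(pp$reverse))
        out[i] <- paste0(concretize_iupac(pp$forward), interior,
                         concretize_iupac(revcomp(pp$reverse)))
      }
      names(out) <- names(truth$taxa[[f]])
      refs[[f]] <- out
    }
    refs
  })
}

#' Write reference amplicons to a labelled FASTA
#'
#' Headers follow the `>label;tax=<lineage>` convention consumed by
#' [read_reference_fasta()].
#'
#' @param refs Output of [make_reference_set()].
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  all <- unlist(unname(lapply(names(refs), function(f) {
    stats::setNames(refs[[f]],
                    sprintf("%s;tax=d:%s,g:%s", names(refs[[f]]), f,
                            names(refs[[f]])))
  })))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(all), path)
  invisible(path)
}

#' Draw sequencing read counts for one spiked sample
#'
#' Multinomial sequencing: read probabilities are proportional to
#' isolation-efficiency-scaled taxon copies plus spike copies. When spikes
#' are added *before* DNA isolation the loss scales spike and community DNA
#' alike (and cancels in downstream ratios); when added *after*, only the
#' community is scaled.
#'
#' @param truth A `truth_record`.
#' @param spike_copies Named numeric, spike copies added per unit per
#'   family.
#' @param depth Reads per family: single number or named vector
#'   (default 2e4).
#' @param spike_timing `"before"` (default) or `"after"` DNA isolation.
#' @param seed Integer seed.
#' @return Named list per family of named integer count vectors (taxa plus
#'   `spike_<family>`).
#' @export
sequence_sample <- function(truth, spike_copies, depth = 2e4,
                            spike_timing = c("before", "after"),
                            seed = NULL) {
  spike_timing <- match.arg(spike_timing)
  fams <- names(truth$taxa)
  if (length(depth) == 1L && is.null(names(depth))) {
    depth <- stats::setNames(rep(depth, length(fams)), fams)
  }
  stopifnot(all(depth[fams] >= 1))
  with_seed(seed, {
    out <- list()
    for (f in fams) {
      eff <- truth$isolation_efficiency
      taxa <- truth$taxa[[f]] * eff
      spike <- spike_copies[[f]] * if (spike_timing == "before") eff else 1
      pool <- c(taxa, stats::setNames(spike, paste0("spike_", f)))
      draw <- stats::rmultinom(1L, size = depth[[f]], prob = pool)[, 1]
      out[[f]] <- draw
    }
    out
  })
}

# Stack per-family count vectors of many samples into a count_table.
counts_to_table <- function(sample_counts) {
  samples <- names(sample_counts)
  fams <- names(sample_counts[[1]])
  categories <- unlist(lapply(fams, function(f) names(sample_counts[[1]][[f]])))
  fam_tag <- unlist(lapply(fams, function(f)
    rep(f, length(sample_counts[[1]][[f]]))))
  names(fam_tag) <- categories
  m <- vapply(samples, function(s) {
    unlist(lapply(fams, function(f) sample_counts[[s]][[f]]))
  }, numeric(length(categories)))
  rownames(m) <- categories
  count_table(m, fam_tag)
}

#' Simulate a full spiked sequencing experiment
#'
#' Builds the standard two-soil style design: for each community (group),
#' each requested spike level is applied in `replicates` biological
#' replicates; per-replicate communities get lognormal biological noise,
#' counts are drawn multinomially, and the matching manifest is emitted.
#'
#' @param communities Named list of `truth_record`s (one per group).
#' @param level_table A `spike_level_table` (default
#'   [spike_level_table()]).
#' @param levels Spike levels to use (default all in the table).
#' @param replicates Biological replicates per (group, level) (default 3).
#' @param depth Reads per (sample, family) (default 2e4).
#' @param bio_sdlog Per-replicate lognormal noise SD on taxon copies
#'   (default 0.1).
#' @param spike_timing `"before"` or `"after"` isolation (default
#'   `"before"`).
#' @param seed Integer seed.
#' @return List with `counts` (a [count_table()]), `manifest`
#'   (`data.frame`), `truth` (per-sample realised family totals) and
#'   `communities`.
#' @export
simulate_experiment <- function(communities, level_table = spike_level_table(),
                                levels = unique(level_table$level),
                                replicates = 3L, depth = 2e4,
                                bio_sdlog = 0.1,
                                spike_timing = "before", seed = 1L) {
  fams <- names(communities[[1]]$taxa)
  sample_counts <- list(); manifest <- list(); truth_rows <- list()
  k <- 0L
  for (g in names(communities)) {
    base <- communities[[g]]
    for (lv in levels) {
      dose <- level_table[level_table$level == lv &
                            level_table$family %in% fams, , drop = FALSE]
      spike <- stats::setNames(dose$copies, dose$family)
      for (r in seq_len(replicates)) {
        k <- k + 1L
        s <- sprintf("%s_L%d_r%d", g, lv, r)
        rep_truth <- base
        rep_truth$taxa <- with_seed(child_seed(seed, k), lapply(
          base$taxa, function(v) {
            if (bio_sdlog > 0)
              v * stats::rlnorm(length(v), 0, bio_sdlog) else v
          }))
        sample_counts[[s]] <- sequence_sample(
          rep_truth, spike, depth = depth, spike_timing = spike_timing,
          seed = child_seed(seed, k + 500000L))
        for (f in fams) {
          manifest[[paste(s, f)]] <- data.frame(
            sample = s, family = f, group = g, spike_level = lv,
            spike_copies = spike[[f]], amount_unit = "g",
            spike_timing = spike_timing, contaminated = FALSE,
            stringsAsFactors = FALSE)
          truth_rows[[paste(s, f)]] <- data.frame(
            sample = s, family = f, group = g, spike_level = lv,
            true_total = sum(rep_truth$taxa[[f]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(counts = counts_to_table(sample_counts),
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)),
       communities = communities)
}

#' Emit simulated reads as FASTQ
#'
#' Turns a latent count table into raw reads consistent with it: each read
#' is its category's reference amplicon wrapped in the sample's barcodes
#' and amplification pads, with optional i.i.d. substitution errors in the
#' amplicon. Qualities are fixed at 'I' (they are not consumed downstream).
#'
#' @param counts A [count_table()] (e.g. from [simulate_experiment()]).
#' @param references Named character vector mapping every category
#'   (including `spike_*`) to its primer-inclusive amplicon — e.g.
#'   `c(unlist(unname(make_reference_set(...))), spike amplicons)`.
#' @param scheme A [demux_scheme()] covering the samples.
#' @param path Output FASTQ path (`.gz` for compressed).
#' @param error_rate Per-base substitution probability in the amplicon
#'   (default 0).
#' @param seed Integer seed (read order and errors).
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(counts, references, scheme, path, error_rate = 0,
                       seed = 1L) {
  missing <- setdiff(rownames(counts)[rowSums(counts) > 0],
                     names(references))
  if (length(missing)) {
    stopf("references missing for categories: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  with_seed(seed, {
    all_reads <- character(0)
    for (s in colnames(counts)) {
      i <- match(s, scheme$samples)
      if (is.na(i)) stopf("sample %s not in demux scheme", s)
      cnt <- unclass(counts)[, s]
      cats <- names(cnt)[cnt > 0]
      amps <- rep(unname(references[cats]), cnt[cats])
      if (error_rate > 0 && length(amps)) {
        amps <- mutate_reads(amps, error_rate)
      }
      reads <- paste0(scheme$barcode_fwd[i], scheme$pad_forward, amps,
                      revcomp(scheme$pad_reverse),
                      revcomp(scheme$barcode_rev[i]))
      all_reads <- c(all_reads, reads)
    }
    all_reads <- all_reads[sample.int(length(all_reads))]
    x <- Biostrings::DNAStringSet(all_reads)
    names(x) <- sprintf("read_%07d", seq_along(x))
    qual <- Biostrings::BStringSet(strrep("I", nchar(all_reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  })
  invisible(path)
}

# i.i.d. substitution errors at `rate` per base.
mutate_reads <- function(seqs, rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Construct the relative-down / absolute-up two-group scenario
#'
#' Two sample groups built so that a designated taxon's true absolute
#' abundance is *higher* in group B while its true relative abundance is
#' *lower* — the other taxa are inflated more. Demonstrates that
#' compositional profiles can reverse the sign of a real change in load.
#'
#' @param seed Integer seed.
#' @param n_taxa Taxa in the (single-family) community (>= 2).
#' @param n_per_group Biological replicates per group (default 10).
#' @param depth Sequencing reads per sample (default 1e5).
#' @param focal_gain Absolute fold-change of the designated taxon in group B
#'   (default 1.5).
#' @param background_gain Absolute fold-change of all other taxa (default
#'   3; must exceed `focal_gain` for the relative sign to flip).
#' @param bio_sdlog Per-replicate lognormal noise (default 0.1).
#' @param family Family label used for the community (default `"P"`).
#' @param total Group-A family total (default 1e9 copies/g).
#' @param focal_share Designated taxon's share of the group-A total
#'   (default 0.1).
#' @return List: `counts` (a [count_table()] over both groups),
#'   `manifest`, `focal_taxon`, and `truth` (true absolute and relative
#'   B/A ratios of the focal taxon).
#' @export
scenario_relative_vs_absolute <- function(seed = 1L, n_taxa = 20L,
                                          n_per_group = 10L, depth = 1e5,
                                          focal_gain = 1.5,
                                          background_gain = 3,
                                          bio_sdlog = 0.1, family = "P",
                                          total = 1e9, focal_share = 0.1) {
  if (n_taxa < 2L) {
    stopf("the scenario needs at least two taxa (relative shares of a single taxon cannot move)")
  }
  stopifnot(background_gain > focal_gain, focal_gain > 1)
  base <- with_seed(seed, {
    w <- stats::rlnorm(n_taxa - 1L, 0, 1)
    c(focal_share * total, (1 - focal_share) * total * w / sum(w))
  })
  names(base) <- sprintf("%s_taxon_%02d", family, seq_len(n_taxa))
  focal <- names(base)[1]
  taxa_b <- base * c(focal_gain, rep(background_gain, n_taxa - 1L))
  spike <- stats::setNames(total, family)  # in-window for both groups

  draw_group <- function(taxa, label, offset) {
    out <- list()
    for (r in seq_len(n_per_group)) {
      tr <- structure(list(
        taxa = stats::setNames(list(with_seed(
          child_seed(seed, offset + r),
          taxa * stats::rlnorm(length(taxa), 0, bio_sdlog))), family),
        family_totals = stats::setNames(sum(taxa), family),
        isolation_efficiency = 1, seed = NULL), class = "truth_record")
      out[[sprintf("%s_r%02d", label, r)]] <- sequence_sample(
        tr, spike, depth = depth,
        seed = child_seed(seed, offset + 1000L + r))
    }
    out
  }
  counts <- counts_to_table(c(draw_group(base, "A", 0L),
                              draw_group(taxa_b, "B", 5000L)))
  manifest <- data.frame(
    sample = colnames(counts),
    family = family,
    group = substr(colnames(counts), 1, 1),
    spike_level = NA_integer_,
    spike_copies = spike[[family]],
    amount_unit = "g", spike_timing = "before", contaminated = FALSE,
    stringsAsFactors = FALSE)
  truth <- list(
    absolute_ratio = unname(taxa_b[focal] / base[focal]),
    relative_ratio = unname((taxa_b[focal] / sum(taxa_b)) /
                              (base[focal] / sum(base))))
  list(counts = counts, manifest = manifest, focal_taxon = focal,
       truth = truth)
}
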