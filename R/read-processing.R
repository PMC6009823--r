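#' Define a dual-barcode demultiplexing scheme
#'
#' Reads carry `barcode_fwd + pad_forward + amplicon +
#' revcomp(pad_reverse) + revcomp(barcode_rev)`: 12 bp amplification pads of
#' known sequence are added in the first PCR and dual sample barcodes
#' targeting the pads in the second.
#'
#' @param samples Character vector of sample identifiers.
#' @param barcode_fwd,barcode_rev Equal-length barcode vectors, one pair per
#'   sample; pairs must be unique.
#' @param pad_forward,pad_reverse 12 bp pad sequences shared by all samples.
#' @return Object of class `demux_scheme`.
#' @export
demux_scheme <- function(samples, barcode_fwd, barcode_rev,
                         pad_forward = "TATGGTAATTGT",
                         pad_reverse = "AGTCAGTCAGCC") {
  barcode_fwd <- toupper(barcode_fwd); barcode_rev <- toupper(barcode_rev)
  stopifnot(length(samples) == length(barcode_fwd),
            length(samples) == length(barcode_rev))
  if (length(unique(nchar(c(barcode_fwd, barcode_rev)))) != 1L) {
    stopf("all barcodes must have equal length")
  }
  key <- paste(barcode_fwd, barcode_rev, sep = ":")
  if (anyDuplicated(key)) stopf("duplicate barcode pairs in scheme")
  if (anyDuplicated(samples)) stopf("duplicate sample identifiers in scheme")
  structure(
    list(samples = as.character(samples), barcode_fwd = barcode_fwd,
         barcode_rev = barcode_rev, pad_forward = toupper(pad_forward),
         pad_reverse = toupper(pad_reverse),
         barcode_length = nchar(barcode_fwd[1])),
    class = "demux_scheme"
  )
}

#' Generate a deterministic demultiplexing scheme
#'
#' Assigns distinct 8 bp barcode pairs to samples, for simulation and
#' fixtures.
#'
#' @param samples Sample identifiers.
#' @param seed Integer seed for barcode generation.
#' @inheritParams demux_scheme
#' @return A [demux_scheme()].
#' @export
make_demux_scheme <- function(samples, seed = 1L,
                              pad_forward = "TATGGTAATTGT",
                              pad_reverse = "AGTCAGTCAGCC") {
  n <- length(samples)
  with_seed(seed, {
    draw <- function(k) {
      out <- character(0)
      while (length(out) < k) {
        cand <- vapply(seq_len(k), function(i) random_dna(8L), "")
        out <- unique(c(out, cand))
      }
      out[seq_len(k)]
    }
    demux_scheme(samples, draw(n), draw(n), pad_forward, pad_reverse)
  })
}

#' Read / write a demultiplexing scheme as TSV
#'
#' Columns `sample`, `barcode_fwd`, `barcode_rev`, `pad_forward`,
#' `pad_reverse` (pads repeated on every row).
#'
#' @param scheme A [demux_scheme()].
#' @param path TSV path.
#' @return `read_demux_scheme` returns a [demux_scheme()].
#' @export
write_demux_scheme <- function(scheme, path) {
  utils::write.table(
    data.frame(sample = scheme$samples, barcode_fwd = scheme$barcode_fwd,
               barcode_rev = scheme$barcode_rev,
               pad_forward = scheme$pad_forward,
               pad_reverse = scheme$pad_reverse),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_demux_scheme
#' @export
read_demux_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  demux_scheme(df$sample, df$barcode_fwd, df$barcode_rev,
               df$pad_forward[1], df$pad_reverse[1])
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ path (plain or gzip).
#' @return Named character vector of read sequences (names = identifiers).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Demultiplex reads by dual barcodes
#'
#' Each read is assigned to exactly one sample (or left unassigned) by its
#' forward barcode prefix and the reverse complement of its reverse barcode
#' suffix; barcodes and pads are trimmed from assigned reads. Reads whose
#' pads do not match within `pad_max_mismatches` are unassigned. Read counts
#' are conserved: every input read lands in one sample bin or in
#' `unassigned`.
#'
#' @param reads Character vector of read sequences (named or not).
#' @param scheme A [demux_scheme()].
#' @param max_mismatches Per-barcode substitution budget (default 0,
#'   exact matching).
#' @param pad_max_mismatches Per-pad substitution budget (default 1).
#' @return List with `samples` (named list of trimmed read vectors),
#'   `unassigned` (untrimmed reads) and `n_input`.
#' @export
demultiplex <- function(reads, scheme, max_mismatches = 0L,
                        pad_max_mismatches = 1L) {
  stopifnot(inherits(scheme, "demux_scheme"))
  bl <- scheme$barcode_length
  pl_f <- nchar(scheme$pad_forward)
  pl_r <- nchar(scheme$pad_reverse)
  n <- nchar(reads)
  min_len <- 2L * bl + pl_f + pl_r + 1L
  long_enough <- n >= min_len

  bc_f <- substring(reads, 1L, bl)
  bc_r <- revcomp(substring(reads, n - bl + 1L, n))
  idx <- rep(NA_integer_, length(reads))
  if (max_mismatches == 0L) {
    key <- paste(bc_f, bc_r, sep = ":")
    idx <- match(key, paste(scheme$barcode_fwd, scheme$barcode_rev,
                            sep = ":"))
  } else {
    best_mm <- rep(Inf, length(reads))
    for (i in seq_along(scheme$samples)) {
      mf <- hamming_to_fixed(bc_f, scheme$barcode_fwd[i])
      mr <- hamming_to_fixed(bc_r, scheme$barcode_rev[i])
      ok <- mf <= max_mismatches & mr <= max_mismatches
      tot <- mf + mr
      take <- ok & tot < best_mm
      idx[take] <- i
      best_mm[take] <- tot[take]
    }
  }
  idx[!long_enough] <- NA_integer_

  # pad check on barcode-trimmed reads
  assigned <- !is.na(idx)
  inner <- substring(reads, bl + 1L, n - bl)
  if (any(assigned)) {
    pf_mm <- iupac_mismatches(inner[assigned], scheme$pad_forward)
    pr_mm <- iupac_mismatches_suffix(inner[assigned],
                                     revcomp(scheme$pad_reverse))
    bad <- pf_mm > pad_max_mismatches | pr_mm > pad_max_mismatches
    idx[assigned][bad] <- NA_integer_
    assigned <- !is.na(idx)
  }

  trimmed <- substring(reads, bl + pl_f + 1L, n - bl - pl_r)
  samples <- stats::setNames(vector("list", length(scheme$samples)),
                             scheme$samples)
  for (i in seq_along(scheme$samples)) {
    samples[[i]] <- trimmed[which(idx == i)]
  }
  list(samples = samples, unassigned = reads[!assigned],
       n_input = length(reads))
}

# Hamming distance of each string in `x` (all same length as `ref`).
hamming_to_fixed <- function(x, ref) {
  k <- nchar(ref)
  mm <- integer(length(x))
  rc <- strsplit(ref, "")[[1]]
  for (i in seq_len(k)) {
    mm <- mm + (substring(x, i, i) != rc[i])
  }
  mm
}

#' Assign reads to amplicon families by primer-binding sites
#'
#' A read belongs to a family when the family's forward primer matches at
#' its 5' end and the reverse primer's reverse complement at its 3' end,
#' each within the substitution budget. When several families match, the one
#' with the fewest total mismatches wins (ties: first in `primer_pairs`
#' order). Both binding sites are trimmed from assigned reads; the
#' primer-inclusive amplicon length is retained for length filtering.
#'
#' @param reads Character vector of pad-trimmed amplicon sequences.
#' @param primer_pairs Named list of [primer_pair()].
#' @param max_mismatches Per-primer substitution budget (default 1).
#' @return `data.frame` with columns `family` (`NA` when no family
#'   matches), `trimmed` (primer-free interior) and `amplicon_length`
#'   (primer-inclusive).
#' @export
assign_family <- function(reads, primer_pairs, max_mismatches = 1L) {
  n <- nchar(reads)
  fam <- rep(NA_character_, length(reads))
  best <- rep(Inf, length(reads))
  mm_store <- list()
  for (f in names(primer_pairs)) {
    pp <- primer_pairs[[f]]
    lf <- nchar(pp$forward); lr <- nchar(pp$reverse)
    mf <- iupac_mismatches(reads, pp$forward)
    mr <- iupac_mismatches_suffix(reads, revcomp(pp$reverse))
    ok <- mf <= max_mismatches & mr <= max_mismatches & n >= (lf + lr)
    tot <- mf + mr
    take <- ok & tot < best
    fam[take] <- f
    best[take] <- tot[take]
  }
  trimmed <- rep(NA_character_, length(reads))
  for (f in names(primer_pairs)) {
    pp <- primer_pairs[[f]]
    sel <- which(fam == f)
    if (length(sel)) {
      trimmed[sel] <- substring(reads[sel], nchar(pp$forward) + 1L,
                                n[sel] - nchar(pp$reverse))
    }
  }
  data.frame(family = fam, trimmed = trimmed, amplicon_length = n,
             stringsAsFactors = FALSE)
}

#' Filter reads by amplicon length window
#'
#' A read is retained iff its family's window contains its primer-inclusive
#' amplicon length (sequenced read lengths are filtered, not trimmed
#' interiors).
#'
#' @param amplicon_length Integer vector of primer-inclusive lengths.
#' @param family Character vector of family assignments (parallel to
#'   `amplicon_length`).
#' @param windows Named list of inclusive `c(low, high)` windows per family
#'   present, or a list of [primer_pair()] (windows taken from them).
#' @return Logical `keep` vector with attribute `"retention"`, a named
#'   per-family retained fraction.
#' @export
length_filter <- function(amplicon_length, family, windows) {
  fams <- unique(stats::na.omit(family))
  win <- lapply(windows, function(w) {
    if (inherits(w, "primer_pair")) w$amplicon_length_window else w
  })
  if (!all(fams %in% names(win))) {
    stopf("length window missing for family: %s",
          paste(setdiff(fams, names(win)), collapse = ", "))
  }
  keep <- rep(FALSE, length(amplicon_length))
  retention <- stats::setNames(numeric(length(fams)), fams)
  for (f in fams) {
    sel <- which(family == f)
    w <- win[[f]]
    ok <- amplicon_length[sel] >= w[1] & amplicon_length[sel] <= w[2]
    keep[sel] <- ok
    retention[f] <- mean(ok)
  }
  attr(keep, "retention") <- retention
  keep
}

#' Classify reads into synthetic and taxon categories
#'
#' Nearest-neighbour classification by Hamming distance over equal-length
#' references: a read is counted to its family's synthetic category when it
#' matches a spike reference within the budget, otherwise to the taxon label
#' of its nearest reference within the budget, otherwise it is unassigned.
#' Ties between taxon references break to the lexicographically first label.
#' Per-sample read totals are conserved
#' (`colSums(counts) + unassigned == input`).
#'
#' @param reads Named list (by sample) of `data.frame`s with columns
#'   `family`, `trimmed` — e.g. the output of [assign_family()] split by
#'   sample, length-filtered.
#' @param spike_refs Named character vector of primer-trimmed spike interiors
#'   (names `spike_<family>`), or full amplicons plus `primer_pairs` to trim.
#' @param taxon_refs Named list per family of named character vectors
#'   (taxon label -> primer-trimmed reference interior), or full amplicons
#'   plus `primer_pairs`.
#' @param max_mismatches Substitution budget (default 2).
#' @param primer_pairs Optional named list of [primer_pair()]; when given,
#'   references are assumed primer-inclusive and are trimmed before
#'   matching.
#' @param drop_singletons Drop categories with a single read across all
#'   samples (optional dereplication path; default `FALSE`).
#' @return A [count_table()] with attribute `"unassigned"` — a
#'   `data.frame` of per (sample, family) unassigned read counts.
#' @export
classify_reads <- function(reads, spike_refs, taxon_refs,
                           max_mismatches = 2L, primer_pairs = NULL,
                           drop_singletons = FALSE) {
  trim_ref <- function(seqs, fam) {
    if (is.null(primer_pairs)) return(seqs)
    pp <- primer_pairs[[fam]]
    stats::setNames(substring(seqs, nchar(pp$forward) + 1L,
                              nchar(seqs) - nchar(pp$reverse)), names(seqs))
  }
  fams <- names(taxon_refs)
  for (f in fams) {
    if (any(vapply(reads, function(df) any(df$family == f, na.rm = TRUE),
                   TRUE)) && length(taxon_refs[[f]]) == 0L) {
      stopf("family %s has reads but no references", f)
    }
  }
  categories <- character(0); cat_family <- character(0)
  for (f in fams) {
    categories <- c(categories, paste0("spike_", f),
                    sort(names(taxon_refs[[f]])))
    cat_family <- c(cat_family, f, rep(f, length(taxon_refs[[f]])))
  }
  names(cat_family) <- categories
  samples <- names(reads)
  counts <- matrix(0L, nrow = length(categories), ncol = length(samples),
                   dimnames = list(categories, samples))
  unassigned <- expand.grid(sample = samples, family = fams,
                            stringsAsFactors = FALSE)
  unassigned$reads <- 0L

  for (f in fams) {
    spike_name <- paste0("spike_", f)
    sref <- trim_ref(unname(spike_refs[spike_name]), f)
    tref <- trim_ref(taxon_refs[[f]], f)
    tref <- tref[order(names(tref))]  # lexicographic tie-break order
    ref_labels <- c(spike_name, names(tref))
    ref_seqs <- c(sref, unname(tref))
    for (s in samples) {
      df <- reads[[s]]
      seqs <- df$trimmed[!is.na(df$family) & df$family == f]
      if (!length(seqs)) next
      tab <- table(seqs)
      uq <- names(tab)
      lab <- classify_unique(uq, ref_labels, ref_seqs, max_mismatches)
      cnt <- as.integer(tab)
      ok <- !is.na(lab)
      if (any(ok)) {
        add <- tapply(cnt[ok], lab[ok], sum)
        counts[names(add), s] <- counts[names(add), s] + as.integer(add)
      }
      urow <- unassigned$sample == s & unassigned$family == f
      unassigned$reads[urow] <- unassigned$reads[urow] + sum(cnt[!ok])
    }
  }
  out <- count_table(counts, cat_family)
  if (drop_singletons) {
    syn <- attr(out, "synthetic")
    keep <- rowSums(out) != 1L | syn
    out <- count_table(unclass(out)[keep, , drop = FALSE],
                       attr(out, "family")[keep], syn[keep])
  }
  attr(out, "unassigned") <- unassigned
  out
}

# Classify unique read sequences against references. Spike reference(s)
# come first in ref_labels/ref_seqs and take priority within budget.
classify_unique <- function(uq, ref_labels, ref_seqs, max_mismatches) {
  lab <- rep(NA_character_, length(uq))
  # fast path: exact matches (spike first, then lexicographic taxon order)
  exact <- match(uq, ref_seqs)
  lab[!is.na(exact)] <- ref_labels[exact[!is.na(exact)]]
  todo <- which(is.na(lab))
  if (!length(todo) || max_mismatches == 0L) return(lab)
  ref_len <- nchar(ref_seqs)
  uq_len <- nchar(uq)
  for (i in todo) {
    cand <- which(ref_len == uq_len[i])
    if (!length(cand)) next
    d <- hamming_to(ref_seqs[cand], uq[i])
    ok <- d <= max_mismatches
    if (!any(ok)) next
    # spike (index 1) priority, then smallest distance, then first label
    if (1L %in% cand[ok] && d[which(cand == 1L)] <= max_mismatches) {
      lab[i] <- ref_labels[1L]
    } else {
      cand <- cand[ok]; d <- d[ok]
      lab[i] <- ref_labels[cand[which.min(d)]]
    }
  }
  lab
}

#' Run the full read-processing pipeline
#'
#' Demultiplex, assign families, apply length windows, classify, in one
#' call, with per-stage read accounting.
#'
#' @param reads Character vector of raw reads, or a FASTQ path.
#' @param scheme A [demux_scheme()].
#' @param primer_pairs Named list of [primer_pair()] (windows taken from
#'   them).
#' @param spike_refs,taxon_refs Primer-inclusive reference amplicons (see
#'   [classify_reads()]; they are trimmed with `primer_pairs`).
#' @param barcode_max_mismatches,primer_max_mismatches,classify_max_mismatches
#'   Stage budgets (defaults 0, 1, 2).
#' @param drop_singletons Passed to [classify_reads()].
#' @return List with `counts` (a [count_table()]), `stats` (per-stage read
#'   counts) and `retention` (per-family length-filter retention).
#' @export
process_reads <- function(reads, scheme, primer_pairs, spike_refs,
                          taxon_refs, barcode_max_mismatches = 0L,
                          primer_max_mismatches = 1L,
                          classify_max_mismatches = 2L,
                          drop_singletons = FALSE) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  dm <- demultiplex(reads, scheme, max_mismatches = barcode_max_mismatches)
  per_sample <- list()
  n_no_family <- 0L; n_off_length <- 0L
  retention <- NULL
  for (s in names(dm$samples)) {
    af <- assign_family(dm$samples[[s]], primer_pairs,
                        max_mismatches = primer_max_mismatches)
    n_no_family <- n_no_family + sum(is.na(af$family))
    af <- af[!is.na(af$family), , drop = FALSE]
    if (nrow(af)) {
      keep <- length_filter(af$amplicon_length, af$family, primer_pairs)
      ret <- attr(keep, "retention")
      retention <- if (is.null(retention)) ret else {
        both <- union(names(retention), names(ret))
        stats::setNames(
          vapply(both, function(f) {
            mean(c(retention[f], ret[f]), na.rm = TRUE)
          }, numeric(1)), both)
      }
      n_off_length <- n_off_length + sum(!keep)
      af <- af[keep, , drop = FALSE]
    }
    per_sample[[s]] <- af
  }
  counts <- classify_reads(per_sample, spike_refs, taxon_refs,
                           max_mismatches = classify_max_mismatches,
                           primer_pairs = primer_pairs,
                           drop_singletons = drop_singletons)
  stats <- data.frame(
    stage = c("input", "demultiplexed", "family_assigned", "length_kept",
              "classified"),
    reads = c(dm$n_input, dm$n_input - length(dm$unassigned),
              dm$n_input - length(dm$unassigned) - n_no_family,
              dm$n_input - length(dm$unassigned) - n_no_family -
                n_off_length,
              sum(counts))
  )
  list(counts = counts, stats = stats, retention = retention)
}

#' Read a labelled reference FASTA
#'
#' Headers follow `>label;tax=<lineage>`; the label becomes the category
#' name and the lineage is kept as an attribute.
#'
#' @param path FASTA path.
#' @param family_map Optional named character vector label -> family; when
#'   absent, labels are expected to start with `<family>_`.
#' @return Named list per family of named character vectors
#'   (label -> sequence), with attribute `"taxonomy"`.
#' @export
read_reference_fasta <- function(path, family_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  label <- sub(";.*$", "", hdr)
  tax <- ifelse(grepl(";tax=", hdr), sub("^.*;tax=", "", hdr), NA_character_)
  fam <- if (!is.null(family_map)) unname(family_map[label]) else {
    sub("_.*$", "", label)
  }
  out <- lapply(split(stats::setNames(as.character(seqs), label), fam),
                identity)
  attr(out, "taxonomy") <- stats::setNames(tax, label)
  out
}
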