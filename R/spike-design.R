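#' Define an amplicon primer pair
#'
#' A primer pair delimits one amplicon family (e.g. prokaryotic 16S rRNA V4,
#' eukaryotic 18S rRNA, fungal ITS1). The target length and window are the
#' full amplicon lengths (primer-binding sites included), matching how read
#' lengths are filtered downstream.
#'
#' @param name Label, e.g. `"P/16S"`.
#' @param forward,reverse IUPAC DNA strings (reverse given 5'->3' on the
#'   opposite strand, as primers are ordered).
#' @param amplicon_length_target Integer, expected amplicon length in bp.
#' @param amplicon_length_window Inclusive integer range `c(low, high)` of
#'   acceptable amplicon lengths; must contain the target.
#' @return An object of class `primer_pair`.
#' @export
#' @examples
#' primer_pair("P/16S", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT",
#'             253, c(252, 254))
primer_pair <- function(name, forward, reverse, amplicon_length_target,
                        amplicon_length_window) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!is_iupac_dna(forward) || !is_iupac_dna(reverse)) {
    stopf("primers must be non-empty IUPAC DNA strings")
  }
  amplicon_length_window <- as.integer(amplicon_length_window)
  amplicon_length_target <- as.integer(amplicon_length_target)
  if (length(amplicon_length_window) != 2L ||
      amplicon_length_window[1] > amplicon_length_window[2]) {
    stopf("amplicon_length_window must be c(low, high) with low <= high")
  }
  if (amplicon_length_target < amplicon_length_window[1] ||
      amplicon_length_target > amplicon_length_window[2]) {
    stopf("amplicon_length_target must lie within amplicon_length_window")
  }
  structure(
    list(name = name, forward = forward, reverse = reverse,
         amplicon_length_target = amplicon_length_target,
         amplicon_length_window = amplicon_length_window),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer pair %s: %s / %s, amplicon %d bp (window %d-%d)\n",
              x$name, x$forward, x$reverse, x$amplicon_length_target,
              x$amplicon_length_window[1], x$amplicon_length_window[2]))
  invisible(x)
}

#' Default primer set for the P/E/F spike families
#'
#' Three widely used soil primer pairs: 515F/806R for the prokaryotic 16S
#' rRNA V4 region (family `P`), F1427/R1616 for eukaryotic 18S rRNA (family
#' `E`) and ITS1F/ITS2 for fungal ITS1 (family `F`). Amplicon length targets
#' default to the centres of the read-length windows used downstream
#' (252-254, 210-212 and 250-300 bp); the ITS target is 272 bp, the modal
#' fungal amplicon size in soil.
#'
#' @param path Optional path to a YAML primer/stock config
#'   (see `system.file("extdata", "primers.yml", package = "spikequant")`).
#' @return Named list of [primer_pair()] objects, with per-family spike
#'   stocks attached as attribute `"stocks"` when present in the config.
#' @export
default_primer_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "primers.yml", package = "spikequant")
  }
  read_primer_config(path)
}

#' Read a primer/stock configuration file
#'
#' The config is YAML with one block per family carrying `name`, `forward`,
#' `reverse`, `amplicon_length_target`, `amplicon_length_window` and
#' optionally `stock_copies_per_ng` and `construct_length_bp`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [primer_pair()] objects; attribute `"stocks"`
#'   holds a list of [spike_stock()] objects for families that declare one.
#' @export
read_primer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pairs <- list(); stocks <- list()
  for (fam in names(cfg)) {
    b <- cfg[[fam]]
    pairs[[fam]] <- primer_pair(
      name = b$name %||% fam, forward = b$forward, reverse = b$reverse,
      amplicon_length_target = b$amplicon_length_target,
      amplicon_length_window = unlist(b$amplicon_length_window)
    )
    if (!is.null(b$stock_copies_per_ng)) {
      stocks[[fam]] <- spike_stock(fam, b$stock_copies_per_ng,
                                   b$construct_length_bp %||% NULL)
    }
  }
  attr(pairs, "stocks") <- stocks
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random stuffer sequence
#'
#' Draws i.i.d. bases biased to the GC target and rejection-samples until the
#' candidate satisfies all constraints: GC fraction within tolerance, no
#' homopolymer longer than `max_homopolymer`, and no window within
#' `motif_max_mismatches` substitutions of any forbidden motif or its reverse
#' complement (used to keep primer-binding sites out of the stuffer).
#'
#' @param length_bp Stuffer length in bp (`0` returns `""`).
#' @param gc_target Target G+C fraction in `[0, 1]`.
#' @param gc_tolerance Maximum absolute deviation from `gc_target`.
#' @param forbidden_motifs Character vector of IUPAC DNA motifs that must not
#'   occur (nor their reverse complements).
#' @param seed Integer seed for reproducibility; the caller's RNG state is
#'   untouched.
#' @param motif_max_mismatches Substitution budget for motif screening
#'   (default 2: windows at Hamming distance <= 2 from a motif are rejected).
#' @param max_homopolymer Longest allowed single-base run (default 8).
#' @param max_attempts Rejection-sampling budget; exceeding it signals
#'   over-constrained inputs and raises an error.
#' @return A plain DNA string of exactly `length_bp` bases.
#' @export
#' @examples
#' s <- generate_stuffer(272, 0.5, 0.02, seed = 1)
#' nchar(s)
#' gc_fraction(s)
generate_stuffer <- function(length_bp, gc_target = 0.5, gc_tolerance = 0.02,
                             forbidden_motifs = character(), seed = NULL,
                             motif_max_mismatches = 2L, max_homopolymer = 8L,
                             max_attempts = 10000L) {
  length_bp <- as.integer(length_bp)
  stopifnot(length_bp >= 0L, gc_target >= 0, gc_target <= 1,
            gc_tolerance >= 0)
  if (length_bp == 0L) return("")
  motifs <- toupper(forbidden_motifs)
  motifs <- unique(c(motifs, revcomp(motifs)))
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      cand <- random_dna(length_bp, gc_target)
      if (abs(gc_fraction(cand) - gc_target) > gc_tolerance + 1e-12) next
      if (max_homopolymer_run(cand) > max_homopolymer) next
      if (has_motif_hit(cand, motifs, motif_max_mismatches)) next
      return(cand)
    }
    stopf(paste("no stuffer satisfying the constraints found in %d attempts;",
                "the GC target/tolerance, homopolymer cap and forbidden",
                "motifs are jointly over-constrained"), max_attempts)
  })
}

# TRUE when any sliding window of `seq` is within `max_mm` substitutions of
# any motif (motifs already include reverse complements).
has_motif_hit <- function(seq, motifs, max_mm) {
  n <- nchar(seq)
  for (m in motifs) {
    k <- nchar(m)
    if (k == 0L || k > n) next
    starts <- seq_len(n - k + 1L)
    windows <- substring(seq, starts, starts + k - 1L)
    if (any(iupac_mismatches(windows, m) <= max_mm)) return(TRUE)
  }
  FALSE
}

#' Assemble a chimeric spike amplicon
#'
#' The spike amplicon is the forward primer-binding site, the stuffer, then
#' the reverse complement of the reverse primer, so that PCR with the pair
#' yields a product of exactly the target length.
#'
#' @param primer_pair A [primer_pair()].
#' @param stuffer Plain DNA string; its length must equal
#'   `amplicon_length_target - nchar(forward) - nchar(reverse)`.
#' @param family Spike family label (e.g. `"P"`).
#' @param gc_target,gc_tolerance Design GC constraint recorded for
#'   validation (defaults 0.5 and 0.02).
#' @param construct_length_bp Optional full delivered-construct length
#'   (plasmid plus insert) used for mass-to-copies conversion.
#' @param resolve_iupac Replace ambiguity codes in the primer-binding sites
#'   by concrete bases (required for a synthesisable construct); uses the
#'   current RNG state, so wrap in a seeded call for reproducibility.
#' @return An object of class `spike_spec` with elements `family`,
#'   `primer_pair`, `stuffer`, `amplicon` and the design parameters.
#' @export
#' @examples
#' pp <- primer_pair("toy", "ACGT", "GGCC", 10, c(9, 11))
#' assemble_spike(pp, "TT", family = "X")$amplicon  # "ACGTTTGGCC"
assemble_spike <- function(primer_pair, stuffer, family = primer_pair$name,
                           gc_target = 0.5, gc_tolerance = 0.02,
                           construct_length_bp = NULL,
                           resolve_iupac = FALSE) {
  stuffer <- toupper(stuffer)
  implied <- primer_pair$amplicon_length_target -
    nchar(primer_pair$forward) - nchar(primer_pair$reverse)
  if (implied < 0L) {
    stopf("primers (%d bp) exceed the amplicon length target (%d bp)",
          nchar(primer_pair$forward) + nchar(primer_pair$reverse),
          primer_pair$amplicon_length_target)
  }
  if (nchar(stuffer) != implied) {
    stopf("stuffer must be %d bp for a %d bp amplicon (got %d bp)",
          implied, primer_pair$amplicon_length_target, nchar(stuffer))
  }
  fwd <- primer_pair$forward
  rev_rc <- revcomp(primer_pair$reverse)
  if (resolve_iupac) {
    fwd <- concretize_iupac(fwd)
    rev_rc <- concretize_iupac(rev_rc)
  }
  amplicon <- paste0(fwd, stuffer, rev_rc)
  structure(
    list(family = family, primer_pair = primer_pair, stuffer = stuffer,
         amplicon = amplicon, gc_target = gc_target,
         gc_tolerance = gc_tolerance,
         construct_length_bp = construct_length_bp),
    class = "spike_spec"
  )
}

#' @export
print.spike_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic spike [%s]: amplicon %d bp, stuffer %d bp (GC %.3f)\n",
    x$family, nchar(x$amplicon), nchar(x$stuffer), gc_fraction(x$stuffer)))
  invisible(x)
}

#' Design a synthetic spike for one primer pair
#'
#' Convenience wrapper: computes the stuffer length implied by the pair's
#' amplicon target, generates a stuffer screened against every primer in
#' `all_primers` (forward and reverse complements), and assembles the
#' amplicon with concrete primer-binding sites.
#'
#' @inheritParams assemble_spike
#' @inheritParams generate_stuffer
#' @param all_primers List of [primer_pair()] whose binding sites must not
#'   appear inside the stuffer (defaults to just `primer_pair`).
#' @return A `spike_spec`.
#' @export
design_spike <- function(primer_pair, family = primer_pair$name,
                         gc_target = 0.5, gc_tolerance = 0.02,
                         all_primers = list(primer_pair), seed = NULL,
                         construct_length_bp = NULL, ...) {
  stuffer_len <- primer_pair$amplicon_length_target -
    nchar(primer_pair$forward) - nchar(primer_pair$reverse)
  motifs <- unlist(lapply(all_primers, function(p) c(p$forward, p$reverse)))
  stuffer <- generate_stuffer(stuffer_len, gc_target, gc_tolerance,
                              forbidden_motifs = motifs, seed = seed, ...)
  with_seed(child_seed(seed, 1L),
            assemble_spike(primer_pair, stuffer, family = family,
                           gc_target = gc_target,
                           gc_tolerance = gc_tolerance,
                           construct_length_bp = construct_length_bp,
                           resolve_iupac = TRUE))
}

#' Design the full default spike set
#'
#' One spike per family in the primer set, each screened against all
#' binding sites in the set.
#'
#' @param primers Named list of [primer_pair()] (default
#'   [default_primer_set()]).
#' @param gc_target,gc_tolerance GC design constraint shared by all spikes.
#' @param seed Integer seed; per-family seeds are derived from it.
#' @param construct_length_bp Full construct length recorded on each spike
#'   (default 2504 bp, a plasmid-plus-insert scale consistent with the
#'   default stock calibration of ~3.7e8 copies/ng).
#' @return Named list of `spike_spec` objects.
#' @export
design_spike_set <- function(primers = default_primer_set(),
                             gc_target = 0.5, gc_tolerance = 0.02,
                             seed = 1L, construct_length_bp = 2504L) {
  out <- list()
  for (i in seq_along(primers)) {
    fam <- names(primers)[i]
    out[[fam]] <- design_spike(primers[[i]], family = fam,
                               gc_target = gc_target,
                               gc_tolerance = gc_tolerance,
                               all_primers = primers,
                               seed = child_seed(seed, i * 13L),
                               construct_length_bp = construct_length_bp)
  }
  out
}

#' In-silico PCR
#'
#' Finds every product delimited by a forward-primer match and a downstream
#' reverse-primer (reverse-complement) match within a size cap. IUPAC
#' ambiguity codes in the primers match their base sets.
#'
#' @param template DNA string (plain or IUPAC).
#' @param primer_pair A [primer_pair()].
#' @param max_mismatches Substitution budget per primer (default 1).
#' @param max_product_bp Size cap on reported products (default 3000).
#' @return `data.frame` with columns `start`, `end`, `length` (1-based,
#'   inclusive, product includes both primer sites); zero rows when there is
#'   no product.
#' @export
in_silico_pcr <- function(template, primer_pair, max_mismatches = 1L,
                          max_product_bp = 3000L) {
  stopifnot(nzchar(template))
  subj <- Biostrings::DNAString(toupper(template))
  fwd_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer_pair$forward), subj,
    max.mismatch = max_mismatches, fixed = FALSE)
  rev_hits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(primer_pair$reverse)),
    subj, max.mismatch = max_mismatches, fixed = FALSE)
  fs <- BiocGenerics::start(fwd_hits)
  fe <- BiocGenerics::end(fwd_hits)
  re <- BiocGenerics::end(rev_hits)
  rs <- BiocGenerics::start(rev_hits)
  out <- data.frame(start = integer(), end = integer(), length = integer())
  for (i in seq_along(fs)) {
    ok <- rs >= fe[i] & (re - fs[i] + 1L) <= max_product_bp
    if (any(ok)) {
      out <- rbind(out, data.frame(start = fs[i], end = re[ok],
                                   length = re[ok] - fs[i] + 1L))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Validate a spike design
#'
#' Checks the design constraints: amplicon length inside the primer pair's
#' window, stuffer GC within tolerance of the design target, no
#' primer-binding site from any pair in the experiment inside the stuffer
#' (Hamming budget over sliding windows, forward and reverse-complement), and
#' no homopolymer beyond the cap.
#'
#' @param spike A `spike_spec`.
#' @param all_primers List of [primer_pair()] to screen against (default:
#'   the spike's own pair).
#' @param motif_max_mismatches Substitution budget for the cross-binding-site
#'   screen (default 2).
#' @param max_homopolymer Longest allowed run (default 8).
#' @return `data.frame` with columns `check`, `pass`, `detail`; attribute
#'   `"pass"` is `TRUE` when every check passed.
#' @export
validate_spike <- function(spike, all_primers = list(spike$primer_pair),
                           motif_max_mismatches = 2L, max_homopolymer = 8L) {
  pp <- spike$primer_pair
  len <- nchar(spike$amplicon)
  len_ok <- len >= pp$amplicon_length_window[1] &&
    len <= pp$amplicon_length_window[2]
  gc <- gc_fraction(spike$stuffer)
  gc_ok <- abs(gc - spike$gc_target) <= spike$gc_tolerance + 1e-12
  motifs <- unlist(lapply(all_primers, function(p) c(p$forward, p$reverse)))
  motifs <- unique(c(toupper(motifs), revcomp(toupper(motifs))))
  pbs_ok <- !has_motif_hit(spike$stuffer, motifs, motif_max_mismatches)
  run <- max_homopolymer_run(spike$stuffer)
  run_ok <- run <= max_homopolymer
  rep <- data.frame(
    check = c("amplicon_length_in_window", "stuffer_gc_in_tolerance",
              "no_pbs_in_stuffer", "homopolymer_cap"),
    pass = c(len_ok, gc_ok, pbs_ok, run_ok),
    detail = c(
      sprintf("length %d, window %d-%d", len, pp$amplicon_length_window[1],
              pp$amplicon_length_window[2]),
      sprintf("GC %.4f, target %.2f +/- %.2f", gc, spike$gc_target,
              spike$gc_tolerance),
      sprintf("screened %d motifs at <=%d mismatches", length(motifs),
              motif_max_mismatches),
      sprintf("longest run %d, cap %d", run, max_homopolymer)
    ),
    stringsAsFactors = FALSE
  )
  attr(rep, "pass") <- all(rep$pass)
  rep
}

#' Write spikes to FASTA
#'
#' One record per spike amplicon; headers carry family, GC and length
#' (`>spike_P family=P gc=0.500 length=253`).
#'
#' @param spikes Named list of `spike_spec`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_spike_fasta <- function(spikes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(spikes, `[[`, "", "amplicon"))
  names(seqs) <- vapply(spikes, function(s) {
    sprintf("spike_%s family=%s gc=%.3f length=%d", s$family, s$family,
            gc_fraction(s$stuffer), nchar(s$amplicon))
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read spike amplicons from FASTA
#'
#' @param path FASTA path written by [write_spike_fasta()] (or any FASTA
#'   whose first header token is `spike_<family>`).
#' @return Named character vector of amplicon sequences, names
#'   `spike_<family>`.
#' @export
read_spike_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  out <- as.character(seqs)
  names(out) <- ids
  out
}
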