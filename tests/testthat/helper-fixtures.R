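# Shared fixtures, built once per test run.

fx_primers <- default_primer_set()
fx_spikes <- design_spike_set(fx_primers, seed = 101)
fx_spike_amps <- stats::setNames(
  vapply(fx_spikes, `[[`, "", "amplicon"),
  paste0("spike_", names(fx_spikes)))

# Independent base counter used as the GC/length oracle (no package code).
count_gc_oracle <- function(s) {
  chars <- strsplit(s, "")[[1]]
  list(length = length(chars), gc = sum(chars %in% c("G", "C")))
}

# Independent sliding-window substring search oracle.
find_substring_oracle <- function(needle, haystack) {
  k <- nchar(needle)
  hits <- integer(0)
  for (i in seq_len(max(0L, nchar(haystack) - k + 1L))) {
    if (substr(haystack, i, i + k - 1L) == needle) hits <- c(hits, i)
  }
  hits
}

# Independent per-position IUPAC containment check.
iupac_mismatches_for_test <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sc <- strsplit(seq, "")[[1]]; pc <- strsplit(pattern, "")[[1]]
  sum(!mapply(function(a, b) a %in% sets[[b]], sc, pc))
}

# Small end-to-end simulated run shared by read-processing tests.
make_small_run <- function(seed = 11, n_taxa = c(P = 8, E = 6, F = 5),
                           depth = 3000, levels = c(7, 8), replicates = 2,
                           error_rate = 0) {
  comm <- make_community(n_taxa = n_taxa, seed = seed)
  refs <- make_reference_set(comm, fx_primers, seed = seed + 1)
  sim <- simulate_experiment(list(soil = comm), levels = levels,
                             replicates = replicates, depth = depth,
                             seed = seed + 2)
  scheme <- make_demux_scheme(colnames(sim$counts), seed = seed + 3)
  all_refs <- c(unlist(unname(refs)), fx_spike_amps)
  fq <- tempfile(fileext = ".fastq")
  emit_fastq(sim$counts, all_refs, scheme, fq, error_rate = error_rate,
             seed = seed + 4)
  list(comm = comm, refs = refs, sim = sim, scheme = scheme, fastq = fq,
       all_refs = all_refs)
}
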