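test_that("demultiplex recovers simulator counts and conserves reads", {
  run <- make_small_run(seed = 21, depth = 1500)
  reads <- read_fastq(run$fastq)
  dm <- demultiplex(reads, run$scheme)
  per_sample <- lengths(dm$samples)
  expected <- colSums(run$sim$counts)
  expect_equal(per_sample[names(expected)], expected)
  expect_identical(sum(per_sample) + length(dm$unassigned), dm$n_input)
  expect_identical(length(dm$unassigned), 0L)
})

test_that("unmatched barcodes and empty input land in unassigned", {
  scheme <- make_demux_scheme(c("s1", "s2"), seed = 5)
  amp <- strrep("ACGT", 30)
  good <- paste0(scheme$barcode_fwd[1], scheme$pad_forward, amp,
                 revcomp(scheme$pad_reverse), revcomp(scheme$barcode_rev[1]))
  bad <- paste0(strrep("A", 8), scheme$pad_forward, amp,
                revcomp(scheme$pad_reverse), strrep("A", 8))
  dm <- demultiplex(c(good, bad), scheme)
  expect_identical(lengths(dm$samples), c(s1 = 1L, s2 = 0L))
  expect_identical(dm$unassigned, bad)
  # barcodes and pads trimmed from the assigned read
  expect_identical(dm$samples$s1, amp)

  empty <- demultiplex(character(0), scheme)
  expect_identical(empty$n_input, 0L)
  expect_identical(lengths(empty$samples), c(s1 = 0L, s2 = 0L))
})

test_that("duplicate barcode pairs are rejected at scheme construction", {
  expect_error(demux_scheme(c("a", "b"), c("AAAAAAAA", "AAAAAAAA"),
                            c("CCCCCCCC", "CCCCCCCC")),
               "duplicate barcode pairs")
})

test_that("assign_family matches PBSs within budget and trims them", {
  # each spike amplicon maps to its own family (bijection)
  af <- assign_family(unname(fx_spike_amps), fx_primers)
  expect_identical(af$family, names(fx_primers))
  expect_identical(af$trimmed, unname(vapply(fx_spikes, `[[`, "", "stuffer")))

  # random sequence without PBS -> none
  set.seed(3)
  junk <- paste(sample(c("A", "C", "G", "T"), 253, TRUE), collapse = "")
  expect_true(is.na(assign_family(junk, fx_primers)$family))

  # one planted substitution in the forward PBS, budget 1 -> still assigned
  amp <- fx_spike_amps[["spike_E"]]
  mutated <- amp
  substr(mutated, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                   substr(amp, 3, 3))[1]
  expect_identical(assign_family(mutated, fx_primers,
                                 max_mismatches = 1)$family, "E")
  expect_true(is.na(assign_family(mutated, fx_primers,
                                  max_mismatches = 0)$family))
})

test_that("length_filter applies primer-inclusive windows per family", {
  keep <- length_filter(c(253L, 260L, 252L, 254L),
                        c("P", "P", "P", "P"), fx_primers)
  expect_identical(as.logical(keep), c(TRUE, FALSE, TRUE, TRUE))

  # planted off-length fraction is recovered in the retention report
  set.seed(9)
  n <- 4000
  off <- runif(n) < 0.05
  lens <- ifelse(off, 249L, sample(252:254, n, TRUE))
  keep <- length_filter(lens, rep("P", n), fx_primers)
  ret <- attr(keep, "retention")[["P"]]
  expect_equal(ret, 0.95, tolerance = 3 * sqrt(0.05 * 0.95 / n) / 0.95)
})

test_that("classify_reads assigns spikes, taxa and budget-limited variants", {
  run <- make_small_run(seed = 31, depth = 1000, levels = 8,
                        replicates = 1)
  s <- colnames(run$sim$counts)[1]
  interiors <- run$refs
  # exact spike read -> synthetic category
  pp <- fx_primers$P
  trim <- function(x) substring(x, nchar(pp$forward) + 1,
                                nchar(x) - nchar(pp$reverse))
  spike_int <- trim(fx_spike_amps[["spike_P"]])
  taxon_int <- trim(run$refs$P[1])
  mut <- taxon_int
  substr(mut, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 50, 50))[1]
  reads <- list(smp = data.frame(
    family = "P",
    trimmed = c(spike_int, taxon_int, mut, strrep("A", nchar(taxon_int))),
    stringsAsFactors = FALSE))
  ct <- classify_reads(reads,
                       spike_refs = c(spike_P = spike_int),
                       taxon_refs = list(P = stats::setNames(
                         trim(run$refs$P), names(run$refs$P))),
                       max_mismatches = 1)
  m <- unclass(ct)[, "smp"]
  expect_identical(m[["spike_P"]], 1L)
  expect_identical(m[[names(run$refs$P)[1]]], 2L)  # exact + 1-substitution
  expect_identical(sum(m), 3L)
  un <- attr(ct, "unassigned")
  expect_identical(un$reads[un$sample == "smp"], 1L)  # poly-A read
})

test_that("nearest-reference ties break to the first label, conserving reads", {
  refA <- "GGGGGGCCCC"  # spike reference, far from the read
  # two references equidistant (1 substitution each) from the read
  read <- "ACGTTCGTAC"
  refs <- c(zeta = "ACGTTCGTAA", alpha = "ACGTTCGTAG")
  ct <- classify_reads(list(s = data.frame(family = "P", trimmed = read)),
                       spike_refs = c(spike_P = refA),
                       taxon_refs = list(P = refs), max_mismatches = 2)
  m <- unclass(ct)[, "s"]
  expect_identical(m[["alpha"]], 1L)   # lexicographically first
  expect_identical(sum(m), 1L)         # never double-counted
})

test_that("the full pipeline reproduces latent counts on error-free reads", {
  run <- make_small_run(seed = 41, depth = 2000)
  res <- process_reads(run$fastq, run$scheme, fx_primers,
                       fx_spike_amps, run$refs)
  m <- unclass(res$counts)[rownames(run$sim$counts),
                           colnames(run$sim$counts)]
  expect_equal(unname(m), unname(unclass(run$sim$counts)),
               ignore_attr = TRUE)
  # conservation at every stage
  expect_true(all(diff(res$stats$reads) <= 0))
  expect_equal(res$stats$reads[1], sum(run$sim$counts))
  expect_equal(res$stats$reads[5], sum(res$counts))
})

test_that("labelled reference FASTA round-trips through disk", {
  comm <- make_community(n_taxa = c(P = 3L, E = 2L, F = 2L), seed = 55)
  refs <- make_reference_set(comm, fx_primers, seed = 56)
  path <- tempfile(fileext = ".fasta")
  write_reference_fasta(refs, path)
  back <- read_reference_fasta(path)
  expect_identical(back[names(refs)], refs[names(refs)])
  tax <- attr(back, "taxonomy")
  expect_true(all(grepl("^d:", tax)))
})

test_that("count tables round-trip through TSV", {
  run <- make_small_run(seed = 51, depth = 500, levels = 8, replicates = 1)
  path <- tempfile(fileext = ".tsv")
  write_count_table(run$sim$counts, path)
  back <- read_count_table(path)
  expect_equal(unclass(back)[rownames(run$sim$counts), , drop = FALSE],
               unclass(run$sim$counts)[, , drop = FALSE],
               ignore_attr = TRUE)
  expect_identical(attr(back, "family"), attr(run$sim$counts, "family"))
})
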