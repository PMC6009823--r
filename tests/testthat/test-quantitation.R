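test_that("the ratio estimator implements reads-ratio times spike copies", {
  expect_equal(absolute_abundance(100, 100, 3.5e7), 3.5e7)  # symmetry
  expect_equal(absolute_abundance(900, 100, 3.5e7), 3.15e8)
  # linear in spike copies and in microbial reads
  expect_equal(absolute_abundance(900, 100, 7e7),
               2 * absolute_abundance(900, 100, 3.5e7))
  expect_equal(absolute_abundance(1800, 100, 3.5e7),
               2 * absolute_abundance(900, 100, 3.5e7))
  expect_error(absolute_abundance(900, 0, 3.5e7), "synthetic_reads")
})

test_that("estimator is consistent on multinomial simulations", {
  env <- 1.9e9
  truth <- make_community(n_taxa = c(P = 30L), family_totals = c(P = env),
                          dispersion = 1.2, seed = 5)
  tab <- spike_level_table()
  ns8 <- tab$copies[tab$family == "P" & tab$level == 8]
  err <- vapply(1:100, function(s) {
    cnt <- sequence_sample(truth, c(P = ns8), depth = 1e5, seed = 1000 + s)$P
    syn <- cnt[["spike_P"]]
    est <- absolute_abundance(sum(cnt) - syn, syn, ns8)
    abs(est - env) / env
  }, numeric(1))
  expect_lt(median(err), 0.02)
  # bias shrinks with depth
  err_deep <- vapply(1:20, function(s) {
    cnt <- sequence_sample(truth, c(P = ns8), depth = 1e6,
                           seed = 2000 + s)$P
    syn <- cnt[["spike_P"]]
    abs(absolute_abundance(sum(cnt) - syn, syn, ns8) - env) / env
  }, numeric(1))
  expect_lt(mean(err_deep), mean(err))
})

test_that("in-window spike levels agree within sampling error", {
  env <- 1.9e9
  truth <- make_community(n_taxa = c(P = 30L), family_totals = c(P = env),
                          dispersion = 1.2, seed = 6)
  tab <- spike_level_table()
  inwin <- tab[tab$family == "P" &
                 flag_window(sr1000(tab$copies, env)), ]
  med <- vapply(seq_len(nrow(inwin)), function(i) {
    ests <- vapply(1:30, function(s) {
      cnt <- sequence_sample(truth, c(P = inwin$copies[i]), depth = 1e5,
                             seed = 300 * i + s)$P
      syn <- cnt[["spike_P"]]
      absolute_abundance(sum(cnt) - syn, syn, inwin$copies[i])
    }, numeric(1))
    median(ests)
  }, numeric(1))
  expect_true(all(abs(med - env) / env < 0.02))
})

test_that("isolation correction rescales only spike-after-isolation samples", {
  expect_equal(isolation_correction(1e9, 10, 10), 1e9)
  expect_equal(isolation_correction(1e9, 20, 10), 2e9)
  expect_error(isolation_correction(1e9, 10, 10, spike_timing = "before"),
               "before|after")

  # 50% isolation loss: spikes added after isolation underestimate ~2x,
  # the correction recovers the truth, spikes-before is immune
  env <- 1.9e9
  truth <- make_community(n_taxa = c(P = 20L), family_totals = c(P = env),
                          dispersion = 1, isolation_efficiency = 0.5,
                          seed = 7)
  ns <- 1.8e9
  est_for <- function(timing, s) {
    cnt <- sequence_sample(truth, c(P = ns), depth = 2e5,
                           spike_timing = timing, seed = s)$P
    syn <- cnt[["spike_P"]]
    absolute_abundance(sum(cnt) - syn, syn, ns)
  }
  before <- vapply(1:20, function(s) est_for("before", s), numeric(1))
  after <- vapply(1:20, function(s) est_for("after", 100 + s), numeric(1))
  expect_equal(median(before) / env, 1, tolerance = 0.05)
  expect_equal(median(after) / env, 0.5, tolerance = 0.05)
  corrected <- isolation_correction(after, predicted_total_dna_ng = 2,
                                    used_dna_ng = 1)
  expect_equal(median(corrected) / env, 1, tolerance = 0.05)
})

test_that("culture control arithmetic and recovery helper", {
  expect_equal(expected_culture_copies(1.11e9, 3), 3.33e9)
  expect_equal(expected_culture_copies(1, 1), 1)
  expect_equal(recovery_percent(c(3.11e9, 3.44e9, 3.38e9), 3.33e9), 99.4,
               tolerance = 1e-3)
})

test_that("taxon profiles scale to the family total and aggregate cleanly", {
  expect_equal(taxon_absolute(c(a = 50), 2e9), c(a = 2e9))
  expect_equal(taxon_absolute(c(a = 10, b = 10), 2e9),
               c(a = 1e9, b = 1e9))
  prof <- taxon_absolute(c(a = 3, b = 5, c = 12), 4e9)
  expect_equal(sum(prof), 4e9)
  # totals conserved under aggregation to a coarser grouping
  expect_equal(sum(prof[c("a", "b")]) + prof[["c"]], 4e9)
  expect_error(taxon_absolute(c(a = 0, b = 0), 1e9), "no microbial")
})

test_that("domain fractions normalise and are scale-invariant", {
  fr <- domain_fractions(c(`16S` = 9.1e9, `18S` = 9.0e8))
  expect_equal(unname(fr), c(91, 9), tolerance = 1e-6)
  expect_equal(sum(fr), 100)
  expect_equal(domain_fractions(c(a = 1, b = 0)), c(a = 100, b = 0))
  expect_equal(domain_fractions(c(a = 5e9, b = 5e8)),
               domain_fractions(c(a = 5, b = 0.5)))
})

test_that("qPCR fractions follow efficiency^-Ct", {
  expect_equal(unname(qpcr_fractions(c(a = 20, b = 20))), c(50, 50))
  expect_equal(unname(qpcr_fractions(c(a = 20, b = 21))),
               c(200, 100) / 3, tolerance = 1e-9)
  # closed-form inversion: minor fraction 7.6% at efficiency 2
  dct <- log2(92.4 / 7.6)
  expect_equal(dct, 3.604, tolerance = 1e-3)
  fr <- qpcr_fractions(c(minor = 20 + dct, major = 20))
  expect_equal(unname(fr[["minor"]]), 7.6, tolerance = 1e-3)
})

test_that("quantify applies QC exclusion and scale equivariance", {
  run <- make_small_run(seed = 71, depth = 4000, levels = c(7, 8),
                        replicates = 2)
  q <- qc_table(run$sim$counts, run$sim$manifest)
  aq <- quantify(run$sim$counts, run$sim$manifest, qc = q)
  e <- aq$estimates
  expect_true(all(e$excluded[e$family %in% c("E", "F")]))  # out of window
  # doubling spike copies doubles every estimate
  man2 <- run$sim$manifest
  man2$spike_copies <- 2 * man2$spike_copies
  aq2 <- quantify(run$sim$counts, man2, qc = q)
  ok <- !e$excluded
  expect_equal(aq2$estimates$copies_per_unit[ok],
               2 * e$copies_per_unit[ok])
  # profiles sum to the family totals
  prof <- absolute_profile(aq, "P")
  ep <- e[e$family == "P" & !e$excluded, ]
  expect_equal(unname(rowSums(prof)[ep$sample]),
               ep$copies_per_unit)
})
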