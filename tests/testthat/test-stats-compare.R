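test_that("compare_groups handles identical and degenerate groups", {
  set.seed(2)
  m <- matrix(rlnorm(40), 4, 10,
              dimnames = list(NULL, sprintf("t%02d", 1:10)))
  cmp <- compare_groups(m, m)
  expect_true(all(cmp$p_value[!is.na(cmp$p_value)] == 1))
  expect_false(any(cmp$tier %in% c("*", "**", "***")))

  # zero variance in both groups -> untestable, not an error
  z <- matrix(5, 3, 2, dimnames = list(NULL, c("a", "b")))
  cmp2 <- compare_groups(z, z)
  expect_true(all(cmp2$tier == "untestable"))
  expect_true(all(is.na(cmp2$p_value)))
})

test_that("Bonferroni adjustment multiplies by the number of tested taxa", {
  set.seed(3)
  a <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, paste0("t", 1:10)))
  b <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, paste0("t", 1:10)))
  cmp <- compare_groups(a, b)
  expect_equal(cmp$p_adjusted, pmin(1, cmp$p_value * 10))
})

test_that("a single strongly shifted taxon is detected with high power", {
  n_hit <- 0L; n_false <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 10; k <- 12
    a <- matrix(rnorm(n * k, 10, 1), n, k,
                dimnames = list(NULL, sprintf("t%02d", 1:k)))
    b <- matrix(rnorm(n * k, 10, 1), n, k,
                dimnames = list(NULL, sprintf("t%02d", 1:k)))
    b[, 1] <- b[, 1] + 5  # 5-SD shift in one taxon
    cmp <- compare_groups(a, b)
    starred <- cmp$taxon[cmp$p_adjusted < 0.05 & !is.na(cmp$p_adjusted)]
    if ("t01" %in% starred) n_hit <- n_hit + 1L
    n_false <- n_false + sum(starred != "t01")
    if (s == 1) {
      expect_identical(cmp$direction[cmp$taxon == "t01"], "B")
    }
  }
  expect_gte(n_hit / 100, 0.95)             # power
  expect_lte(n_false / (100 * 11), 0.05)    # per-taxon false positives
})

test_that("family-wise error under the null stays at the Bonferroni level", {
  n_fwe <- 0L
  reps <- 500
  for (s in seq_len(reps)) {
    set.seed(10000 + s)
    k <- 20; n <- 10
    a <- matrix(rlnorm(n * k, 0, 1), n, k,
                dimnames = list(NULL, sprintf("t%02d", 1:k)))
    b <- matrix(rlnorm(n * k, 0, 1), n, k,
                dimnames = list(NULL, sprintf("t%02d", 1:k)))
    cmp <- compare_groups(a, b)
    if (any(cmp$p_adjusted < 0.05, na.rm = TRUE)) n_fwe <- n_fwe + 1L
  }
  fwer <- n_fwe / reps
  # a Monte Carlo estimate of a rate bounded at 0.05: reject only if
  # significantly above the nominal level
  expect_gt(stats::binom.test(n_fwe, reps, 0.05,
                              alternative = "greater")$p.value, 0.01)
  expect_lt(fwer, 0.10)
})

test_that("Bray-Curtis matches the hand formula and its bounds", {
  m <- rbind(x = c(1, 3), y = c(3, 1))
  d <- bray_curtis_matrix(m, standardise = FALSE, sqrt_transform = FALSE)
  expect_equal(d["x", "y"], 0.5)  # (2+2)/(4+4)
  expect_equal(diag(d), c(x = 0, y = 0))

  # identical samples -> 0; disjoint supports -> 1
  m2 <- rbind(a = c(2, 0, 1), b = c(2, 0, 1), c = c(0, 5, 0))
  d2 <- bray_curtis_matrix(m2, standardise = FALSE, sqrt_transform = FALSE)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)

  set.seed(4)
  m3 <- matrix(rpois(60, 5), 6, 10,
               dimnames = list(paste0("s", 1:6), NULL))
  d3 <- bray_curtis_matrix(m3)
  expect_true(all(d3 >= 0 & d3 <= 1))
  expect_equal(d3, t(d3))
})

test_that("standardised Bray-Curtis is invariant to sample-wise rescaling", {
  set.seed(5)
  m <- matrix(rpois(50, 10) + 1, 5, 10,
              dimnames = list(paste0("s", 1:5), NULL))
  scaled <- sweep(m, 1, runif(5, 0.5, 20), `*`)
  expect_equal(bray_curtis_matrix(m), bray_curtis_matrix(scaled))
})

test_that("all-zero samples are excluded from the dissimilarity matrix", {
  m <- rbind(a = c(1, 2), b = c(0, 0), c = c(2, 1))
  expect_message(d <- bray_curtis_matrix(m, standardise = FALSE,
                                         sqrt_transform = FALSE),
                 "all-zero")
  expect_identical(attr(d, "excluded"), "b")
  expect_identical(rownames(d), c("a", "c"))
})

test_that("classical MDS round-trips planted Euclidean configurations", {
  set.seed(6)
  xy <- matrix(rnorm(24), 12, 2)
  rownames(xy) <- paste0("s", 1:12)
  d <- as.matrix(dist(xy))
  co <- ordinate(d, k = 2)
  expect_lt(max(abs(as.matrix(dist(co)) - d)), 1e-6)

  # three equidistant samples -> equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  co3 <- ordinate(d3, k = 2)
  side <- as.matrix(dist(co3))
  expect_equal(side[lower.tri(side)], rep(1, 3), tolerance = 1e-9)
})

test_that("ordination commutes with sample permutation", {
  set.seed(7)
  m <- matrix(rpois(80, 8), 8, 10,
              dimnames = list(paste0("s", 1:8), NULL))
  d <- bray_curtis_matrix(m)
  perm <- sample(rownames(d))
  dist_orig <- as.matrix(dist(ordinate(d)))
  dist_perm <- as.matrix(dist(ordinate(d[perm, perm])))
  expect_equal(dist_perm[rownames(d), rownames(d)], dist_orig,
               tolerance = 1e-9)
})

test_that("two simulated soils separate in ordination; spike level does not", {
  soils <- list(
    Bawburgh = make_community(n_taxa = c(P = 25L),
                              family_totals = c(P = 1.9e9),
                              dispersion = 1.2, seed = 81),
    Wytham = make_community(n_taxa = c(P = 25L),
                            family_totals = c(P = 4.1e9),
                            dispersion = 1.2, seed = 82))
  tab <- spike_level_table()
  sim <- simulate_experiment(soils, levels = 1:8, replicates = 1,
                             depth = 5000, seed = 83)
  rel <- relative_profile(sim$counts, "P")
  d <- bray_curtis_matrix(rel)
  co <- ordinate(d)
  grp <- sub("_.*", "", rownames(co))
  between <- mean(d[grp == "Bawburgh", grp == "Wytham"])
  within <- mean(c(d[grp == "Bawburgh", grp == "Bawburgh"],
                   d[grp == "Wytham", grp == "Wytham"]))
  expect_gt(between, 2 * within)
  # spike level does not structure the community profile: distances between
  # same-soil samples at far-apart levels stay near the within-soil mean
  lev <- as.integer(sub(".*_L(\\d+)_.*", "\\1", rownames(co)))
  baw <- grp == "Bawburgh"
  d_far <- mean(d[baw & lev <= 2, baw & lev >= 7])
  expect_lt(d_far, 2 * within)
})
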