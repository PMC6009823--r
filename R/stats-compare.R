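#' Per-taxon group comparison with Bonferroni correction
#'
#' Two-sample t-tests (Welch by default) per taxon between two groups of
#' sample profiles, on either the relative or the absolute scale, with
#' Bonferroni adjustment over the taxa actually tested. Taxa with zero
#' variance in both groups and equal means are untestable and reported with
#' `NA` p-values.
#'
#' @param a,b Samples x taxa matrices (>= 2 rows each, same column set).
#' @param scale Label recorded in the output (`"relative"` or
#'   `"absolute"`).
#' @param name_a,name_b Group labels used for the direction column.
#' @param var_equal Use Student's pooled-variance t-test instead of Welch.
#' @return `data.frame` with one row per taxon: group means and SDs,
#'   `p_value`, `p_adjusted` (`min(1, p * n_tested)`), `direction` (the
#'   group with the higher mean) and `tier` (`"***"`, `"**"`, `"*"` or
#'   `"ns"` at adjusted p < 0.001 / 0.01 / 0.05; `"untestable"` for
#'   degenerate taxa).
#' @export
compare_groups <- function(a, b, scale = c("absolute", "relative"),
                           name_a = "A", name_b = "B", var_equal = FALSE) {
  scale <- match.arg(scale)
  stopifnot(nrow(a) >= 2L, nrow(b) >= 2L)
  if (!identical(sort(colnames(a)), sort(colnames(b)))) {
    stopf("groups must share the same taxon set")
  }
  b <- b[, colnames(a), drop = FALSE]
  taxa <- colnames(a)
  p <- rep(NA_real_, length(taxa))
  for (j in seq_along(taxa)) {
    x <- a[, j]; y <- b[, j]
    p[j] <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
  }
  n_tested <- sum(!is.na(p))
  p_adj <- pmin(1, p * n_tested)
  mean_a <- colMeans(a); mean_b <- colMeans(b)
  tier <- ifelse(is.na(p_adj), "untestable",
          ifelse(p_adj < 0.001, "***",
          ifelse(p_adj < 0.01, "**",
          ifelse(p_adj < 0.05, "*", "ns"))))
  data.frame(
    taxon = taxa, scale = scale,
    mean_a = mean_a, sd_a = apply(a, 2, stats::sd),
    mean_b = mean_b, sd_b = apply(b, 2, stats::sd),
    p_value = p, p_adjusted = p_adj,
    direction = ifelse(mean_a == mean_b, NA_character_,
                       ifelse(mean_a > mean_b, name_a, name_b)),
    tier = tier, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x - y| / sum(x + y)` after optional per-sample
#' standardisation to proportions and square-root transformation (the
#' PRIMER-style pre-treatment). Computed with [vegan::vegdist()]. All-zero
#' samples have undefined distances and are excluded with a message.
#'
#' @param profiles Samples x taxa matrix of non-negative values (>= 2
#'   samples).
#' @param standardise Divide each sample by its total first (default
#'   `TRUE`).
#' @param sqrt_transform Square-root transform after standardisation
#'   (default `TRUE`).
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal;
#'   attribute `"excluded"` lists dropped all-zero samples.
#' @export
#' @examples
#' m <- rbind(x = c(1, 3), y = c(3, 1))
#' bray_curtis_matrix(m, standardise = FALSE, sqrt_transform = FALSE)
bray_curtis_matrix <- function(profiles, standardise = TRUE,
                               sqrt_transform = TRUE) {
  m <- as.matrix(profiles)
  stopifnot(all(m >= 0))
  tot <- rowSums(m)
  excluded <- rownames(m)[tot == 0]
  if (length(excluded)) {
    message("excluding all-zero sample(s): ", paste(excluded, collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stopf("need at least two non-empty samples")
  if (standardise) m <- m / rowSums(m)
  if (sqrt_transform) m <- sqrt(m)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  attr(d, "excluded") <- excluded
  d
}

#' Ordinate samples from a dissimilarity matrix
#'
#' Classical (metric) multidimensional scaling by default, for
#' deterministic coordinates; non-metric MDS (Kruskal stress, initialised
#' from the classical solution so it is deterministic too) as an option.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param k Number of dimensions (default 2).
#' @param method `"classical"` (default) or `"nonmetric"`.
#' @return Samples x k coordinate matrix; for `"nonmetric"` the final
#'   stress (percent) is attached as attribute `"stress"`.
#' @export
ordinate <- function(d, k = 2, method = c("classical", "nonmetric")) {
  method <- match.arg(method)
  dd <- stats::as.dist(d)
  if (method == "classical") {
    coords <- stats::cmdscale(dd, k = k)
  } else {
    fit <- MASS::isoMDS(dd, y = stats::cmdscale(dd, k = k), k = k,
                        trace = FALSE)
    coords <- fit$points
    attr(coords, "stress") <- fit$stress
  }
  colnames(coords) <- paste0("MDS", seq_len(k))
  coords
}
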