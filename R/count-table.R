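#' Construct a count table
#'
#' Samples-by-category read counts, where categories are taxa at a chosen
#' rank plus one synthetic category per amplicon family (named
#' `spike_<family>`). Stored as an integer matrix (rows = categories,
#' columns = samples) with a per-category family tag.
#'
#' @param counts Non-negative numeric matrix, rows = categories (rownames
#'   required), columns = samples (colnames required).
#' @param family Named character vector mapping each category to its
#'   amplicon family.
#' @param synthetic Optional named logical per category; defaults to
#'   categories named `spike_*`.
#' @return Object of class `count_table` (a matrix with attributes
#'   `family` and `synthetic`).
#' @export
count_table <- function(counts, family, synthetic = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have category rownames and sample colnames")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!all(rownames(counts) %in% names(family))) {
    stopf("every category needs a family tag")
  }
  family <- family[rownames(counts)]
  if (is.null(synthetic)) {
    synthetic <- startsWith(rownames(counts), "spike_")
    names(synthetic) <- rownames(counts)
  } else {
    synthetic <- synthetic[rownames(counts)]
  }
  structure(counts, family = family, synthetic = synthetic,
            class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  fam <- attr(x, "family")
  cat(sprintf(
    "count_table: %d categories (%d synthetic) x %d samples, %s reads\n",
    nrow(x), sum(attr(x, "synthetic")), ncol(x),
    format(sum(x), big.mark = ",")))
  for (f in unique(fam)) {
    cat(sprintf("  family %s: %d categories, %s reads\n", f,
                sum(fam == f), format(sum(x[fam == f, , drop = FALSE]),
                                      big.mark = ",")))
  }
  invisible(x)
}

#' Per-sample read summaries for one family
#'
#' @param x A [count_table()].
#' @param family Family label.
#' @return `data.frame` with columns `sample`, `total_reads`,
#'   `synthetic_reads`, `microbial_reads`.
#' @export
family_read_totals <- function(x, family) {
  fam <- attr(x, "family"); syn <- attr(x, "synthetic")
  rows <- fam == family
  m <- x[rows, , drop = FALSE]
  s <- syn[rows]
  data.frame(
    sample = colnames(x),
    total_reads = colSums(m),
    synthetic_reads = colSums(m[s, , drop = FALSE]),
    microbial_reads = colSums(m[!s, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read / write count tables as TSV
#'
#' Layout: columns `category`, `family`, `synthetic`, then one column per
#' sample.
#'
#' @param x A [count_table()].
#' @param path TSV path.
#' @return `read_count_table` returns a [count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(category = rownames(x), family = attr(x, "family"),
                   synthetic = attr(x, "synthetic"),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("category", "family", "synthetic")
  if (!all(meta %in% names(df))) {
    stopf("count table TSV must have columns %s", paste(meta, collapse = ", "))
  }
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$category
  fam <- stats::setNames(df$family, df$category)
  syn <- stats::setNames(as.logical(df$synthetic), df$category)
  count_table(m, fam, syn)
}

#' Read a sample manifest TSV
#'
#' One row per (sample, family): columns `sample`, `family`, `group`,
#' `spike_level`, `spike_copies` (copies added per unit of sample),
#' `amount_unit` (`"g"` or `"ml"`), `spike_timing` (`"before"` or
#' `"after"` DNA isolation), and optionally `predicted_total_dna_ng`,
#' `used_dna_ng` (for the isolation-loss correction) and `contaminated`
#' (manual flag).
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample", "family", "group", "spike_copies")
  if (!all(needed %in% names(df))) {
    stopf("manifest must have columns %s", paste(needed, collapse = ", "))
  }
  if (is.null(df$spike_timing)) df$spike_timing <- "before"
  if (is.null(df$amount_unit)) df$amount_unit <- "g"
  if (is.null(df$contaminated)) df$contaminated <- FALSE
  df
}
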