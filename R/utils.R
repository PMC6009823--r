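# Internal helpers shared across modules.

# IUPAC ambiguity code -> set of plain bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_SETS)

is_iupac_dna <- function(x) {
  nzchar(x) & !grepl(sprintf("[^%s]", paste(IUPAC_ALPHABET, collapse = "")),
                     toupper(x))
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' accepts and returns plain character vectors. IUPAC ambiguity codes are
#' complemented correctly (e.g. `R` -> `Y`).
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("GGAA")   # "TTCC"
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' GC fraction of DNA strings
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of G+C fractions in `[0, 1]`; `NaN` for
#'   zero-length strings.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgcSs]", "", x))
  gc / n
}

# Count per-sequence mismatches of `seqs` against an IUPAC `pattern`
# anchored at position `at` (1-based). A sequence base matches when it is in
# the pattern symbol's IUPAC set; positions beyond the end of a sequence
# count as mismatches.
iupac_mismatches <- function(seqs, pattern, at = 1L) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  mm <- integer(length(seqs))
  for (i in seq_along(pc)) {
    base <- substring(seqs, at + i - 1L, at + i - 1L)
    mm <- mm + !(base %in% IUPAC_SETS[[pc[i]]])
  }
  mm
}

# Mismatches of the 3' end of each sequence against `pattern` (already in
# read orientation), i.e. pattern anchored at length - nchar(pattern) + 1.
iupac_mismatches_suffix <- function(seqs, pattern) {
  k <- nchar(pattern)
  n <- nchar(seqs)
  out <- rep.int(k, length(seqs))
  ok <- n >= k
  if (any(ok)) {
    suff <- substring(seqs[ok], n[ok] - k + 1L, n[ok])
    out[ok] <- iupac_mismatches(suff, pattern)
  }
  out
}

# Hamming distance between equal-length plain strings, vectorised over seqs.
hamming_to <- function(seqs, ref) {
  rr <- charToRaw(ref)
  vapply(seqs, function(s) sum(charToRaw(s) != rr), integer(1),
         USE.NAMES = FALSE)
}

# Longest homopolymer run in a DNA string.
max_homopolymer_run <- function(x) {
  if (!nzchar(x)) return(0L)
  max(rle(strsplit(x, "")[[1]])$lengths)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. `seed = NULL` leaves the RNG
# alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed, kept within 32-bit
# integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# Replace IUPAC ambiguity codes by a concrete base drawn from each code's
# set (deterministic under with_seed in callers).
concretize_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  amb <- !(chars %in% c("A", "C", "G", "T"))
  if (any(amb)) {
    chars[amb] <- vapply(chars[amb], function(ch) {
      s <- IUPAC_SETS[[ch]]
      s[sample.int(length(s), 1L)]
    }, character(1))
  }
  paste(chars, collapse = "")
}

# Random plain-DNA string with i.i.d. bases at a given GC probability.
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
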