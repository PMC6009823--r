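#' Spike stock calibration
#'
#' A stock links a spike family to the number of construct molecules per
#' nanogram of stock DNA. The measured value takes precedence over a
#' length-derived conversion because the dose tables are calibrated to it.
#'
#' @param family Spike family label.
#' @param copies_per_ng Molecules per ng of stock (> 0).
#' @param construct_length_bp Optional full construct length for
#'   first-principles conversion via [copies_per_ng_from_length()].
#' @return Object of class `spike_stock`.
#' @export
spike_stock <- function(family, copies_per_ng, construct_length_bp = NULL) {
  stopifnot(copies_per_ng > 0)
  structure(list(family = family, copies_per_ng = as.numeric(copies_per_ng),
                 construct_length_bp = construct_length_bp),
            class = "spike_stock")
}

#' Convert a DNA mass to molecule copies
#'
#' `copies = (mass_pg / 1000) * copies_per_ng`. Dose tables print copies at
#' 2 significant figures; use [signif()] on the result to match that
#' precision, full precision is returned here.
#'
#' @param mass_pg Picograms of construct DNA (vectorised, >= 0).
#' @param stock A [spike_stock()], or a bare `copies_per_ng` number.
#' @return Numeric copies.
#' @export
#' @examples
#' signif(mass_to_copies(32, 3.7e8), 2)    # 1.2e7
#' signif(mass_to_copies(1931, 3.7e8), 2)  # 7.1e8
mass_to_copies <- function(mass_pg, stock) {
  stopifnot(all(mass_pg >= 0))
  cpn <- if (inherits(stock, "spike_stock")) stock$copies_per_ng
         else as.numeric(stock)
  mass_pg / 1000 * cpn
}

#' Convert molecule copies back to a DNA mass
#'
#' Inverse of [mass_to_copies()].
#'
#' @param copies Molecule copies (>= 0).
#' @inheritParams mass_to_copies
#' @return Picograms.
#' @export
copies_to_mass <- function(copies, stock) {
  stopifnot(all(copies >= 0))
  cpn <- if (inherits(stock, "spike_stock")) stock$copies_per_ng
         else as.numeric(stock)
  copies / cpn * 1000
}

#' Copies per nanogram from construct length
#'
#' First-principles conversion for double-stranded DNA:
#' `1e-9 g / (length_bp * mean_bp_mass_da * 1.66054e-24 g/Da)`.
#'
#' @param construct_length_bp Construct length in bp (> 0).
#' @param mean_bp_mass_da Mean mass of a double-stranded base pair in
#'   daltons (default 650).
#' @return Molecules per ng.
#' @export
#' @examples
#' copies_per_ng_from_length(1000)  # ~9.26e8
copies_per_ng_from_length <- function(construct_length_bp,
                                      mean_bp_mass_da = 650) {
  stopifnot(all(construct_length_bp > 0), mean_bp_mass_da > 0)
  1e-9 / (construct_length_bp * mean_bp_mass_da * 1.66054e-24)
}

#' Marker-gene copies per nanogram of genomic DNA
#'
#' `(1e-9 g / (genome_mass_da * 1.66054e-24 g/Da)) * operons_per_genome`.
#' For a 4e9 Da genome with 3 rRNA operons this gives ~4.52e5 copies/ng.
#' (Published figures computed with unstated constants can differ; e.g. a
#' reported 377,155 copies/ng for the same inputs is not reproducible with
#' standard constants.)
#'
#' @param genome_mass_da Genome mass in daltons (> 0).
#' @param operons_per_genome Marker-gene operon copies per genome (>= 1).
#' @return Gene copies per ng of genomic DNA.
#' @export
genome_copies_per_ng <- function(genome_mass_da, operons_per_genome) {
  stopifnot(all(genome_mass_da > 0), all(operons_per_genome >= 1))
  1e-9 / (genome_mass_da * 1.66054e-24) * operons_per_genome
}

#' Build a spike dose-level table
#'
#' Each level doses `fraction%` of the family's top (level-8) mass; copies
#' follow from the stock calibration.
#'
#' @param stocks Named list of [spike_stock()] (names = families).
#' @param top_masses_pg Named numeric, the level-8 (100%) picogram dose per
#'   family.
#' @param fractions Percent-of-top per level, in `(0, 100]`
#'   (default `c(1, 2, 5, 10, 15, 20, 50, 100)`).
#' @return `data.frame` of class `spike_level_table` with columns `level`,
#'   `family`, `fraction_pct`, `mass_pg`, `copies`, ordered by family then
#'   level.
#' @export
#' @examples
#' st <- list(P = spike_stock("P", 3.7e8))
#' build_level_table(st, c(P = 9657))
build_level_table <- function(stocks, top_masses_pg,
                              fractions = c(1, 2, 5, 10, 15, 20, 50, 100)) {
  stopifnot(all(fractions > 0), all(fractions <= 100))
  fams <- names(top_masses_pg)
  rows <- lapply(fams, function(fam) {
    mass <- fractions / 100 * top_masses_pg[[fam]]
    data.frame(level = seq_along(fractions), family = fam,
               fraction_pct = fractions, mass_pg = mass,
               copies = mass_to_copies(mass, stocks[[fam]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spike_level_table", "data.frame")
  out
}

#' The default eight-level P/E/F dose table
#'
#' The published dosing protocol: eight levels at 1, 2, 5, 10, 15, 20, 50 and
#' 100% of the top per-gram dose (9657 pg P, 5661 pg E, 3213 pg F), with
#' stock calibrations of 3.7e8 (P), 3.8e8 (E) and 3.7e8 (F) copies/ng. The
#' returned masses are the protocol's printed (rounded) picogram doses, so
#' copies recomputed from them match the printed table at 2 significant
#' figures for its self-consistent cells.
#'
#' @param stocks Optional named list of [spike_stock()] overriding the
#'   defaults.
#' @return A `spike_level_table` (see [build_level_table()]).
#' @export
spike_level_table <- function(stocks = NULL) {
  if (is.null(stocks)) {
    stocks <- list(P = spike_stock("P", 3.7e8, 2504L),
                   E = spike_stock("E", 3.8e8, 2504L),
                   F = spike_stock("F", 3.7e8, 2504L))
  }
  masses <- list(
    P = c(97, 193, 483, 966, 1449, 1931, 4829, 9657),
    E = c(57, 113, 283, 566, 849, 1132, 2831, 5661),
    F = c(32, 64, 161, 321, 482, 643, 1607, 3213)
  )
  fractions <- c(1, 2, 5, 10, 15, 20, 50, 100)
  rows <- lapply(names(masses), function(fam) {
    data.frame(level = 1:8, family = fam, fraction_pct = fractions,
               mass_pg = masses[[fam]],
               copies = mass_to_copies(masses[[fam]], stocks[[fam]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spike_level_table", "data.frame")
  out
}

#' Read / write spike level tables as TSV
#'
#' Columns `level`, `family`, `fraction_pct`, `mass_pg`, `copies`.
#'
#' @param x A `spike_level_table`.
#' @param path TSV path.
#' @return `read_level_table` returns a `spike_level_table`;
#'   `write_level_table` returns `path` invisibly.
#' @export
write_level_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_level_table
#' @export
read_level_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("level", "family", "mass_pg", "copies")
  if (!all(needed %in% names(out))) {
    stopf("level table must have columns %s", paste(needed, collapse = ", "))
  }
  class(out) <- c("spike_level_table", "data.frame")
  out
}

#' Soil organic matter to organic carbon
#'
#' The van Bemmelen factor: organic carbon = 0.58 x organic matter.
#'
#' @param som Soil organic matter content (percent or mg/g; units are
#'   preserved).
#' @return 0.58 * `som`.
#' @export
#' @examples
#' organic_matter_to_carbon(16.78)  # 9.73
organic_matter_to_carbon <- function(som) {
  stopifnot(all(som >= 0))
  0.58 * som
}
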