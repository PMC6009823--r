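#' Expected synthetic reads per 1000 total reads
#'
#' The dose-planning model: a spike added at `NS` copies per gram competes
#' with `ENV` environmental gene copies per gram for sequencing reads, so its
#' expected share of the output is `NS / (NS + ENV)`, reported per 1000
#' reads:
#' \deqn{SR_{1000} = \frac{NS}{(NS + ENV)/1000}}
#' The model is scale-invariant (`sr1000(cNS, cENV) = sr1000(NS, ENV)`) and
#' complementary (`sr1000(NS, ENV) + sr1000(ENV, NS) = 1000`).
#'
#' @param NS Spike copies added per gram of sample (>= 0, vectorised).
#' @param ENV Environmental gene copies per gram (>= 0, vectorised).
#' @return Expected synthetic reads per 1000 total reads, in `[0, 1000]`.
#' @export
#' @examples
#' sr1000(3.5e9, 1.9e9)  # ~648
#' sr1000(1e9, 1e9)      # 500
sr1000 <- function(NS, ENV) {
  stopifnot(all(NS >= 0), all(ENV >= 0))
  if (any(NS + ENV == 0)) stopf("NS + ENV must be positive")
  NS / ((NS + ENV) / 1000)
}

#' Annotate spike levels with planner verdicts
#'
#' For each dose level, predicts the synthetic read share with [sr1000()]
#' against an expected environmental abundance and flags whether it falls in
#' the acceptance window (default 200-800 synthetic reads per 1000, strict
#' bounds) and whether the dose fraction `NS/(NS+ENV)` obeys the 20-80%
#' dosing rule (algebraically the same predicate as the window at its
#' default bounds).
#'
#' @param level_table A `spike_level_table` (see [spike_level_table()]).
#' @param env_estimate Expected environmental gene copies per gram: a single
#'   number, or a named vector per family (> 0).
#' @param window Acceptance window on `sr1000`, default `c(200, 800)`,
#'   strict (`low < sr1000 < high`).
#' @param dose_range Acceptable dose fraction range, default `c(0.2, 0.8)`.
#' @return The level table with columns `env`, `sr1000`, `dose_fraction`,
#'   `in_window`, `dose_ok` appended.
#' @export
#' @examples
#' tab <- spike_level_table()
#' sel <- select_levels(tab, c(P = 3.0e9, E = 1.85e8, F = 6.65e6))
#' subset(sel, family == "P" & in_window)$level  # 7 8
select_levels <- function(level_table, env_estimate,
                          window = c(200, 800), dose_range = c(0.2, 0.8)) {
  stopifnot(all(env_estimate > 0))
  env <- if (length(env_estimate) == 1L && is.null(names(env_estimate))) {
    rep(env_estimate, nrow(level_table))
  } else {
    if (!all(level_table$family %in% names(env_estimate))) {
      stopf("env_estimate must name every family in the level table")
    }
    unname(env_estimate[level_table$family])
  }
  out <- as.data.frame(level_table)
  out$env <- env
  out$sr1000 <- sr1000(out$copies, env)
  out$dose_fraction <- out$copies / (out$copies + env)
  out$in_window <- out$sr1000 > window[1] & out$sr1000 < window[2]
  out$dose_ok <- out$dose_fraction >= dose_range[1] &
    out$dose_fraction <= dose_range[2]
  out[order(out$family, out$level), , drop = FALSE]
}
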