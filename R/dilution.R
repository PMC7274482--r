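#' Convert between dilution factors and continuous mortality rates
#'
#' A serial transfer that keeps 1/DF of the culture each cycle removes
#' biomass at the same average rate as a continuous mortality
#' `delta = log(DF) / T`, with `T` the cycle duration in days.  This
#' logarithmic relation is why fluctuating dilution factors time-average as
#' a geometric mean (see [schedule_equivalent_df()]).
#'
#' @param df fold dilution per cycle; must be `>= 1` (DF 1000 means 1/1000
#'   of the culture is carried over).  Fractions kept (values in (0, 1],
#'   e.g. `1e-3` written as a transfer fraction) are accepted and
#'   normalized to fold dilution with a message.
#' @param delta continuous mortality rate, 1/day.
#' @param cycle_hours duration of one growth cycle in hours (default 24).
#' @return `df_to_delta` returns the mortality rate in 1/day;
#'   `delta_to_df` returns the fold dilution.
#' @examples
#' df_to_delta(1000)        # 3 log(10) ~ 6.9078 per day
#' delta_to_df(df_to_delta(100)) # 100
#' @export
df_to_delta <- function(df, cycle_hours = 24) {
  df <- normalize_df(df)
  if (cycle_hours <= 0) stop_lv("lvdilute_invalid_dilution", "cycle_hours must be positive")
  log(df) / (cycle_hours / 24)
}

#' @rdname df_to_delta
#' @export
delta_to_df <- function(delta, cycle_hours = 24) {
  if (any(delta < 0)) stop_lv("lvdilute_invalid_delta", "delta must be >= 0")
  exp(delta * (cycle_hours / 24))
}

# Canonical dilution-factor convention: fold dilution >= 1.  Experimental
# write-ups sometimes record the transfer fraction 10^-k instead; values in
# (0, 1) are interpreted that way and inverted, with a message.
normalize_df <- function(df) {
  if (any(!is.finite(df)) || any(df <= 0)) {
    stop_lv("lvdilute_invalid_dilution", "dilution factors must be finite and positive")
  }
  frac <- df < 1
  if (any(frac)) {
    message(sprintf(
      "normalizing %d dilution entr%s given as transfer fraction(s) to fold dilution (1/x)",
      sum(frac), if (sum(frac) == 1) "y" else "ies"))
    df[frac] <- 1 / df[frac]
  }
  df
}

#' Dilution schedule
#'
#' An ordered sequence of per-cycle dilution factors plus the common cycle
#' duration; the simulator repeats the sequence cyclically.  A constant
#' environment is a length-1 schedule.
#'
#' @param dfs numeric vector of fold dilutions, one per cycle (values below
#'   1 are read as transfer fractions and inverted).
#' @param cycle_hours cycle duration in hours.
#' @return An object of class `lv_schedule`.
#' @examples
#' alt <- dilution_schedule(c(10, 1e5))
#' schedule_equivalent_df(alt) # 1000
#' @export
dilution_schedule <- function(dfs, cycle_hours = 24) {
  if (length(dfs) < 1) stop_lv("lvdilute_invalid_dilution", "schedule must be non-empty")
  dfs <- normalize_df(as.numeric(dfs))
  if (cycle_hours <= 0) stop_lv("lvdilute_invalid_dilution", "cycle_hours must be positive")
  structure(list(dfs = dfs, cycle_hours = cycle_hours), class = "lv_schedule")
}

as_schedule <- function(x, cycle_hours = 24) {
  if (inherits(x, "lv_schedule")) x else dilution_schedule(x, cycle_hours)
}

#' @export
print.lv_schedule <- function(x, ...) {
  cat(sprintf("Dilution schedule: %d cycle(s) of %g h\n", length(x$dfs), x$cycle_hours))
  cat("  DFs:", paste(format(x$dfs, digits = 4), collapse = ", "), "\n")
  cat("  equivalent constant DF (geometric mean):",
      format(schedule_equivalent_df(x), digits = 6), "\n")
  invisible(x)
}

#' Equivalent constant dilution factor of a fluctuating schedule
#'
#' Because per-capita growth in the Lotka-Volterra model is linear in the
#' mortality rate, a fluctuating mortality time-averages: the equivalent
#' constant dilution factor is the geometric mean of the schedule's dilution
#' factors (the exponential of the mean per-cycle `delta * T`).  The result
#' is invariant under permutation of the schedule.
#'
#' @param schedule an [lv_schedule] or a numeric vector of dilution factors.
#' @return The equivalent constant fold dilution.
#' @examples
#' schedule_equivalent_df(c(10, 1e5))  # 1000
#' schedule_equivalent_df(c(100, 1e4)) # 1000
#' @export
schedule_equivalent_df <- function(schedule) {
  schedule <- as_schedule(schedule)
  exp(mean(log(schedule$dfs)))
}
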