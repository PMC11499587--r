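#' Assign an acquisition day to a growth-stage third
#'
#' The full-heading-to-maturity interval (FHtM) of a plot runs from its
#' full heading day (`fhs_day`, the day the heading ratio reaches 80%) to
#' its maturity day (`ms_day`). The interval is split into thirds with
#' half-open `[a, b)` boundaries, except that `ms_day` itself closes the
#' final third. Days before full heading are `pre_heading`, days after
#' maturity `post_maturity`; both are excluded from panicle datasets.
#'
#' For a plot with `fhs = 90`, `ms = 120` (FHtM of 30 d), acquisition day
#' 98 falls in the first third, 104 in the second, 111 in the final, and
#' 125 is excluded.
#'
#' @param fhs_day,ms_day full-heading and maturity days after sowing
#'   (vectors recycle)
#' @param acq_day acquisition day after sowing
#' @return factor with levels `pre_heading`, `first_third`, `second_third`,
#'   `final_third`, `post_maturity`
#' @export
assign_stage <- function(fhs_day, ms_day, acq_day) {
  n <- max(length(fhs_day), length(ms_day), length(acq_day))
  fhs <- rep_len(fhs_day, n); ms <- rep_len(ms_day, n)
  acq <- rep_len(acq_day, n)
  if (any(!(fhs < ms))) stop("invalid calendar: fhs_day must precede ms_day")
  if (any(acq < 0)) stop("acq_day must be non-negative")
  d <- ms - fhs
  out <- ifelse(acq < fhs, "pre_heading",
         ifelse(acq > ms, "post_maturity",
         ifelse(acq < fhs + d / 3, "first_third",
         ifelse(acq < fhs + 2 * d / 3, "second_third", "final_third"))))
  factor(out, levels = stage_levels())
}

stage_levels <- function() {
  c("pre_heading", "first_third", "second_third", "final_third",
    "post_maturity")
}

#' Stage every plot x acquisition combination
#'
#' @param calendar data frame with `plot_id, fhs_day, ms_day`
#' @param acq_days data frame with `acq_id, day`, or a numeric day vector
#' @return data frame `plot_id, acq_id, day, stage`
#' @export
stage_table <- function(calendar, acq_days) {
  if (is.numeric(acq_days))
    acq_days <- data.frame(acq_id = seq_along(acq_days), day = acq_days)
  g <- expand.grid(i = seq_len(nrow(calendar)), j = seq_len(nrow(acq_days)))
  data.frame(plot_id = calendar$plot_id[g$i],
             acq_id = acq_days$acq_id[g$j],
             day = acq_days$day[g$j],
             stage = assign_stage(calendar$fhs_day[g$i],
                                  calendar$ms_day[g$i],
                                  acq_days$day[g$j]))
}

#' Heading duration from a heading-ratio time series
#'
#' The interval between 10% and 80% heading, an indicator of synchronous
#' maturation. Measurement noise is removed with a running maximum
#' (heading is cumulative), then the two crossing days are found by linear
#' interpolation between the bracketing observations.
#'
#' @param day observation days, sorted ascending
#' @param ratio heading ratios in `[0, 1]`
#' @param lo,hi the bracketing ratios (defaults 0.10 and 0.80)
#' @return duration in days: `day(hi) - day(lo)`
#' @export
heading_duration <- function(day, ratio, lo = 0.10, hi = 0.80) {
  stopifnot(length(day) == length(ratio), length(day) >= 2,
            !is.unsorted(day))
  r <- cummax(ratio)
  if (r[1] > lo)
    stop("incomplete heading series: first observation already above ",
         lo * 100, "% heading")
  if (max(r) < hi)
    stop("incomplete heading series: never reaches ", hi * 100, "% heading")
  crossing_day(day, r, hi) - crossing_day(day, r, lo)
}

crossing_day <- function(day, r, target) {
  i <- which(r >= target)[1]
  if (i == 1) return(day[1])
  if (r[i] == r[i - 1]) return(day[i])
  day[i - 1] + (target - r[i - 1]) / (r[i] - r[i - 1]) * (day[i] - day[i - 1])
}
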