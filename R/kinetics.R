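#' Digestion time course
#'
#' Percent of DNA remaining attached to the nuclear matrix as a function of
#' DNase I digestion time, with across-replicate SD and replicate count.
#'
#' @param label sample label (e.g., an age group such as "P0").
#' @param time_min digestion times in minutes, strictly increasing, first 0.
#' @param pct_attached percent NM-attached DNA in \[0, 100\]; must be 100 at
#'   time 0.
#' @param sd per-timepoint standard deviation (percent); may be `NA`.
#' @param n replicate count per timepoint; may be `NA`.
#' @return data.frame of class `digestion_timecourse` with attribute `label`.
#' @examples
#' digestion_timecourse("P7", c(0, 5, 15, 30, 60),
#'                      c(100, 49.2, 24.3, 20.5, 17.4))
#' @export
digestion_timecourse <- function(label, time_min, pct_attached,
                                 sd = NA_real_, n = NA_integer_) {
  if (length(time_min) != length(pct_attached))
    stopf("time_min and pct_attached lengths differ")
  if (anyDuplicated(time_min)) stopf("duplicate digestion times")
  if (any(diff(time_min) <= 0)) stopf("digestion times must be strictly increasing")
  if (time_min[1] != 0) stopf("first timepoint must be 0, got %g", time_min[1])
  if (abs(pct_attached[1] - 100) > 1e-9)
    stopf("pct_attached at time 0 must be 100, got %g", pct_attached[1])
  if (any(pct_attached < 0 | pct_attached > 100))
    stopf("pct_attached outside [0, 100]")
  tc <- data.frame(time_min = as.numeric(time_min),
                   pct_attached = as.numeric(pct_attached),
                   sd = as.numeric(rep_len(sd, length(time_min))),
                   n = as.integer(rep_len(n, length(time_min))))
  attr(tc, "label") <- as.character(label)
  class(tc) <- c("digestion_timecourse", "data.frame")
  tc
}

#' @export
print.digestion_timecourse <- function(x, ...) {
  cat(sprintf("Digestion time course '%s' (%d timepoints)\n",
              attr(x, "label"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Local slopes between consecutive digestion timepoints
#'
#' The local slope S over each interval is the finite difference
#' `(pct(t2) - pct(t1)) / (t2 - t1)` in percentage points per minute; the
#' reported value is rounded half-away-from-zero to `decimals` places
#' ([round_half_away()]), the convention that reproduces published slope
#' tables. A positive raw slope (attached DNA increasing) is physically
#' impossible under digestion and triggers a QC warning.
#'
#' @param tc a [digestion_timecourse()] with at least two points.
#' @param decimals decimal places for the rounded slope (default 1).
#' @return data.frame of class `slope_table`: `t_start`, `t_end`,
#'   `slope_raw`, `slope`.
#' @examples
#' tc <- digestion_timecourse("P7", c(0, 5, 15, 30, 60),
#'                            c(100, 49.2, 24.3, 20.5, 17.4))
#' local_slopes(tc)$slope  # -10.2 -2.5 -0.3 -0.1
#' @export
local_slopes <- function(tc, decimals = 1L) {
  stopifnot(inherits(tc, "digestion_timecourse"))
  if (nrow(tc) < 2L) stopf("need at least 2 timepoints for slopes")
  if (anyDuplicated(tc$time_min)) stopf("duplicate digestion times")
  raw <- diff(tc$pct_attached) / diff(tc$time_min)
  out <- data.frame(t_start = tc$time_min[-nrow(tc)],
                    t_end = tc$time_min[-1],
                    slope_raw = raw,
                    slope = round_half_away(raw, decimals))
  if (any(raw > 0))
    warning(sprintf("QC: positive local slope in '%s' (attached DNA increased over %s)",
                    attr(tc, "label"),
                    paste(sprintf("%g-%g min", out$t_start[raw > 0], out$t_end[raw > 0]),
                          collapse = ", ")), call. = FALSE)
  attr(out, "label") <- attr(tc, "label")
  class(out) <- c("slope_table", "data.frame")
  out
}

#' Plateau of a digestion time course
#'
#' Percent NM-attached DNA at the final timepoint; since local slopes are
#' close to zero by the end of the sampled course, this is the operational
#' digestion-resistant plateau.
#'
#' @param tc a [digestion_timecourse()].
#' @return percent attached at the last timepoint.
#' @export
plateau_fraction <- function(tc) {
  stopifnot(inherits(tc, "digestion_timecourse"), nrow(tc) >= 1L)
  tc$pct_attached[nrow(tc)]
}

#' Topological-zone scheme bound to digestion timepoints
#'
#' Binds ordered topological zones -- by convention D (distal), P
#' (proximal), VC (very close), E (embedded within the NM) -- to the
#' successive non-zero digestion timepoints, outermost zone at the earliest
#' time. A per-zone slope summary (magnitude of the local slope over the
#' interval ending at the zone's timepoint, and the timepoint SD) is
#' attached for reporting.
#'
#' @param tc a [digestion_timecourse()].
#' @param labels zone labels, outermost first; must match the number of
#'   non-zero timepoints.
#' @return data.frame of class `zone_scheme`: `zone`, `timepoint_min`,
#'   `slope_magnitude`, `sd`.
#' @examples
#' tc <- digestion_timecourse("P7", c(0, 5, 15, 30, 60),
#'                            c(100, 49.2, 24.3, 20.5, 17.4))
#' zone_scheme_from_timepoints(tc)
#' @export
zone_scheme_from_timepoints <- function(tc, labels = c("D", "P", "VC", "E")) {
  stopifnot(inherits(tc, "digestion_timecourse"))
  times <- tc$time_min[tc$time_min > 0]
  if (length(times) != length(labels))
    stopf("%d zone labels for %d non-zero timepoints", length(labels), length(times))
  if (anyDuplicated(labels)) stopf("zone labels must be unique")
  sl <- local_slopes(tc)
  sch <- data.frame(zone = as.character(labels),
                    timepoint_min = times,
                    slope_magnitude = abs(sl$slope_raw),
                    sd = tc$sd[match(times, tc$time_min)],
                    stringsAsFactors = FALSE)
  class(sch) <- c("zone_scheme", "data.frame")
  sch
}

#' Construct a zone scheme directly from timepoints
#'
#' Lower-level companion of [zone_scheme_from_timepoints()] for when no
#' measured time course is at hand (e.g. simulation ground truth): binds
#' zone labels to non-zero digestion timepoints without a slope summary.
#'
#' @param timepoint_min non-zero digestion timepoints, strictly increasing.
#' @param zone unique zone labels, outermost first.
#' @return data.frame of class `zone_scheme`.
#' @export
zone_scheme <- function(timepoint_min, zone = c("D", "P", "VC", "E")) {
  if (length(timepoint_min) != length(zone))
    stopf("%d zone labels for %d timepoints", length(zone), length(timepoint_min))
  if (any(timepoint_min <= 0) || any(diff(timepoint_min) <= 0))
    stopf("zone timepoints must be positive and strictly increasing")
  if (anyDuplicated(zone)) stopf("zone labels must be unique")
  sch <- data.frame(zone = as.character(zone),
                    timepoint_min = as.numeric(timepoint_min),
                    slope_magnitude = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  class(sch) <- c("zone_scheme", "data.frame")
  sch
}

#' Distance ranks of a zone scheme
#'
#' Fixed integer distance ranks for shift statistics: innermost zone
#' (longest digestion) = 1, outermost = number of zones (so with the
#' default scheme E = 1, VC = 2, P = 3, D = 4).
#'
#' @param scheme a [zone_scheme_from_timepoints()] result.
#' @return named integer vector of ranks.
#' @export
zone_ranks <- function(scheme) {
  stopifnot(inherits(scheme, "zone_scheme"))
  stats::setNames(rev(seq_len(nrow(scheme))), scheme$zone)
}

#' Compare two digestion time courses on a shared time grid
#'
#' Reports pointwise differences and which course digests more slowly:
#' the course with percent-attached greater than or equal to the other at
#' every shared non-zero timepoint. Crossing curves yield no slower label.
#'
#' @param tc_a,tc_b [digestion_timecourse()] objects on identical grids.
#' @return list with `differences` (data.frame `time_min`, `a`, `b`,
#'   `diff`), `slower_label` (label or `NA`), `crossing` flag.
#' @export
compare_timecourses <- function(tc_a, tc_b) {
  stopifnot(inherits(tc_a, "digestion_timecourse"),
            inherits(tc_b, "digestion_timecourse"))
  if (!identical(tc_a$time_min, tc_b$time_min))
    stopf("time grids differ between '%s' and '%s'",
          attr(tc_a, "label"), attr(tc_b, "label"))
  nz <- tc_a$time_min > 0
  d <- tc_a$pct_attached - tc_b$pct_attached
  a_ge <- all(d[nz] >= 0)
  b_ge <- all(d[nz] <= 0)
  slower <- if (a_ge && b_ge) NA_character_  # identical at all nonzero points
  else if (a_ge) attr(tc_a, "label")
  else if (b_ge) attr(tc_b, "label")
  else NA_character_
  list(differences = data.frame(time_min = tc_a$time_min,
                                a = tc_a$pct_attached, b = tc_b$pct_attached,
                                diff = d),
       slower_label = slower,
       crossing = !a_ge && !b_ge)
}

#' Compare recomputed local slopes with a printed slope column
#'
#' Published slope tables occasionally contain entries that are not equal
#' to the finite difference of the printed percentages. This report
#' recomputes every local slope from the time course, rounds it with the
#' same convention, and flags any interval whose printed value disagrees --
#' documenting the discrepancy rather than repairing either number.
#'
#' @param tc a [digestion_timecourse()].
#' @param printed numeric vector of printed slopes, one per interval.
#' @param decimals rounding decimals (default 1).
#' @return data.frame: `t_start`, `t_end`, `computed`, `printed`,
#'   `consistent`.
#' @export
slope_discrepancy_report <- function(tc, printed, decimals = 1L) {
  sl <- local_slopes(tc, decimals)
  if (length(printed) != nrow(sl))
    stopf("%d printed slopes for %d intervals", length(printed), nrow(sl))
  data.frame(t_start = sl$t_start, t_end = sl$t_end,
             computed = sl$slope, printed = as.numeric(printed),
             consistent = abs(sl$slope - as.numeric(printed)) < 10^(-decimals) / 2)
}
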