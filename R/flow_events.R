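# Burst detection and phenotyping in nano-flow cytometry intensity
# traces, side-scatter size calibration, and recovery-rate arithmetic.

#' Construct a flow trace
#'
#' Three synchronized intensity channels sampled on a common time base:
#' side scatter (SSC, the particle-detection and sizing channel) and two
#' fluorescence channels (fl1 = AF488/CD9, fl2 = AF647/CD81).
#'
#' @param time_ms sampling times, ms (equally spaced).
#' @param ssc,fl1,fl2 intensities, arbitrary units.
#' @return a `"flow_trace"` data.frame.
#' @export
flow_trace <- function(time_ms, ssc, fl1, fl2) {
  n <- length(time_ms)
  stopifnot(length(ssc) == n, length(fl1) == n, length(fl2) == n, n > 0)
  out <- data.frame(time_ms = time_ms, ssc = ssc, fl1 = fl1, fl2 = fl2)
  class(out) <- c("flow_trace", "data.frame")
  out
}

#' Detect particle events in a flow trace
#'
#' The detection threshold is set from the trace itself: robust baseline
#' (median) plus `k_sigma` times the MAD-scaled robust SD of the SSC
#' channel (bursts would bias a plain mean/SD upward).  Each contiguous
#' supra-threshold excursion yields one event; per-channel heights are
#' read at the SSC peak sample, baseline-subtracted with each channel's
#' own median.
#'
#' @param trace a `"flow_trace"` with at least 100 samples.
#' @param k_sigma threshold multiplier (default 5).
#' @return data.frame `time_ms, ssc_height, fl1_height, fl2_height` (one
#'   row per event) with attributes `"threshold"` and `"baseline"`.  A
#'   flat trace (zero robust SD) returns zero events with a warning.
#' @export
detect_events <- function(trace, k_sigma = 5) {
  stopifnot(inherits(trace, "flow_trace"))
  if (nrow(trace) < 100L) stop("need >= 100 samples for baseline estimation")
  check_num(k_sigma, "k_sigma", lower = 0, strict = TRUE)
  base <- stats::median(trace$ssc)
  sdev <- stats::mad(trace$ssc)
  empty <- data.frame(time_ms = numeric(0), ssc_height = numeric(0),
                      fl1_height = numeric(0), fl2_height = numeric(0))
  if (sdev <= 0) {
    warning("flat SSC trace (robust SD = 0): no events detected")
    attr(empty, "threshold") <- NA_real_
    attr(empty, "baseline") <- base
    return(empty)
  }
  threshold <- base + k_sigma * sdev
  above <- trace$ssc > threshold
  if (!any(above)) {
    attr(empty, "threshold") <- threshold
    attr(empty, "baseline") <- base
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  b1 <- stats::median(trace$fl1)
  b2 <- stats::median(trace$fl2)
  peak <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(trace$ssc[seg])]
  }, integer(1))
  out <- data.frame(time_ms = trace$time_ms[peak],
                    ssc_height = trace$ssc[peak] - base,
                    fl1_height = trace$fl1[peak] - b1,
                    fl2_height = trace$fl2[peak] - b2)
  attr(out, "threshold") <- threshold
  attr(out, "baseline") <- base
  out
}

#' Call flow-event phenotypes and tabulate percentages
#'
#' Per-channel positivity is fluorescence height strictly above the
#' channel threshold.  Percentages are over ALL SSC-detected events
#' (double negatives included) and sum to 100.
#'
#' @param events event data.frame from [detect_events()].
#' @param fl1_threshold,fl2_threshold per-channel positivity thresholds,
#'   a.u. (instrument/run specific; no published defaults).
#' @param min_events minimum event count for a reliable sample (default
#'   1000); fewer events sets the `"low_counts"` attribute and warns.
#' @return named numeric vector
#'   `c(double_negative, CD9_only, CD81_only, double_positive)` of
#'   percentages summing to 100, with a `"phenotype"` attribute giving the
#'   per-event calls.
#' @export
call_flow_phenotypes <- function(events, fl1_threshold, fl2_threshold,
                                 min_events = 1000L) {
  n <- nrow(events)
  if (n == 0L) stop("no events")
  low <- n < min_events
  if (low) {
    warning(sprintf("only %d events (< %d): percentages may be unreliable",
                    n, min_events))
  }
  p9 <- events$fl1_height > fl1_threshold   # fl1 = AF488/CD9
  p81 <- events$fl2_height > fl2_threshold  # fl2 = AF647/CD81
  pheno <- ifelse(p9 & p81, "double_positive",
                  ifelse(p9, "CD9_only",
                         ifelse(p81, "CD81_only", "double_negative")))
  lv <- c("double_negative", "CD9_only", "CD81_only", "double_positive")
  pct <- 100 * as.numeric(table(factor(pheno, levels = lv))) / n
  names(pct) <- lv
  attr(pct, "phenotype") <- pheno
  attr(pct, "low_counts") <- low
  pct
}

#' Recalculate phenotype percentages without double negatives
#'
#' Rescales the three positive percentages to sum to 100 after dropping
#' the double-negative share, the recalculation used to compare flow
#' percentages with imaging fractions.
#'
#' @param p percentage quadruple
#'   `c(double_negative, CD9_only, CD81_only, double_positive)` (named or
#'   in this order).
#' @return named percentage triple `c(CD9_only, CD81_only,
#'   double_positive)` summing to 100.
#' @export
recalc_without_double_negatives <- function(p) {
  lv <- c("double_negative", "CD9_only", "CD81_only", "double_positive")
  if (!is.null(names(p)) && all(lv %in% names(p))) p <- p[lv]
  stopifnot(length(p) == 4L, all(p >= 0))
  pos <- sum(p[-1])
  if (pos <= 0) stop("all events are double negative: recalculation undefined")
  out <- 100 * p[-1] / pos
  names(out) <- lv[-1]
  out
}

#' Fit a side-scatter size calibration from beads
#'
#' Size beads of known diameter define a log-log piecewise-linear map from
#' SSC intensity to diameter; within the bead range events are
#' interpolated (so an event at a bead's SSC gets exactly that bead's
#' diameter, and log-log linearity maps geometric means to geometric
#' means), outside it the end segments are extended and the event is
#' flagged as extrapolated.
#'
#' @param beads data.frame with columns `diameter_nm` and `ssc` (>= 2
#'   rows); SSC must increase with diameter.
#' @return object of class `"ssc_calibration"`.
#' @export
fit_ssc_calibration <- function(beads) {
  stopifnot(all(c("diameter_nm", "ssc") %in% names(beads)), nrow(beads) >= 2L)
  beads <- beads[order(beads$diameter_nm), , drop = FALSE]
  if (any(diff(beads$ssc) <= 0) || any(beads$ssc <= 0) ||
      any(beads$diameter_nm <= 0)) {
    stop("bead table must be positive and strictly increasing in SSC")
  }
  structure(list(log_ssc = log(beads$ssc),
                 log_d = log(beads$diameter_nm),
                 beads = beads),
            class = "ssc_calibration")
}

#' Assign estimated diameters to flow events
#'
#' @param cal an `"ssc_calibration"`.
#' @param events event data.frame from [detect_events()].
#' @return `events` with columns `est_diameter` (nm) and `extrapolated`
#'   (logical) added; non-positive SSC heights get `NA`.
#' @export
calibrate_size <- function(cal, events) {
  stopifnot(inherits(cal, "ssc_calibration"))
  ls <- log(pmax(events$ssc_height, .Machine$double.xmin))
  k <- length(cal$log_ssc)
  inside <- ls >= cal$log_ssc[1] & ls <= cal$log_ssc[k]
  logd <- numeric(length(ls))
  if (any(inside)) {
    logd[inside] <- stats::approx(cal$log_ssc, cal$log_d,
                                  xout = ls[inside])$y
  }
  lo <- ls < cal$log_ssc[1]
  hi <- ls > cal$log_ssc[k]
  slope1 <- (cal$log_d[2] - cal$log_d[1]) / (cal$log_ssc[2] - cal$log_ssc[1])
  slopek <- (cal$log_d[k] - cal$log_d[k - 1]) /
    (cal$log_ssc[k] - cal$log_ssc[k - 1])
  logd[lo] <- cal$log_d[1] + slope1 * (ls[lo] - cal$log_ssc[1])
  logd[hi] <- cal$log_d[k] + slopek * (ls[hi] - cal$log_ssc[k])
  events$est_diameter <- exp(logd)
  events$est_diameter[events$ssc_height <= 0] <- NA_real_
  events$extrapolated <- lo | hi
  events
}

#' Particle recovery rate across a preparation step
#'
#' `100 * conc_after * dilution_factor / conc_before` — e.g. > 90% for
#' BSA-pretreated centrifugal filters versus a ~100-fold concentration
#' drop (about 1%) for size-exclusion columns.
#'
#' @param conc_before,conc_after particle concentrations (same units).
#' @param dilution_factor fold dilution applied between the measurements
#'   (default 1).
#' @return recovery percentage.
#' @export
recovery_rate <- function(conc_before, conc_after, dilution_factor = 1) {
  check_num(conc_before, "conc_before", lower = 0, strict = TRUE)
  check_num(conc_after, "conc_after", lower = 0)
  check_num(dilution_factor, "dilution_factor", lower = 0, strict = TRUE)
  100 * conc_after * dilution_factor / conc_before
}
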