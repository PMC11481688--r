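# Synthetic ground-truth data: two-channel localization tables emulating
# dSTORM imaging of antibody-labelled EVs, and nano-flow intensity traces
# with Poisson particle arrivals.  Every generated particle/event carries
# its true class and phenotype so downstream stages can be scored without
# instrument data.

#' Imaging simulation configuration
#'
#' The generated world: EVs are membrane-like annuli whose radius is
#' lognormal (median 60 nm by default, matching the observed
#' double-positive size component), antibody aggregates are tight Gaussian
#' clouds (median radius 20 nm) carrying a single channel's molecules,
#' marker molecules blink several times with geometric re-blink gaps
#' obeying the temporal-grouping frame structure, and free-dye background
#' localizations are uniform over the field of view.
#'
#' @param n_ev number of EV particles (default 500).
#' @param n_aggregate number of antibody aggregates (default 0; the
#'   default world is the labelled EV sample — simulate an antibody-only
#'   control with `n_ev = 0, n_aggregate > 0`).
#' @param ev_radius_median,ev_radius_sigma lognormal radius of EVs, nm
#'   (defaults 60, 0.4).
#' @param ab_radius_median,ab_radius_sigma lognormal radius of aggregates,
#'   nm (defaults 20, 0.4).
#' @param dp_fraction fraction of EVs carrying both markers (default
#'   0.59, the observed double-positive fraction); the remainder splits
#'   evenly between CD81-only and CD9-only.
#' @param molecules_per_marker Poisson mean of detected antibodies per
#'   carried marker (default 25; see the methods vignette for why this
#'   must comfortably exceed the >15-molecules-per-cluster detection
#'   rule).
#' @param localizations_per_molecule mean blinks per molecule (geometric,
#'   default 5).
#' @param background_locs_per_um2 free-dye localization density over the
#'   FOV, per square micrometre, split between channels (default 2).
#' @param fov_um field-of-view side length, micrometres (default 30).
#' @param loc_sd_nm localization precision, nm (default 10).
#' @param frame_gap,frames_per_channel blink timing structure (defaults 2
#'   and 1500, matching the grouping defaults and acquisition length).
#' @param seed integer seed.
#' @return a validated list of class `"imaging_sim_config"`.
#' @export
imaging_sim_config <- function(n_ev = 500L, n_aggregate = 0L,
                               ev_radius_median = 60, ev_radius_sigma = 0.4,
                               ab_radius_median = 20, ab_radius_sigma = 0.4,
                               dp_fraction = 0.59,
                               molecules_per_marker = 25,
                               localizations_per_molecule = 5,
                               background_locs_per_um2 = 2,
                               fov_um = 30, loc_sd_nm = 10,
                               frame_gap = 2L, frames_per_channel = 1500L,
                               seed = 1L) {
  check_num(n_ev, "n_ev", lower = 0)
  check_num(n_aggregate, "n_aggregate", lower = 0)
  check_num(ev_radius_median, "ev_radius_median", lower = 0, strict = TRUE)
  check_num(ev_radius_sigma, "ev_radius_sigma", lower = 0, strict = TRUE)
  check_num(ab_radius_median, "ab_radius_median", lower = 0, strict = TRUE)
  check_num(ab_radius_sigma, "ab_radius_sigma", lower = 0, strict = TRUE)
  check_num(dp_fraction, "dp_fraction", lower = 0)
  if (dp_fraction > 1) stop("'dp_fraction' must be in [0, 1]")
  check_num(molecules_per_marker, "molecules_per_marker", lower = 0,
            strict = TRUE)
  check_num(localizations_per_molecule, "localizations_per_molecule",
            lower = 1)
  check_num(background_locs_per_um2, "background_locs_per_um2", lower = 0)
  check_num(fov_um, "fov_um", lower = 0, strict = TRUE)
  check_num(loc_sd_nm, "loc_sd_nm", lower = 0)
  structure(as.list(environment()), class = "imaging_sim_config")
}

#' Simulate a two-channel localization table with ground truth
#'
#' See [imaging_sim_config()] for the generated world.  Identical seed and
#' configuration give bit-identical output.
#'
#' @param cfg an `"imaging_sim_config"`.
#' @return list with `locs` (a [loc_table()]) and `truth` (data.frame
#'   `particle, class, x, y, radius, phenotype, n_mol_ch1, n_mol_ch2`,
#'   where class is `"ev"` or `"aggregate"` and phenotype the true marker
#'   phenotype).
#' @export
simulate_imaging <- function(cfg) {
  stopifnot(inherits(cfg, "imaging_sim_config"))
  with_seed(cfg$seed, simulate_imaging_impl(cfg))
}

simulate_imaging_impl <- function(cfg) {
  fov_nm <- cfg$fov_um * 1000
  n_part <- cfg$n_ev + cfg$n_aggregate
  margin <- 4 * cfg$ev_radius_median
  truth <- data.frame(
    particle = seq_len(n_part),
    class = rep(c("ev", "aggregate"), c(cfg$n_ev, cfg$n_aggregate)),
    x = stats::runif(n_part, margin, max(margin, fov_nm - margin)),
    y = stats::runif(n_part, margin, max(margin, fov_nm - margin)),
    radius = rep(NA_real_, n_part),
    phenotype = rep(NA_character_, n_part),
    n_mol_ch1 = rep(0L, n_part), n_mol_ch2 = rep(0L, n_part)
  )
  sp_levels <- c("CD81_only", "CD9_only")
  mol <- list()
  for (i in seq_len(nrow(truth))) {
    if (truth$class[i] == "ev") {
      r <- stats::rlnorm(1, log(cfg$ev_radius_median), cfg$ev_radius_sigma)
      ph <- if (stats::runif(1) < cfg$dp_fraction) "double_positive" else
        sample(sp_levels, 1L)
      channels <- switch(ph, double_positive = c(1L, 2L),
                         CD81_only = 1L, CD9_only = 2L)
      for (ch in channels) {
        k <- stats::rpois(1, cfg$molecules_per_marker)
        if (k > 0) {
          theta <- stats::runif(k, 0, 2 * pi)  # membrane annulus
          mol[[length(mol) + 1L]] <- data.frame(
            particle = i, channel = ch,
            x = truth$x[i] + r * cos(theta),
            y = truth$y[i] + r * sin(theta))
        }
        if (ch == 1L) truth$n_mol_ch1[i] <- k else truth$n_mol_ch2[i] <- k
      }
    } else {
      r <- stats::rlnorm(1, log(cfg$ab_radius_median), cfg$ab_radius_sigma)
      ch <- sample(c(1L, 2L), 1L)  # aggregates are single-channel clumps
      ph <- if (ch == 1L) "CD81_only" else "CD9_only"
      k <- stats::rpois(1, cfg$molecules_per_marker)
      if (k > 0) {
        # Gaussian clump with per-axis SD r/sqrt(2) so Rg ~ r
        mol[[length(mol) + 1L]] <- data.frame(
          particle = i, channel = ch,
          x = stats::rnorm(k, truth$x[i], r / sqrt(2)),
          y = stats::rnorm(k, truth$y[i], r / sqrt(2)))
      }
      if (ch == 1L) truth$n_mol_ch1[i] <- k else truth$n_mol_ch2[i] <- k
    }
    truth$radius[i] <- r
    truth$phenotype[i] <- ph
  }
  mols <- if (length(mol)) do.call(rbind, mol) else
    data.frame(particle = integer(0), channel = integer(0),
               x = numeric(0), y = numeric(0))
  # expand molecules into blinking localizations
  loc <- expand_blinks(mols, cfg)
  # free-dye background
  n_bg <- stats::rpois(1, cfg$background_locs_per_um2 * cfg$fov_um^2)
  if (n_bg > 0) {
    bg <- data.frame(
      particle = NA_integer_,
      frame = sample.int(cfg$frames_per_channel, n_bg, replace = TRUE) - 1L,
      x = stats::runif(n_bg, 0, fov_nm),
      y = stats::runif(n_bg, 0, fov_nm),
      channel = sample(c(1L, 2L), n_bg, replace = TRUE))
    loc <- rbind(loc, bg)
  }
  tbl <- loc_table(frame = loc$frame, x = loc$x, y = loc$y,
                   channel = loc$channel,
                   frames_per_channel = cfg$frames_per_channel,
                   fov_nm = c(fov_nm, fov_nm))
  attr(tbl, "particle") <- loc$particle
  list(locs = tbl, truth = truth)
}

# Each molecule blinks 1 + Geom times; successive blink frames advance by
# 1..(frame_gap + 1), so all blinks of one molecule chain under the
# grouping rule.  Each blink gets isotropic localization noise.
expand_blinks <- function(mols, cfg) {
  n <- nrow(mols)
  if (n == 0L) {
    return(data.frame(particle = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), channel = integer(0)))
  }
  n_blinks <- 1L + stats::rgeom(n, 1 / cfg$localizations_per_molecule)
  idx <- rep.int(seq_len(n), n_blinks)
  total <- length(idx)
  start <- sample.int(cfg$frames_per_channel, n, replace = TRUE) - 1L
  step <- sample.int(cfg$frame_gap + 1L, total, replace = TRUE)
  # cumulative steps within each molecule, first blink at its start frame
  first <- !duplicated(idx)
  step[first] <- 0L
  frame <- start[idx] + as.integer(stats::ave(step, idx, FUN = cumsum))
  frame <- pmin(frame, cfg$frames_per_channel - 1L)
  data.frame(
    particle = mols$particle[idx],
    frame = frame,
    x = mols$x[idx] + stats::rnorm(total, 0, cfg$loc_sd_nm),
    y = mols$y[idx] + stats::rnorm(total, 0, cfg$loc_sd_nm),
    channel = mols$channel[idx])
}

#' Flow simulation configuration
#'
#' Poisson particle arrivals on a noisy three-channel trace.  Each
#' particle is a Gaussian pulse on SSC; fluorescence pulses appear on the
#' channels its phenotype carries.  The default phenotype mix is the 400x
#' dilution measurement (5.2% double positive, 10.6% CD81, 0.7% CD9,
#' remainder double negative); amplitudes are lognormal with median 15
#' noise-SD so labelled events sit well above a 5-sigma detection
#' threshold.
#'
#' @param event_rate_per_min particle arrival rate (default 6000/min;
#'   buffer blanks run at 200-400/min).
#' @param duration_ms trace duration (default 500 ms, one displayed trace
#'   window; use longer durations to accumulate the recommended >= 1000
#'   events).
#' @param dt_ms sampling interval (default 0.05 ms).
#' @param noise_sd white-noise SD on every channel, a.u. (default 1).
#' @param pulse_sigma_ms Gaussian pulse SD (default 0.15 ms).
#' @param mix phenotype probabilities
#'   `c(double_negative, CD9_only, CD81_only, double_positive)`, summing
#'   to 1.
#' @param ssc_amp_median,fl_amp_median,amp_sigma lognormal pulse-height
#'   parameters in absolute a.u. (defaults 15, 15, 0.5 — i.e. 15 noise
#'   SDs at the default unit noise).
#' @param seed integer seed.
#' @return a validated list of class `"flow_sim_config"`.
#' @export
flow_sim_config <- function(event_rate_per_min = 6000, duration_ms = 500,
                            dt_ms = 0.05, noise_sd = 1,
                            pulse_sigma_ms = 0.15,
                            mix = c(double_negative = 0.835,
                                    CD9_only = 0.007, CD81_only = 0.106,
                                    double_positive = 0.052),
                            ssc_amp_median = 15, fl_amp_median = 15,
                            amp_sigma = 0.5, seed = 1L) {
  check_num(event_rate_per_min, "event_rate_per_min", lower = 0)
  check_num(duration_ms, "duration_ms", lower = 0, strict = TRUE)
  check_num(dt_ms, "dt_ms", lower = 0, strict = TRUE)
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(pulse_sigma_ms, "pulse_sigma_ms", lower = 0, strict = TRUE)
  stopifnot(length(mix) == 4L, all(mix >= 0))
  if (abs(sum(mix) - 1) > 1e-9) stop("'mix' must sum to 1")
  names(mix) <- c("double_negative", "CD9_only", "CD81_only",
                  "double_positive")
  structure(as.list(environment()), class = "flow_sim_config")
}

#' Simulate a flow trace with ground truth
#'
#' @param cfg a `"flow_sim_config"`.
#' @return list with `trace` (a [flow_trace()]) and `truth` (data.frame
#'   `time_ms, phenotype, ssc_amp, fl1_amp, fl2_amp`).  Warns when more
#'   than 10% of pulses overlap within 4 pulse SDs.
#' @export
simulate_flow <- function(cfg) {
  stopifnot(inherits(cfg, "flow_sim_config"))
  with_seed(cfg$seed, simulate_flow_impl(cfg))
}

simulate_flow_impl <- function(cfg) {
  t_grid <- seq(0, cfg$duration_ms, by = cfg$dt_ms)
  n_samp <- length(t_grid)
  rate_ms <- cfg$event_rate_per_min / 60000
  n_ev <- stats::rpois(1, rate_ms * cfg$duration_ms)
  times <- sort(stats::runif(n_ev, 0, cfg$duration_ms))
  pheno <- if (n_ev > 0) {
    sample(names(cfg$mix), n_ev, replace = TRUE, prob = cfg$mix)
  } else {
    character(0)
  }
  ssc_amp <- stats::rlnorm(n_ev, log(cfg$ssc_amp_median), cfg$amp_sigma)
  fl_amp <- function(on) {
    ifelse(on, stats::rlnorm(n_ev, log(cfg$fl_amp_median), cfg$amp_sigma), 0)
  }
  fl1_amp <- fl_amp(pheno %in% c("CD9_only", "double_positive"))
  fl2_amp <- fl_amp(pheno %in% c("CD81_only", "double_positive"))
  if (n_ev > 1) {
    overlap <- mean(diff(times) < 4 * cfg$pulse_sigma_ms)
    if (overlap > 0.10) {
      warning(sprintf("%.0f%% of pulses overlap: rate too high for clean detection",
                      100 * overlap))
    }
  }
  ssc <- stats::rnorm(n_samp, 0, cfg$noise_sd)
  fl1 <- stats::rnorm(n_samp, 0, cfg$noise_sd)
  fl2 <- stats::rnorm(n_samp, 0, cfg$noise_sd)
  half_win <- ceiling(4 * cfg$pulse_sigma_ms / cfg$dt_ms)
  for (i in seq_len(n_ev)) {
    c0 <- round(times[i] / cfg$dt_ms) + 1
    win <- max(1, c0 - half_win):min(n_samp, c0 + half_win)
    shape <- exp(-(t_grid[win] - times[i])^2 / (2 * cfg$pulse_sigma_ms^2))
    ssc[win] <- ssc[win] + ssc_amp[i] * shape
    if (fl1_amp[i] > 0) fl1[win] <- fl1[win] + fl1_amp[i] * shape
    if (fl2_amp[i] > 0) fl2[win] <- fl2[win] + fl2_amp[i] * shape
  }
  list(trace = flow_trace(t_grid, ssc, fl1, fl2),
       truth = data.frame(time_ms = times, phenotype = pheno,
                          ssc_amp = ssc_amp, fl1_amp = fl1_amp,
                          fl2_amp = fl2_amp))
}
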