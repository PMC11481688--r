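# Lognormal decomposition of radius-of-gyration histograms and
# size-based correction of phenotype counts.
#
# The radius used throughout this module is the radius_of_gyration feature
# (the "approximate radius" of a particle).  Double-positive particles give
# the EV reference component (median ~60 nm); antibody-only control
# particles give the aggregate reference (median ~20 nm).  Single-positive
# histograms are decomposed as a weighted sum of the two reference
# densities; the EV weight is the estimated purity of that single-positive
# class.

#' Probability-density histogram of particle radii
#'
#' Uniform bins of `bin_width` nm from 0 to the 99.5th percentile of the
#' radii (rounded up to a whole bin), the default binning for
#' thousands-of-particles radius histograms (50 nm bins).
#'
#' @param radii positive radii in nm.
#' @param bin_width bin width in nm (default 50).
#' @param upper optional fixed upper edge; defaults to the 99.5th
#'   percentile rule.
#' @return list with `breaks`, `mids`, `density`, `counts`, `n`.
#' @export
radius_histogram <- function(radii, bin_width = 50, upper = NULL) {
  radii <- radii[is.finite(radii)]
  if (!length(radii)) stop("no finite radii")
  if (any(radii <= 0)) stop("radii must be positive")
  check_num(bin_width, "bin_width", lower = 0, strict = TRUE)
  if (is.null(upper)) upper <- stats::quantile(radii, 0.995, names = FALSE)
  upper <- max(bin_width, ceiling(upper / bin_width) * bin_width)
  breaks <- seq(0, upper, by = bin_width)
  inside <- radii[radii <= upper]
  h <- graphics::hist(inside, breaks = breaks, plot = FALSE)
  # densities normalized over the histogram range
  list(breaks = breaks, mids = h$mids, density = h$density,
       counts = h$counts, n = length(inside))
}

#' Construct a lognormal size component from median and log-scale sigma
#'
#' Useful for stating reference components directly (e.g. median 60 nm,
#' sigma 0.4 for EVs; median 20 nm for aggregates) rather than fitting
#' them.
#'
#' @param median_nm component median, nm (= exp(meanlog)).
#' @param sigma lognormal log-scale parameter (> 0).
#' @return a `"lognormal_fit"` component (without fit diagnostics).
#' @export
lognormal_component <- function(median_nm, sigma) {
  check_num(median_nm, "median_nm", lower = 0, strict = TRUE)
  check_num(sigma, "sigma", lower = 0, strict = TRUE)
  structure(list(meanlog = log(median_nm), sdlog = sigma,
                 median = median_nm, rss = NA_real_, r_squared = NA_real_,
                 mle = NULL, histogram = NULL),
            class = "lognormal_fit")
}

#' Fit a lognormal component to a radius histogram
#'
#' Least-squares fit of the lognormal density to the probability-density
#' histogram (the histogram-fitting procedure), initialized at and
#' cross-checked against the direct maximum-likelihood estimate
#' (log-mean / log-SD of the radii).
#'
#' @param radii positive radii in nm (>= 50 recommended).
#' @param bin_width histogram bin width, nm (default 50).
#' @param upper optional fixed histogram upper edge.
#' @return object of class `"lognormal_fit"`: list with `meanlog`,
#'   `sdlog`, `median` (= exp(meanlog), nm), `rss`, `r_squared`, `mle`
#'   (named meanlog/sdlog from MLE), and the `histogram`.
#' @export
fit_lognormal <- function(radii, bin_width = 50, upper = NULL) {
  radii <- radii[is.finite(radii)]
  if (any(radii <= 0)) stop("radii must be positive")
  lr <- log(radii)
  if (stats::sd(lr) < sqrt(.Machine$double.eps)) {
    stop("degenerate fit: all radii (near-)equal")
  }
  mle <- c(meanlog = mean(lr), sdlog = stats::sd(lr))
  h <- radius_histogram(radii, bin_width = bin_width, upper = upper)
  obj <- function(p) {
    sum((h$density - lognormal_bin_density(p[1], exp(p[2]), h$breaks))^2)
  }
  fit <- stats::optim(c(mle[["meanlog"]], log(mle[["sdlog"]])), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  meanlog <- fit$par[1]
  sdlog <- exp(fit$par[2])
  rss <- fit$value
  sstot <- sum((h$density - mean(h$density))^2)
  structure(list(meanlog = meanlog, sdlog = sdlog, median = exp(meanlog),
                 rss = rss,
                 r_squared = if (sstot > 0) 1 - rss / sstot else NA_real_,
                 mle = mle, histogram = h),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> median %.1f nm (meanlog %.3f, sdlog %.3f), R^2 %.3f\n",
              x$median, x$meanlog, x$sdlog, x$r_squared))
  invisible(x)
}

# Bin-averaged lognormal density over histogram bins, normalized over the
# histogram range: with finite (50 nm) bins the midpoint density is a
# biased model of a probability-density histogram, the bin-integrated
# probability divided by the bin width is not.
lognormal_bin_density <- function(meanlog, sdlog, breaks) {
  p <- stats::plnorm(breaks, meanlog, sdlog)
  total <- p[length(p)] - p[1]
  if (total <= 0) return(rep(0, length(breaks) - 1L))
  diff(p) / (diff(breaks) * total)
}

#' Decompose a single-positive radius histogram into EV and aggregate parts
#'
#' With the two component shapes fixed at their reference fits (EV from
#' double positives, aggregate from the antibody-only control), the only
#' free parameter is the mixture weight `w_ev`, estimated by least squares
#' on the probability-density histogram of the single-positive radii
#' (closed-form projection, clipped to `[0, 1]`).  With
#' `fix_shapes = FALSE` all five parameters (two shapes and the weight)
#' are refit by Nelder-Mead starting from the references.
#'
#' @param sp_radii radii of one single-positive class, nm.
#' @param ev_ref,ab_ref `"lognormal_fit"` reference components.
#' @param bin_width histogram bin width, nm (default 50).
#' @param fix_shapes keep component shapes frozen at the references
#'   (default `TRUE`).
#' @return object of class `"mixture_decomposition"`: `w_ev`, `w_ab`
#'   (areas of the weighted curves, summing to 1), `r_squared` of the
#'   combined fit, the `ev` and `ab` components used, `n` radii, and
#'   `ill_conditioned` (TRUE when the reference medians differ by < 10%).
#' @export
decompose_single_positive <- function(sp_radii, ev_ref, ab_ref,
                                      bin_width = 50, fix_shapes = TRUE) {
  stopifnot(inherits(ev_ref, "lognormal_fit"), inherits(ab_ref, "lognormal_fit"))
  sp_radii <- sp_radii[is.finite(sp_radii)]
  if (!length(sp_radii)) stop("sp_radii is empty")
  ill <- abs(log(ev_ref$median / ab_ref$median)) < log(1.1)
  if (ill) {
    warning("reference medians within 10%: weight estimate is ill-conditioned")
  }
  h <- radius_histogram(sp_radii, bin_width = bin_width)
  y <- h$density
  if (fix_shapes) {
    f_ev <- lognormal_bin_density(ev_ref$meanlog, ev_ref$sdlog, h$breaks)
    f_ab <- lognormal_bin_density(ab_ref$meanlog, ab_ref$sdlog, h$breaks)
    # y ~ w*f_ev + (1-w)*f_ab : 1-D least squares, closed form, clipped
    d <- f_ev - f_ab
    w <- if (sum(d^2) > 0) sum((y - f_ab) * d) / sum(d^2) else 0.5
    w <- min(1, max(0, w))
    ev_out <- ev_ref; ab_out <- ab_ref
    fitted <- w * f_ev + (1 - w) * f_ab
  } else {
    obj <- function(p) {
      w <- stats::plogis(p[1])
      f <- w * lognormal_bin_density(p[2], exp(p[3]), h$breaks) +
        (1 - w) * lognormal_bin_density(p[4], exp(p[5]), h$breaks)
      sum((y - f)^2)
    }
    start <- c(0, ev_ref$meanlog, log(ev_ref$sdlog),
               ab_ref$meanlog, log(ab_ref$sdlog))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    w <- stats::plogis(fit$par[1])
    ev_out <- structure(list(meanlog = fit$par[2], sdlog = exp(fit$par[3]),
                             median = exp(fit$par[2])),
                        class = "lognormal_fit")
    ab_out <- structure(list(meanlog = fit$par[4], sdlog = exp(fit$par[5]),
                             median = exp(fit$par[4])),
                        class = "lognormal_fit")
    fitted <- w * lognormal_bin_density(ev_out$meanlog, ev_out$sdlog,
                                        h$breaks) +
      (1 - w) * lognormal_bin_density(ab_out$meanlog, ab_out$sdlog, h$breaks)
  }
  rss <- sum((y - fitted)^2)
  sstot <- sum((y - mean(y))^2)
  structure(list(w_ev = w, w_ab = 1 - w,
                 r_squared = if (sstot > 0) 1 - rss / sstot else NA_real_,
                 ev = ev_out, ab = ab_out, n = h$n,
                 histogram = h, fitted = fitted,
                 ill_conditioned = ill),
            class = "mixture_decomposition")
}

#' @export
print.mixture_decomposition <- function(x, ...) {
  cat(sprintf("<mixture_decomposition> w_ev %.3f / w_ab %.3f, R^2 %.3f (n=%d)\n",
              x$w_ev, x$w_ab, x$r_squared, x$n))
  invisible(x)
}

#' Correct a phenotype summary using size decompositions
#'
#' Each single-positive count is multiplied by the EV weight of its class's
#' decomposition (removing the estimated antibody aggregates); the
#' double-positive count is unchanged; fractions are renormalized over the
#' corrected totals.
#'
#' @param raw a `"phenotype_summary"`.
#' @param decomp_cd9 decomposition of the CD9-only (channel 2) radii.
#' @param decomp_cd81 decomposition of the CD81-only (channel 1) radii.
#' @param w_ev_cd9,w_ev_cd81 alternatively, EV weights given directly
#'   (overriding the decomposition objects).
#' @return object of class `"corrected_summary"`: corrected `counts`,
#'   `fractions`, the weights used, and `correction_method = "size_fit"`.
#' @export
correct_summary <- function(raw, decomp_cd9 = NULL, decomp_cd81 = NULL,
                            w_ev_cd9 = NULL, w_ev_cd81 = NULL) {
  stopifnot(inherits(raw, "phenotype_summary"))
  if (is.null(w_ev_cd9)) w_ev_cd9 <- decomp_cd9$w_ev
  if (is.null(w_ev_cd81)) w_ev_cd81 <- decomp_cd81$w_ev
  stopifnot(is.numeric(w_ev_cd9), is.numeric(w_ev_cd81),
            w_ev_cd9 >= 0, w_ev_cd9 <= 1, w_ev_cd81 >= 0, w_ev_cd81 <= 1)
  corrected <- c(
    CD81_only = unname(raw$counts[["CD81_only"]] * w_ev_cd81),
    CD9_only = unname(raw$counts[["CD9_only"]] * w_ev_cd9),
    double_positive = unname(raw$counts[["double_positive"]])
  )
  total <- sum(corrected)
  fractions <- if (total > 0) corrected / total else corrected * NA_real_
  structure(list(counts = corrected, fractions = fractions,
                 w_ev = c(CD9 = w_ev_cd9, CD81 = w_ev_cd81),
                 correction_method = "size_fit"),
            class = "corrected_summary")
}

#' @export
print.corrected_summary <- function(x, ...) {
  cat(sprintf("<corrected_summary> (%s)\n", x$correction_method))
  cat("  counts:   ", paste(sprintf("%s=%.1f", names(x$counts), x$counts),
                            collapse = "  "), "\n")
  cat("  fractions:", paste(sprintf("%s=%.3f", names(x$fractions),
                                    x$fractions), collapse = "  "), "\n")
  invisible(x)
}
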