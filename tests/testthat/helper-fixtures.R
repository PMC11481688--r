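# Programmatic fixtures shared across test files.

# A loc_table from bare coordinate vectors (single frame/channel defaults).
make_locs <- function(x, y, channel = 1L, frame = 0L) {
  loc_table(frame = rep_len(frame, length(x)), x = x, y = y,
            channel = rep_len(channel, length(x)))
}

# n points uniform in a disc of radius r centred at (cx, cy).
disc_points <- function(n, r, cx = 0, cy = 0) {
  rr <- r * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# Build an ev_clusters object through the public API from molecule points:
# a list of groups, each a data.frame/list with x, y, channel vectors.
clusters_from_points <- function(groups, link_radius = 150,
                                 min_molecules = 0L) {
  mols <- do.call(rbind, lapply(groups, function(g) {
    data.frame(x = g$x, y = g$y, channel = as.integer(g$channel))
  }))
  mols <- data.frame(molecule = seq_len(nrow(mols)), x = mols$x, y = mols$y,
                     channel = mols$channel, n_locs = 1L,
                     first_frame = 0L, last_frame = 0L)
  detect_clusters(mols, link_radius = link_radius,
                  min_molecules = min_molecules)
}

# k molecule positions within `radius` of a centre, on a ring (so all are
# inside the phenotype counting radius by construction).
ring_points <- function(k, radius, cx = 0, cy = 0, channel = 1L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-1L]
  list(x = cx + radius * cos(th), y = cy + radius * sin(th),
       channel = rep(channel, k))
}

# Feature data.frame with the 12 descriptor columns filled from a matrix.
feature_frame <- function(m) {
  df <- as.data.frame(m)
  names(df) <- feature_names()[seq_len(ncol(m))]
  for (nm in setdiff(feature_names(), names(df))) df[[nm]] <- 0
  df$degenerate <- FALSE
  df
}

# Well-separated two-class feature sets (EV-like large vs aggregate-like
# small radius of gyration) for classifier tests.
toy_feature_classes <- function(n_ev = 60, n_ab = 60, sep = 4, seed = 42) {
  set.seed(seed)
  base <- function(n, rg_mean) {
    rg <- stats::rnorm(n, rg_mean, 8)
    data.frame(
      radius_of_gyration = rg,
      num_localisations = stats::rpois(n, 120),
      convex_hull_area = pi * rg^2 + stats::rnorm(n, 0, 500),
      distance_birth = abs(stats::rnorm(n, 20, 5)),
      skew = abs(stats::rnorm(n, 0.4, 0.2)),
      discretised_area = 100 * stats::rpois(n, 60),
      distance_depth = abs(stats::rnorm(n, 30, 8)),
      circularity = stats::runif(n, 0.6, 1),
      density = stats::runif(n, 0.001, 0.05),
      length = 2.5 * rg,
      ch1_binned_counts = stats::rpois(n, 60),
      ch2_binned_counts = stats::rpois(n, 60),
      degenerate = FALSE)
  }
  list(dp = base(n_ev, 60), ab = base(n_ab, 60 - sep * 10))
}
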