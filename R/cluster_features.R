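# Per-cluster shape/density descriptors used for filtering and for
# aggregate-vs-EV classification.

#' Names of the per-cluster feature descriptors
#'
#' The twelve descriptors computed per cluster: radius of gyration (nm),
#' number of localizations, convex-hull area (nm^2), single-linkage birth
#' distance (nm), per-axis skewness magnitude, discretised (pixelated
#' support) area (nm^2), single-linkage persistence depth (nm), hull
#' circularity, localization density (per nm^2), maximum extent (nm), and
#' per-channel localization counts.
#'
#' @return character vector of length 12.
#' @export
feature_names <- function() {
  c("radius_of_gyration", "num_localisations", "convex_hull_area",
    "distance_birth", "skew", "discretised_area", "distance_depth",
    "circularity", "density", "length", "ch1_binned_counts",
    "ch2_binned_counts")
}

#' Compute feature descriptors for every cluster
#'
#' Definitions: radius of gyration is the RMS distance of member
#' localizations from their centroid; convex-hull area/perimeter come from
#' the 2-D hull of member localizations; circularity is `4*pi*A / P^2`
#' (1 for a disc); length is the maximum pairwise distance; skew is the
#' Euclidean norm of the two per-axis sample skewnesses; discretised area
#' is the number of occupied pixels on a `pixel_nm` grid times the pixel
#' area; distance_birth / distance_depth are the median and the span
#' (max - min) of the single-linkage merge heights of the cluster's member
#' molecules; density is localizations per unit hull area.  Clusters with a
#' degenerate (collinear or coincident) hull get hull-based features set to
#' 0 and `degenerate = TRUE`.
#'
#' @param cl an `"ev_clusters"` object from [detect_clusters()].
#' @param locs the [loc_table()] the molecules were grouped from.
#' @param loc_molecule integer molecule id per localization row; defaults
#'   to the `"loc_molecule"` attribute recorded by [group_temporally()].
#' @param pixel_nm pixel size for the discretised area, nm (default 10,
#'   comparable to localization precision).
#' @return data.frame with `cluster_id`, the 12 columns of
#'   [feature_names()], a logical `degenerate` flag, and per-channel
#'   auxiliary columns (`disc_area_ch1/2`, `distance_birth_ch1/2`,
#'   `distance_depth_ch1/2`) used by [build_training_set()] to construct
#'   single-channel views of double-positive clusters.
#' @export
compute_features <- function(cl, locs, loc_molecule = NULL, pixel_nm = 10) {
  stopifnot(inherits(cl, "ev_clusters"))
  if (is.null(loc_molecule)) {
    loc_molecule <- attr(cl$molecules, "loc_molecule")
  }
  if (is.null(loc_molecule) || length(loc_molecule) != nrow(locs)) {
    stop("need a localization->molecule assignment of length nrow(locs)")
  }
  mol_cluster <- cl$molecules$cluster_id
  loc_cluster <- mol_cluster[loc_molecule]
  ids <- cl$clusters$cluster_id
  rows <- lapply(ids, function(cid) {
    li <- which(!is.na(loc_cluster) & loc_cluster == cid)
    mi <- which(!is.na(mol_cluster) & mol_cluster == cid)
    cluster_feature_row(locs$x[li], locs$y[li], locs$channel[li],
                        cl$molecules$x[mi], cl$molecules$y[mi],
                        cl$molecules$channel[mi], pixel_nm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    cols <- c(feature_names(), "degenerate", "disc_area_ch1",
              "disc_area_ch2", "distance_birth_ch1", "distance_birth_ch2",
              "distance_depth_ch1", "distance_depth_ch2")
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols),
                                dimnames = list(NULL, cols)))
  }
  cbind(cluster_id = ids, out)
}

# Feature row for one cluster; x/y/channel are member localizations,
# mx/my/mch the member molecule positions and channels.
cluster_feature_row <- function(x, y, channel, mx, my, mch, pixel_nm) {
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  rg <- sqrt(mean((x - cx)^2 + (y - cy)^2))
  hull <- hull_geometry(x, y)
  degenerate <- hull$area <= 0
  circ <- if (degenerate || hull$perimeter <= 0) 0 else {
    min(1, 4 * pi * hull$area / hull$perimeter^2)
  }
  len <- max_extent(x, y, hull$idx)
  m2x <- mean((x - cx)^2); m2y <- mean((y - cy)^2)
  sk_x <- if (m2x > 0) mean((x - cx)^3) / m2x^1.5 else 0
  sk_y <- if (m2y > 0) mean((y - cy)^3) / m2y^1.5 else 0
  skew <- sqrt(sk_x^2 + sk_y^2)
  disc <- function(sel) {
    if (!any(sel)) return(0)
    pix <- unique(paste(floor(x[sel] / pixel_nm), floor(y[sel] / pixel_nm)))
    length(pix) * pixel_nm^2
  }
  disc_area <- disc(rep(TRUE, n))
  linkage <- function(sel) {
    if (sum(sel) < 2) return(c(0, 0))
    h <- stats::hclust(stats::dist(cbind(mx[sel], my[sel])),
                       method = "single")$height
    c(stats::median(h), max(h) - min(h))
  }
  bd <- linkage(rep(TRUE, length(mx)))
  birth <- bd[1]; depth <- bd[2]
  bd1 <- linkage(mch == 1L); bd2 <- linkage(mch == 2L)
  data.frame(
    radius_of_gyration = rg,
    num_localisations = n,
    convex_hull_area = if (degenerate) 0 else hull$area,
    distance_birth = birth,
    skew = skew,
    discretised_area = disc_area,
    distance_depth = depth,
    circularity = circ,
    density = if (degenerate) 0 else n / hull$area,
    length = len,
    ch1_binned_counts = sum(channel == 1L),
    ch2_binned_counts = sum(channel == 2L),
    degenerate = degenerate,
    disc_area_ch1 = disc(channel == 1L),
    disc_area_ch2 = disc(channel == 2L),
    distance_birth_ch1 = bd1[1],
    distance_birth_ch2 = bd2[1],
    distance_depth_ch1 = bd1[2],
    distance_depth_ch2 = bd2[2]
  )
}

hull_geometry <- function(x, y) {
  if (length(x) < 3L) return(list(area = 0, perimeter = 0, idx = seq_along(x)))
  idx <- tryCatch(grDevices::chull(x, y), error = function(e) integer(0))
  if (length(idx) < 3L) return(list(area = 0, perimeter = 0, idx = idx))
  hx <- x[idx]; hy <- y[idx]
  nx <- c(hx[-1], hx[1]); ny <- c(hy[-1], hy[1])
  area <- abs(sum(hx * ny - nx * hy)) / 2
  perimeter <- sum(sqrt((nx - hx)^2 + (ny - hy)^2))
  list(area = area, perimeter = perimeter, idx = idx)
}

max_extent <- function(x, y, hull_idx) {
  if (length(x) < 2L) return(0)
  # the diameter of a point set is attained at hull vertices; fall back to
  # all points for degenerate hulls
  if (length(hull_idx) >= 2L) {
    px <- x[hull_idx]; py <- y[hull_idx]
  } else {
    px <- x; py <- y
  }
  if (length(px) > 1500L) {  # guard: subsample pathological inputs
    keep <- unique(round(seq(1L, length(px), length.out = 1500L)))
    px <- px[keep]; py <- py[keep]
  }
  max(stats::dist(cbind(px, py)))
}

#' Skew/circularity shape filter for candidate EV clusters
#'
#' Clusters are retained iff skew lies in `skew_range` and circularity in
#' `circ_range` (bounds inclusive): the selection window skew in [1, 2.9]
#' and circularity in [0.43, 1].
#'
#' @param features data.frame from [compute_features()] (or any data.frame
#'   with `skew` and `circularity` columns).
#' @param skew_range,circ_range inclusive `[lo, hi]` bounds.
#' @return logical vector, one element per row of `features`.
#' @export
shape_filter <- function(features, skew_range = c(1, 2.9),
                         circ_range = c(0.43, 1)) {
  stopifnot(length(skew_range) == 2L, length(circ_range) == 2L)
  features$skew >= skew_range[1] & features$skew <= skew_range[2] &
    features$circularity >= circ_range[1] &
    features$circularity <= circ_range[2]
}
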