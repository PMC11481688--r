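# Temporal grouping of blinking events into molecules and spatial
# clustering of molecules into candidate particles.

#' Group repeated blinking events into molecules
#'
#' A single fluorophore blinks repeatedly over nearby frames.  Two
#' localizations of the same channel belong to the same molecule iff they
#' are linked by a chain of steps each at most `max_distance` apart
#' spatially and at most `frame_gap + 1` frames apart (the transitive
#' closure of the step relation).  Channels are acquired sequentially and
#' are never merged.  The molecule position is the unweighted mean of its
#' member localizations.
#'
#' @param tbl a [loc_table()].
#' @param frame_gap maximum number of dark frames between successive blinks
#'   of one molecule (default 2, i.e. steps of up to 3 frames).
#' @param max_distance maximum spatial step between linked localizations,
#'   in nm (default 30).
#' @return a data.frame of molecules with columns `molecule, x, y, channel,
#'   n_locs, first_frame, last_frame`, ordered by first appearance.  The
#'   attribute `"loc_molecule"` gives the molecule id of every input row.
#' @export
group_temporally <- function(tbl, frame_gap = 2L, max_distance = 30) {
  check_num(frame_gap, "frame_gap", lower = 0)
  check_num(max_distance, "max_distance", lower = 0, strict = TRUE)
  if (nrow(tbl) == 0L) {
    out <- data.frame(molecule = integer(0), x = numeric(0), y = numeric(0),
                      channel = integer(0), n_locs = integer(0),
                      first_frame = integer(0), last_frame = integer(0))
    attr(out, "loc_molecule") <- integer(0)
    return(out)
  }
  comp <- radius_components(tbl$x, tbl$y, radius = max_distance,
                            channel = tbl$channel, frame = tbl$frame,
                            max_frame_diff = frame_gap + 1L)
  out <- data.frame(
    molecule = seq_along(unique(comp)),
    x = as.numeric(tapply(tbl$x, comp, mean)),
    y = as.numeric(tapply(tbl$y, comp, mean)),
    channel = as.integer(tapply(tbl$channel, comp, `[`, 1L)),
    n_locs = as.integer(tabulate(comp)),
    first_frame = as.integer(tapply(tbl$frame, comp, min)),
    last_frame = as.integer(tapply(tbl$frame, comp, max))
  )
  attr(out, "loc_molecule") <- comp
  out
}

#' Detect particle clusters among molecules
#'
#' Clusters are connected components of the cross-channel molecule graph
#' with an edge between any two molecules at most `link_radius` apart.
#' Only components with strictly more than `min_molecules` members are
#' returned (the particle-detection rule: clusters with more than 15
#' individual molecules count as EV candidates).
#'
#' @param molecules molecule data.frame from [group_temporally()].
#' @param link_radius linking radius in nm (default 150, the phenotype
#'   radius scale).
#' @param min_molecules strict lower bound on total molecules per cluster
#'   (default 15: a cluster needs more than 15 molecules).
#' @return an object of class `"ev_clusters"`: a list with
#'   \describe{
#'     \item{clusters}{data.frame `cluster_id, x, y, n_molecules, n_ch1,
#'       n_ch2` (centre = unweighted centroid of member molecules)}
#'     \item{molecules}{the input molecules with a `cluster_id` column
#'       (`NA` for molecules in no retained cluster)}
#'   }
#' @export
detect_clusters <- function(molecules, link_radius = 150, min_molecules = 15L) {
  check_num(link_radius, "link_radius", lower = 0, strict = TRUE)
  check_num(min_molecules, "min_molecules", lower = 0)
  molecules <- as.data.frame(molecules)
  n <- nrow(molecules)
  if (n == 0L) {
    return(empty_clusters(molecules))
  }
  comp <- radius_components(molecules$x, molecules$y, radius = link_radius)
  sizes <- tabulate(comp)
  keep <- which(sizes > min_molecules)
  if (!length(keep)) return(empty_clusters(molecules))
  new_id <- rep(NA_integer_, max(comp))
  new_id[keep] <- seq_along(keep)
  molecules$cluster_id <- new_id[comp]
  kept <- !is.na(molecules$cluster_id)
  g <- molecules$cluster_id[kept]
  clusters <- data.frame(
    cluster_id = seq_along(keep),
    x = as.numeric(tapply(molecules$x[kept], g, mean)),
    y = as.numeric(tapply(molecules$y[kept], g, mean)),
    n_molecules = as.integer(tabulate(g, nbins = length(keep))),
    n_ch1 = as.integer(tapply(molecules$channel[kept] == 1L, g, sum)),
    n_ch2 = as.integer(tapply(molecules$channel[kept] == 2L, g, sum))
  )
  structure(list(clusters = clusters, molecules = molecules),
            class = "ev_clusters")
}

empty_clusters <- function(molecules) {
  molecules$cluster_id <- rep(NA_integer_, nrow(molecules))
  structure(list(
    clusters = data.frame(cluster_id = integer(0), x = numeric(0),
                          y = numeric(0), n_molecules = integer(0),
                          n_ch1 = integer(0), n_ch2 = integer(0)),
    molecules = molecules
  ), class = "ev_clusters")
}

#' @export
print.ev_clusters <- function(x, ...) {
  cat(sprintf("<ev_clusters> %d cluster(s) from %d molecule(s)\n",
              nrow(x$clusters), nrow(x$molecules)))
  invisible(x)
}
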