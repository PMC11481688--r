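# Localization table input/output and pipeline-wide conventions.
#
# Coordinates are in nanometres with the imaging convention: origin at the
# top-left of the field of view, y increasing downward.  Channel 1 is
# CD81/AF647, channel 2 is CD9/AF488; the two channels are acquired
# sequentially (default 1500 frames each) and are treated as independent
# frame sequences throughout.

#' Channel to marker mapping
#'
#' Channel 1 carries the AF647 anti-CD81 signal, channel 2 the AF488
#' anti-CD9 signal.
#'
#' @return named integer vector `c(CD81 = 1, CD9 = 2)`.
#' @export
channel_markers <- function() c(CD81 = 1L, CD9 = 2L)

#' Construct a localization table
#'
#' A localization is one detected blinking event of a single fluorophore.
#' The table is an ordinary data.frame with class `"loc_table"` and an
#' acquisition-metadata attribute.
#'
#' @param frame integer frame index (0-based) within the channel's own
#'   acquisition sequence.
#' @param x,y coordinates in nm.
#' @param channel integer channel (1 = CD81/AF647, 2 = CD9/AF488).
#' @param photons optional photon counts (arbitrary units).
#' @param id optional unique integer ids; defaults to row order.
#' @param frames_per_channel,exposure_ms,fov_nm acquisition metadata:
#'   frames recorded per channel (default 1500), exposure per frame in ms
#'   (default 30), and the field-of-view extent `c(width, height)` in nm
#'   (default derived from the data).
#' @return a `loc_table` data.frame with columns `id, frame, x, y, channel,
#'   photons`.
#' @export
loc_table <- function(frame, x, y, channel, photons = NA_real_, id = NULL,
                      frames_per_channel = 1500L, exposure_ms = 30,
                      fov_nm = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(frame) == n, length(channel) == n)
  frame <- as.integer(frame)
  channel <- as.integer(channel)
  if (n > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("localization coordinates must be finite")
    }
    if (any(frame < 0L)) stop("frame indices must be >= 0")
    if (!all(channel %in% c(1L, 2L))) stop("channel must be 1 or 2")
  }
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("localization ids must be unique")
  if (is.null(fov_nm)) {
    fov_nm <- if (n > 0) c(max(x), max(y)) else c(0, 0)
  }
  out <- data.frame(id = as.integer(id), frame = frame, x = as.numeric(x),
                    y = as.numeric(y), channel = channel,
                    photons = rep_len(as.numeric(photons), n))
  attr(out, "metadata") <- list(frames_per_channel = frames_per_channel,
                                exposure_ms = exposure_ms, fov_nm = fov_nm)
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Column-name dialect for localization CSV files
#'
#' Maps this package's canonical column names onto the names used by a
#' particular exporter, with an optional coordinate scale for files not in
#' nm (e.g. `xy_scale = 1000` for micrometre coordinates).
#'
#' @param frame,x,y,channel,photons column names in the file; `photons` may
#'   be `NA` if absent.
#' @param xy_scale multiplicative factor converting file coordinates to nm.
#' @return a named list of class `"loc_dialect"`.
#' @export
loc_dialect <- function(frame = "frame", x = "x", y = "y",
                        channel = "channel", photons = "photons",
                        xy_scale = 1) {
  check_num(xy_scale, "xy_scale", lower = 0, strict = TRUE)
  structure(list(frame = frame, x = x, y = y, channel = channel,
                 photons = photons, xy_scale = xy_scale),
            class = "loc_dialect")
}

#' Read a localization dialect from a key=value file
#'
#' One `key=value` pair per line; keys are the arguments of [loc_dialect()].
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a `loc_dialect`.
#' @export
read_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  args <- as.list(vals)
  names(args) <- keys
  if (!is.null(args$xy_scale)) args$xy_scale <- as.numeric(args$xy_scale)
  do.call(loc_dialect, args)
}

#' Read a two-channel localization table from CSV
#'
#' Rows with non-numeric or missing coordinates/frames and rows with an
#' unrecognized channel are dropped; their count is recorded in the
#' `"n_malformed"` attribute and reported with a warning.  Channel values
#' may be `1`/`2`, `"CH1"`/`"CH2"`, or marker names `"CD81"`/`"CD9"`.
#'
#' @param path CSV file with a header row.
#' @param dialect a [loc_dialect()] mapping canonical names to file columns.
#' @param ... further arguments passed to [loc_table()] (metadata).
#' @return a `loc_table`.
#' @export
read_localizations <- function(path, dialect = loc_dialect(), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(frame = dialect$frame, x = dialect$x, y = dialect$y,
              channel = dialect$channel)
  missing_cols <- needed[!needed %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))
  }
  frame <- suppressWarnings(as.numeric(raw[[dialect$frame]]))
  x <- suppressWarnings(as.numeric(raw[[dialect$x]])) * dialect$xy_scale
  y <- suppressWarnings(as.numeric(raw[[dialect$y]])) * dialect$xy_scale
  channel <- parse_channel(raw[[dialect$channel]])
  photons <- if (!is.na(dialect$photons) && dialect$photons %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[dialect$photons]]))
  } else {
    NA_real_
  }
  ok <- is.finite(frame) & is.finite(x) & is.finite(y) & !is.na(channel) &
    frame >= 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("dropped %d malformed row(s) of %d", n_bad, length(ok)))
  }
  out <- loc_table(frame = frame[ok], x = x[ok], y = y[ok],
                   channel = channel[ok],
                   photons = if (length(photons) > 1L) photons[ok] else photons,
                   ...)
  attr(out, "n_malformed") <- n_bad
  out
}

parse_channel <- function(v) {
  if (is.numeric(v)) {
    ch <- as.integer(v)
  } else {
    key <- toupper(trimws(as.character(v)))
    ch <- rep(NA_integer_, length(key))
    ch[key %in% c("1", "CH1", "CD81", "AF647")] <- 1L
    ch[key %in% c("2", "CH2", "CD9", "AF488")] <- 2L
  }
  ch[!ch %in% c(1L, 2L)] <- NA_integer_
  ch
}

#' Write a localization table to CSV
#'
#' @param tbl a `loc_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_localizations <- function(tbl, path) {
  df <- as.data.frame(tbl)
  df$x <- format_real(df$x)
  df$y <- format_real(df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_real <- function(v) {
  out <- vapply(v, function(z) format(z, digits = 17, scientific = FALSE,
                                      trim = TRUE), "")
  out[is.na(v)] <- "NA"
  out
}

#' Write / read a cluster summary table
#'
#' The cluster table holds one row per detected particle cluster: centre
#' coordinates (nm, unweighted centroid of member molecules), total and
#' per-channel molecule counts.  `write_clusters()` followed by
#' `read_clusters()` round-trips integers exactly and reals to better than
#' 1e-9 relative error.
#'
#' @param clusters a cluster data.frame (from [detect_clusters()], the
#'   `$clusters` element, or a compatible data.frame with columns
#'   `cluster_id, x, y, n_molecules, n_ch1, n_ch2`).
#' @param path CSV path.
#' @return `write_clusters()` returns `path` invisibly; `read_clusters()`
#'   returns the cluster data.frame.
#' @export
write_clusters <- function(clusters, path) {
  if (is.list(clusters) && !is.data.frame(clusters) &&
      !is.null(clusters$clusters)) {
    clusters <- clusters$clusters
  }
  cols <- c("cluster_id", "x", "y", "n_molecules", "n_ch1", "n_ch2")
  if (!all(cols %in% names(clusters))) {
    stop("cluster table must have columns: ", paste(cols, collapse = ", "))
  }
  df <- as.data.frame(clusters)[, cols, drop = FALSE]
  df$x <- format_real(df$x)
  df$y <- format_real(df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  int_cols <- c("cluster_id", "n_molecules", "n_ch1", "n_ch2")
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  df
}
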