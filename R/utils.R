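# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the caller's RNG state, so
#' seeded operations (simulation, model training) do not perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Connected components of the fixed-radius neighbour graph.
#
# Points i, j are linked iff dist(i, j) <= radius, channel[i] == channel[j]
# (when `channel` is given) and 0 <= |frame_i - frame_j| <= max_frame_diff
# (when `frame` is given).  Returns an integer component label per point
# (labels are 1..k in order of first appearance).  Uses grid binning at cell
# size = radius so only the 3x3 cell neighbourhood is searched; exact, not
# approximate.
radius_components <- function(x, y, radius, channel = NULL, frame = NULL,
                              max_frame_diff = NULL) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  stopifnot(length(y) == n, radius > 0)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cx <- floor(x / radius)  # numeric: avoids integer overflow at tiny radii
  cy <- floor(y / radius)
  key <- paste(cx, cy)
  if (!is.null(channel)) key <- paste(key, as.integer(channel))
  cells <- split(seq_len(n), key)
  # index cells for neighbour lookup
  cell_env <- new.env(hash = TRUE, parent = emptyenv(), size = length(cells))
  for (k in names(cells)) assign(k, cells[[k]], envir = cell_env)
  r2 <- radius^2
  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  for (k in names(cells)) {
    i_idx <- cells[[k]]
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    kx <- as.numeric(parts[1]); ky <- as.numeric(parts[2])
    suffix <- if (length(parts) > 2L) paste0(" ", parts[3]) else ""
    nb <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      nk <- paste0(kx + offsets$dx[o], " ", ky + offsets$dy[o], suffix)
      if (!identical(nk, k) && exists(nk, envir = cell_env, inherits = FALSE)) {
        nb <- c(nb, get(nk, envir = cell_env))
      }
    }
    cand <- c(i_idx, nb)
    # pairs (i in cell, j in cell-or-neighbours) with i < j to avoid repeats
    for (i in i_idx) {
      j_ok <- cand[cand > i]
      if (!length(j_ok)) next
      d2 <- (x[j_ok] - x[i])^2 + (y[j_ok] - y[i])^2
      hit <- j_ok[d2 <= r2]
      if (!is.null(frame)) {
        hit <- hit[abs(frame[hit] - frame[i]) <= max_frame_diff]
      }
      for (j in hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Assert a scalar is a single finite number; used by config constructors.
check_num <- function(value, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  bad <- if (strict) value <= lower else value < lower
  if (bad) {
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(value)
}
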