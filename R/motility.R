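#' Link per-frame nucleus detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking, a deliberately simple
#' stand-in for dedicated trackers: for each pair of consecutive frames,
#' candidate (track end, detection) pairs within `max_displacement` are
#' processed in ascending distance order; each track end takes its nearest
#' unmatched detection, unmatched detections seed new tracks, and a track
#' with a missed frame terminates. Adequate for well-separated nuclei; not a
#' collision- or gap-aware tracker.
#'
#' @param detections Data frame with `frame`, `x`, `y`, `quality` (and any
#'   extra columns); frames must form a contiguous integer range.
#' @param max_displacement Maximum allowed step length in input units.
#' @return List of trajectories; each is a data frame of `frame`, `x`, `y`,
#'   `quality` ordered by frame, with a `track_id` attribute-free `track_id`
#'   column `L1`, `L2`, ...
#' @export
link_detections <- function(detections, max_displacement) {
  if (is.null(detections) || nrow(detections) == 0L) stop("empty detection table")
  stopifnot(max_displacement > 0)
  frames <- sort(unique(detections$frame))
  if (!all(diff(frames) == 1L)) stop("frames must form a contiguous range")
  tracks <- list()     # each: list(rows = data.frame, open = TRUE/FALSE)
  cur <- detections[detections$frame == frames[1L], , drop = FALSE]
  for (i in seq_len(nrow(cur)))
    tracks[[i]] <- cur[i, c("frame", "x", "y", "quality"), drop = FALSE]
  open <- rep(TRUE, length(tracks))
  for (f in frames[-1L]) {
    det <- detections[detections$frame == f, , drop = FALSE]
    oi <- which(open)
    matched_track <- integer(); matched_det <- integer()
    if (length(oi) && nrow(det)) {
      ends <- do.call(rbind, lapply(tracks[oi], function(tr) tr[nrow(tr), c("x", "y")]))
      dmat <- sqrt(outer(ends$x, det$x, "-")^2 + outer(ends$y, det$y, "-")^2)
      cand <- which(dmat <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_t <- logical(length(oi)); used_d <- logical(nrow(det))
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1L]; di <- cand[r, 2L]
          if (!used_t[ti] && !used_d[di]) {
            used_t[ti] <- TRUE; used_d[di] <- TRUE
            matched_track <- c(matched_track, oi[ti])
            matched_det <- c(matched_det, di)
          }
        }
      }
    }
    for (j in seq_along(matched_track))
      tracks[[matched_track[j]]] <- rbind(
        tracks[[matched_track[j]]],
        det[matched_det[j], c("frame", "x", "y", "quality"), drop = FALSE])
    open[setdiff(oi, matched_track)] <- FALSE   # missed frame terminates
    for (di in setdiff(seq_len(nrow(det)), matched_det)) {
      tracks[[length(tracks) + 1L]] <- det[di, c("frame", "x", "y", "quality"),
                                           drop = FALSE]
      open <- c(open, TRUE)
    }
  }
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    rownames(tr) <- NULL
    tr$track_id <- paste0("L", i)
    tr
  })
}

#' Group a detections table by provided track ids
#'
#' Bypasses linking when the table already carries a `track_id` column
#' (TrackMate-style exports); points are ordered by frame within each track.
#'
#' @param detections Data frame with `track_id`, `frame`, `x`, `y`, `quality`.
#' @return List of trajectory data frames, one per track id.
#' @export
split_tracks <- function(detections) {
  stopifnot("track_id" %in% colnames(detections))
  lapply(split(detections, detections$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (anyDuplicated(tr$frame)) stop("duplicate frame in track ", tr$track_id[1L])
    rownames(tr) <- NULL
    tr
  })
}

#' Filter trajectories on quality, duration, and region of interest
#'
#' Keeps tracks with mean quality strictly above `min_mean_quality`
#' (boundary excluded), at least `min_occurrences` points (boundary
#' included), and — when an ROI is given — every point inside the half-open
#' pixel rectangle `[x0, x0 + width) x [y0, y0 + height)`.
#'
#' @param tracks List of trajectory data frames.
#' @param min_mean_quality Quality threshold (default 100, strict `>`).
#' @param min_occurrences Minimum point count (default 10, inclusive).
#' @param roi `NULL` or numeric `c(x0, y0, width, height)` (default 800x800
#'   when origin is supplied as length-2).
#' @return Filtered list of trajectories.
#' @export
filter_tracks <- function(tracks, min_mean_quality = 100, min_occurrences = 10L,
                          roi = NULL) {
  if (!is.null(roi) && length(roi) == 2L) roi <- c(roi, 800, 800)
  keep <- vapply(tracks, function(tr) {
    if (mean(tr$quality) <= min_mean_quality) return(FALSE)
    if (nrow(tr) < min_occurrences) return(FALSE)
    if (!is.null(roi)) {
      inside <- tr$x >= roi[1L] & tr$x < roi[1L] + roi[3L] &
                tr$y >= roi[2L] & tr$y < roi[2L] + roi[4L]
      if (!all(inside)) return(FALSE)
    }
    TRUE
  }, logical(1L))
  tracks[keep]
}

#' Distance and range metrics for a trajectory
#'
#' `total_distance` is the sum of Euclidean step lengths between consecutive
#' points; `movement_range` is the trajectory diameter, the maximum pairwise
#' Euclidean distance among the track's points (net first-to-last
#' displacement available via `range_type = "net"`). A single-point track has
#' both metrics 0. Always `total_distance >= movement_range`.
#'
#' @param track Trajectory data frame (`frame`, `x`, `y`, `quality`).
#' @param range_type `"diameter"` (default) or `"net"`.
#' @return One-row `data.frame`: `track_id`, `n_points`, `mean_quality`,
#'   `total_distance`, `movement_range`.
#' @export
track_metrics <- function(track, range_type = c("diameter", "net")) {
  range_type <- match.arg(range_type)
  n <- nrow(track)
  id <- if ("track_id" %in% colnames(track)) track$track_id[1L] else NA_character_
  if (n == 1L) {
    dist <- 0; rng <- 0
  } else {
    dx <- diff(track$x); dy <- diff(track$y)
    dist <- sum(sqrt(dx^2 + dy^2))
    rng <- if (range_type == "net") {
      sqrt((track$x[n] - track$x[1L])^2 + (track$y[n] - track$y[1L])^2)
    } else {
      max(stats::dist(cbind(track$x, track$y)))
    }
  }
  data.frame(track_id = id, n_points = n, mean_quality = mean(track$quality),
             total_distance = dist, movement_range = rng,
             stringsAsFactors = FALSE)
}

#' Metrics table for a list of trajectories
#' @param tracks List of trajectory data frames.
#' @inheritParams track_metrics
#' @return Row-bound [track_metrics()] results.
#' @export
track_metrics_table <- function(tracks, range_type = c("diameter", "net")) {
  range_type <- match.arg(range_type)
  do.call(rbind, lapply(tracks, track_metrics, range_type = range_type))
}

#' Normalize trans-well bottom-chamber area to the initial top-chamber area
#'
#' @param bottom_area Numeric time series of bottom-chamber cell area.
#' @param top_area_initial Positive scalar, the initial top-chamber area.
#' @return `bottom_area / top_area_initial`.
#' @export
transwell_normalize <- function(bottom_area, top_area_initial) {
  if (!is.finite(top_area_initial) || top_area_initial <= 0)
    stop("top_area_initial must be > 0")
  bottom_area / top_area_initial
}

#' Normalize a confluency series to its first time point
#'
#' @param series Numeric time series; first value must be positive.
#' @return `series / series[1]`; first element is 1.
#' @export
confluency_normalize <- function(series) {
  if (!length(series) || !is.finite(series[1L]) || series[1L] <= 0)
    stop("first value must be > 0")
  series / series[1L]
}
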