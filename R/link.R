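#' Track-linking parameters
#'
#' Defaults follow the standard CCV settings: subsequent localizations
#' within a 3-pixel radius, a maximum gap of five frames, and a minimum of
#' five observed frames per track.
#'
#' @param link_radius Maximum matching distance, px (> 0).
#' @param max_gap Maximum number of consecutive missing frames that can be
#'   bridged (>= 0).
#' @param min_length Minimum number of observed frames per accepted track
#'   (>= 2). Counts observations, not span.
#' @param gap_radius_scale If `TRUE`, the search radius during gap closing
#'   grows as `link_radius * sqrt(gap)` (diffusive scaling); default
#'   `FALSE`, a fixed radius.
#' @return A `link_params` list.
#' @export
link_params <- function(link_radius = 3, max_gap = 5, min_length = 5,
                        gap_radius_scale = FALSE) {
  if (link_radius <= 0) abort("`link_radius` must be > 0.")
  if (max_gap < 0) abort("`max_gap` must be >= 0.")
  if (min_length < 2) abort("`min_length` must be >= 2.")
  structure(list(link_radius = link_radius, max_gap = as.integer(max_gap),
                 min_length = as.integer(min_length),
                 gap_radius_scale = gap_radius_scale),
            class = "link_params")
}

#' Link per-frame detections into tracks
#'
#' Frame-by-frame greedy nearest-neighbour association: candidate pairs
#' between active tracks and the current frame's unclaimed detections are
#' resolved globally per frame in ascending distance order (ties broken by
#' lower track id, then lower detection row), each within `link_radius` of
#' the track's last observed position. Unmatched detections seed new
#' tracks; unmatched tracks stay active for up to `max_gap` missing frames
#' (a gap of `max_gap` frames is bridged, one more is not), then close.
#' Tracks with fewer than `min_length` observations are discarded. Gap
#' frames remain unobserved; no positions are interpolated.
#'
#' @param detections Tibble/data frame with columns `frame`, `x`, `y` and
#'   optionally `amplitude`, sorted by frame (it is re-sorted defensively,
#'   preserving within-frame row order).
#' @param params A [link_params()].
#' @return Tibble `(track_id, frame, x, y, amplitude)` of class
#'   `vt_tracks`; track ids are 1..n in order of first appearance.
#' @export
link_tracks <- function(detections, params = link_params()) {
  cols <- c("frame", "x", "y")
  missing_cols <- setdiff(cols, names(detections))
  if (length(missing_cols)) {
    abort(paste0("`detections` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  empty <- tibble::tibble(track_id = integer(), frame = integer(),
                          x = numeric(), y = numeric(), amplitude = numeric())
  if (nrow(detections) == 0) {
    return(structure(empty, class = c("vt_tracks", class(empty)),
                     params = params))
  }
  det <- as.data.frame(detections)[, intersect(c(cols, "amplitude"),
                                               names(detections))]
  if (!"amplitude" %in% names(det)) det$amplitude <- NA_real_
  det <- det[order(det$frame), , drop = FALSE]  # stable sort keeps row order

  # active track state (parallel vectors)
  t_id <- integer(0); t_x <- numeric(0); t_y <- numeric(0)
  t_last <- integer(0)           # last observed frame
  t_rows <- list()               # detection row indices per active track
  done_rows <- list()            # closed tracks
  next_id <- 1L

  frames <- sort(unique(det$frame))
  row_of_frame <- split(seq_len(nrow(det)), det$frame)
  for (f in frames) {
    # close tracks whose gap has grown too large
    expire <- t_last < f - params$max_gap - 1L
    if (any(expire)) {
      done_rows <- c(done_rows, t_rows[expire])
      keep <- !expire
      t_id <- t_id[keep]; t_x <- t_x[keep]; t_y <- t_y[keep]
      t_last <- t_last[keep]; t_rows <- t_rows[keep]
    }
    rows <- row_of_frame[[as.character(f)]]
    dx <- det$x[rows]; dy <- det$y[rows]
    n_det <- length(rows)
    det_taken <- rep(FALSE, n_det)
    if (length(t_id) && n_det) {
      # all candidate pairs within radius
      dist2 <- outer(t_x, dx, "-")^2 + outer(t_y, dy, "-")^2
      gap <- f - t_last  # >= 1
      radius <- if (params$gap_radius_scale) {
        params$link_radius * sqrt(pmax(gap, 1))
      } else rep(params$link_radius, length(t_id))
      ok <- dist2 <= matrix(radius^2, length(t_id), n_det)
      idx <- which(ok, arr.ind = TRUE)
      if (nrow(idx)) {
        d <- sqrt(dist2[idx])
        ord <- order(d, t_id[idx[, 1]], idx[, 2])
        trk_taken <- rep(FALSE, length(t_id))
        for (k in ord) {
          ti <- idx[k, 1]; di <- idx[k, 2]
          if (trk_taken[ti] || det_taken[di]) next
          trk_taken[ti] <- TRUE; det_taken[di] <- TRUE
          t_x[ti] <- dx[di]; t_y[ti] <- dy[di]; t_last[ti] <- f
          t_rows[[ti]] <- c(t_rows[[ti]], rows[di])
        }
      }
    }
    # unmatched detections seed new tracks (any frame, even the last)
    for (di in which(!det_taken)) {
      t_id <- c(t_id, next_id); next_id <- next_id + 1L
      t_x <- c(t_x, dx[di]); t_y <- c(t_y, dy[di]); t_last <- c(t_last, f)
      t_rows <- c(t_rows, list(rows[di]))
    }
  }
  done_rows <- c(done_rows, t_rows)
  done_rows <- done_rows[lengths(done_rows) >= params$min_length]
  if (!length(done_rows)) {
    return(structure(empty, class = c("vt_tracks", class(empty)),
                     params = params))
  }
  # canonical track numbering: first frame, then first position (stable
  # under within-frame input row shuffles)
  f1 <- purrr::map_dbl(done_rows, function(r) det$frame[r[1]])
  x1 <- purrr::map_dbl(done_rows, function(r) det$x[r[1]])
  y1 <- purrr::map_dbl(done_rows, function(r) det$y[r[1]])
  done_rows <- done_rows[order(f1, x1, y1)]
  out <- purrr::imap_dfr(done_rows, function(r, i) {
    tibble::tibble(track_id = i, frame = as.integer(det$frame[r]),
                   x = det$x[r], y = det$y[r], amplitude = det$amplitude[r])
  })
  structure(out, class = c("vt_tracks", class(empty)), params = params)
}

#' Flatten tracks to a plain long-format table
#'
#' Accepts either the tidy track table produced by [link_tracks()] or a
#' list of per-track data frames, and returns a plain tibble
#' `(track_id, frame, x, y, amplitude)` that round-trips losslessly
#' through [write_tracks()] / [read_tracks()].
#'
#' @param tracks A `vt_tracks` tibble or a list of data frames each with
#'   `frame`, `x`, `y` (and optional `amplitude`).
#' @return A tibble.
#' @export
track_table <- function(tracks) {
  if (is.data.frame(tracks)) {
    out <- tibble::as_tibble(as.data.frame(tracks))
  } else {
    out <- purrr::imap_dfr(tracks, function(tr, i) {
      tr <- as.data.frame(tr)
      if (!"amplitude" %in% names(tr)) tr$amplitude <- NA_real_
      tibble::tibble(track_id = if ("track_id" %in% names(tr)) tr$track_id else i,
                     frame = as.integer(tr$frame), x = tr$x, y = tr$y,
                     amplitude = tr$amplitude)
    })
  }
  if (nrow(out) == 0 && !"track_id" %in% names(out)) {
    out <- tibble::tibble(track_id = integer(), frame = integer(),
                          x = numeric(), y = numeric(), amplitude = numeric())
  }
  out
}
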