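#' Mean square displacement of a track
#'
#' For a contiguous track of `N` frames the curve is
#' `MSD(tau) = (1/(N - tau)) * sum_t (x[t+tau] - x[t])^2 + (y[t+tau] - y[t])^2`
#' for `tau = 1 .. N-1`. Tracks with gaps are averaged over all pairs of
#' observed frames exactly `tau` apart (the contiguous formula is recovered
#' exactly when there are no gaps); `n_pairs` records how many pairs
#' entered each lag, and lags with zero pairs are omitted.
#'
#' @param track Data frame with columns `frame`, `x`, `y` (one track).
#' @return Tibble `(lag, msd, n_pairs)` of class `msd_curve`, with the
#'   track span attached as attribute `N`.
#' @export
#' @examples
#' tr <- tibble::tibble(frame = 0:3, x = 0:3, y = 0)
#' msd(tr)  # ballistic: MSD(tau) = tau^2
msd <- function(track) {
  track <- as.data.frame(track)
  if (nrow(track) < 2) abort("MSD needs at least 2 observed frames.")
  f <- as.integer(track$frame)
  if (is.unsorted(f, strictly = TRUE)) {
    o <- order(f)
    f <- f[o]; track <- track[o, ]
    if (anyDuplicated(f)) abort("Duplicate frames within one track.")
  }
  x <- track$x; y <- track$y
  span <- f[length(f)] - f[1]
  lags <- seq_len(span)
  pos <- match(seq(f[1], f[length(f)]), f)  # index by frame offset, NA = gap
  vals <- rep(NA_real_, span)
  npairs <- integer(span)
  for (tau in lags) {
    i <- pos[seq_len(span + 1 - tau)]
    j <- pos[seq_len(span + 1 - tau) + tau]
    ok <- !is.na(i) & !is.na(j)
    npairs[tau] <- sum(ok)
    if (npairs[tau] > 0) {
      vals[tau] <- mean((x[j[ok]] - x[i[ok]])^2 + (y[j[ok]] - y[i[ok]])^2)
    }
  }
  keep <- npairs > 0
  out <- tibble::tibble(lag = lags[keep], msd = vals[keep],
                        n_pairs = npairs[keep])
  structure(out, class = c("msd_curve", class(out)), N = span + 1L,
            track_id = if ("track_id" %in% names(track)) track$track_id[1])
}

#' Apparent diffusion constant from an MSD curve
#'
#' Fits an unweighted least-squares line through the first `n_lags` points
#' of the MSD curve and derives `D` from `MSD(t) = 4 D t`, i.e. `D =
#' slope / 4`. The intercept is free by default (it absorbs static
#' localization noise); `intercept = "origin"` forces the literal
#' through-origin relation.
#'
#' @param curve An `msd_curve` from [msd()] (or any table with `lag`,
#'   `msd`).
#' @param n_lags Number of initial lags to fit (default 4, the standard
#'   first-four-time-steps rule).
#' @param intercept `"free"` (default) or `"origin"`.
#' @return A `diffusion_fit` object; `coef()` returns `D`, and
#'   [tidy()]/[glance()] methods are provided. `D` may be negative for
#'   noisy short tracks and is reported as-is.
#' @export
#' @examples
#' curve <- tibble::tibble(lag = 1:4, msd = c(2, 4, 6, 8))
#' fit_diffusion(curve)$D  # 0.5
fit_diffusion <- function(curve, n_lags = 4, intercept = c("free", "origin")) {
  intercept <- match.arg(intercept)
  lags <- seq_len(n_lags)
  have <- match(lags, curve$lag)
  if (anyNA(have)) {
    id <- attr(curve, "track_id")
    abort(sprintf("MSD curve%s has fewer than %d initial lags.",
                  if (is.null(id)) "" else paste0(" (track ", id, ")"), n_lags))
  }
  d <- data.frame(lag = lags, msd = curve$msd[have])
  fit <- if (intercept == "free") lm(msd ~ lag, data = d) else
    lm(msd ~ lag + 0, data = d)
  slope <- coef(fit)[["lag"]]
  structure(list(D = slope / 4, slope = slope,
                 intercept = if (intercept == "free") coef(fit)[["(Intercept)"]] else 0,
                 n_lags = n_lags, fit = fit,
                 track_id = attr(curve, "track_id")),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.5g px^2/frame (slope %.5g over %d lags, intercept %.3g)\n",
              x$D, x$slope, x$n_lags, x$intercept))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(D = object$D)

#' @rdname fit_diffusion
#' @param x,object A `diffusion_fit`.
#' @param ... Unused.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname fit_diffusion
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, slope = x$slope, intercept = x$intercept,
                 n_lags = x$n_lags,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Turning angles along tracks
#'
#' For every triple of consecutive observed frames `(p1, p2, p3)` (no gap
#' inside the triple) the angle between successive displacement vectors
#' `v1 = p2 - p1`, `v2 = p3 - p2` is
#' `alpha = |atan2(det(v1, v2), dot(v1, v2))|` in degrees, in
#' \[0, 180\]: 0 means continuing in the same direction, 180 a full
#' reversal. The two-argument arctangent resolves the quadrant that the
#' plain ratio `det/dot` cannot. Triples containing a zero-length
#' displacement are skipped.
#'
#' @param tracks Data frame with `frame`, `x`, `y` and optionally
#'   `track_id` (angles are computed per track and pooled).
#' @return Tibble `(track_id, angle)`; empty (not an error) when no track
#'   has 3 usable consecutive frames.
#' @export
turning_angles <- function(tracks) {
  tracks <- as.data.frame(tracks)
  if (!"track_id" %in% names(tracks)) tracks$track_id <- 1L
  if (nrow(tracks) == 0) {
    return(tibble::tibble(track_id = integer(), angle = numeric()))
  }
  one <- function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    if (n < 3) return(numeric(0))
    consec1 <- diff(tr$frame) == 1
    ok <- consec1[-length(consec1)] & consec1[-1]   # triple i, i+1, i+2
    i <- which(ok)
    if (!length(i)) return(numeric(0))
    v1x <- tr$x[i + 1] - tr$x[i];     v1y <- tr$y[i + 1] - tr$y[i]
    v2x <- tr$x[i + 2] - tr$x[i + 1]; v2y <- tr$y[i + 2] - tr$y[i + 1]
    nz <- (v1x^2 + v1y^2) > 0 & (v2x^2 + v2y^2) > 0
    det <- v1x[nz] * v2y[nz] - v1y[nz] * v2x[nz]
    dot <- v1x[nz] * v2x[nz] + v1y[nz] * v2y[nz]
    abs(atan2(det, dot)) * 180 / pi
  }
  split_idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  purrr::imap_dfr(split_idx, function(rows, id) {
    a <- one(tracks[rows, , drop = FALSE])
    tibble::tibble(track_id = rep(tracks$track_id[rows[1]], length(a)),
                   angle = a)
  })
}

#' Asymmetry coefficient of pooled turning angles
#'
#' `AC = P(alpha >= reversal_min) / P(alpha <= forward_max)`: the ratio of
#' near-reversal to near-persistent turning-angle frequencies (default
#' bins 180 +/- 30 degrees versus 0-30 degrees). For isotropic Brownian
#' motion the turning angle is uniform on \[0, 180\] and AC is 1; directed
#' motion concentrates angles near 0, driving AC towards 0 — the lower the
#' AC, the more directional the motion.
#'
#' @param angles Numeric vector of angles in degrees, or a tibble from
#'   [turning_angles()].
#' @param reversal_min Lower edge of the reversal bin, degrees.
#' @param forward_max Upper edge of the persistence bin, degrees.
#' @return Scalar AC; `NA` (with a diagnostic message) when the
#'   persistence-bin frequency is zero, never infinity.
#' @export
asymmetry_coefficient <- function(angles, reversal_min = 150,
                                  forward_max = 30) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (!length(angles)) abort("No angles supplied.")
  num <- mean(angles >= reversal_min)
  den <- mean(angles <= forward_max)
  if (den == 0) {
    inform(sprintf(
      "Asymmetry coefficient undefined: no angles <= %g degrees (reversal fraction %.3g).",
      forward_max, num))
    return(NA_real_)
  }
  num / den
}

#' Track length in observed frames
#'
#' The number of frames in which the vesicle is actually observed; gap
#' frames do not count (a track observed in frames 0-4 and 10-14 has
#' length 10, not span 15).
#'
#' @param track Data frame with a `frame` column (one track).
#' @return Integer count of observed frames.
#' @export
track_length <- function(track) {
  nrow(as.data.frame(track))
}

#' Per-track metrics table
#'
#' Computes track length, the apparent diffusion constant (first
#' `n_lags` lags) and MSD values at selected lags for every track.
#'
#' @param tracks A `vt_tracks` tibble (long format with `track_id`).
#' @param n_lags Lags used for the diffusion fit.
#' @param msd_lags Lags at which to report MSD values.
#' @return Tibble with one row per track: `track_id`, `track_length`, `D`,
#'   and `msd_lag<k>` columns (`NA` where a track lacks the lag).
#' @export
track_metrics <- function(tracks, n_lags = 4, msd_lags = 1:4) {
  stopifnot("track_id" %in% names(tracks))
  purrr::map_dfr(split(as.data.frame(tracks), tracks$track_id), function(tr) {
    curve <- msd(tr)
    D <- tryCatch(fit_diffusion(curve, n_lags = n_lags)$D,
                  error = function(e) NA_real_)
    m <- setNames(curve$msd[match(msd_lags, curve$lag)],
                  paste0("msd_lag", msd_lags))
    dplyr::bind_cols(
      tibble::tibble(track_id = tr$track_id[1],
                     track_length = track_length(tr), D = D),
      tibble::as_tibble(as.list(m)))
  })
}

#' Summarize a field of view
#'
#' Pools all tracks of one movie/field: number of tracks, the asymmetry
#' coefficient over all pooled displacements, mean MSD at the requested
#' lags (averaged over tracks possessing those lags), mean track length,
#' and the median apparent diffusion constant. When a [calibration()] is
#' supplied, per-frame/px quantities are additionally reported in s/um
#' units.
#'
#' @param tracks A `vt_tracks` tibble.
#' @param cal Optional [calibration()].
#' @param msd_lags Lags for the mean-MSD columns.
#' @param n_lags Lags for the per-track diffusion fits.
#' @param reversal_min,forward_max AC bin edges, degrees.
#' @return One-row tibble (`field_summary`).
#' @export
summarize_field <- function(tracks, cal = NULL, msd_lags = 1:4, n_lags = 4,
                            reversal_min = 150, forward_max = 30) {
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(n_tracks = 0L, asymmetry_coefficient = NA_real_,
                          mean_track_length = NA_real_, median_D = NA_real_)
    return(structure(out, class = c("field_summary", class(out))))
  }
  tm <- track_metrics(tracks, n_lags = n_lags, msd_lags = msd_lags)
  ang <- turning_angles(tracks)
  ac <- if (nrow(ang)) {
    asymmetry_coefficient(ang, reversal_min, forward_max)
  } else NA_real_
  msd_means <- dplyr::summarise(tm, dplyr::across(
    dplyr::starts_with("msd_lag"), function(v) mean(v, na.rm = TRUE)))
  names(msd_means) <- paste0("mean_", names(msd_means))
  out <- dplyr::bind_cols(
    tibble::tibble(n_tracks = dplyr::n_distinct(tracks$track_id),
                   asymmetry_coefficient = ac,
                   mean_track_length = mean(tm$track_length),
                   median_D = median(tm$D, na.rm = TRUE)),
    msd_means)
  if (!is.null(cal)) {
    px2 <- cal$pixel_size_um^2
    out$median_D_um2_s <- diffusion_to_physical(out$median_D, cal)
    out$mean_track_length_s <- out$mean_track_length * cal$frame_interval_s
    for (k in msd_lags) {
      out[[paste0("mean_msd_lag", k, "_um2")]] <-
        out[[paste0("mean_msd_lag", k)]] * px2
    }
  }
  structure(out, class = c("field_summary", class(out)))
}
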