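#' Spot detection parameters
#'
#' Acceptance gates follow the standard live-cell CCV settings: fitted
#' amplitude at least 5 a.u. above background and fitted sigma between 1
#' and 15 px. Candidates are local maxima of a Gaussian-smoothed copy of
#' the frame; the intensity pre-filter can be evaluated on the smoothed or
#' the raw image (`candidate_gate`).
#'
#' @param intensity_threshold Minimum fitted amplitude above background, a.u.
#' @param sigma_min,sigma_max Accepted range for the fitted PSF sigma, px.
#' @param candidate_smoothing_sigma Gaussian sigma for candidate detection,
#'   px.
#' @param fit_window_halfwidth Half-width of the square fit window, px;
#'   default `ceiling(3 * candidate_smoothing_sigma)`.
#' @param candidate_gate Which image the candidate intensity pre-filter
#'   reads: `"smoothed"` (default), `"raw"`, or `"none"` (fitted-amplitude
#'   gate only).
#' @return A `detection_params` list.
#' @export
detection_params <- function(intensity_threshold = 5,
                             sigma_min = 1, sigma_max = 15,
                             candidate_smoothing_sigma = 2,
                             fit_window_halfwidth = NULL,
                             candidate_gate = c("smoothed", "raw", "none")) {
  candidate_gate <- match.arg(candidate_gate)
  if (intensity_threshold < 0) abort("`intensity_threshold` must be >= 0.")
  if (!(sigma_min > 0 && sigma_min < sigma_max)) {
    abort("Require 0 < sigma_min < sigma_max.")
  }
  if (is.null(fit_window_halfwidth)) {
    fit_window_halfwidth <- ceiling(3 * candidate_smoothing_sigma)
  }
  structure(
    list(intensity_threshold = intensity_threshold,
         sigma_min = sigma_min, sigma_max = sigma_max,
         candidate_smoothing_sigma = candidate_smoothing_sigma,
         fit_window_halfwidth = as.integer(fit_window_halfwidth),
         candidate_gate = candidate_gate),
    class = "detection_params"
  )
}

#' Estimate the background level of a frame
#'
#' The global background is the median pixel intensity: robust to the
#' sparse bright spots that the threshold is meant to separate from it.
#' (The local offset used for photometry is fitted per spot instead.)
#'
#' @param frame A numeric matrix.
#' @return Scalar background estimate, a.u.
#' @export
estimate_background <- function(frame) {
  if (length(frame) == 0) abort("Empty image.")
  if (all(is.na(frame))) abort("All-NA image.")
  median(frame, na.rm = TRUE)
}

# Gaussian-smooth a matrix (EBImage); returns a plain matrix.
smooth_frame <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  img <- EBImage::gblur(EBImage::Image(frame), sigma = sigma)
  matrix(EBImage::imageData(img), nrow(frame), ncol(frame))
}

# 3x3-neighbourhood local maxima (strict against at least one neighbour,
# >= against all); returns matrix of (row, col) 1-based indices.
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  is_max <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    is_max <- is_max & (m >= nb)
  }
  # exclude flat plateaus interior to constant regions: require strictly
  # greater than the minimum neighbour
  strict <- matrix(FALSE, H, W)
  nbmin <- matrix(Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    nbmin <- pmin(nbmin, nb)
  }
  strict <- m > nbmin
  which(is_max & strict, arr.ind = TRUE)
}

# Weighted least-squares fit of one isotropic Gaussian in a window.
# Returns a one-row data frame or NULL on failure.
fit_gaussian_spot <- function(frame, row0, col0, hw, bg, params) {
  # strip any names (e.g. from which(arr.ind = TRUE)) so they cannot leak
  # into the nls parameter names
  row0 <- unname(row0); col0 <- unname(col0)
  H <- nrow(frame); W <- ncol(frame)
  rr <- max(1, row0 - hw):min(H, row0 + hw)
  cc <- max(1, col0 - hw):min(W, col0 + hw)
  if (length(rr) < 5 || length(cc) < 5) return(NULL)
  v <- as.vector(frame[rr, cc])
  px <- rep(cc - 1, each = length(rr))   # x = column, 0-based
  py <- rep(rr - 1, times = length(cc))  # y = row, 0-based
  w <- 1 / pmax(v, 1)
  a0 <- max(frame[row0, col0] - bg, 1)
  start <- list(b = bg, A = a0, x0 = col0 - 1, y0 = row0 - 1,
                s = params$candidate_smoothing_sigma)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-((px - x0)^2 + (py - y0)^2) / (2 * s^2)),
      start = start, weights = w,
      lower = c(b = -Inf, A = 0, x0 = min(px), y0 = min(py), s = 0.3),
      upper = c(b = Inf, A = Inf, x0 = max(px), y0 = max(py),
                s = 3 * params$sigma_max),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  data.frame(x = cf[["x0"]], y = cf[["y0"]], amplitude = cf[["A"]],
             sigma = cf[["s"]], background = cf[["b"]],
             residual = sqrt(mean(stats::residuals(fit)^2)))
}

#' Detect sub-pixel spots in one frame
#'
#' Re-implements weighted least-squares Gaussian PSF fitting: (1) candidate
#' peaks are local maxima of a Gaussian-smoothed copy of the frame passing
#' the intensity pre-filter `background + intensity_threshold`; (2) a 2-D
#' isotropic Gaussian (offset, amplitude, center, sigma) is fitted to the
#' surrounding window by least squares with Poisson-motivated weights
#' `1 / max(pixel, 1)`; (3) fits are accepted when the fitted sigma lies in
#' `[sigma_min, sigma_max]`, the fitted amplitude is at least
#' `intensity_threshold` above the local offset, and the center stays
#' inside the window; (4) duplicate fits closer than 1 px keep the
#' lower-residual one. Non-converging fits are discarded and counted in
#' the `n_failed` attribute, never an error.
#'
#' @param frame Numeric matrix (one frame).
#' @param params A [detection_params()].
#' @return Tibble with columns `x`, `y` (0-based, sub-pixel, x = column),
#'   `amplitude`, `sigma`, `background`, `residual`.
#' @export
detect_spots <- function(frame, params = detection_params()) {
  hw <- params$fit_window_halfwidth
  if (any(dim(frame) < 2 * hw + 1)) {
    abort("Frame smaller than the fit window.")
  }
  empty <- tibble::tibble(x = numeric(), y = numeric(), amplitude = numeric(),
                          sigma = numeric(), background = numeric(),
                          residual = numeric())
  bg <- estimate_background(frame)
  sm <- smooth_frame(frame, params$candidate_smoothing_sigma)
  cand <- local_maxima(sm)
  if (nrow(cand) == 0) return(structure(empty, n_failed = 0L))
  gate_img <- switch(params$candidate_gate,
                     smoothed = sm, raw = frame, none = NULL)
  if (!is.null(gate_img)) {
    keep <- gate_img[cand] >= bg + params$intensity_threshold
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(structure(empty, n_failed = 0L))

  n_failed <- 0L
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- fit_gaussian_spot(frame, cand[i, 1], cand[i, 2], hw, bg, params)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    ok <- f$sigma >= params$sigma_min && f$sigma <= params$sigma_max &&
      f$amplitude >= params$intensity_threshold &&
      abs(f$x - (cand[i, 2] - 1)) <= hw && abs(f$y - (cand[i, 1] - 1)) <= hw &&
      f$x >= 0 && f$x <= ncol(frame) - 1 && f$y >= 0 && f$y <= nrow(frame) - 1
    if (ok) fits[[i]] <- f
  }
  fits <- dplyr::bind_rows(fits)
  if (nrow(fits) == 0) return(structure(empty, n_failed = n_failed))

  # merge duplicates < 1 px apart, keeping the lower-residual fit
  fits <- fits[order(fits$residual), , drop = FALSE]
  keep <- rep(TRUE, nrow(fits))
  for (i in seq_len(nrow(fits))) {
    if (!keep[i]) next
    if (i < nrow(fits)) {
      j <- (i + 1):nrow(fits)
      d2 <- (fits$x[j] - fits$x[i])^2 + (fits$y[j] - fits$y[i])^2
      keep[j][d2 < 1] <- FALSE
    }
  }
  out <- tibble::as_tibble(fits[keep, , drop = FALSE])
  structure(out[order(out$y, out$x), ], n_failed = n_failed)
}

#' Detect spots in every frame of a movie
#'
#' @param stack An `image_stack` (H x W x T array) or a list of matrices.
#' @param params A [detection_params()].
#' @return Tibble of detections with a leading 0-based `frame` column.
#' @export
detect_movie <- function(stack, params = detection_params()) {
  frames <- if (is.list(stack)) stack else {
    purrr::map(seq_len(dim(stack)[3]), function(t) stack_frame(stack, t))
  }
  if (!length(frames)) abort("Movie has no frames.")
  n_failed <- 0L
  res <- purrr::imap(frames, function(f, t) {
    d <- detect_spots(f, params)
    nf <- attr(d, "n_failed")
    n_failed <<- n_failed + if (is.null(nf)) 0L else nf
    dplyr::bind_cols(tibble::tibble(frame = rep(t - 1L, nrow(d))), d)
  })
  structure(dplyr::bind_rows(res), n_failed = n_failed)
}
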