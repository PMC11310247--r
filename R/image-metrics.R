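# offsets and heights of a hemispherical (rolling-ball) structuring element
ball_element <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= radius^2
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]),
       h = sqrt(radius^2 - d2[keep]))
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image
#' with a ball-shaped (hemispherical, non-flat) structuring element of the
#' given radius — the classic rolling-ball formulation — and subtracts it.
#' No pre-smoothing is applied. Structures narrower than the ball are
#' preserved in the output; broad background is removed. Output is clipped
#' at 0.
#'
#' For large radii the image is first reduced by block-minimum
#' downsampling (factor ~ radius/25), the ball rolled on the reduced
#' image, and the background re-expanded by bilinear interpolation — the
#' standard acceleration, exact for constant images and accurate to a few
#' grey levels otherwise.
#'
#' @param image Numeric matrix.
#' @param radius Ball radius in px (>= 1). A radius larger than the image
#'   degenerates to subtracting the image minimum.
#' @param shrink Integer downsampling factor; default `round(radius/25)`
#'   (1 = exact, no shrinking).
#' @return Background-subtracted matrix (same dimensions).
#' @export
rolling_ball_subtract <- function(image, radius = 50, shrink = NULL) {
  if (radius < 1) abort("`radius` must be >= 1.")
  if (2 * radius + 1 > max(dim(image))) {
    bg <- min(image)
  } else {
    s <- if (is.null(shrink)) max(1L, as.integer(round(radius / 25)))
         else max(1L, as.integer(shrink))
    if (s > 1) {
      small <- block_min(image, s)
      bg_small <- ball_open(small, radius / s)
      bg <- upsample_bilinear(bg_small, nrow(image), ncol(image), s)
    } else {
      bg <- ball_open(image, radius)
    }
  }
  pmax(image - bg, 0)
}

ball_open <- function(image, radius) {
  se <- ball_element(radius)
  eroded <- morph_nonflat_cpp(image, se$dr, se$dc, se$h, FALSE)
  morph_nonflat_cpp(eroded, se$dr, se$dc, se$h, TRUE)
}

# Minimum over s x s blocks, padding edges by replication.
block_min <- function(m, s) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / s) * s; W2 <- ceiling(W / s) * s
  if (H2 > H) m <- m[c(seq_len(H), rep(H, H2 - H)), , drop = FALSE]
  if (W2 > W) m <- m[, c(seq_len(W), rep(W, W2 - W)), drop = FALSE]
  out <- matrix(Inf, H2 / s, W2 / s)
  for (dr in seq_len(s)) for (dc in seq_len(s)) {
    out <- pmin(out, m[seq(dr, H2, by = s), seq(dc, W2, by = s)])
  }
  out
}

# Bilinear expansion of a block-sampled matrix back to (H, W); block
# centers sit at (i - 0.5) * s + 0.5 in 1-based full coordinates.
upsample_bilinear <- function(small, H, W, s) {
  centers <- function(n) (seq_len(n) - 0.5) * s + 0.5
  interp_rows <- function(m, n_out) {
    cx <- centers(nrow(m))
    apply(m, 2, function(col) {
      stats::approx(cx, col, xout = seq_len(n_out), rule = 2)$y
    })
  }
  t(interp_rows(t(interp_rows(small, H)), W))
}

# Principal-axis (orthogonal) regression of g on r: g = a + b r.
pa_regression <- function(r, g) {
  sr <- sd(r); sg <- sd(g)
  if (sr == 0 || sg == 0) return(c(a = mean(g), b = 0))
  b <- sign(cor(r, g)) * sg / sr
  if (b == 0) b <- sg / sr
  c(a = mean(g) - b * mean(r), b = b)
}

#' Costes automatic thresholds for two channels
#'
#' Implements the Costes iterative procedure used by ImageJ's
#' Colocalisation Threshold function: the threshold pair lies on the
#' orthogonal regression line of green on red, and is lowered from the
#' maximum until the Pearson correlation of the pixels *below* both
#' thresholds drops to zero or less. Returns the largest such pair.
#'
#' @param red,green Numeric vectors (pixels, already masked).
#' @param n_steps Number of candidate threshold steps.
#' @return Named numeric `c(red = , green = )`.
#' @export
costes_thresholds <- function(red, green, n_steps = 200) {
  ab <- pa_regression(red, green)
  ts <- seq(max(red), min(red), length.out = n_steps)
  for (t_r in ts) {
    t_g <- ab[["a"]] + ab[["b"]] * t_r
    below <- red < t_r & green < t_g
    if (sum(below) >= 20) {
      r_below <- suppressWarnings(cor(red[below], green[below]))
      if (!is.na(r_below) && r_below <= 0) {
        return(c(red = t_r, green = t_g))
      }
    }
  }
  # correlation never reached zero: threshold at the minimum (all pixels in)
  c(red = min(red), green = ab[["a"]] + ab[["b"]] * min(red))
}

#' Manders overlap coefficient
#'
#' `MOC = sum(R * G) / sqrt(sum(R^2) * sum(G^2))` over the analysed pixels:
#' those inside `mask` where at least one channel exceeds its threshold
#' (so spatially disjoint patterns score 0 rather than being dropped).
#' MOC is 1 for identical patterns (Cauchy-Schwarz equality), 0 when the
#' channels never overlap, symmetric in the channels and invariant to
#' scaling either channel by a positive constant.
#'
#' When `thresholds` is `NULL` they are set automatically by the Costes
#' procedure ([costes_thresholds()]) on the masked pixels; pass
#' `c(0, 0)` to use every masked pixel.
#'
#' @param red,green Numeric matrices of identical shape.
#' @param mask Optional logical/0-1 matrix; pixels outside are ignored.
#' @param thresholds Optional numeric pair `(red, green)`.
#' @return One-row tibble `(moc, threshold_red, threshold_green,
#'   n_mask_pixels, n_selected)`; `moc` is `NA` (with a diagnostic) for an
#'   empty mask or an all-zero channel within the mask.
#' @export
manders_overlap <- function(red, green, mask = NULL, thresholds = NULL) {
  if (!all(dim(red) == dim(green))) abort("Channel images differ in shape.")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(red), ncol(red))
  if (!all(dim(mask) == dim(red))) abort("Mask shape differs from channels.")
  mask <- mask > 0
  r <- red[mask]; g <- green[mask]
  na_result <- function(msg, tr = NA_real_, tg = NA_real_) {
    inform(msg)
    tibble::tibble(moc = NA_real_, threshold_red = tr, threshold_green = tg,
                   n_mask_pixels = sum(mask), n_selected = 0L)
  }
  if (!length(r)) return(na_result("MOC undefined: empty mask."))
  if (all(r == 0) || all(g == 0)) {
    return(na_result("MOC undefined: a channel is all zero inside the mask."))
  }
  if (is.null(thresholds)) {
    thr <- costes_thresholds(r, g)
  } else {
    thr <- c(red = thresholds[1], green = thresholds[2])
  }
  sel <- r > thr[["red"]] | g > thr[["green"]]
  if (!any(sel)) {
    return(na_result("MOC undefined: no pixels above threshold.",
                     thr[["red"]], thr[["green"]]))
  }
  rs <- r[sel]; gs <- g[sel]
  moc <- sum(rs * gs) / sqrt(sum(rs^2) * sum(gs^2))
  tibble::tibble(moc = moc, threshold_red = thr[["red"]],
                 threshold_green = thr[["green"]],
                 n_mask_pixels = length(r), n_selected = sum(sel))
}

#' Mean intensity of the thresholded area
#'
#' Thresholds the image to select the area covered by cells and returns
#' the mean intensity of the selected pixels — the standard readout for
#' whole-field live-cell stains such as FerroOrange.
#'
#' @param image Numeric matrix.
#' @param threshold_method `"otsu"` (two-class automatic) or `"fixed"`.
#' @param threshold Threshold value when `threshold_method = "fixed"`.
#'   Pixels strictly above the threshold are selected; with Otsu the
#'   threshold falls between the two classes.
#' @return Scalar mean, or `NA` (with a diagnostic) when no pixel passes.
#' @export
mean_intensity_above_threshold <- function(image,
                                           threshold_method = c("otsu", "fixed"),
                                           threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (!length(image)) abort("Empty image.")
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) abort("`threshold` required for fixed method.")
    threshold
  } else {
    otsu_threshold(image)
  }
  sel <- image > thr
  if (!any(sel)) {
    inform(sprintf("No pixels above threshold %.4g.", thr))
    return(NA_real_)
  }
  mean(image[sel])
}

# Two-class Otsu threshold on an arbitrary-range numeric matrix (EBImage's
# otsu works on [0,1]-scaled data with a fixed level count).
otsu_threshold <- function(image, levels = 256) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (image - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = levels)
  rng[1] + t01 * diff(rng)
}
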