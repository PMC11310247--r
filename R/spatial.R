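#' Maximum-intensity projection of a stack
#'
#' @param stack An `image_stack` array or list of matrices.
#' @return A matrix: per-pixel maximum over frames.
#' @export
max_projection <- function(stack) {
  if (is.list(stack)) return(Reduce(pmax, stack))
  apply(unclass(stack), c(1, 2), max)
}

#' Prepare a cell mask image from a projection
#'
#' The mask recipe applied to a maximum-intensity projection:
#' rolling-ball background subtraction (radius 50), linear rescale of the
#' intensity window \[`min_int`, `max_int`\] to \[0, 1\] with clipping,
#' then Gaussian blur with sigma 5. The result is a smooth blob image on
#' which [segment_cells()] runs Otsu thresholding.
#'
#' @param projection Numeric matrix (maximum projection).
#' @param ball_radius Rolling-ball radius, px.
#' @param min_int,max_int Intensity window bounds, a.u.
#' @param blur_sigma Gaussian blur sigma, px.
#' @return Numeric matrix in \[0, 1\].
#' @export
make_cell_mask <- function(projection, ball_radius = 50,
                           min_int = 3, max_int = 30, blur_sigma = 5) {
  rb <- rolling_ball_subtract(projection, ball_radius)
  clipped <- (pmin(pmax(rb, min_int), max_int) - min_int) / (max_int - min_int)
  smooth_frame(clipped, blur_sigma)
}

#' Segment cells by Otsu thresholding
#'
#' Two-class Otsu thresholding followed by connected-component labeling.
#' Objects touching any image border are flagged `on_border` and are
#' excluded from downstream statistics. Centroids use the 0-based
#' pixel-center convention (x = column).
#'
#' @param mask_image Numeric matrix (e.g. from [make_cell_mask()]).
#' @param min_area Discard components smaller than this many px^2.
#' @return Tibble `(label, area, x, y, on_border)` of class `cell_set`,
#'   with the integer label image attached as attribute `label_image`.
#' @export
segment_cells <- function(mask_image, min_area = 25) {
  H <- nrow(mask_image); W <- ncol(mask_image)
  empty <- tibble::tibble(label = integer(), area = numeric(),
                          x = numeric(), y = numeric(), on_border = logical())
  if (diff(range(mask_image)) == 0) {
    return(structure(empty, class = c("cell_set", class(empty)),
                     label_image = matrix(0L, H, W)))
  }
  thr <- otsu_threshold(mask_image)
  bin <- mask_image > thr
  labels <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- matrix(as.integer(EBImage::imageData(labels)), H, W)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- purrr::map_dfr(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_area) return(NULL)
    tibble::tibble(
      label = id, area = nrow(px),
      x = mean(px[, 2] - 1), y = mean(px[, 1] - 1),
      on_border = any(px[, 1] == 1 | px[, 1] == H |
                        px[, 2] == 1 | px[, 2] == W))
  })
  if (is.null(rows) || nrow(rows) == 0) rows <- empty
  # zero out labels removed by the area filter
  lab[!(lab %in% rows$label)] <- 0L
  structure(rows, class = c("cell_set", class(empty)), label_image = lab)
}

#' Enhance speckles (white top-hat)
#'
#' White top-hat transform with a disk structuring element of diameter
#' `feature_size`: retains structures smaller than the element (the
#' vesicle speckles) and suppresses larger-scale background such as the
#' cell body.
#'
#' @param image Numeric matrix.
#' @param feature_size Disk diameter, px (>= 1; rounded up to odd).
#' @return Numeric matrix.
#' @export
enhance_speckles <- function(image, feature_size = 20) {
  if (feature_size < 1) abort("`feature_size` must be >= 1.")
  size <- as.integer(feature_size)
  if (size %% 2 == 0) size <- size + 1L
  if (diff(range(image)) == 0) return(matrix(0, nrow(image), ncol(image)))
  brush <- EBImage::makeBrush(size, shape = "disc")
  rng <- range(image)
  scaled <- (image - rng[1]) / diff(rng)
  th <- EBImage::whiteTopHat(EBImage::Image(scaled), brush)
  matrix(EBImage::imageData(th), nrow(image), ncol(image)) * diff(rng)
}

#' Identify vesicle points inside segmented cells
#'
#' The speckle-enhanced image is masked to the retained (non-border)
#' cells, lightly smoothed (`smoothing_sigma`, which narrows the top-hat
#' noise floor before thresholding), thresholded by the background method
#' (threshold = `bg_multiplier` times the mode of the masked
#' nonzero-intensity histogram), and labeled. Clumped objects are split at
#' intensity local maxima by watershed. Objects smaller than `min_area`
#' px are discarded as noise speckle. Each surviving object is shrunk to
#' its intensity-weighted centroid and assigned the parent cell whose mask
#' contains it; points falling outside every retained cell are dropped.
#'
#' @param enhanced Numeric matrix from [enhance_speckles()].
#' @param cells A `cell_set` from [segment_cells()].
#' @param bg_multiplier Multiplier on the histogram mode.
#' @param smoothing_sigma Gaussian sigma (px) applied before thresholding;
#'   0 disables.
#' @param min_area Minimum object size in px.
#' @param ws_tolerance Watershed intensity tolerance for declumping.
#' @param n_breaks Histogram bin count for the mode estimate.
#' @return Tibble `(parent, x, y)`; empty when no vesicles are found.
#' @export
identify_vesicles <- function(enhanced, cells, bg_multiplier = 2,
                              smoothing_sigma = 1.5, min_area = 5,
                              ws_tolerance = 1, n_breaks = 256) {
  lab <- attr(cells, "label_image")
  retained <- cells$label[!cells$on_border]
  empty <- tibble::tibble(parent = integer(), x = numeric(), y = numeric())
  if (!length(retained)) return(empty)
  cellmask <- matrix(lab %in% retained, nrow(lab), ncol(lab))
  masked <- enhanced * cellmask
  if (smoothing_sigma > 0) {
    masked <- smooth_frame(masked, smoothing_sigma) * cellmask
  }
  nz <- masked[masked > 0]
  if (!length(nz)) return(empty)
  hh <- graphics::hist(nz, breaks = n_breaks, plot = FALSE)
  mode_val <- hh$mids[which.max(hh$counts)]
  thr <- bg_multiplier * mode_val
  bin <- masked > thr
  if (!any(bin)) return(empty)
  ws <- EBImage::watershed(EBImage::Image(masked * bin),
                           tolerance = ws_tolerance, ext = 1)
  wlab <- matrix(as.integer(EBImage::imageData(ws)), nrow(lab), ncol(lab))
  ids <- setdiff(sort(unique(as.vector(wlab))), 0L)
  pts <- purrr::map_dfr(ids, function(id) {
    px <- which(wlab == id, arr.ind = TRUE)
    if (nrow(px) < min_area) return(NULL)
    w <- masked[px]
    x <- sum((px[, 2] - 1) * w) / sum(w)
    y <- sum((px[, 1] - 1) * w) / sum(w)
    parent <- lab[round(y) + 1, round(x) + 1]
    tibble::tibble(parent = as.integer(parent), x = x, y = y)
  })
  if (is.null(pts) || nrow(pts) == 0) return(empty)
  pts[pts$parent %in% retained, , drop = FALSE]
}

#' Distance of each vesicle to its parent-cell centroid
#'
#' @param vesicles Tibble `(parent, x, y)` from [identify_vesicles()].
#' @param cells A `cell_set`.
#' @return `vesicles` with an added `distance` column (px).
#' @export
distance_to_centroid <- function(vesicles, cells) {
  ctr <- tibble::tibble(parent = cells$label, cx = cells$x, cy = cells$y)
  out <- dplyr::left_join(tibble::as_tibble(vesicles), ctr, by = "parent")
  out$distance <- sqrt((out$x - out$cx)^2 + (out$y - out$cy)^2)
  dplyr::select(out, -"cx", -"cy")
}

#' Per-cell distance summary
#'
#' @param vesicles Output of [distance_to_centroid()].
#' @param cells A `cell_set`.
#' @return Tibble `(label, area, n_vesicles, mean_distance)`; cells with
#'   no children get `NA` mean distance.
#' @export
cell_distances <- function(vesicles, cells) {
  per <- dplyr::summarise(dplyr::group_by(vesicles, .data$parent),
                          n_vesicles = dplyr::n(),
                          mean_distance = mean(.data$distance),
                          .groups = "drop")
  out <- dplyr::left_join(
    tibble::tibble(label = cells$label, area = cells$area,
                   on_border = cells$on_border),
    dplyr::rename(per, label = "parent"), by = "label")
  out$n_vesicles[is.na(out$n_vesicles)] <- 0L
  out[!out$on_border, setdiff(names(out), "on_border"), drop = FALSE]
}

#' Area-corrected distance to centroid
#'
#' Cells grown under different conditions differ in size, so the raw mean
#' child-centroid distance confounds radial position with cell area. Two
#' corrections are offered. The default `"dimensionless"` mode reports
#' `mean_distance / sqrt(area)`, a scale-free radial position index that
#' is invariant under uniform rescaling of the scene. The
#' `"paper_literal"` mode computes the normalization factor `alpha =
#' sqrt(area) / mean_distance` and multiplies the mean distance by it —
#' which algebraically collapses to `sqrt(area)`, erasing the radial
#' information; it is provided for comparability and always emits a
#' warning.
#'
#' @param cell_summary Tibble from [cell_distances()] (needs
#'   `mean_distance`, `area`).
#' @param mode `"dimensionless"` (default) or `"paper_literal"`.
#' @return `cell_summary` with added `corrected_distance` (and `alpha` in
#'   literal mode). Zero mean distance yields `NA`.
#' @export
corrected_distance <- function(cell_summary,
                               mode = c("dimensionless", "paper_literal")) {
  mode <- match.arg(mode)
  md <- cell_summary$mean_distance
  md[!is.na(md) & md == 0] <- NA_real_
  if (mode == "dimensionless") {
    cell_summary$corrected_distance <- md / sqrt(cell_summary$area)
  } else {
    warn(paste("paper_literal mode: mean_distance * alpha collapses to",
               "sqrt(area); the radial information is lost."))
    cell_summary$alpha <- sqrt(cell_summary$area) / md
    cell_summary$corrected_distance <- md * cell_summary$alpha
  }
  cell_summary
}

#' Radial fraction-at-distance profile
#'
#' Bins each cell's vesicle points into `n_bins` concentric equal-width
#' annuli reaching from the centroid to the cell's maximum
#' centroid-to-boundary distance; reports the fraction of points per bin
#' (fractions sum to 1). Distances beyond the outermost edge (possible
#' for centroids of objects overhanging the mask) are counted in the last
#' bin.
#'
#' @param vesicles Output of [distance_to_centroid()].
#' @param cells A `cell_set`.
#' @param n_bins Number of annuli (default 4).
#' @return Tibble `(label, bin, r_inner, r_outer, fraction)` of class
#'   `radial_profile`; only cells with at least one child appear.
#' @export
fraction_at_distance <- function(vesicles, cells, n_bins = 4) {
  lab <- attr(cells, "label_image")
  out <- purrr::map_dfr(which(!cells$on_border), function(i) {
    id <- cells$label[i]
    ch <- vesicles[vesicles$parent == id, , drop = FALSE]
    if (nrow(ch) == 0) return(NULL)
    px <- which(lab == id, arr.ind = TRUE)
    rmax <- sqrt(max((px[, 2] - 1 - cells$x[i])^2 +
                       (px[, 1] - 1 - cells$y[i])^2))
    edges <- seq(0, rmax, length.out = n_bins + 1)
    bin <- pmin(findInterval(ch$distance, edges, rightmost.closed = TRUE),
                n_bins)
    bin <- pmax(bin, 1L)
    counts <- tabulate(bin, nbins = n_bins)
    tibble::tibble(label = id, bin = seq_len(n_bins),
                   r_inner = edges[-(n_bins + 1)], r_outer = edges[-1],
                   fraction = counts / sum(counts))
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(label = integer(), bin = integer(),
                          r_inner = numeric(), r_outer = numeric(),
                          fraction = numeric())
  }
  structure(out, class = c("radial_profile", class(out)))
}

#' Run the full radial-distribution pipeline on one scene
#'
#' Convenience wrapper: mask preparation, cell segmentation, speckle
#' enhancement, vesicle identification, distances and radial profile.
#'
#' @param cell_image Projection image for the cell channel.
#' @param vesicle_image Projection for the vesicle channel (may be the
#'   same image, as with a single-stain acquisition).
#' @param n_bins Annuli for the radial profile.
#' @param mode Correction mode passed to [corrected_distance()].
#' @param ball_radius,blur_sigma Mask-preparation scales, px
#'   ([make_cell_mask()]).
#' @param feature_size Speckle-enhancement scale, px
#'   ([enhance_speckles()]). These three are length scales: when analysing
#'   a uniformly rescaled scene they should be rescaled with it.
#' @param ... Passed to [identify_vesicles()].
#' @return List: `cells`, `vesicles` (with distances), `per_cell`
#'   (corrected distances), `profile`.
#' @export
radial_pipeline <- function(cell_image, vesicle_image = cell_image,
                            n_bins = 4, mode = "dimensionless",
                            ball_radius = 50, blur_sigma = 5,
                            feature_size = 20, ...) {
  maskimg <- make_cell_mask(cell_image, ball_radius = ball_radius,
                            blur_sigma = blur_sigma)
  cells <- segment_cells(maskimg)
  enhanced <- enhance_speckles(vesicle_image, feature_size = feature_size)
  vesicles <- identify_vesicles(enhanced, cells, ...)
  vesicles <- distance_to_centroid(vesicles, cells)
  per_cell <- corrected_distance(cell_distances(vesicles, cells), mode = mode)
  profile <- fraction_at_distance(vesicles, cells, n_bins = n_bins)
  list(cells = cells, vesicles = vesicles, per_cell = per_cell,
       profile = profile)
}
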