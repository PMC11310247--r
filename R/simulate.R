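#' Simulate ground-truth particle trajectories
#'
#' Draws `n_tracks` trajectories over `n_frames` frames under a
#' [motion_model()]. Positions are in the 0-based pixel-center convention
#' (x = column, y = row). Time is measured in frames; physical units enter
#' only through the optics calibration at render/analysis time.
#'
#' Disappearance (`p_off`) is permanent once drawn; blinking (`p_blink`)
#' produces missing frames with later reappearance. A particle that leaves
#' the field of view keeps its true position but is flagged `in_field =
#' FALSE`, so recovery statistics can be restricted to renderable spots.
#'
#' @param model A [motion_model()].
#' @param n_tracks Number of particles (>= 1).
#' @param n_frames Number of frames (>= 2).
#' @param shape Image shape `(height, width)` in px; bounds for the
#'   in-field flag and for drawing start positions.
#' @param seed Optional integer seed.
#' @param margin Start positions are drawn uniformly at least this many px
#'   from the image edge.
#' @param min_start_separation If > 0, start positions are re-drawn until
#'   all pairs are at least this far apart (a well-separated field, the
#'   regime in which track identities are unambiguous).
#' @return A tibble with columns `particle_id`, `frame` (0-based), `x`,
#'   `y`, `visible`, `in_field`, of class `vt_truth`.
#' @export
#' @examples
#' tr <- simulate_tracks(motion_model("brownian", D = 0.05), 3, 20, seed = 1)
#' head(tr)
simulate_tracks <- function(model, n_tracks, n_frames, shape = c(128L, 128L),
                            seed = NULL, margin = 6,
                            min_start_separation = 0) {
  stopifnot(inherits(model, "motion_model"))
  if (n_tracks < 1) abort("`n_tracks` must be >= 1.")
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]
  starts <- if (min_start_separation > 0) {
    place_points(n_tracks, c(H, W), min_start_separation, margin)
  } else NULL
  step_sd <- if (model$kind == "brownian" || model$kind == "directed") {
    sqrt(2 * model$D)
  } else 0
  drift <- if (model$kind == "directed") {
    model$v * c(cos(model$heading * pi / 180), sin(model$heading * pi / 180))
  } else c(0, 0)

  one <- function(id) {
    if (is.null(starts)) {
      x0 <- runif(1, margin, W - 1 - margin)
      y0 <- runif(1, margin, H - 1 - margin)
    } else {
      x0 <- starts$x[id]; y0 <- starts$y[id]
    }
    dx <- rnorm(n_frames - 1, drift[1], step_sd)
    dy <- rnorm(n_frames - 1, drift[2], step_sd)
    x <- x0 + cumsum(c(0, dx))
    y <- y0 + cumsum(c(0, dy))
    visible <- rep(TRUE, n_frames)
    if (model$p_off > 0) {
      off <- which(runif(n_frames - 1) < model$p_off)
      if (length(off)) visible[(off[1] + 1):n_frames] <- FALSE
    }
    if (model$p_blink > 0) {
      t <- 2L
      while (t <= n_frames) {
        if (visible[t] && runif(1) < model$p_blink) {
          len <- if (model$blink_multi) rgeom(1, prob = 1 - model$p_blink) + 1L else 1L
          gap <- t:min(n_frames, t + len - 1L)
          visible[gap] <- FALSE
          t <- t + len
        }
        t <- t + 1L
      }
    }
    tibble::tibble(
      particle_id = id, frame = 0:(n_frames - 1), x = x, y = y,
      visible = visible,
      in_field = x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    )
  }
  out <- purrr::map_dfr(seq_len(n_tracks), one)
  structure(out, class = c("vt_truth", class(tibble::tibble()))
            , shape = as.integer(c(H, W)), n_frames = as.integer(n_frames))
}

# Additive render of isotropic Gaussian spots at pixel centers.
# spots: data frame with x, y (0-based); returns H x W matrix (no noise).
render_spots <- function(spots, H, W, psf_sigma, amplitude, background) {
  img <- matrix(background, H, W)
  if (nrow(spots) == 0) return(img)
  r <- ceiling(5 * psf_sigma)
  for (i in seq_len(nrow(spots))) {
    x0 <- spots$x[i]; y0 <- spots$y[i]
    c0 <- max(0, floor(x0) - r); c1 <- min(W - 1, ceiling(x0) + r)
    r0 <- max(0, floor(y0) - r); r1 <- min(H - 1, ceiling(y0) + r)
    if (c0 > c1 || r0 > r1) next  # spot entirely outside the field
    cc <- c0:c1; rr <- r0:r1
    gx <- exp(-(cc - x0)^2 / (2 * psf_sigma^2))
    gy <- exp(-(rr - y0)^2 / (2 * psf_sigma^2))
    img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + amplitude * outer(gy, gx)
  }
  img
}

apply_noise <- function(img, optics) {
  if (isTRUE(optics$poisson_noise)) {
    img <- matrix(rpois(length(img), lambda = pmax(img, 0)),
                  nrow(img), ncol(img))
  }
  if (optics$read_noise_sigma > 0) {
    img <- img + matrix(rnorm(length(img), 0, optics$read_noise_sigma),
                        nrow(img), ncol(img))
  }
  img
}

#' Render a movie from ground-truth trajectories
#'
#' Each visible, in-field particle is drawn as a 2-D isotropic Gaussian of
#' peak height `optics$amplitude` and width `optics$psf_sigma` on a constant
#' background, evaluated at pixel centers. Poisson noise is applied to the
#' expected counts when enabled, followed by additive Gaussian read noise.
#' Out-of-field particles are clipped from rendering but remain in the
#' truth table.
#'
#' @param truth A `vt_truth` tibble from [simulate_tracks()] (or any table
#'   with `frame`, `x`, `y` and optional `visible`/`in_field` columns).
#' @param optics An [optics_model()].
#' @param seed Optional integer seed for the noise realization.
#' @return A numeric array of dim `(H, W, n_frames)` with class
#'   `image_stack`; calibration is attached as attributes.
#' @export
render_movie <- function(truth, optics, seed = NULL) {
  stopifnot(inherits(optics, "optics_model"))
  if (!is.null(seed)) set.seed(seed)
  H <- optics$image_shape[1]; W <- optics$image_shape[2]
  n_frames <- if (!is.null(attr(truth, "n_frames"))) attr(truth, "n_frames")
              else if (nrow(truth)) max(truth$frame) + 1L else 1L
  vis <- if ("visible" %in% names(truth)) truth$visible else TRUE
  inf <- if ("in_field" %in% names(truth)) truth$in_field else TRUE
  shown <- truth[vis & inf, , drop = FALSE]
  arr <- array(0, dim = c(H, W, n_frames))
  for (t in seq_len(n_frames) - 1L) {
    spots <- shown[shown$frame == t, , drop = FALSE]
    img <- render_spots(spots, H, W, optics$psf_sigma,
                        optics$amplitude, optics$background)
    arr[, , t + 1L] <- apply_noise(img, optics)
  }
  image_stack(arr, optics)
}

#' Construct an image stack
#'
#' @param data Numeric array `(H, W, T)` or matrix (one frame).
#' @param optics Optional [optics_model()] whose calibration to attach.
#' @return `image_stack` array.
#' @export
image_stack <- function(data, optics = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  structure(data, class = "image_stack",
            pixel_size_um = if (!is.null(optics)) optics$pixel_size_um,
            frame_interval_s = if (!is.null(optics)) optics$frame_interval_s)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

# Get frame t (1-based index) as a plain matrix.
stack_frame <- function(stack, t) {
  unclass(stack)[, , t, drop = TRUE]
}

# Rejection-sample n points with pairwise separation >= min_sep,
# at least `margin` px from the border.
place_points <- function(n, shape, min_sep, margin) {
  H <- shape[1]; W <- shape[2]
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, margin, W - 1 - margin)
    y <- runif(1, margin, H - 1 - margin)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 20000L * n) {
      abort("Could not place points with the requested separation; reduce `n_spots` or `min_sep`.")
    }
  }
  tibble::tibble(x = xs, y = ys)
}

#' Simulate a two-channel colocalization scene
#'
#' Places `n_spots` spots per channel, of which `round(overlap_fraction *
#' n_spots)` positions are shared between the channels; the remainder are
#' placed independently. All spot centers (shared and channel-specific) are
#' kept at least `4 * psf_sigma` apart so non-shared spots do not overlap by
#' accident.
#'
#' @param n_spots Spots per channel (>= 1).
#' @param overlap_fraction Fraction of shared positions, in \[0, 1\].
#' @param optics An [optics_model()].
#' @param seed Optional integer seed.
#' @return A list with elements `red` and `green` (H x W matrices) and
#'   `truth`, a tibble of spot positions with a `channel` column
#'   (`"both"`, `"red"`, `"green"`).
#' @export
make_coloc_pair <- function(n_spots, overlap_fraction, optics = optics_model(),
                            seed = NULL) {
  if (n_spots < 1) abort("`n_spots` must be >= 1.")
  if (!is.finite(overlap_fraction) || overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  H <- optics$image_shape[1]; W <- optics$image_shape[2]
  n_shared <- round(overlap_fraction * n_spots)
  n_only <- n_spots - n_shared
  sep <- 4 * optics$psf_sigma
  pts <- place_points(n_shared + 2 * n_only, c(H, W), sep,
                      margin = ceiling(4 * optics$psf_sigma))
  channel <- c(rep("both", n_shared), rep("red", n_only), rep("green", n_only))
  truth <- tibble::tibble(x = pts$x, y = pts$y, channel = channel,
                          shared = channel == "both")
  red_spots <- truth[truth$channel %in% c("both", "red"), ]
  green_spots <- truth[truth$channel %in% c("both", "green"), ]
  red <- apply_noise(render_spots(red_spots, H, W, optics$psf_sigma,
                                  optics$amplitude, optics$background), optics)
  green <- apply_noise(render_spots(green_spots, H, W, optics$psf_sigma,
                                    optics$amplitude, optics$background), optics)
  list(red = red, green = green, truth = truth)
}

#' Simulate a cell scene with radially placed vesicles
#'
#' Renders a cell channel (filled disks, segmentable by thresholding) and a
#' vesicle channel (Gaussian spots) whose true distances to the cell
#' centroid are known. Vesicle radii follow `radial_law`: `"uniform_disk"`
#' draws positions uniformly over the cell disk (radius `R * sqrt(U)`, so
#' the mean distance tends to `2R/3`), `"ring"` places every vesicle at
#' `ring_radius`.
#'
#' @param cell_radius Cell disk radius, px.
#' @param n_vesicles Number of vesicles per cell (0 allowed: empty cell).
#' @param radial_law `"uniform_disk"` or `"ring"`.
#' @param optics An [optics_model()]; `image_shape` sets the scene size.
#' @param seed Optional integer seed.
#' @param ring_radius Ring radius, px; required for `"ring"` and must be
#'   smaller than `cell_radius`.
#' @param centers Optional matrix/data frame of cell centers (x, y); default
#'   a single cell at the image center.
#' @param cell_amplitude Cell-channel plateau height above background, a.u.
#' @return A list: `cell` and `vesicle` images (H x W matrices), `truth`
#'   (tibble: `cell`, `x`, `y`, `r_true`), `cells` (tibble: `cell`, `cx`,
#'   `cy`, `radius`, `border_touching`).
#' @export
make_cell_scene <- function(cell_radius = 60, n_vesicles = 50,
                            radial_law = c("uniform_disk", "ring"),
                            optics = optics_model(image_shape = c(192L, 192L)),
                            seed = NULL, ring_radius = NULL, centers = NULL,
                            cell_amplitude = 40) {
  radial_law <- match.arg(radial_law)
  if (radial_law == "ring") {
    if (is.null(ring_radius)) abort("`ring_radius` is required for radial_law = 'ring'.")
    if (ring_radius >= cell_radius) abort("`ring_radius` must be < `cell_radius`.")
  }
  if (!is.null(seed)) set.seed(seed)
  H <- optics$image_shape[1]; W <- optics$image_shape[2]
  if (is.null(centers)) {
    centers <- data.frame(x = (W - 1) / 2, y = (H - 1) / 2)
  } else {
    centers <- as.data.frame(centers)
    names(centers) <- c("x", "y")
  }
  n_cells <- nrow(centers)

  cells <- tibble::tibble(
    cell = seq_len(n_cells),
    cx = centers$x, cy = centers$y, radius = cell_radius,
    border_touching = centers$x - cell_radius < 0 |
      centers$x + cell_radius > W - 1 |
      centers$y - cell_radius < 0 | centers$y + cell_radius > H - 1
  )

  # vesicle placement is drawn before any pixel noise so that scenes with
  # the same seed share their geometry regardless of image size
  draw_r <- function(n) switch(radial_law,
    uniform_disk = cell_radius * sqrt(runif(n)),
    ring = rep(ring_radius, n))
  truth <- purrr::map_dfr(seq_len(n_cells), function(i) {
    if (n_vesicles == 0) return(tibble::tibble(
      cell = integer(), x = numeric(), y = numeric(), r_true = numeric()))
    r <- draw_r(n_vesicles)
    th <- runif(n_vesicles, 0, 2 * pi)
    tibble::tibble(cell = i,
                   x = cells$cx[i] + r * cos(th),
                   y = cells$cy[i] + r * sin(th),
                   r_true = r)
  })

  # cell channel: plateau disks
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  cell_img <- matrix(optics$background, H, W)
  for (i in seq_len(n_cells)) {
    inside <- (xs - cells$cx[i])^2 + (ys - cells$cy[i])^2 <= cell_radius^2
    cell_img[inside] <- cell_img[inside] + cell_amplitude
  }
  cell_img <- apply_noise(cell_img, optics)

  ves_img <- render_spots(truth, H, W, optics$psf_sigma,
                          optics$amplitude, optics$background)
  ves_img <- apply_noise(ves_img, optics)

  list(cell = cell_img, vesicle = ves_img, truth = truth, cells = cells)
}
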