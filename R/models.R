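#' Motion model for simulated particles
#'
#' Describes how a simulated vesicle moves from frame to frame. Brownian
#' steps are isotropic Gaussian with per-axis variance `2 * D` per frame so
#' that the ensemble mean square displacement is `4 * D * tau`; directed
#' motion adds a constant drift of `v` px/frame along `heading`. Particles
#' can disappear permanently (photobleach/uncoating, `p_off`) or blink off
#' transiently (`p_blink`).
#'
#' @param kind One of `"stationary"`, `"brownian"`, `"directed"`.
#' @param D Diffusion constant, px^2/frame. Must be finite and >= 0.
#' @param v Drift speed, px/frame (used by `"directed"`). Finite, >= 0.
#' @param heading Drift direction in degrees (0 = +x).
#' @param p_off Per-frame probability of permanent disappearance, in \[0, 1\].
#' @param p_blink Per-frame probability of entering a transient dark gap,
#'   in \[0, 1\].
#' @param blink_multi If `TRUE`, gap lengths are drawn geometrically with
#'   success probability `1 - p_blink` (so larger `p_blink` gives longer
#'   gaps); if `FALSE` (default) every gap lasts a single frame.
#' @return A `motion_model` list.
#' @export
#' @examples
#' motion_model("brownian", D = 0.05)
#' motion_model("directed", v = 1, heading = 90)
motion_model <- function(kind = c("brownian", "stationary", "directed"),
                         D = 0, v = 0, heading = 0,
                         p_off = 0, p_blink = 0, blink_multi = FALSE) {
  kind <- match.arg(kind)
  if (!is.finite(D) || D < 0) abort("`D` must be finite and >= 0.")
  if (!is.finite(v) || v < 0) abort("`v` must be finite and >= 0.")
  for (p in c(p_off = p_off, p_blink = p_blink)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      abort("`p_off` and `p_blink` must lie in [0, 1].")
    }
  }
  structure(
    list(kind = kind, D = D, v = v, heading = heading,
         p_off = p_off, p_blink = p_blink, blink_multi = blink_multi),
    class = "motion_model"
  )
}

#' Optics and camera model for rendering
#'
#' Collects the parameters that turn true particle positions into pixel
#' values: an isotropic Gaussian point spread function of width `psf_sigma`
#' evaluated at pixel centers, a constant `background` offset, shot noise
#' (Poisson on the expected counts) and additive Gaussian read noise.
#' Physical calibration (`pixel_size_um`, `frame_interval_s`) is carried
#' along so downstream metrics can be converted out of px/frame units; the
#' default frame interval is 1 s, matching typical 1 frame/s live-cell
#' acquisition of clathrin-coated vesicles.
#'
#' @param psf_sigma PSF standard deviation in px (> 0).
#' @param amplitude Peak height of a rendered spot above background, a.u.
#' @param background Constant background level, a.u. (>= 0).
#' @param read_noise_sigma Std. dev. of additive Gaussian read noise, a.u.
#' @param poisson_noise Apply Poisson noise to expected counts?
#' @param image_shape Integer `(height, width)` of rendered frames, px.
#' @param pixel_size_um Physical pixel size, micrometres per px.
#' @param frame_interval_s Time between frames, seconds.
#' @return An `optics_model` list.
#' @export
optics_model <- function(psf_sigma = 2, amplitude = 100, background = 10,
                         read_noise_sigma = 0, poisson_noise = TRUE,
                         image_shape = c(128L, 128L),
                         pixel_size_um = 0.16, frame_interval_s = 1) {
  if (!is.finite(psf_sigma) || psf_sigma <= 0) abort("`psf_sigma` must be > 0.")
  if (!is.finite(amplitude) || amplitude <= 0) abort("`amplitude` must be > 0.")
  if (!is.finite(background) || background < 0) abort("`background` must be >= 0.")
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    abort("`image_shape` must be (height, width) with both >= 8 px.")
  }
  structure(
    list(psf_sigma = psf_sigma, amplitude = amplitude, background = background,
         read_noise_sigma = read_noise_sigma, poisson_noise = poisson_noise,
         image_shape = as.integer(image_shape),
         pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s),
    class = "optics_model"
  )
}

#' Physical calibration of a movie
#'
#' @param pixel_size_um Micrometres per pixel.
#' @param frame_interval_s Seconds per frame.
#' @return A `calibration` list.
#' @export
calibration <- function(pixel_size_um = 0.16, frame_interval_s = 1) {
  if (pixel_size_um <= 0 || frame_interval_s <= 0) {
    abort("Calibration values must be positive.")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "calibration")
}

#' Convert an apparent diffusion constant to physical units
#'
#' `D[um^2/s] = D[px^2/frame] * pixel_size_um^2 / frame_interval_s`.
#'
#' @param D_px2_frame Diffusion constant in px^2/frame.
#' @param cal A [calibration()] object.
#' @return Diffusion constant in um^2/s.
#' @export
diffusion_to_physical <- function(D_px2_frame, cal) {
  D_px2_frame * cal$pixel_size_um^2 / cal$frame_interval_s
}

#' @rdname diffusion_to_physical
#' @param D_um2_s Diffusion constant in um^2/s.
#' @export
diffusion_to_pixels <- function(D_um2_s, cal) {
  D_um2_s * cal$frame_interval_s / cal$pixel_size_um^2
}
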