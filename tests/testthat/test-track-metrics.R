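test_that("MSD handles ballistic, stationary and gapped tracks exactly", {
  ball <- tibble::tibble(frame = 0:3, x = 0:3, y = 0)
  expect_equal(msd(ball)$msd, c(1, 4, 9))
  still <- tibble::tibble(frame = 0:5, x = 2, y = 7)
  expect_true(all(msd(still)$msd == 0))
  zig <- tibble::tibble(frame = 0:3, x = c(0, 1, 0, 1), y = c(0, 1, 0, 1))
  expect_equal(msd(zig)$msd, c(2, 0, 2))
  expect_equal(msd(zig)$n_pairs, c(3L, 2L, 1L))
  expect_error(msd(tibble::tibble(frame = 1, x = 0, y = 0)), "2 observed")
})

test_that("MSD matches the brute-force double-loop oracle on random tracks", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    tr <- random_track(sample(5:200, 1), with_gaps = i %% 2 == 0)
    got <- msd(tr)
    want <- msd_oracle(tr)
    expect_equal(got$lag, want$lag)
    expect_equal(got$n_pairs, want$n_pairs)
    rel <- abs(got$msd - want$msd) / pmax(want$msd, .Machine$double.eps)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-12)
})

test_that("diffusion fit recovers slope/4 with a free intercept", {
  curve <- tibble::tibble(lag = 1:4, msd = c(2, 4, 6, 8))
  fit <- fit_diffusion(curve)
  expect_equal(fit$D, 0.5)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), 0.5)
  flat <- fit_diffusion(tibble::tibble(lag = 1:4, msd = rep(0, 4)))
  expect_equal(flat$D, 0)
  # offset MSD (localization noise): free intercept still recovers D
  noisy <- tibble::tibble(lag = 1:4, msd = 1.5 + 2 * (1:4))
  expect_equal(fit_diffusion(noisy)$D, 0.5)
  expect_error(fit_diffusion(tibble::tibble(lag = 1:2, msd = 1:2)), "lags")
  # tidy/glance surface
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$D, 0.5)
})

test_that("turning angles resolve direction, perpendicular and reversal", {
  tr <- function(xy) tibble::tibble(frame = 0:2, x = xy[, 1], y = xy[, 2])
  straight <- tr(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(turning_angles(straight)$angle, 0)
  perp <- tr(cbind(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(turning_angles(perp)$angle, 90)
  reverse <- tr(cbind(c(0, 1, 0), c(0, 0, 0)))
  expect_equal(turning_angles(reverse)$angle, 180)
  # zero-length displacement skips the triple; gaps break triples
  pause <- tibble::tibble(frame = 0:2, x = c(0, 1, 1), y = 0)
  expect_equal(nrow(turning_angles(pause)), 0)
  gapped <- tibble::tibble(frame = c(0, 1, 3), x = 0:2, y = 0)
  expect_equal(nrow(turning_angles(gapped)), 0)
  expect_equal(nrow(turning_angles(tibble::tibble(frame = 0:1, x = 0:1, y = 0))), 0)
})

test_that("asymmetry coefficient hits its limiting values", {
  expect_equal(asymmetry_coefficient(rep(0, 100)), 0)
  expect_message(ac90 <- asymmetry_coefficient(rep(90, 100)), "undefined")
  expect_true(is.na(ac90))
  expect_equal(asymmetry_coefficient(c(rep(10, 50), rep(170, 50))), 1)
  # Brownian pooled angles -> uniform turning angle -> AC = 1
  tr <- simulate_tracks(motion_model("brownian", D = 0.5), 150, 80, seed = 3,
                        shape = c(4096L, 4096L), margin = 1500)
  names(tr)[1] <- "track_id"
  ang <- turning_angles(tr)
  expect_gte(nrow(ang), 1e4)
  expect_equal(asymmetry_coefficient(ang), 1, tolerance = 0.1)
})

test_that("AC decreases monotonically with drift-to-noise ratio", {
  sigma_step <- 1
  acs <- vapply(c(0, 1, 2, 4), function(v) {
    tr <- simulate_tracks(motion_model("directed", D = sigma_step^2 / 2,
                                       v = v, heading = 30),
                          120, 60, seed = 7 + v,
                          shape = c(4096L, 4096L), margin = 1500)
    names(tr)[1] <- "track_id"
    asymmetry_coefficient(turning_angles(tr))
  }, 0)
  expect_true(all(diff(acs) < 0))
  expect_lt(acs[3], 0.2)  # v = 2 * sigma_step
})

test_that("MSD, D and AC are invariant under rotation and translation", {
  set.seed(41)
  tr <- random_track(40, with_gaps = TRUE)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- as.matrix(tr[, c("x", "y")]) %*% R
  tr2 <- tibble::tibble(frame = tr$frame, x = rot[, 1] + 55, y = rot[, 2] - 12)
  expect_equal(msd(tr)$msd, msd(tr2)$msd, tolerance = 1e-10)
  expect_equal(fit_diffusion(msd(tr))$D, fit_diffusion(msd(tr2))$D,
               tolerance = 1e-10)
  expect_equal(sort(turning_angles(tr)$angle), sort(turning_angles(tr2)$angle),
               tolerance = 1e-8)
})

test_that("track length counts observed frames, not span", {
  expect_equal(track_length(tibble::tibble(frame = 0:9, x = 0, y = 0)), 10)
  gappy <- tibble::tibble(frame = c(0:4, 10:14), x = 0, y = 0)
  expect_equal(track_length(gappy), 10)
})

test_that("physical-unit conversion round-trips", {
  cal <- calibration(pixel_size_um = 0.16, frame_interval_s = 1)
  D <- 0.05
  expect_equal(diffusion_to_physical(D, cal), 0.05 * 0.16^2)
  expect_equal(diffusion_to_pixels(diffusion_to_physical(D, cal), cal), D)
})

test_that("field summaries count tracks and order AC by drift", {
  empty <- summarize_field(link_tracks(tibble::tibble(
    frame = integer(), x = numeric(), y = numeric())))
  expect_equal(empty$n_tracks, 0)

  mk_field <- function(v, seed) {
    tr <- simulate_tracks(motion_model("directed", D = 0.3, v = v),
                          35, 40, seed = seed, shape = c(2048L, 2048L),
                          margin = 400)
    structure(dplyr::rename(tr, track_id = "particle_id"),
              class = c("vt_tracks", class(tr)))
  }
  drift <- summarize_field(mk_field(2, 1), cal = calibration())
  still <- summarize_field(mk_field(0, 2), cal = calibration())
  expect_equal(drift$n_tracks, 35)
  expect_equal(still$n_tracks, 35)
  expect_lt(drift$asymmetry_coefficient, still$asymmetry_coefficient)
  expect_equal(still$mean_track_length, 40)
  expect_equal(still$mean_msd_lag1_um2, still$mean_msd_lag1 * 0.16^2)
})
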