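test_that("stationary and noiseless directed motion are exact", {
  tr <- simulate_tracks(motion_model("stationary"), 1, 10, seed = 1)
  expect_equal(nrow(tr), 10)
  expect_equal(length(unique(tr$x)), 1)
  expect_equal(length(unique(tr$y)), 1)

  tr <- simulate_tracks(motion_model("directed", v = 1, heading = 0, D = 0),
                        1, 5, seed = 1)
  expect_equal(diff(tr$x), rep(1, 4))
  expect_equal(diff(tr$y), rep(0, 4), tolerance = 1e-12)
})

test_that("invalid motion parameters error", {
  expect_error(motion_model("brownian", D = -1), "D")
  expect_error(motion_model("directed", v = NaN), "v")
  expect_error(motion_model("brownian", p_off = 1.5), "0, 1")
})

test_that("Brownian ensemble MSD matches 4*D*tau within 5%", {
  D <- 0.05
  tr <- simulate_tracks(motion_model("brownian", D = D), 500, 100,
                        shape = c(512L, 512L), seed = 42, margin = 100)
  names(tr)[names(tr) == "particle_id"] <- "track_id"
  curves <- lapply(split(tr, tr$track_id), msd)
  for (tau in c(1, 5, 10)) {
    vals <- vapply(curves, function(cv) cv$msd[cv$lag == tau], 0)
    expect_equal(mean(vals), 4 * D * tau, tolerance = 0.05)
  }
})

test_that("disappearance is permanent and blinking reappears", {
  tr <- simulate_tracks(motion_model("brownian", D = 0.1, p_off = 0.2),
                        50, 30, seed = 7)
  for (id in unique(tr$particle_id)) {
    v <- tr$visible[tr$particle_id == id]
    if (any(!v)) expect_false(any(v[which(!v)[1]:length(v)]))
  }
  tr <- simulate_tracks(motion_model("brownian", D = 0.1, p_blink = 0.2),
                        50, 30, seed = 8)
  v <- tr$visible
  # some particle blinks off and comes back
  reappears <- vapply(split(v, tr$particle_id), function(vi) {
    any(!vi) && any(vi[seq_along(vi) > which(!vi)[1]])
  }, TRUE)
  expect_true(any(reappears))
})

test_that("noiseless rendering places the Gaussian peak correctly", {
  opt <- quiet_optics()
  truth <- tibble::tibble(particle_id = 1L, frame = 0L, x = 30, y = 20,
                          visible = TRUE, in_field = TRUE)
  f <- vesitrack:::stack_frame(render_movie(truth, opt), 1)
  pk <- which(f == max(f), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(21, 31))  # row = y+1, col = x+1
  expect_equal(max(f), opt$background + opt$amplitude)

  # empty truth: pure background
  f0 <- vesitrack:::stack_frame(
    render_movie(truth[0, ], quiet_optics(shape = c(32L, 32L))), 1)
  expect_true(all(f0 == 10))
})

test_that("integrated spot intensity equals amplitude * 2 * pi * sigma^2", {
  opt <- quiet_optics(shape = c(64L, 64L), psf_sigma = 2)
  truth <- tibble::tibble(particle_id = 1L, frame = 0L, x = 31.5, y = 31.5,
                          visible = TRUE, in_field = TRUE)
  f <- vesitrack:::stack_frame(render_movie(truth, opt), 1)
  total <- sum(f - opt$background)
  expect_equal(total, opt$amplitude * 2 * pi * opt$psf_sigma^2,
               tolerance = 0.01)
})

test_that("Poisson rendering preserves the mean background", {
  opt <- optics_model(background = 10, poisson_noise = TRUE,
                      read_noise_sigma = 0, image_shape = c(16L, 16L))
  empty <- tibble::tibble(particle_id = integer(), frame = integer(),
                          x = numeric(), y = numeric(),
                          visible = logical(), in_field = logical())
  attr(empty, "n_frames") <- 1000L
  set.seed(11)
  mv <- render_movie(empty, opt)
  expect_equal(mean(mv), 10, tolerance = 0.01)
})

test_that("rendering is seed-reproducible", {
  opt <- optics_model(image_shape = c(32L, 32L), read_noise_sigma = 2)
  tr <- simulate_tracks(motion_model("brownian", D = 0.2), 3, 5, seed = 5,
                        shape = c(32L, 32L))
  m1 <- render_movie(tr, opt, seed = 9)
  m2 <- render_movie(tr, opt, seed = 9)
  m3 <- render_movie(tr, opt, seed = 10)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
})

test_that("coloc pair shares exactly round(f * n) positions", {
  opt <- quiet_optics(shape = c(128L, 128L))
  sc <- make_coloc_pair(40, 0.5, opt, seed = 3)
  expect_equal(sum(sc$truth$shared), 20)
  sc1 <- make_coloc_pair(10, 1, opt, seed = 4)
  expect_equal(sum(sc1$truth$shared), 10)
  expect_equal(sc1$red, sc1$green)  # noiseless, fully shared
  sc0 <- make_coloc_pair(10, 0, opt, seed = 5)
  expect_equal(sum(sc0$truth$shared), 0)
  # pairwise separation >= 4 sigma
  d <- as.matrix(dist(cbind(sc0$truth$x, sc0$truth$y)))
  diag(d) <- Inf
  expect_gte(min(d), 4 * opt$psf_sigma)
  expect_error(make_coloc_pair(10, 1.2, opt), "overlap")
})

test_that("cell scenes respect the radial law", {
  opt <- quiet_optics(shape = c(192L, 192L))
  ring <- make_cell_scene(60, 50, "ring", opt, seed = 2, ring_radius = 20)
  expect_true(all(abs(ring$truth$r_true - 20) < 1e-12))
  set.seed(1)
  unif <- make_cell_scene(60, 4000, "uniform_disk", opt, seed = 6)
  expect_equal(mean(unif$truth$r_true), 2 * 60 / 3, tolerance = 0.02)
  expect_false(any(unif$cells$border_touching))
  # a cell overlapping the border is flagged
  edge <- make_cell_scene(60, 5, "uniform_disk", opt, seed = 7,
                          centers = data.frame(x = 10, y = 96))
  expect_true(all(edge$cells$border_touching))
  expect_error(make_cell_scene(30, 5, "ring", opt, ring_radius = 40), "ring")
})
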