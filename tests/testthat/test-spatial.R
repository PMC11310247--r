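scene_opt <- function(shape = c(192L, 192L)) {
  optics_model(image_shape = shape, background = 2, amplitude = 60,
               read_noise_sigma = 1, poisson_noise = TRUE)
}

test_that("cell-mask preparation zeroes constant images and keeps disks apart", {
  expect_true(all(make_cell_mask(matrix(9, 120, 120)) == 0))

  sc <- make_cell_scene(35, 0, "uniform_disk", scene_opt(c(160L, 160L)),
                        seed = 1,
                        centers = data.frame(x = c(45, 115), y = c(45, 115)))
  msk <- make_cell_mask(sc$cell)
  cells <- segment_cells(msk)
  expect_equal(nrow(cells), 2)
})

test_that("segmentation recovers disk area and centroid; border cells drop", {
  sc <- make_cell_scene(50, 0, "uniform_disk", scene_opt(c(160L, 160L)),
                        seed = 2)
  cells <- segment_cells(make_cell_mask(sc$cell))
  expect_equal(nrow(cells), 1)
  expect_equal(cells$area, pi * 50^2, tolerance = 0.06)
  expect_lt(abs(cells$x - 79.5), 1)
  expect_lt(abs(cells$y - 79.5), 1)
  expect_false(cells$on_border)

  edge <- make_cell_scene(50, 0, "uniform_disk", scene_opt(c(160L, 160L)),
                          seed = 3, centers = data.frame(x = 20, y = 80))
  ec <- segment_cells(make_cell_mask(edge$cell))
  expect_true(all(ec$on_border))

  expect_equal(nrow(segment_cells(matrix(1, 50, 50))), 0)
})

test_that("speckle enhancement keeps small spots and kills large blobs", {
  expect_true(all(enhance_speckles(matrix(4, 60, 60)) == 0))

  grad <- outer(seq(0, 50, length.out = 100), seq(0, 50, length.out = 100), "+") / 2
  spots <- render_test_frame(tibble::tibble(x = c(30, 70), y = c(40, 60)),
                             quiet_optics(shape = c(100L, 100L), psf_sigma = 1.5,
                                          background = 0))
  enh <- enhance_speckles(grad + spots, 20)
  expect_gt(enh[41, 31], 0.9 * 100)
  expect_gt(enh[61, 71], 0.9 * 100)

  blob <- matrix(0, 120, 120)
  xs <- matrix(rep(0:119, each = 120), 120); ys <- matrix(rep(0:119, 120), 120)
  inside <- (xs - 60)^2 + (ys - 60)^2 <= 20^2
  blob[inside] <- 100  # 40-px-wide structure
  eb <- enhance_speckles(blob, 20)
  # interior suppressed below 10% of height (a 1-px discretization ring can
  # survive at the boundary)
  core <- (xs - 60)^2 + (ys - 60)^2 <= 17^2
  expect_lt(max(eb[core]), 10)
  expect_lt(mean(eb[inside]), 10)
})

test_that("vesicles are identified, declumped, and assigned to parents", {
  sc <- make_cell_scene(55, 1, "ring", scene_opt(), seed = 4, ring_radius = 15)
  out <- radial_pipeline(sc$cell, sc$vesicle)
  expect_equal(nrow(out$vesicles), 1)
  expect_equal(out$vesicles$parent, out$cells$label[!out$cells$on_border])

  # two spots 30 px apart
  sc2 <- make_cell_scene(55, 2, "ring", scene_opt(), seed = 12, ring_radius = 15)
  # regenerate until the two drawn angles give separation > 25 px (seeded scan)
  sep <- function(s) if (nrow(s$truth) == 2)
    sqrt(diff(s$truth$x)^2 + diff(s$truth$y)^2) else 0
  s <- 12
  while (sep(sc2) < 25) { s <- s + 1; sc2 <- make_cell_scene(55, 2, "ring",
    scene_opt(), seed = s, ring_radius = 15) }
  out2 <- radial_pipeline(sc2$cell, sc2$vesicle)
  expect_equal(nrow(out2$vesicles), 2)

  # declumping: two overlapping Gaussians with peaks 6 px apart
  cellimg <- make_cell_scene(60, 0, "uniform_disk", scene_opt(), seed = 5)$cell
  ves <- render_test_frame(tibble::tibble(x = c(92, 98), y = c(96, 96)),
                           quiet_optics(shape = c(192L, 192L), background = 0,
                                        psf_sigma = 1.8))
  cells <- segment_cells(make_cell_mask(cellimg))
  pts <- identify_vesicles(enhance_speckles(ves), cells)
  expect_equal(nrow(pts), 2)
  expect_equal(sort(round(pts$x)), c(92, 98))
})

test_that("distances to centroid and their correction behave geometrically", {
  cells <- tibble::tibble(label = 1L, area = 400, x = 50, y = 50,
                          on_border = FALSE)
  ves <- tibble::tibble(parent = 1L, x = 60, y = 50)
  d <- distance_to_centroid(ves, cells)
  expect_equal(d$distance, 10)
  summ <- cell_distances(d, cells)
  expect_equal(summ$mean_distance, 10)
  expect_equal(corrected_distance(summ)$corrected_distance, 0.5)  # 10 / 20
  expect_warning(lit <- corrected_distance(summ, "paper_literal"), "sqrt")
  expect_equal(lit$corrected_distance, 20)
  expect_equal(lit$alpha, 2)

  # scale invariance of the dimensionless form
  big <- tibble::tibble(label = 1L, area = 400 * 4, x = 100, y = 100,
                        on_border = FALSE)
  dbig <- distance_to_centroid(tibble::tibble(parent = 1L, x = 120, y = 100), big)
  expect_equal(corrected_distance(cell_distances(dbig, big))$corrected_distance,
               0.5)
})

test_that("ring placement is recovered end to end within 5%", {
  sc <- make_cell_scene(55, 40, "ring", scene_opt(), seed = 31,
                        ring_radius = 20)
  out <- radial_pipeline(sc$cell, sc$vesicle)
  expect_equal(out$per_cell$mean_distance, 20, tolerance = 0.05)
})

test_that("uniform-disk placement gives area-proportional radial fractions", {
  outs <- lapply(33:35, function(s) {
    sc <- make_cell_scene(60, 70, "uniform_disk", scene_opt(c(224L, 224L)),
                          seed = s)
    radial_pipeline(sc$cell, sc$vesicle)
  })
  means <- vapply(outs, function(o) o$per_cell$mean_distance, 0)
  expect_equal(mean(means), 2 * 60 / 3, tolerance = 0.07)
  fracs <- rowMeans(vapply(outs, function(o) o$profile$fraction, numeric(4)))
  for (o in outs) {
    expect_equal(sum(o$profile$fraction), 1)
    expect_true(all(o$profile$fraction >= 0 & o$profile$fraction <= 1))
  }
  expect_equal(fracs, c(1, 3, 5, 7) / 16, tolerance = 0.3)
  expect_true(all(diff(fracs) > 0))
})

test_that("radial profile limiting cases land in the right bins", {
  cells <- segment_cells(make_cell_mask(
    make_cell_scene(50, 0, "uniform_disk", scene_opt(c(160L, 160L)),
                    seed = 35)$cell))
  ctr <- c(cells$x, cells$y)
  near <- tibble::tibble(parent = cells$label, x = ctr[1] + 0.5, y = ctr[2])
  near <- distance_to_centroid(near, cells)
  expect_equal(fraction_at_distance(near, cells)$fraction, c(1, 0, 0, 0))
  rmax <- 50
  far <- tibble::tibble(parent = cells$label,
                        x = ctr[1] + 0.9 * rmax, y = ctr[2])
  far <- distance_to_centroid(far, cells)
  expect_equal(fraction_at_distance(far, cells)$fraction, c(0, 0, 0, 1))
})

test_that("per-vesicle distances are invariant under 90-degree rotation", {
  sc <- make_cell_scene(45, 25, "uniform_disk", scene_opt(c(160L, 160L)),
                        seed = 37)
  out <- radial_pipeline(sc$cell, sc$vesicle)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # 90-degree rotation
  out_r <- radial_pipeline(rot(sc$cell), rot(sc$vesicle))
  expect_equal(nrow(out_r$vesicles), nrow(out$vesicles))
  # watershed tie-breaking at object boundaries is orientation-dependent at
  # the sub-pixel level, so compare distances with a small absolute slack
  expect_equal(sort(out_r$vesicles$distance), sort(out$vesicles$distance),
               tolerance = 0.01)
  expect_equal(mean(out_r$vesicles$distance), mean(out$vesicles$distance),
               tolerance = 1e-3)
})

test_that("dimensionless corrected distance is invariant under x2 rescale", {
  # uniform rescale of the whole geometry: cell, vesicle placement, PSF and
  # the pipeline's length scales all double
  base <- make_cell_scene(40, 60, "uniform_disk", scene_opt(c(160L, 160L)),
                          seed = 39)
  opt2 <- optics_model(image_shape = c(320L, 320L), background = 2,
                       amplitude = 60, read_noise_sigma = 1,
                       psf_sigma = 4)
  doubled <- make_cell_scene(80, 60, "uniform_disk", opt2, seed = 39)
  expect_equal(doubled$truth$r_true, 2 * base$truth$r_true)
  a <- radial_pipeline(base$cell, base$vesicle)$per_cell$corrected_distance
  b <- radial_pipeline(doubled$cell, doubled$vesicle,
                       ball_radius = 100, blur_sigma = 10, feature_size = 40,
                       smoothing_sigma = 3, min_area = 20)$per_cell$corrected_distance
  expect_equal(a, b, tolerance = 0.02)
})
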