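test_that("shape factor hits its closed-form anchors", {
  circ <- generate_shape(shape_spec("circle", radius = 10,
                                    n_vertices = 1e4))
  expect_equal(shape_factor(circ$polygon), 1, tolerance = 1e-6)

  square <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), ncol = 2, byrow = TRUE)
  expect_equal(shape_factor(square), pi / 4, tolerance = 1e-12)

  # 2:1 ellipse vs independent quadrature of area and arc length
  a <- 6; b <- 3
  ell <- generate_shape(shape_spec("ellipse", axes = c(a, b),
                                   n_vertices = 1e4))
  area <- pi * a * b
  arc <- stats::integrate(function(th) sqrt(a^2 * sin(th)^2 +
                                              b^2 * cos(th)^2),
                          0, 2 * pi, rel.tol = 1e-12)$value
  expect_equal(shape_factor(ell$polygon), 4 * pi * area / arc^2,
               tolerance = 1e-5)

  expect_error(shape_factor(matrix(c(0, 0, 1, 1, 2, 2), ncol = 2,
                                   byrow = TRUE)), "degenerate")
  expect_error(shape_factor(matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE)),
               "3 vertices")
})

test_that("isoperimetric bound and scale invariance hold on random polygons", {
  set.seed(17)
  for (i in 1:1000) {
    n_v <- sample(16:64, 1)
    spec <- shape_spec("blob", radius = runif(1, 1, 20),
                       roughness = runif(1, 0, 0.6), n_vertices = n_v,
                       seed = i)
    poly <- tryCatch(generate_shape(spec)$polygon, error = function(e) NULL)
    if (is.null(poly)) next
    sf <- shape_factor(poly)
    expect_lte(sf, 1)
    s <- runif(1, 0.01, 100)
    expect_equal(shape_factor(poly * s), sf, tolerance = 1e-12)
  }
})

test_that("segmentation matches analytic areas and 4-connectivity", {
  # rasterized disc radius 20 at threshold 0.5
  msk <- generate_shape(shape_spec("circle", radius = 20), pixel_size = 1)
  img <- matrix(0, nrow(msk$mask), ncol(msk$mask))
  img[msk$mask] <- 1
  g <- segment_granules(img, threshold = 0.5)
  expect_equal(nrow(g), 1)
  expect_equal(g$area_um2, pi * 400, tolerance = 0.03)
  expect_gt(g$shape_factor, 0.85)
  expect_lte(g$shape_factor, 1.1)

  # two blocks separated by a single background column
  img2 <- matrix(0, 30, 60)
  img2[10:20, 10:20] <- 1
  img2[10:20, 22:32] <- 1
  g2 <- segment_granules(img2, threshold = 0.5)
  expect_equal(nrow(g2), 2)

  # diagonal contact is NOT connected under 4-connectivity
  img3 <- matrix(0, 12, 12)
  img3[2:4, 2:4] <- 1
  img3[5:7, 5:7] <- 1
  g3 <- segment_granules(img3, threshold = 0.5, min_area_px = 1)
  expect_equal(nrow(g3), 2)

  expect_equal(nrow(segment_granules(matrix(0, 8, 8), threshold = 0.5)), 0)
})

test_that("component labelling agrees with an independent flood fill", {
  set.seed(23)
  for (i in 1:20) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    img <- matrix(0, 30, 30); img[mask] <- 1
    g <- segment_granules(img, threshold = 0.5, min_area_px = 1)
    # fill_holes changes areas, not outer component count
    filled <- rnpdyn:::fill_holes(mask)
    expect_equal(length(unique(g$label)), flood_fill_count(filled))
  }
})

test_that("frozen Otsu threshold is reused across frames", {
  set.seed(5)
  base <- matrix(10, 40, 40)
  base[10:20, 10:20] <- 100
  frames <- array(0, c(3, 40, 40))
  frames[1, , ] <- base + rnorm(1600)
  frames[2, , ] <- base * 0.6 + rnorm(1600)  # dimmer later frame
  frames[3, , ] <- base * 0.6 + rnorm(1600)
  sq <- image_sequence(frames, 1, 1)
  g <- segment_granules(sq)
  thr <- attr(g, "threshold")
  expect_equal(thr, rnpdyn:::otsu_threshold(frames[1, , ]))
  # the frozen threshold still segments the dimmer frames
  expect_setequal(unique(g$frame), 1:3)
})

test_that("Mann-Whitney comparison matches exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- size_distribution(a, b)
  oracle <- enumerate_mw(a, b)
  expect_equal(res$U, oracle$U)
  expect_equal(res$U, 0)  # complete separation, minimal U
  expect_equal(res$p_value, oracle$p)

  set.seed(31)
  for (i in 1:10) {
    a <- round(runif(sample(3:6, 1), 0, 10), 2)
    b <- round(runif(sample(3:6, 1), 0, 10), 2)
    res <- size_distribution(a, b)
    oracle <- enumerate_mw(a, b)
    expect_equal(res$U, oracle$U)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }

  # identical groups: U = n^2/2 (with ties) and p in the no-difference region
  res_id <- suppressWarnings(size_distribution(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res_id$U, 4.5)
  expect_gt(res_id$p_value, 0.9)

  # strong synthetic "hexanediol" effect is detected
  set.seed(41)
  big <- rlnorm(120, log(2), 0.4)
  small <- big * 0.3
  expect_lt(size_distribution(big, small)$p_value, 1e-4)

  expect_error(size_distribution(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("track linking computes speeds and respects the distance gate", {
  # single granule moving (3,4) px per frame at 1 um/px, 10 s interval
  frames <- array(0, c(3, 64, 64))
  pos <- list(c(10, 10), c(13, 14), c(16, 18))
  for (t in 1:3) {
    p <- pos[[t]]
    frames[t, p[2] + (0:3), p[1] + (0:3)] <- 1
  }
  sq <- image_sequence(frames, 1, 10)
  g <- segment_granules(sq, threshold = 0.5)
  ts <- link_tracks(g, max_link_distance_um = 10, frame_interval_s = 10)
  expect_equal(length(unique(ts$tracks$track)), 1)
  expect_equal(ts$steps$speed_um_s, c(0.5, 0.5), tolerance = 1e-12)

  # static granules: zero speeds
  frames_static <- array(0, c(3, 64, 64))
  for (t in 1:3) frames_static[t, , ] <- frames[1, , ]
  sq2 <- image_sequence(frames_static, 1, 10)
  ts2 <- link_tracks(segment_granules(sq2, threshold = 0.5),
                     max_link_distance_um = 5, frame_interval_s = 10)
  expect_true(all(ts2$steps$speed_um_s == 0))

  # a jump beyond the gate starts a new track
  ts3 <- link_tracks(g, max_link_distance_um = 2, frame_interval_s = 10)
  expect_equal(length(unique(ts3$tracks$track)), 3)
})

test_that("tracked Brownian granules reproduce 4 D dt within 15%", {
  # sparse field: keeps spots from overlapping, so centroids are clean and
  # the link gate only removes the (negligible) Rayleigh tail
  mov <- simulate_brownian_movie(brownian_movie_config(
    n_particles = 15, diffusion_um2_s = 0.02, field_um = 30,
    pixel_size_um = 0.25, frame_interval_s = 10, n_frames = 60,
    psf_sigma_um = 0.3, particle_intensity = 500, background_level = 0,
    noise_sigma = 0, seed = 51))
  g <- segment_granules(mov$sequence, threshold = 30, min_area_px = 3)
  ts <- link_tracks(g, max_link_distance_um = 2.5, frame_interval_s = 10)
  # exclude wrap-around steps via the distance gate; compare mean squared step
  msq <- mean(ts$steps$displacement_um^2)
  expect_equal(msq, 4 * 0.02 * 10, tolerance = 0.15)
})

test_that("circularity time course tracks morphing shapes", {
  # disc morphing into a 3:1 ellipse across frames
  n <- 80
  frames <- array(0, c(4, n, n))
  ratios <- c(1, 1.5, 2, 3)
  for (t in 1:4) {
    a <- 12 * sqrt(ratios[t]); b <- 12 / sqrt(ratios[t])
    xs <- matrix(rep(0:(n - 1), each = n), n)
    ys <- matrix(rep(0:(n - 1), times = n), n)
    frames[t, , ] <- ((xs - 40)^2 / a^2 + (ys - 40)^2 / b^2 <= 1) * 1
  }
  sq <- image_sequence(frames, 1, 1)
  g <- segment_granules(sq, threshold = 0.5)
  ts <- link_tracks(g, max_link_distance_um = 10, frame_interval_s = 1)
  tc <- circularity_timecourse(ts)
  expect_equal(nrow(tc), 4)
  expect_true(all(diff(tc$shape_factor) < 0))
  # polygon oracle per frame: raster factor tracks the analytic one
  for (t in 1:4) {
    a <- 12 * sqrt(ratios[t]); b <- 12 / sqrt(ratios[t])
    poly <- generate_shape(shape_spec("ellipse", axes = c(a, b),
                                      n_vertices = 4096))$polygon
    expect_equal(tc$shape_factor[t], shape_factor(poly), tolerance = 0.08)
  }
})

test_that("merged granules sum their parents' areas", {
  frames <- array(0, c(2, 40, 60))
  frames[1, 10:19, 10:19] <- 1   # 100 px
  frames[1, 10:19, 30:39] <- 1   # 100 px
  frames[2, 10:19, 10:39] <- 1   # merged 300 px bridge
  sq <- image_sequence(frames, 1, 1)
  g <- segment_granules(sq, threshold = 0.5)
  a1 <- sum(g$area_um2[g$frame == 1])
  a2 <- g$area_um2[g$frame == 2]
  expect_equal(length(a2), 1)
  expect_gte(a2, a1)  # merged granule covers at least the parents
})
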