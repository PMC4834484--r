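test_that("pixel statistics match the two-pass oracle", {
  # constant stack: m = c, s = 0
  st <- stack_from_frames(replicate(4, matrix(7L, 5, 5), simplify = FALSE))
  ps <- pixel_stats(st)
  expect_true(all(ps$m == 7))
  expect_true(all(ps$s == 0))

  # five hand-written 2x2 frames against the direct two-pass formula
  frames <- list(matrix(c(1L, 2L, 3L, 4L), 2), matrix(c(2L, 2L, 3L, 0L), 2),
                 matrix(c(9L, 1L, 3L, 8L), 2), matrix(c(0L, 0L, 3L, 4L), 2),
                 matrix(c(5L, 5L, 3L, 4L), 2))
  st2 <- stack_from_frames(frames)
  ps2 <- pixel_stats(st2)
  oracle <- two_pass_stats(st2)
  expect_equal(ps2$m, oracle$m, tolerance = 1e-12)
  expect_equal(ps2$s, oracle$s, tolerance = 1e-12)
  # the pixel holding (1,2,9,0,5): mean 3.4, sd from first principles
  expect_equal(ps2$m[1, 1], mean(c(1, 2, 9, 0, 5)))
  expect_equal(ps2$s[1, 1], sd(c(1, 2, 9, 0, 5)))

  # streaming-vs-oracle equivalence on random stacks (<= 1e-8 relative)
  set.seed(31)
  for (rep in 1:3) {
    fr <- lapply(1:7, function(i) matrix(rpois(16 * 16, runif(1, 1, 200)), 16))
    stk <- stack_from_frames(fr)
    a <- pixel_stats(stk)
    b <- two_pass_stats(stk)
    expect_lt(max(abs(a$m - b$m) / pmax(abs(b$m), 1e-12)), 1e-8)
    expect_lt(max(abs(a$s - b$s) / pmax(abs(b$s), 1e-12)), 1e-8)
  }

  expect_error(pixel_stats(stack_from_frames(list(matrix(1L, 3, 3)))),
               "at least 2 frames")
})

test_that("Poisson stacks satisfy s^2 ~ m per pixel", {
  g <- tiny_geom(24)
  st <- simulate_stack(stack_config(500, flat_medium(8), geometry = g, seed = 41))
  ps <- pixel_stats(st)
  # variance/mean ratio concentrates around 1 (relative sd ~ sqrt(2/n))
  ratio <- ps$s^2 / ps$m
  expect_lt(abs(mean(ratio) - 1), 0.02)
})

test_that("m + 3s rejection removes outliers and preserves coverage", {
  # constant stack: nothing exceeds m, clean image is the constant
  st <- stack_from_frames(replicate(5, matrix(3L, 4, 4), simplify = FALSE))
  cb <- clean_background(st)
  expect_true(all(cb$image == 3))
  expect_true(all(cb$n_kept == 5))

  # 50 baseline frames + one Bragg-bright frame at a single pixel:
  # hand arithmetic puts m + 3s ~ 445 < 1000, so the outlier is rejected
  frames <- replicate(50, matrix(10L, 3, 3), simplify = FALSE)
  spiky <- matrix(10L, 3, 3); spiky[2, 2] <- 1000L
  st2 <- stack_from_frames(c(frames, list(spiky)))
  ps2 <- pixel_stats(st2)
  m <- mean(c(rep(10, 50), 1000)); s <- sd(c(rep(10, 50), 1000))
  expect_equal(ps2$m[2, 2], m)
  expect_lt(m + 3 * s, 1000)
  cb2 <- clean_background(st2, ps2)
  expect_equal(cb2$image[2, 2], 10)
  expect_identical(cb2$n_kept[2, 2], 50L)
  expect_true(all(cb2$n_kept[-5] == 51L))

  expect_error(clean_background(st2, pixel_stats(st)), "frame count|shape")
})

test_that("cleaning a Bragg-contaminated stack approaches its spot-free twin", {
  g <- tiny_geom(48)
  # sparse patterns (small cell, tight excitation) so individual pixels are
  # contaminated in only a few frames, the regime the m + 3s clip targets
  cr <- crystal_model(cell = c(30, 30, 15, 90, 90, 90), d_min = 4,
                      excitation_halfwidth = 0.001, mean_spot_photons = 2000)
  cfg_hits <- stack_config(150, flat_medium(6), geometry = g,
                           hit_fraction = 0.3, crystal = cr, seed = 51)
  cfg_clean <- stack_config(150, flat_medium(6), geometry = g, seed = 51)
  st_hits <- simulate_stack(cfg_hits)
  st_clean <- simulate_stack(cfg_clean)
  expect_gt(sum(st_hits$manifest$n_spots_rendered), 0)

  ps <- pixel_stats(st_hits)
  cb <- clean_background(st_hits, ps)
  naive <- apply(st_hits$frames, c(1, 2), mean)
  truth <- apply(st_clean$frames, c(1, 2), mean)

  # rejection monotonicity and survivor guarantee
  expect_true(all(cb$image <= naive + 1e-12))
  expect_true(all(cb$n_kept >= 1))
  # Bragg removal: clean image far closer to the spot-free truth
  err_clean <- mean(abs(cb$image - truth))
  err_naive <- mean(abs(naive - truth))
  expect_lt(err_clean, 0.5 * err_naive)
})

test_that("radial averaging reproduces per-pixel binning", {
  g <- tiny_geom(32)
  sh <- make_shells(g, 12)

  cb <- list(image = matrix(4.5, 32, 32))
  prof <- radial_average(cb, g, sh, label = "const")
  expect_true(all(abs(prof$mean_intensity[prof$n_pixels > 0] - 4.5) < 1e-12))

  # azimuthally symmetric image: profile equals brute-force shell means
  q <- pixel_q_map(g)
  img <- 3 + 40 * q^2
  prof2 <- radial_average(list(image = img), g, sh)
  for (b in which(prof2$n_pixels > 0)) {
    expect_equal(prof2$mean_intensity[b], mean(img[which(sh$index == b)]),
                 tolerance = 1e-12)
  }

  # masked-out shell is reported missing (NA), not zero
  q_lo <- sh$scheme$edges_q[3]; q_hi <- sh$scheme$edges_q[4]
  mask <- !(q >= q_lo & q <= q_hi)
  gm <- default_geometry(32, mask = mask)
  shm <- make_shells(gm, 12)
  empty_shells <- which(tabulate(shm$index[!is.na(shm$index)], 12) == 0)
  if (length(empty_shells)) {
    profm <- radial_average(list(image = img), gm, shm)
    expect_true(all(is.na(profm$mean_intensity[empty_shells])))
  }
})

test_that("profile scaling anchors the highest-resolution shell", {
  g <- tiny_geom(32)
  sh <- make_shells(g, 10)
  q <- pixel_q_map(g)
  p1 <- radial_average(list(image = 2 + 0 * q), g, sh, label = "a")
  p2 <- radial_average(list(image = 4 + 0 * q), g, sh, label = "b")
  p3 <- radial_average(list(image = 1 + 10 * q), g, sh, label = "c")

  out <- scale_profiles(list(p1, p1))
  expect_equal(attr(out[[1]], "scale_factor"), 1)
  expect_equal(attr(out[[2]], "scale_factor"), 1)

  out2 <- scale_profiles(list(p1, p2))
  expect_equal(attr(out2[[2]], "scale_factor"), 0.5)

  out3 <- scale_profiles(list(p1, p2, p3))
  anchors <- vapply(out3, function(p) p$scaled_intensity[10], numeric(1))
  expect_lt(max(abs(anchors - anchors[1]) / anchors[1]), 1e-12)

  # idempotence: scaling already-scaled profiles changes nothing
  out4 <- scale_profiles(out3)
  for (i in 1:3) {
    expect_equal(out4[[i]]$scaled_intensity, out3[[i]]$scaled_intensity)
    expect_equal(attr(out4[[i]], "scale_factor"), attr(out3[[i]], "scale_factor"))
  }

  pz <- p1; pz$mean_intensity[10] <- 0
  expect_error(scale_profiles(list(p1, pz)), "anchor")
  expect_error(scale_profiles(list(p1)), "at least 2")
})

test_that("ring detection finds sharp rings but not broad bands", {
  g <- tiny_geom(64)
  sh <- make_shells(g, 100)

  flat <- radial_average(list(image = matrix(5, 64, 64)), g, sh)
  expect_identical(nrow(detect_rings(flat)), 0L)

  # clean expectation image of the AZ preset: exactly one ring near 14 A,
  # despite the much larger broad 4-5 A diffuse band
  img <- background_expectation(g, medium_preset("az_grease"))
  prof <- radial_average(list(image = img), g, sh)
  rings <- detect_rings(prof)
  expect_identical(nrow(rings), 1L)
  width_q <- diff(sh$scheme$edges_q[1:2])
  expect_lt(abs(rings$q[1] - 1 / 14), width_q)

  # hyaluronic acid: no ring anywhere
  img2 <- background_expectation(g, medium_preset("hyaluronic_acid"))
  expect_identical(nrow(detect_rings(radial_average(list(image = img2), g, sh))), 0L)
})

test_that("per-frame ring classification recovers the manifest", {
  g <- tiny_geom(96)
  cfg <- stack_config(300, "super_lube", geometry = g, seed = 61)
  st <- simulate_stack(cfg)
  rp <- ring_prevalence(st, d_center = 4.8)
  truth <- st$manifest$ring_4.8
  expect_gte(mean(rp$flags == truth), 0.95)
  se <- sqrt(0.3 * 0.7 / 300)
  expect_lt(abs(rp$prevalence - 0.30), 3 * se + se) # estimator noise on top

  # no-ring stack: nothing flagged
  st2 <- simulate_stack(stack_config(100, "hyaluronic_acid", geometry = g, seed = 62))
  rp2 <- ring_prevalence(st2, d_center = 4.8)
  expect_equal(rp2$prevalence, 0)
})

test_that("media comparison reports profiles, rings and band summaries", {
  g <- tiny_geom(48)
  st <- simulate_stack(stack_config(60, "super_lube", geometry = g, seed = 71))
  # comparing a stack with itself: identical profiles, unit scale factors
  cmp <- compare_media(list(st, st), n_shells = 30)
  expect_equal(cmp$scale$scale_factor, c(1, 1))
  wide <- split(cmp$profiles, cmp$profiles$dataset)
  expect_equal(wide[[1]]$scaled_intensity, wide[[2]]$scaled_intensity)
  # one row per dataset per band
  expect_identical(nrow(cmp$bands), 2L * 2L)
  expect_error(compare_media(list(st)), "at least 2")
})
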