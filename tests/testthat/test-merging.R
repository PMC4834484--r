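test_that("canonical indices reduce 4/mmm orbits correctly", {
  # Friedel mates and the h/k exchange collapse to one representative
  expect_identical(canonical_hkl(c(1, 2, 3)), canonical_hkl(c(-1, -2, -3)))
  expect_identical(canonical_hkl(c(2, 1, 3)), canonical_hkl(c(1, 2, 3)))
  expect_identical(canonical_hkl(c(1, 2, 3)), c(2L, 1L, 3L))
  expect_error(canonical_hkl(c(0, 0, 0)), "canonical")

  set.seed(17)
  m <- matrix(sample(-9:9, 3 * 300, replace = TRUE), ncol = 3)
  m <- m[rowSums(m == 0) < 3, ]
  canon <- canonical_hkl(m)
  # idempotence
  expect_identical(canonical_hkl(canon), canon)
  # closed-form oracle: (max|h|,|k|, min, |l|)
  oracle <- t(apply(m, 1, function(v) closed_form_canonical(v[1], v[2], v[3])))
  expect_identical(canon, matrix(as.integer(oracle), ncol = 3))
})

test_that("orbit sizes divide 16 and shrink on special zones", {
  orbit_size <- function(hkl) {
    # explicit orbit under the group by scanning a small index box
    box <- expand.grid(h = -9:9, k = -9:9, l = -9:9)
    box <- as.matrix(box[rowSums(box == 0) < 3, ])
    canon_all <- canonical_hkl(box)
    target <- canonical_hkl(hkl)
    sum(canon_all[, 1] == target[1] & canon_all[, 2] == target[2] &
          canon_all[, 3] == target[3])
  }
  for (hkl in list(c(1, 2, 3), c(1, 1, 2), c(3, 0, 1))) {
    expect_identical(16L %% orbit_size(hkl), 0L)
  }
  expect_identical(orbit_size(c(0, 0, 4)), 2L)   # 00l zone: just +-l
  expect_identical(orbit_size(c(2, 0, 0)), 4L)   # h00 zone
  expect_identical(orbit_size(c(1, 2, 3)), 16L)  # general position
})

test_that("unique-reflection counts agree with brute-force enumeration", {
  cell <- c(10, 10, 10, 90, 90, 90)
  # independent oracle: enumerate every HKL in a box, keep the resolution
  # window, reduce with an orbit routine that never touches the package's
  # wedge enumeration
  brute <- function(d_max, d_min, include_absences) {
    box <- expand.grid(h = -3:3, k = -3:3, l = -3:3)
    box <- box[rowSums(box == 0) < 3, ]
    d <- 1 / sqrt((box$h^2 + box$k^2) / 100 + box$l^2 / 100)
    box <- box[d >= d_min & d <= d_max, ]
    reps <- unique(t(apply(box, 1, function(v) closed_form_canonical(v[1], v[2], v[3]))))
    if (!include_absences) {
      absent <- (reps[, 1] == 0 & reps[, 2] == 0 & reps[, 3] %% 4 != 0) |
        (reps[, 2] == 0 & reps[, 3] == 0 & reps[, 1] %% 2 != 0)
      reps <- reps[!absent, , drop = FALSE]
    }
    nrow(reps)
  }
  for (inc in c(TRUE, FALSE)) {
    expect_identical(count_unique(cell, d_max = 30, d_min = 5,
                                  include_absences = inc),
                     brute(30, 5, inc))
    expect_identical(count_unique(cell, d_max = 30, d_min = 3.4,
                                  include_absences = inc),
                     brute(30, 3.4, inc))
  }
  # monotone non-decreasing as d_min decreases
  counts <- vapply(c(6, 5, 4, 3.5, 3),
                   function(dm) count_unique(cell, d_max = 30, d_min = dm),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_unique(c(10, 11, 12, 90, 90, 90), d_max = 30, d_min = 3),
               "tetragonal")
})

test_that("Monte Carlo merging averages symmetry-equivalent observations", {
  obs <- data.frame(h = c(1, 2), k = c(2, 3), l = c(3, 4), I = c(5, 8))
  m <- mc_merge(obs)
  expect_identical(nrow(m), 2L)
  expect_equal(m$I_merged, c(5, 8)) # single observation: identity

  obs2 <- data.frame(h = c(1, -1, 2), k = c(2, -2, 1), l = c(3, -3, 3),
                     I = c(10, 20, 30))
  m2 <- mc_merge(obs2) # all three are 4/mmm-equivalent
  expect_identical(nrow(m2), 1L)
  expect_equal(m2$I_merged, 20)
  expect_identical(m2$n_obs, 3L)
})

test_that("half-set splitting is balanced, seeded and exclusion-aware", {
  obs <- data.frame(h = rep(3, 4), k = rep(1, 4), l = rep(2, 4), I = 1:4)
  sp <- split_half(obs, seed = 5)
  expect_identical(nrow(sp$a), 2L)
  expect_identical(nrow(sp$b), 2L)

  obs5 <- data.frame(h = rep(3, 5), k = rep(1, 5), l = rep(2, 5), I = 1:5)
  sp5 <- split_half(obs5, seed = 5)
  expect_identical(sort(c(nrow(sp5$a), nrow(sp5$b))), c(2L, 3L))

  expect_identical(split_half(obs5, seed = 9)$a$I, split_half(obs5, seed = 9)$a$I)
  sizes <- function(s) c(nrow(s$a), nrow(s$b))
  expect_identical(sizes(split_half(obs5, seed = 1)), sizes(split_half(obs5, seed = 2)))

  mixed <- rbind(obs, data.frame(h = 5, k = 0, l = 0, I = 9))
  expect_message(spm <- split_half(mixed, seed = 1), "1 reflection")
  expect_identical(spm$n_excluded, 1L)
})

test_that("R_split matches its formula and responds to averaging", {
  mk <- function(I) data.frame(h = seq_along(I) + 10, k = 1, l = 1, I_merged = I)
  expect_equal(r_split(mk(c(3, 7, 1)), mk(c(3, 7, 1))), 0)
  # single reflection A=2, B=1: 100/sqrt(2) * 1 / 1.5
  expect_equal(r_split(mk(2), mk(1)), 100 / sqrt(2) / 1.5, tolerance = 1e-12)
  expect_equal(r_split(mk(2), mk(1)), 47.14, tolerance = 1e-4)
  # invariance under a common positive rescaling
  a <- mk(c(4, 9, 2, 6)); b <- mk(c(5, 8, 3, 5))
  a2 <- a; b2 <- b; a2$I_merged <- a2$I_merged * 7; b2$I_merged <- b2$I_merged * 7
  expect_equal(r_split(a, b), r_split(a2, b2))
  expect_error(r_split(mk(1), mk(-1)), "denominator")

  # more observations per reflection -> smaller R_split (sigma/I = 0.1)
  set.seed(23)
  true_I <- runif(50, 50, 150)
  rsplit_at <- function(n_obs) {
    obs <- do.call(rbind, lapply(seq_along(true_I), function(i) {
      data.frame(h = i + 50, k = 1, l = 1,
                 I = rnorm(n_obs, true_I[i], 0.1 * true_I[i]))
    }))
    sp <- split_half(obs, seed = 3)
    r_split(mc_merge(sp$a), mc_merge(sp$b))
  }
  vals <- vapply(c(4, 16, 64), rsplit_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("CC1/2 is the half-set Pearson correlation in percent", {
  mk <- function(I) data.frame(h = seq_along(I) + 10, k = 1, l = 1, I_merged = I)
  a <- mk(c(1, 5, 3, 9))
  expect_equal(cc_half(a, a), 100)
  b <- a; b$I_merged <- -a$I_merged
  expect_equal(cc_half(a, b), -100)
  # hand-computed Pearson on a 4-point toy set
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc_half(mk(x), mk(y)), 100 * r_hand, tolerance = 1e-12)
  expect_error(cc_half(mk(c(2, 2, 2)), mk(c(1, 2, 3))), "degenerate")
  expect_error(cc_half(mk(c(1, 2)), mk(c(1, 2))), ">= 3")
})

test_that("completeness counts distinct observed unique reflections", {
  cell <- c(10, 10, 10, 90, 90, 90)
  full <- unique_reflections(cell, d_max = 30, d_min = 4)
  expect_equal(completeness(full, cell, d_max = 30, d_min = 4), 100)
  expect_equal(completeness(full[0, ], cell, d_max = 30, d_min = 4), 0)
  half <- full[seq(1, nrow(full), by = 2), ]
  expect_equal(completeness(half, cell, d_max = 30, d_min = 4),
               100 * nrow(half) / nrow(full))
  # duplicated symmetry mates do not inflate the count
  dup <- rbind(full, data.frame(h = -full$h, k = -full$k, l = -full$l, d = full$d))
  expect_equal(completeness(dup, cell, d_max = 30, d_min = 4), 100)
})

test_that("observation tables round-trip through plain text", {
  obs <- data.frame(h = c(1L, 2L), k = c(0L, 1L), l = c(3L, 4L),
                    I = c(12.5, 8), sigma = c(1.1, 0.9))
  path <- withr::local_tempfile(fileext = ".txt")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back, obs)
})
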