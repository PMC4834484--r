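# Still-diffraction spot simulation for tetragonal crystals: reciprocal
# lattice rotated by a random orientation, kept where it grazes the Ewald
# sphere, projected to the flat detector.

#' Tetragonal crystal model for spot simulation
#'
#' Only the tetragonal case (`a = b`, all angles 90°, Laue class 4/mmm) is
#' supported; defaults follow a lysozyme-like cell. `screw_absences`
#' applies the reflection conditions of space group P4\out{<sub>3</sub>}2\out{<sub>1</sub>}2:
#' 00l present only for l = 4n, h00 (and 0k0) present only for even h.
#'
#' @param cell Numeric length-6: a, b, c (Å), alpha, beta, gamma (deg).
#' @param laue_group Laue class label; only `"4/mmm"` is supported.
#' @param screw_absences Drop systematically absent reflections when
#'   simulating spots (default `TRUE`).
#' @param d_min High-resolution cutoff for generated reflections (Å).
#' @param excitation_halfwidth Maximum distance of a reciprocal-lattice
#'   point from the Ewald sphere for it to diffract (1/Å). A crude stand-in
#'   for beam bandwidth/divergence and crystal mosaicity in still patterns.
#' @param spot_sigma Rendered spot width on the detector (pixels).
#' @param mean_spot_photons Mean integrated photons per spot (intensities
#'   are drawn exponentially, a Wilson-like heavy-tailed choice).
#' @return An object of class `crystal_model`.
#' @export
crystal_model <- function(cell = c(79.1, 79.1, 38.0, 90, 90, 90),
                          laue_group = "4/mmm", screw_absences = TRUE,
                          d_min = 2.5, excitation_halfwidth = 0.002,
                          spot_sigma = 1.2, mean_spot_photons = 500) {
  cell <- as.numeric(cell)
  if (length(cell) != 6L || any(!is.finite(cell)) || any(cell[1:3] <= 0)) {
    stop("cell must be (a, b, c, alpha, beta, gamma) with positive lengths")
  }
  if (!isTRUE(all.equal(cell[1], cell[2])) ||
      !isTRUE(all.equal(cell[4:6], c(90, 90, 90)))) {
    stop("only tetragonal cells are supported (a = b, angles 90)")
  }
  if (!identical(laue_group, "4/mmm")) stop("unsupported Laue group: ", laue_group)
  stopifnot(d_min > 0, excitation_halfwidth > 0, spot_sigma > 0,
            mean_spot_photons > 0)
  structure(list(cell = cell, laue_group = laue_group,
                 screw_absences = isTRUE(screw_absences), d_min = d_min,
                 excitation_halfwidth = excitation_halfwidth,
                 spot_sigma = spot_sigma,
                 mean_spot_photons = mean_spot_photons),
            class = "crystal_model")
}

#' Uniform random crystal orientations
#'
#' Samples unit quaternions uniformly on SO(3) by normalising 4-D standard
#' Gaussian vectors.
#'
#' @param n Number of orientations.
#' @return `n x 4` matrix of unit quaternions (rows).
#' @export
random_orientation <- function(n = 1L) {
  q <- matrix(stats::rnorm(4L * n), n, 4L)
  nrm <- sqrt(rowSums(q^2))
  while (any(nrm < 1e-12)) { # essentially impossible, but stay safe
    bad <- nrm < 1e-12
    q[bad, ] <- matrix(stats::rnorm(4L * sum(bad)), sum(bad), 4L)
    nrm <- sqrt(rowSums(q^2))
  }
  q / nrm
}

# Rotation matrix from a unit quaternion (w, x, y, z).
.quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# P4_3 2_1 2 reflection-condition filter: TRUE = systematically absent.
.is_absent_p43212 <- function(h, k, l) {
  (h == 0L & k == 0L & l %% 4L != 0L) |
    (k == 0L & l == 0L & h %% 2L != 0L) |
    (h == 0L & l == 0L & k %% 2L != 0L)
}

#' Simulate Bragg spot positions for one still pattern
#'
#' Enumerates all reciprocal-lattice points with `d >= d_min`, rotates them
#' by the crystal orientation, keeps those within `excitation_halfwidth` of
#' the Ewald sphere (still-diffraction condition), and projects the
#' diffracted beams onto the detector plane. Points violating the screw-axis
#' reflection conditions are excluded when `screw_absences` is set; spots
#' falling outside the detector are dropped. Integrated photon counts are
#' drawn from an exponential distribution with mean `mean_spot_photons`
#' using the current RNG state.
#'
#' @param geom A [detector_geometry()].
#' @param crystal A [crystal_model()].
#' @param orientation Unit quaternion (length 4, |q| = 1 within 1e-6).
#' @return `data.frame` with one row per spot: `fast`, `slow` (0-based
#'   pixel coordinates), `photons`, `h`, `k`, `l`, `d`.
#' @export
simulate_spots <- function(geom, crystal, orientation) {
  stopifnot(inherits(geom, "detector_geometry"), inherits(crystal, "crystal_model"))
  orientation <- as.numeric(orientation)
  if (length(orientation) != 4L || abs(sqrt(sum(orientation^2)) - 1) > 1e-6) {
    stop("orientation must be a unit quaternion (length 4)")
  }
  a <- crystal$cell[1]; c_ <- crystal$cell[3]
  lam <- geometry_wavelength(geom)
  hmax <- floor(a / crystal$d_min)
  lmax <- floor(c_ / crystal$d_min)
  empty <- data.frame(fast = numeric(0), slow = numeric(0), photons = numeric(0),
                      h = integer(0), k = integer(0), l = integer(0), d = numeric(0))
  if (hmax < 1L && lmax < 1L) return(empty)
  hs <- seq.int(-hmax, hmax)
  ls <- seq.int(-lmax, lmax)
  grid <- expand.grid(h = hs, k = hs, l = ls, KEEP.OUT.ATTRS = FALSE)
  h <- grid$h; k <- grid$k; l <- grid$l
  keep <- !(h == 0L & k == 0L & l == 0L)
  q2 <- (h^2 + k^2) / a^2 + l^2 / c_^2
  keep <- keep & q2 <= 1 / crystal$d_min^2
  if (crystal$screw_absences) keep <- keep & !.is_absent_p43212(h, k, l)
  if (!any(keep)) return(empty)
  h <- h[keep]; k <- k[keep]; l <- l[keep]
  g0 <- cbind(h / a, k / a, l / c_)
  R <- .quat_to_matrix(orientation)
  g <- g0 %*% t(R)
  kz <- 1 / lam + g[, 3]
  knorm <- sqrt(g[, 1]^2 + g[, 2]^2 + kz^2)
  hit <- abs(knorm - 1 / lam) <= crystal$excitation_halfwidth & kz > 0
  if (!any(hit)) return(empty)
  h <- h[hit]; k <- k[hit]; l <- l[hit]
  gx <- g[hit, 1]; gy <- g[hit, 2]; kz <- kz[hit]
  fast <- geom$beam_center_fast + (gx / kz) * geom$camera_length / geom$pixel_size
  slow <- geom$beam_center_slow + (gy / kz) * geom$camera_length / geom$pixel_size
  on <- fast >= -0.5 & fast <= geom$n_fast - 0.5 &
        slow >= -0.5 & slow <= geom$n_slow - 0.5
  if (!any(on)) return(empty)
  h <- h[on]; k <- k[on]; l <- l[on]
  fast <- fast[on]; slow <- slow[on]
  d <- 1 / sqrt((h^2 + k^2) / a^2 + l^2 / c_^2)
  photons <- stats::rexp(length(fast), rate = 1 / crystal$mean_spot_photons)
  data.frame(fast = fast, slow = slow, photons = photons,
             h = as.integer(h), k = as.integer(k), l = as.integer(l), d = d)
}

# Add isotropic Gaussian spots (sigma in px, truncated at 4 sigma) to an
# expectation image; each spot's kernel is normalised so its rendered sum
# equals the spot's integrated photons.
.render_spots <- function(img, spots, sigma) {
  if (!nrow(spots)) return(img)
  ns <- nrow(img); nf <- ncol(img)
  half <- ceiling(4 * sigma)
  off <- seq.int(-half, half)
  for (i in seq_len(nrow(spots))) {
    cf <- spots$fast[i]; cs <- spots$slow[i]
    fc <- round(cf); sc <- round(cs)
    fi <- fc + off; si <- sc + off
    okf <- fi >= 0L & fi < nf; oks <- si >= 0L & si < ns
    if (!any(okf) || !any(oks)) next
    fi <- fi[okf]; si <- si[oks]
    w <- exp(-outer((si - cs)^2, (fi - cf)^2, "+") / (2 * sigma^2))
    img[si + 1L, fi + 1L] <- img[si + 1L, fi + 1L] +
      spots$photons[i] * w / sum(w)
  }
  img
}
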