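# Detector metrology: beam parameters and pixel coordinates -> scattering
# angle and d-spacing; resolution-shell construction for radial averaging.

# hc in keV * Angstrom; 5-significant-figure standard value.
.hc_keV_A <- 12.3984

#' Convert photon energy to X-ray wavelength
#'
#' Uses `lambda = hc / E` with `hc = 12.3984` keV·Å, so 7 keV gives the
#' 1.77 Å wavelength typical of SFX experiments at SACLA BL3.
#'
#' @param energy Photon energy in keV (positive, finite; vectorised).
#' @return Wavelength in Å.
#' @examples
#' energy_to_wavelength(7)        # ~1.77
#' wavelength_to_energy(1.0)      # 12.3984
#' @seealso [wavelength_to_energy()]
#' @export
energy_to_wavelength <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0)) {
    stop("photon energy must be positive and finite (keV)")
  }
  .hc_keV_A / energy
}

#' @rdname energy_to_wavelength
#' @param wavelength Wavelength in Å (positive, finite; vectorised).
#' @export
wavelength_to_energy <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("wavelength must be positive and finite (Angstrom)")
  }
  .hc_keV_A / wavelength
}

#' Flat-detector geometry description
#'
#' A minimal single-panel detector metrology: pixel grid, pixel pitch,
#' sample-to-detector distance, beam centre and photon energy. Pixel
#' coordinates are 0-based and refer to pixel centres; the beam centre may
#' be fractional. The detector is assumed flat and normal to the beam.
#'
#' @param n_fast,n_slow Pixel counts along the fast and slow axes (>= 1).
#' @param pixel_size Pixel edge length in mm.
#' @param camera_length Sample-to-detector distance in mm.
#' @param beam_center_fast,beam_center_slow Beam position in (fractional)
#'   pixel units along the fast / slow axis.
#' @param photon_energy Photon energy in keV.
#' @param mask Optional logical matrix (`n_slow` x `n_fast`); `TRUE` marks a
#'   valid pixel. Masked (invalid) pixels are excluded from all statistics.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(64, 64, 0.2, 50, 31.5, 31.5, 7)
#' range(pixel_resolution_map(geom))
#' @export
detector_geometry <- function(n_fast, n_slow, pixel_size, camera_length,
                              beam_center_fast, beam_center_slow,
                              photon_energy, mask = NULL) {
  n_fast <- as.integer(n_fast)
  n_slow <- as.integer(n_slow)
  if (is.na(n_fast) || is.na(n_slow) || n_fast < 1L || n_slow < 1L) {
    stop("n_fast and n_slow must be integers >= 1")
  }
  for (nm in c("pixel_size", "camera_length", "photon_energy")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a positive finite scalar", nm))
    }
  }
  for (nm in c("beam_center_fast", "beam_center_slow")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("%s must be a finite scalar (pixels)", nm))
    }
  }
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !identical(dim(mask), c(n_slow, n_fast))) {
      stop("mask must be an n_slow x n_fast matrix")
    }
    mask <- matrix(as.logical(mask), n_slow, n_fast)
    if (anyNA(mask)) stop("mask must not contain NA")
  }
  wl <- energy_to_wavelength(photon_energy)
  if (!is.finite(wl) || wl <= 0) stop("derived wavelength is not positive and finite")
  structure(
    list(n_fast = n_fast, n_slow = n_slow, pixel_size = pixel_size,
         camera_length = camera_length,
         beam_center_fast = beam_center_fast,
         beam_center_slow = beam_center_slow,
         photon_energy = photon_energy, mask = mask),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d px, %.4g mm/px, L = %.4g mm\n",
              x$n_fast, x$n_slow, x$pixel_size, x$camera_length))
  cat(sprintf("  beam centre (fast, slow) = (%.3f, %.3f) px; E = %.4g keV (lambda = %.4f A)\n",
              x$beam_center_fast, x$beam_center_slow, x$photon_energy,
              energy_to_wavelength(x$photon_energy)))
  if (!is.null(x$mask)) cat(sprintf("  mask: %d valid pixels\n", sum(x$mask)))
  invisible(x)
}

#' Wavelength of a geometry
#' @param geom A [detector_geometry()].
#' @return Wavelength in Å.
#' @export
geometry_wavelength <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  energy_to_wavelength(geom$photon_energy)
}

# radial distance (mm) of every pixel centre from the beam centre;
# matrix is n_slow x n_fast (rows = slow axis).
.pixel_radius_mm <- function(geom) {
  df <- (seq_len(geom$n_fast) - 1 - geom$beam_center_fast) * geom$pixel_size
  ds <- (seq_len(geom$n_slow) - 1 - geom$beam_center_slow) * geom$pixel_size
  sqrt(outer(ds^2, df^2, "+"))
}

#' Per-pixel resolution (d-spacing) map
#'
#' For each pixel centre the in-plane distance `r` from the beam centre
#' gives the scattering angle `2*theta = atan(r / camera_length)` and the
#' resolution `d = lambda / (2 sin theta)` (Bragg's law). A pixel exactly at
#' the beam centre has no finite resolution and maps to `Inf`.
#'
#' @param geom A [detector_geometry()].
#' @return Numeric matrix (`n_slow` x `n_fast`) of d-spacings in Å.
#' @export
pixel_resolution_map <- function(geom) {
  q <- pixel_q_map(geom)
  d <- ifelse(q > 0, 1 / q, Inf)
  d
}

#' Per-pixel momentum-transfer map q = 1/d
#'
#' @inheritParams pixel_resolution_map
#' @return Numeric matrix of `q = 2 sin(theta) / lambda` in 1/Å (0 at the
#'   beam centre).
#' @export
pixel_q_map <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  r <- .pixel_radius_mm(geom)
  tth <- atan(r / geom$camera_length)
  2 * sin(tth / 2) / geometry_wavelength(geom)
}

#' Resolution shells equal-width in q
#'
#' Builds `n_shells` bins spanning the detector's finite resolution range,
#' equal-width in `q = 1/d` (near-uniform pixel counts per shell), and
#' assigns every unmasked finite-resolution pixel to exactly one shell.
#' Masked pixels and a pixel exactly at the beam centre are assigned none.
#'
#' @param geom A [detector_geometry()].
#' @param n_shells Number of shells (>= 1).
#' @return A list with components:
#'   \describe{
#'     \item{scheme}{`shell_scheme` object: `n_shells`, `d_min`, `d_max`,
#'       `edges_q` (length `n_shells + 1`, strictly increasing),
#'       `centers_q`, `centers_d`.}
#'     \item{index}{Integer matrix of shell indices (1-based), `NA` where a
#'       pixel is masked or has no finite resolution.}
#'   }
#' @export
make_shells <- function(geom, n_shells) {
  stopifnot(inherits(geom, "detector_geometry"))
  n_shells <- as.integer(n_shells)
  if (is.na(n_shells) || n_shells < 1L) stop("n_shells must be an integer >= 1")
  q <- pixel_q_map(geom)
  ok <- is.finite(q) & q > 0
  if (!is.null(geom$mask)) ok <- ok & geom$mask
  if (!any(ok)) stop("no unmasked pixel with finite resolution: cannot build shells")
  qmin <- min(q[ok])
  qmax <- max(q[ok])
  if (qmax <= qmin) { # degenerate: all binnable pixels at one q
    qmax <- qmin * (1 + 1e-9)
  }
  edges <- seq(qmin, qmax, length.out = n_shells + 1L)
  idx <- matrix(NA_integer_, geom$n_slow, geom$n_fast)
  idx[ok] <- pmin.int(pmax.int(findInterval(q[ok], edges, rightmost.closed = TRUE),
                               1L), n_shells)
  centers_q <- (edges[-1] + edges[-length(edges)]) / 2
  scheme <- structure(
    list(n_shells = n_shells, d_min = 1 / qmax, d_max = 1 / qmin,
         edges_q = edges, centers_q = centers_q, centers_d = 1 / centers_q),
    class = "shell_scheme"
  )
  list(scheme = scheme, index = idx)
}

#' @export
print.shell_scheme <- function(x, ...) {
  cat(sprintf("<shell_scheme> %d shells, d %.3g-%.3g A (equal-width in q)\n",
              x$n_shells, x$d_max, x$d_min))
  invisible(x)
}

#' Synthetic square detector calibrated to an edge resolution
#'
#' Builds an `n x n` single-panel geometry with the beam at the exact frame
#' centre and the camera length solved so the corner pixel sits at the
#' requested resolution (`d_corner`, default 2.3 Å at 7 keV, mimicking a
#' detector whose edge reaches the 2.3 Å limit of typical SFX data sets).
#'
#' @param n Pixels per side (default 512).
#' @param pixel_size Pixel pitch in mm (default 0.2).
#' @param photon_energy Photon energy in keV (default 7).
#' @param d_corner Resolution at the frame-corner pixel centre, Å.
#' @param mask Optional mask, passed through.
#' @return A [detector_geometry()].
#' @export
default_geometry <- function(n = 512L, pixel_size = 0.2, photon_energy = 7.0,
                             d_corner = 2.3, mask = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  lam <- energy_to_wavelength(photon_energy)
  if (lam / (2 * d_corner) >= 1) stop("d_corner unreachable at this wavelength")
  bc <- (n - 1) / 2
  r_corner <- bc * sqrt(2) * pixel_size
  theta <- asin(lam / (2 * d_corner))
  camera_length <- r_corner / tan(2 * theta)
  detector_geometry(n, n, pixel_size, camera_length, bc, bc, photon_energy,
                    mask = mask)
}

#' Read / write detector geometry as flat JSON
#'
#' The JSON document carries exactly the `detector_geometry` field names;
#' lengths in mm, energy in keV. A mask, if present, is stored as a 0/1
#' matrix under `mask`.
#'
#' @param path File path.
#' @return `read_geometry` returns a [detector_geometry()];
#'   `write_geometry` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  doc <- jsonlite::fromJSON(path)
  need <- c("n_fast", "n_slow", "pixel_size", "camera_length",
            "beam_center_fast", "beam_center_slow", "photon_energy")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("geometry JSON missing field(s): ", paste(miss, collapse = ", "))
  mask <- NULL
  if (!is.null(doc$mask)) {
    mask <- matrix(as.logical(doc$mask), as.integer(doc$n_slow), as.integer(doc$n_fast))
  }
  detector_geometry(doc$n_fast, doc$n_slow, doc$pixel_size, doc$camera_length,
                    doc$beam_center_fast, doc$beam_center_slow,
                    doc$photon_energy, mask = mask)
}

#' @rdname read_geometry
#' @param geom A [detector_geometry()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "detector_geometry"))
  doc <- geom[c("n_fast", "n_slow", "pixel_size", "camera_length",
                "beam_center_fast", "beam_center_slow", "photon_energy")]
  if (!is.null(geom$mask)) doc$mask <- unclass(geom$mask) * 1L
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
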