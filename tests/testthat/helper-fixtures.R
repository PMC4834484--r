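# Small fixtures shared across test files; everything is generated in code.

# compact calibrated geometry (corner at 2.3 A, 7 keV) for fast tests
tiny_geom <- function(n = 32L, ...) default_geometry(n, ...)

# medium with a flat smooth profile and no rings
flat_medium <- function(amplitude = 10, name = "flat") {
  medium_model(name, data.frame(q = c(0, 1), amplitude = rep(amplitude, 2)))
}

# medium with a single ring on a zero (or flat) smooth background
ring_medium <- function(d_center = 14, amplitude = 12, fwhm_q = 0.006,
                        occurrence = 1, base = 0, name = "ring") {
  medium_model(name, data.frame(q = c(0, 1), amplitude = rep(base, 2)),
               data.frame(d_center = d_center, fwhm_q = fwhm_q,
                          amplitude = amplitude, occurrence = occurrence))
}

# build a frame_stack directly from a list of matrices
stack_from_frames <- function(frames, geom = NULL) {
  d <- dim(frames[[1]])
  if (is.null(geom)) {
    geom <- detector_geometry(d[2], d[1], 0.1, 50, (d[2] - 1) / 2,
                              (d[1] - 1) / 2, 7)
  }
  arr <- array(0L, c(d[1], d[2], length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  frame_stack(arr, geom)
}

# independent two-pass mean/sd oracle (per pixel over frames)
two_pass_stats <- function(stack) {
  fr <- stack$frames
  n <- dim(fr)[3]
  m <- apply(fr, c(1, 2), mean)
  s <- apply(fr, c(1, 2), sd)
  list(m = m, s = s, n_total = n)
}

# independent closed-form canonical representative under 4/mmm:
# (max(|h|,|k|), min(|h|,|k|), |l|)
closed_form_canonical <- function(h, k, l) {
  c(max(abs(h), abs(k)), min(abs(h), abs(k)), abs(l))
}
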