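# Synthetic serial-diffraction stacks: medium background + optional Bragg
# spots, Poisson counting noise, and a per-frame ground-truth manifest.

#' Configuration for a simulated frame stack
#'
#' @param n_frames Number of frames (>= 1).
#' @param medium A [medium_model()] or preset name (see [medium_preset()]).
#' @param geometry A [detector_geometry()]; default [default_geometry()].
#' @param hit_fraction Probability that a frame contains crystal
#'   diffraction (requires `crystal` when > 0).
#' @param crystal Optional [crystal_model()].
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce bit-identical stacks.
#' @return An object of class `stack_config`.
#' @export
stack_config <- function(n_frames, medium, geometry = default_geometry(),
                         hit_fraction = 0, crystal = NULL, seed = 1L) {
  if (is.character(medium)) medium <- medium_preset(medium)
  stopifnot(inherits(medium, "medium_model"),
            inherits(geometry, "detector_geometry"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be an integer >= 1")
  if (!is.numeric(hit_fraction) || hit_fraction < 0 || hit_fraction > 1) {
    stop("hit_fraction must lie in [0, 1]")
  }
  if (hit_fraction > 0 && is.null(crystal)) {
    stop("hit_fraction > 0 requires a crystal model")
  }
  if (!is.null(crystal)) stopifnot(inherits(crystal, "crystal_model"))
  structure(list(n_frames = n_frames, medium = medium, geometry = geometry,
                 hit_fraction = hit_fraction, crystal = crystal,
                 seed = as.integer(seed)),
            class = "stack_config")
}

# Per-frame RNG substream seed derived from (seed, frame index); keeps the
# draw for frame i independent of how many frames precede it.
.frame_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 100003 + as.numeric(i) * 7919) %% 2147483629) + 1L
}

#' In-memory frame stack
#'
#' Wraps an integer count array with its geometry and (for simulated
#' stacks) a ground-truth manifest. Frames are stored as an
#' `n_slow x n_fast x n_frames` array.
#'
#' @param frames Non-negative integer array, `n_slow x n_fast x n_frames`.
#' @param geometry A [detector_geometry()] matching the frame shape.
#' @param manifest Optional per-frame `data.frame` (simulated stacks).
#' @param spots Optional list of per-frame spot tables (simulated hits).
#' @param label Dataset label used in reports.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, geometry, manifest = NULL, spots = NULL,
                        label = "stack") {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a 3-d array (n_slow x n_fast x n_frames)")
  }
  d <- dim(frames)
  if (d[1] != geometry$n_slow || d[2] != geometry$n_fast) {
    stop(sprintf("frames shape %dx%d does not match geometry %dx%d",
                 d[1], d[2], geometry$n_slow, geometry$n_fast))
  }
  if (anyNA(frames) || min(frames) < 0) stop("frames must be non-negative counts")
  if (!is.null(manifest) && nrow(manifest) != d[3]) {
    stop("manifest length must equal n_frames")
  }
  structure(list(frames = frames, geometry = geometry, manifest = manifest,
                 spots = spots, label = label),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> '%s': %d frames of %d x %d px%s\n", x$label,
              d[3], d[1], d[2],
              if (is.null(x$manifest)) " (no manifest)" else ""))
  if (!is.null(x$manifest) && "is_hit" %in% names(x$manifest)) {
    cat(sprintf("  hits: %d / %d\n", sum(x$manifest$is_hit), d[3]))
  }
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack A [frame_stack()].
#' @param i Frame index (1-based).
#' @export
get_frame <- function(stack, i) stack$frames[, , i]

#' Simulate a serial-diffraction frame stack
#'
#' Per frame: each ring of the medium is drawn present with its occurrence
#' probability; the frame is a crystal hit with probability `hit_fraction`;
#' the expectation image is the medium background plus rendered Gaussian
#' spots (hits only, random uniform orientation); the observed image is an
#' independent Poisson draw of the expectation. All draws use a per-frame
#' RNG substream derived from `(seed, frame index)`, so identical
#' configurations give bit-identical stacks and the manifest records every
#' draw.
#'
#' @param config A [stack_config()].
#' @param label Dataset label (defaults to the medium name).
#' @return A [frame_stack()] whose `manifest` has columns `frame`,
#'   `is_hit`, `n_spots_rendered`, `q1..q4` (orientation quaternion, NA for
#'   non-hits) and one logical `ring_<d>` column per ring of the medium.
#' @export
simulate_stack <- function(config, label = NULL) {
  stopifnot(inherits(config, "stack_config"))
  geom <- config$geometry
  medium <- config$medium
  n <- config$n_frames
  if (is.null(label)) label <- medium$name
  npx <- geom$n_slow * geom$n_fast

  smooth_img <- background_expectation(geom, medium,
                                       ring_draws = rep(FALSE, nrow(medium$rings)))
  nring <- nrow(medium$rings)
  ring_imgs <- vector("list", nring)
  if (nring) {
    qmap <- pixel_q_map(geom)
    for (j in seq_len(nring)) ring_imgs[[j]] <- .ring_image(qmap, medium$rings[j, ])
  }

  frames <- array(0L, c(geom$n_slow, geom$n_fast, n))
  is_hit <- logical(n)
  n_spots <- integer(n)
  quat <- matrix(NA_real_, n, 4L)
  ring_flags <- matrix(FALSE, n, nring)
  spots_list <- if (config$hit_fraction > 0) vector("list", n) else NULL

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  for (i in seq_len(n)) {
    set.seed(.frame_seed(config$seed, i))
    lambda <- smooth_img
    if (nring) {
      draws <- stats::runif(nring) < medium$rings$occurrence
      ring_flags[i, ] <- draws
      for (j in seq_len(nring)[draws]) lambda <- lambda + ring_imgs[[j]]
    }
    hit <- config$hit_fraction > 0 && stats::runif(1) < config$hit_fraction
    is_hit[i] <- hit
    if (hit) {
      q <- as.numeric(random_orientation(1L))
      quat[i, ] <- q
      sp <- simulate_spots(geom, config$crystal, q)
      n_spots[i] <- nrow(sp)
      spots_list[[i]] <- sp
      lambda <- .render_spots(lambda, sp, config$crystal$spot_sigma)
    }
    frames[, , i] <- stats::rpois(npx, lambda)
  }

  manifest <- data.frame(frame = seq_len(n), is_hit = is_hit,
                         n_spots_rendered = n_spots,
                         q1 = quat[, 1], q2 = quat[, 2],
                         q3 = quat[, 3], q4 = quat[, 4])
  if (nring) {
    rf <- as.data.frame(ring_flags)
    names(rf) <- paste0("ring_", medium$rings$d_center)
    manifest <- cbind(manifest, rf)
  }
  frame_stack(frames, geom, manifest = manifest, spots = spots_list,
              label = label)
}
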