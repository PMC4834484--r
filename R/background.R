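# Core background computation: robust per-pixel statistics with Bragg
# rejection, clean background image, resolution-resolved radial profile,
# cross-dataset scaling, ring detection and media comparison.

#' Per-pixel mean and standard deviation over frames
#'
#' Computes, for every detector pixel, the mean `m` and sample standard
#' deviation `s` (n - 1 denominator) of its values over all frames, in a
#' single numerically stable streaming pass (Welford updates), equivalent
#' to a two-pass computation to ~1e-8 relative. Masked pixels are `NA`.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @return An object of class `pixel_stats`: list with matrices `m`, `s`
#'   and the frame count `n_total`.
#' @export
pixel_stats <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  if (n < 2L) stop("at least 2 frames are required (s is undefined for n < 2)")
  geom <- stack$geometry
  m <- matrix(0, geom$n_slow, geom$n_fast)
  M2 <- matrix(0, geom$n_slow, geom$n_fast)
  for (i in seq_len(n)) {
    x <- stack$frames[, , i]
    delta <- x - m
    m <- m + delta / i
    M2 <- M2 + delta * (x - m)
  }
  s <- sqrt(pmax(M2, 0) / (n - 1))
  if (!is.null(geom$mask)) {
    m[!geom$mask] <- NA_real_
    s[!geom$mask] <- NA_real_
  }
  structure(list(m = m, s = s, n_total = n), class = "pixel_stats")
}

#' Clean background image by m + 3s rejection
#'
#' Removes Bragg-spot contamination: for each pixel, per-frame observations
#' strictly brighter than that pixel's `m + 3s` are rejected and the
#' survivors re-averaged. The rejection is per (pixel, frame) observation,
#' not per detector pixel, so the clean image keeps full spatial coverage.
#' A single pass is used (no iteration); since `m >= min` and `s >= 0`, the
#' minimum observation always survives, so every unmasked pixel retains at
#' least one observation.
#'
#' @param stack A [frame_stack()].
#' @param stats A [pixel_stats()] computed from the same stack (computed on
#'   the fly when omitted).
#' @return An object of class `clean_background`: list with the re-averaged
#'   `image` and the per-pixel surviving-observation count `n_kept`.
#' @export
clean_background <- function(stack, stats = pixel_stats(stack)) {
  stopifnot(inherits(stack, "frame_stack"), inherits(stats, "pixel_stats"))
  geom <- stack$geometry
  if (!identical(dim(stats$m), c(geom$n_slow, geom$n_fast))) {
    stop("pixel_stats shape does not match the stack")
  }
  if (stats$n_total != n_frames(stack)) {
    stop("pixel_stats frame count does not match the stack")
  }
  thr <- stats$m + 3 * stats$s
  acc <- matrix(0, geom$n_slow, geom$n_fast)
  kept <- matrix(0L, geom$n_slow, geom$n_fast)
  masked <- if (!is.null(geom$mask)) !geom$mask else NULL
  if (!is.null(masked)) thr[masked] <- Inf # masked pixels: keep arithmetic NA-free
  for (i in seq_len(n_frames(stack))) {
    x <- stack$frames[, , i]
    keep <- x <= thr
    acc <- acc + x * keep
    kept <- kept + keep
  }
  img <- acc / kept
  if (!is.null(masked)) {
    img[masked] <- NA_real_
    kept[masked] <- NA_integer_
  }
  structure(list(image = img, n_kept = kept), class = "clean_background")
}

#' Radially average an image by resolution shell
#'
#' Unweighted mean of clean-background pixel values over the pixels
#' assigned to each resolution shell of the detector metrology. Shells with
#' no contributing pixel are reported as `NA` (missing), never zero.
#'
#' @param clean A [clean_background()] (or any list with an `image`
#'   matrix).
#' @param geom The [detector_geometry()] the image was recorded on.
#' @param shells Result of [make_shells()] built from the same geometry.
#' @param label Dataset label attached to the profile.
#' @return A `radial_profile`: `data.frame` with columns `shell`,
#'   `d_center`, `q_center`, `mean_intensity`, `n_pixels`, plus attributes
#'   `label`, `scale_factor` (1 when unscaled) and `scheme`.
#' @export
radial_average <- function(clean, geom, shells, label = "dataset") {
  img <- if (is.matrix(clean)) clean else clean$image
  stopifnot(inherits(geom, "detector_geometry"))
  if (!identical(dim(img), c(geom$n_slow, geom$n_fast))) {
    stop("image shape does not match geometry")
  }
  idx <- shells$index
  scheme <- shells$scheme
  if (!identical(dim(idx), dim(img))) stop("shells were not built from this geometry")
  ok <- !is.na(idx) & !is.na(img)
  if (!any(ok)) stop("all shells are empty: nothing to average")
  nb <- scheme$n_shells
  counts <- tabulate(idx[ok], nbins = nb)
  sums <- numeric(nb)
  rs <- rowsum(img[ok], idx[ok])
  sums[as.integer(rownames(rs))] <- rs[, 1]
  mean_int <- ifelse(counts > 0, sums / counts, NA_real_)
  prof <- data.frame(shell = seq_len(nb), d_center = scheme$centers_d,
                     q_center = scheme$centers_q, mean_intensity = mean_int,
                     n_pixels = counts)
  attr(prof, "label") <- label
  attr(prof, "scale_factor") <- 1
  attr(prof, "scheme") <- scheme
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

.profile_values <- function(p) {
  if ("scaled_intensity" %in% names(p)) p$scaled_intensity else p$mean_intensity
}

#' Scale radial profiles to a common highest-resolution anchor
#'
#' The first profile is the reference (its factor is 1); every other
#' profile is multiplied so that its value at the highest-resolution
#' (smallest d) shell equals the reference's. After scaling all profiles
#' agree exactly at that anchor shell. Scaling already-scaled profiles is a
#' no-op.
#'
#' @param profiles List of >= 2 `radial_profile`s on a common shell scheme.
#' @return The list with a `scaled_intensity` column and updated
#'   `scale_factor` attributes.
#' @export
scale_profiles <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to scale")
  schemes <- lapply(profiles, attr, "scheme")
  ref_edges <- schemes[[1]]$edges_q
  for (sc in schemes[-1]) {
    if (!isTRUE(all.equal(sc$edges_q, ref_edges))) {
      stop("profiles are not on a common shell scheme")
    }
  }
  anchor <- schemes[[1]]$n_shells # highest-resolution (smallest d) shell
  vals <- vapply(profiles, function(p) .profile_values(p)[anchor], numeric(1))
  if (any(!is.finite(vals)) || any(vals == 0)) {
    stop("missing or zero value in the highest-resolution anchor shell")
  }
  factors <- vals[1] / vals
  Map(function(p, f) {
    p$scaled_intensity <- .profile_values(p) * f
    attr(p, "scale_factor") <- attr(p, "scale_factor") * f
    p
  }, profiles, factors)
}

#' Detect sharp rings in a radial profile
#'
#' Subtracts a smooth baseline (moving median, default window 11 shells)
#' and reports local maxima of the residual whose height exceeds
#' `min_prominence`. Sharp powder-like rings survive the median baseline
#' while broad diffuse bands do not.
#'
#' @param profile A `radial_profile` with at least 5 shells.
#' @param window Odd moving-median window in shells (default 11).
#' @param min_prominence Minimum residual height (photons/pixel, on the
#'   profile's current intensity scale) for a peak to be reported.
#' @return `data.frame` with columns `d`, `q`, `shell`, `prominence`,
#'   sorted by descending prominence; zero rows when no ring is found.
#' @export
detect_rings <- function(profile, window = 11L, min_prominence = 1) {
  stopifnot(inherits(profile, "radial_profile"))
  y <- .profile_values(profile)
  ok <- !is.na(y)
  if (sum(ok) < 5L) stop("ring detection needs at least 5 non-missing shells")
  yy <- y[ok]
  d <- profile$d_center[ok]
  q <- profile$q_center[ok]
  sh <- profile$shell[ok]
  window <- min(as.integer(window), length(yy) - (1 - length(yy) %% 2))
  if (window %% 2L == 0L) window <- window - 1L
  window <- max(window, 3L)
  base <- stats::runmed(yy, window, endrule = "median")
  res <- yy - base
  n <- length(res)
  peak <- which(res[-c(1, n)] > res[-c(n - 1, n)] &
                res[-c(1, n)] >= res[-c(1, 2)]) + 1L
  peak <- peak[res[peak] > min_prominence]
  out <- data.frame(d = d[peak], q = q[peak], shell = sh[peak],
                    prominence = res[peak])
  out[order(-out$prominence), , drop = FALSE]
}

#' Per-frame presence of an intermittent ring
#'
#' Classifies each frame of a stack as ring-present/absent at a given ring
#' position. First the stack's mean image is radially averaged and
#' [detect_rings()] must find a ring within one shell of `d_center`;
#' otherwise every frame is reported ring-free (broad diffuse features do
#' not survive the moving-median baseline, so they cannot masquerade as an
#' intermittent ring). When a ring is present, the per-frame statistic is
#' the median counts over the shells covering the ring minus the average
#' of the two flanking-shell medians (local linear baseline); frames whose
#' statistic exceeds half the largest statistic are flagged. Medians make
#' the statistic robust to Bragg spots.
#'
#' @param stack A [frame_stack()].
#' @param geom Its [detector_geometry()] (defaults to the stack's).
#' @param shells Result of [make_shells()]; default 100 shells.
#' @param d_center Ring position (Å).
#' @param fwhm_q Ring width used to pick covering shells (1/Å).
#' @param min_prominence Stack-level ring-detection floor, passed to
#'   [detect_rings()] (photons/pixel in the mean image).
#' @return List with `flags` (logical per frame), `prevalence` (fraction of
#'   flagged frames), `stat` (per-frame statistic), `threshold` and
#'   `ring_detected`.
#' @export
ring_prevalence <- function(stack, geom = stack$geometry,
                            shells = make_shells(geom, 100L),
                            d_center, fwhm_q = 0.006,
                            min_prominence = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  q0 <- 1 / d_center
  centers <- shells$scheme$centers_q
  width <- diff(shells$scheme$edges_q[1:2])
  in_ring <- which(abs(centers - q0) <= pmax(fwhm_q, width) / 1.999)
  if (!length(in_ring)) in_ring <- which.min(abs(centers - q0))
  gap <- max(3L, ceiling(2 * fwhm_q / width))
  lo <- min(in_ring) - gap
  hi <- max(in_ring) + gap
  sides <- list(lo = lo[lo >= 1L], hi = hi[hi <= shells$scheme$n_shells])
  if (!length(unlist(sides))) stop("ring shells have no usable flanking baseline")
  idx <- shells$index
  ring_px <- which(!is.na(idx) & matrix(idx %in% in_ring, nrow(idx), ncol(idx)))
  side_px <- lapply(sides, function(s) {
    if (!length(s)) integer(0) else which(!is.na(idx) & matrix(idx == s, nrow(idx), ncol(idx)))
  })
  side_px <- side_px[lengths(side_px) > 0]
  n <- n_frames(stack)
  stat <- numeric(n)
  mean_img <- matrix(0, geom$n_slow, geom$n_fast)
  for (i in seq_len(n)) {
    x <- stack$frames[, , i]
    mean_img <- mean_img + x
    base <- mean(vapply(side_px, function(px) stats::median(x[px]), numeric(1)))
    stat[i] <- stats::median(x[ring_px]) - base
  }
  mean_img <- mean_img / n
  prof <- radial_average(list(image = mean_img), geom, shells, label = stack$label)
  rings <- detect_rings(prof, min_prominence = min_prominence)
  ring_detected <- nrow(rings) > 0 && any(abs(rings$q - q0) <= pmax(fwhm_q, width))
  threshold <- if (!ring_detected) Inf else max(stat) / 2
  flags <- stat > threshold
  list(flags = flags, prevalence = mean(flags), stat = stat,
       threshold = threshold, ring_detected = ring_detected)
}

#' Full background analysis of one stack
#'
#' Convenience chain: [pixel_stats()] -> [clean_background()] ->
#' [radial_average()].
#'
#' @param stack A [frame_stack()].
#' @param n_shells Number of resolution shells (default 100).
#' @param shells Optional precomputed [make_shells()] result.
#' @return A `radial_profile` (see [radial_average()]).
#' @export
analyze_stack <- function(stack, n_shells = 100L,
                          shells = make_shells(stack$geometry, n_shells)) {
  st <- pixel_stats(stack)
  cb <- clean_background(stack, st)
  radial_average(cb, stack$geometry, shells, label = stack$label)
}

#' Compare background scattering across carrier media
#'
#' Runs the full chain per stack (per-pixel statistics, m + 3s clean
#' background, radial averaging), scales all profiles to a common
#' highest-resolution anchor, detects rings on the scaled profiles, and
#' summarises the scaled intensity in the diagnostic resolution bands
#' (5–4 Å and 3.5–2.5 Å by default). Inputs given as [stack_config()]s are
#' simulated on demand and released after analysis, so only one full stack
#' is held in memory at a time.
#'
#' @param inputs List of [frame_stack()] and/or [stack_config()] objects
#'   (>= 2), all on the same geometry.
#' @param n_shells Number of resolution shells (default 100).
#' @param bands Named list of `c(d_max, d_min)` resolution bands (Å).
#' @param ring_args List of extra arguments for [detect_rings()].
#' @param prevalence Optional named list mapping a dataset label to a ring
#'   position (Å); for matching stacks, per-frame ring presence is
#'   estimated with [ring_prevalence()] while the stack is in memory and
#'   compared against the manifest when one is available.
#' @return An object of class `media_comparison`: list with `profiles`
#'   (long `data.frame`), `rings`, `bands`, `scale` and (when requested)
#'   `prevalence` tables.
#' @export
compare_media <- function(inputs, n_shells = 100L,
                          bands = list(band_5_4 = c(5, 4),
                                       band_3.5_2.5 = c(3.5, 2.5)),
                          ring_args = list(), prevalence = NULL) {
  if (length(inputs) < 2L) stop("need at least 2 stacks or configurations")
  geom <- NULL
  profiles <- vector("list", length(inputs))
  prev_rows <- list()
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    if (inherits(x, "stack_config")) {
      stack <- simulate_stack(x)
      simulated <- TRUE
    } else if (inherits(x, "frame_stack")) {
      stack <- x
      simulated <- FALSE
    } else {
      stop("inputs must be frame_stack or stack_config objects")
    }
    g <- stack$geometry
    if (is.null(geom)) {
      geom <- g
      shells <- make_shells(geom, n_shells)
    } else if (!identical(g[c("n_fast", "n_slow", "pixel_size", "camera_length")],
                          geom[c("n_fast", "n_slow", "pixel_size", "camera_length")])) {
      stop("all stacks must share a common geometry")
    }
    profiles[[i]] <- analyze_stack(stack, shells = shells)
    if (!is.null(prevalence) && stack$label %in% names(prevalence)) {
      d0 <- prevalence[[stack$label]]
      rp <- ring_prevalence(stack, shells = shells, d_center = d0)
      man_col <- paste0("ring_", d0)
      has_man <- !is.null(stack$manifest) && man_col %in% names(stack$manifest)
      prev_rows[[length(prev_rows) + 1L]] <- data.frame(
        dataset = stack$label, d_center = d0, prevalence = rp$prevalence,
        n_frames = n_frames(stack),
        manifest_prevalence = if (has_man) mean(stack$manifest[[man_col]]) else NA_real_,
        agreement = if (has_man) mean(rp$flags == stack$manifest[[man_col]]) else NA_real_)
    }
    if (simulated) { rm(stack); gc(FALSE) }
  }
  if (length(unique(vapply(profiles, attr, "", "label"))) < length(profiles)) {
    for (i in seq_along(profiles)) {
      attr(profiles[[i]], "label") <-
        paste0(attr(profiles[[i]], "label"), "_", i)
    }
  }
  scaled <- scale_profiles(profiles)
  labels <- vapply(scaled, attr, "", "label")

  long <- do.call(rbind, Map(function(p, lab) {
    data.frame(dataset = lab, shell_index = p$shell, d_center_A = p$d_center,
               q_center_invA = p$q_center, mean_intensity = p$mean_intensity,
               scaled_intensity = p$scaled_intensity,
               scale_factor = attr(p, "scale_factor"))
  }, scaled, labels))

  rings <- do.call(rbind, Map(function(p, lab) {
    r <- do.call(detect_rings, c(list(p), ring_args))
    if (nrow(r)) cbind(dataset = lab, r) else NULL
  }, scaled, labels))
  if (is.null(rings)) {
    rings <- data.frame(dataset = character(0), d = numeric(0), q = numeric(0),
                        shell = integer(0), prominence = numeric(0))
  }

  band_rows <- lapply(names(bands), function(bn) {
    dmx <- max(bands[[bn]]); dmn <- min(bands[[bn]])
    means <- vapply(scaled, function(p) {
      sel <- p$d_center <= dmx & p$d_center >= dmn & !is.na(p$scaled_intensity)
      mean(p$scaled_intensity[sel])
    }, numeric(1))
    data.frame(dataset = labels, band = bn, d_max = dmx, d_min = dmn,
               mean_scaled_intensity = means)
  })
  band_df <- do.call(rbind, band_rows)

  structure(list(
    profiles = long,
    rings = rings,
    bands = band_df,
    scale = data.frame(dataset = labels,
                       scale_factor = vapply(scaled, attr, numeric(1), "scale_factor")),
    prevalence = if (length(prev_rows)) do.call(rbind, prev_rows) else NULL
  ), class = "media_comparison")
}

#' @export
print.media_comparison <- function(x, ...) {
  cat("<media_comparison>\n")
  cat("  scale factors:\n")
  print(x$scale, row.names = FALSE)
  cat("  detected rings:\n")
  if (nrow(x$rings)) print(x$rings, row.names = FALSE) else cat("   (none)\n")
  cat("  band summary (scaled intensity):\n")
  print(x$bands, row.names = FALSE)
  if (!is.null(x$prevalence)) {
    cat("  ring prevalence:\n")
    print(x$prevalence, row.names = FALSE)
  }
  invisible(x)
}
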