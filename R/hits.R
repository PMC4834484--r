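# Spot finding on single frames and hit / indexing-rate bookkeeping.

#' Find Bragg spots on a single frame
#'
#' Subtracts the clean background, flags pixels whose excess signal exceeds
#' `snr_min` Poisson standard deviations of the background
#' (`sqrt(max(background, 1))`), groups candidate pixels into 8-connected
#' components, and keeps components with at least `min_pix` pixels.
#' Centroids are signal-weighted mean positions in 0-based pixel units.
#'
#' @param image Count matrix (one frame).
#' @param background Clean background image of the same shape (matrix or
#'   [clean_background()]).
#' @param snr_min Signal-to-noise threshold (default 5).
#' @param min_pix Minimum pixels per spot (default 2).
#' @return `data.frame` with one row per spot: `fast`, `slow` (centroid),
#'   `intensity` (integrated background-subtracted counts), `n_pixels`.
#' @export
find_spots <- function(image, background, snr_min = 5, min_pix = 2L) {
  bg <- if (is.matrix(background)) background else background$image
  if (!identical(dim(image), dim(bg))) {
    stop("image and background must have the same shape")
  }
  sig <- image - bg
  noise <- sqrt(pmax(bg, 1))
  cand <- which(!is.na(sig) & sig > snr_min * noise)
  empty <- data.frame(fast = numeric(0), slow = numeric(0),
                      intensity = numeric(0), n_pixels = integer(0))
  if (!length(cand)) return(empty)
  ns <- nrow(image)
  row <- (cand - 1L) %% ns + 1L
  col <- (cand - 1L) %/% ns + 1L
  pos <- match(cand, cand) # identity, but keeps the mapping explicit
  # edges to E, S, SE, SW neighbours that are also candidates (8-connectivity)
  edges <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nr <- row + off[1]; nc <- col + off[2]
    valid <- nr >= 1L & nr <= ns & nc >= 1L & nc <= ncol(image)
    nb <- (nc - 1L) * ns + nr
    j <- match(nb, cand)
    keep <- valid & !is.na(j)
    if (any(keep)) edges <- rbind(edges, cbind(pos[keep], j[keep]))
  }
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  w <- sig[cand]
  sums <- rowsum(cbind(w, w * (col - 1L), w * (row - 1L)), comp)
  sizes <- tabulate(comp, nbins = max(comp))
  keep <- sizes >= as.integer(min_pix)
  if (!any(keep)) return(empty)
  out <- data.frame(fast = sums[keep, 2] / sums[keep, 1],
                    slow = sums[keep, 3] / sums[keep, 1],
                    intensity = sums[keep, 1],
                    n_pixels = sizes[keep])
  out[order(-out$intensity), , drop = FALSE]
}

#' Classify a frame as a crystal hit
#'
#' A frame is accepted as a hit when it has strictly more than `min_spots`
#' spots (default 20, the standard SFX hit criterion).
#'
#' @param spots A spot table from [find_spots()] or a spot count.
#' @param min_spots Threshold (strict; default 20).
#' @return Logical flag.
#' @export
classify_hit <- function(spots, min_spots = 20L) {
  n <- if (is.data.frame(spots)) nrow(spots) else as.integer(spots)
  n > min_spots
}

# round half-up to `digits` decimals (printed-rate convention; R's round()
# is round-half-even).
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Hit and indexing rate summary
#'
#' Rates are percentages of collected images, reported rounded half-up to
#' one decimal — the convention that reproduces printed indexing rates from
#' printed image counts.
#'
#' @param n_collected Number of collected images (> 0).
#' @param n_hits Number of hit images (optional, `NA` if unknown).
#' @param n_indexed Number of indexed images (optional). Indexing itself is
#'   performed by external programs; only the bookkeeping is done here.
#' @return An object of class `rate_summary`: list with the counts plus
#'   `hit_rate` and `indexing_rate` in percent (NA where the count is NA).
#' @export
rate_summary <- function(n_collected, n_hits = NA_integer_,
                         n_indexed = NA_integer_) {
  if (!is.numeric(n_collected) || is.na(n_collected) || n_collected <= 0) {
    stop("n_collected must be a positive count")
  }
  for (v in list(n_hits, n_indexed)) {
    if (!is.na(v) && (v < 0 || v > n_collected)) {
      stop("counts must satisfy 0 <= n_indexed <= n_hits <= n_collected")
    }
  }
  if (!is.na(n_hits) && !is.na(n_indexed) && n_indexed > n_hits) {
    stop("counts must satisfy 0 <= n_indexed <= n_hits <= n_collected")
  }
  structure(list(
    n_collected = n_collected, n_hits = n_hits, n_indexed = n_indexed,
    hit_rate = if (is.na(n_hits)) NA_real_ else .round_half_up(100 * n_hits / n_collected),
    indexing_rate = if (is.na(n_indexed)) NA_real_ else .round_half_up(100 * n_indexed / n_collected)
  ), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary> collected %s", format(x$n_collected, big.mark = ",")))
  if (!is.na(x$n_hits)) cat(sprintf(", hits %s (%.1f%%)",
                                    format(x$n_hits, big.mark = ","), x$hit_rate))
  if (!is.na(x$n_indexed)) cat(sprintf(", indexed %s (%.1f%%)",
                                       format(x$n_indexed, big.mark = ","), x$indexing_rate))
  cat("\n")
  invisible(x)
}

#' Spot statistics for every frame of a stack
#'
#' Runs [find_spots()] against the stack's own clean background and applies
#' the hit criterion per frame.
#'
#' @param stack A [frame_stack()].
#' @param snr_min,min_pix Passed to [find_spots()].
#' @param min_spots Passed to [classify_hit()].
#' @return List with `per_frame` (`data.frame`: `frame`, `n_spots`,
#'   `is_hit`) and the [rate_summary()] over the stack (hits only;
#'   `n_indexed` stays NA).
#' @export
hit_stats <- function(stack, snr_min = 5, min_pix = 2L, min_spots = 20L) {
  stopifnot(inherits(stack, "frame_stack"))
  cb <- clean_background(stack)
  n <- n_frames(stack)
  n_spots <- integer(n)
  for (i in seq_len(n)) {
    n_spots[i] <- nrow(find_spots(stack$frames[, , i], cb,
                                  snr_min = snr_min, min_pix = min_pix))
  }
  is_hit <- n_spots > as.integer(min_spots)
  list(per_frame = data.frame(frame = seq_len(n), n_spots = n_spots,
                              is_hit = is_hit),
       rates = rate_summary(n, n_hits = sum(is_hit)))
}
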