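# HDF5 persistence for frame stacks: /frames (n_frames x n_slow x n_fast,
# unsigned counts, C order), /manifest subgroup, /geometry attributes.

#' Write a frame stack to HDF5
#'
#' Layout: dataset `/frames` with C-order dimensions
#' `n_frames x n_slow x n_fast` (integer counts); group `/manifest` with
#' per-frame datasets (`is_hit`, `n_spots_rendered`, `orientation`, ring
#' flags) when the stack carries a manifest; group `/geometry` whose
#' attributes mirror the geometry JSON schema (lengths mm, energy keV).
#'
#' @param stack A [frame_stack()].
#' @param path Output file (overwritten).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fr <- stack$frames
  storage.mode(fr) <- "integer"
  # R is column-major, HDF5 row-major: writing a (n_fast, n_slow, n_frames)
  # R array yields C-order (n_frames, n_slow, n_fast) in the file.
  rhdf5::h5write(aperm(fr, c(2, 1, 3)), path, "frames")
  g <- stack$geometry
  rhdf5::h5createGroup(path, "geometry")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "geometry")
  for (nm in c("n_fast", "n_slow", "pixel_size", "camera_length",
               "beam_center_fast", "beam_center_slow", "photon_energy")) {
    rhdf5::h5writeAttribute(g[[nm]], gid, nm)
  }
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  man <- stack$manifest
  if (!is.null(man)) {
    rhdf5::h5createGroup(path, "manifest")
    rhdf5::h5write(as.integer(man$is_hit), path, "manifest/is_hit")
    rhdf5::h5write(as.integer(man$n_spots_rendered), path,
                   "manifest/n_spots_rendered")
    quat <- as.matrix(man[, c("q1", "q2", "q3", "q4")])
    rhdf5::h5write(quat, path, "manifest/orientation")
    ring_cols <- grep("^ring_", names(man), value = TRUE)
    if (length(ring_cols)) {
      rhdf5::h5write(sapply(man[ring_cols], as.integer), path,
                     "manifest/rings_present")
      rhdf5::h5write(sub("^ring_", "", ring_cols), path, "manifest/ring_d")
    }
  }
  invisible(path)
}

#' Read a frame stack from HDF5
#'
#' Inverse of [write_stack()]: the round trip reproduces counts and
#' manifest exactly. Files without a `/manifest` group load with the
#' manifest marked absent (real-data mode). Frames containing negative
#' values are rejected.
#'
#' @param path HDF5 file written by [write_stack()] (or following the same
#'   layout).
#' @param label Dataset label for the returned stack.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, label = sub("\\.h5$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  paths <- file.path(ls$group, ls$name)
  if (!any(paths %in% c("//frames", "/frames"))) {
    stop("format error: missing dataset 'frames'")
  }
  fr <- rhdf5::h5read(path, "frames")
  if (length(dim(fr)) != 3L) stop("format error: 'frames' must be 3-dimensional")
  fr <- aperm(fr, c(2, 1, 3))
  if (min(fr) < 0) stop("format error: 'frames' contains negative counts")
  storage.mode(fr) <- "integer"
  has_geo <- any(grepl("geometry", ls$group) | ls$name == "geometry")
  if (!has_geo) stop("format error: missing group 'geometry'")
  fid <- rhdf5::H5Fopen(path)
  geo_attrs <- lapply(rhdf5::h5readAttributes(fid, "geometry"), as.vector)
  rhdf5::H5Fclose(fid)
  need <- c("n_fast", "n_slow", "pixel_size", "camera_length",
            "beam_center_fast", "beam_center_slow", "photon_energy")
  miss <- setdiff(need, names(geo_attrs))
  if (length(miss)) {
    stop("format error: geometry attribute(s) missing: ",
         paste(miss, collapse = ", "))
  }
  geom <- detector_geometry(geo_attrs$n_fast, geo_attrs$n_slow,
                            geo_attrs$pixel_size, geo_attrs$camera_length,
                            geo_attrs$beam_center_fast,
                            geo_attrs$beam_center_slow,
                            geo_attrs$photon_energy)
  if (dim(fr)[1] != geom$n_slow || dim(fr)[2] != geom$n_fast) {
    stop("format error: 'frames' shape does not match 'geometry' attributes")
  }
  manifest <- NULL
  if (any(paths %in% c("//manifest", "/manifest")) || "manifest" %in% ls$name) {
    is_hit <- as.logical(rhdf5::h5read(path, "manifest/is_hit"))
    nsp <- as.integer(rhdf5::h5read(path, "manifest/n_spots_rendered"))
    quat <- rhdf5::h5read(path, "manifest/orientation")
    manifest <- data.frame(frame = seq_along(is_hit), is_hit = is_hit,
                           n_spots_rendered = nsp, q1 = quat[, 1],
                           q2 = quat[, 2], q3 = quat[, 3], q4 = quat[, 4])
    if (any(paths == "/manifest/rings_present")) {
      rp <- rhdf5::h5read(path, "manifest/rings_present")
      rd <- rhdf5::h5read(path, "manifest/ring_d")
      rp <- matrix(as.logical(rp), nrow = length(is_hit))
      colnames(rp) <- paste0("ring_", rd)
      manifest <- cbind(manifest, as.data.frame(rp))
    }
  }
  frame_stack(fr, geom, manifest = manifest, label = label)
}
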