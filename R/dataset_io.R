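# File I/O: the native frequency-domain dataset container, canonical
# geometry/config serialization, and NIfTI volume export.

PTX_MAGIC <- "PTXDATA1"

#' Write / read a frequency-domain dataset
#'
#' The native on-disk container: a JSON header (geometry, frequencies,
#' provenance, record keys) followed by the complex records as
#' little-endian IEEE-754 doubles (interleaved real/imaginary). The
#' round-trip is lossless: complex values are bit-exact.
#'
#' @param ds an [fd_dataset()].
#' @param path file path (conventional extension `.ptxd`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   reconstructed `fd_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "fd_dataset"))
  keys <- names(ds$data)
  hdr <- jsonlite::toJSON(list(
    magic = PTX_MAGIC,
    geometry = unclass(ds$geometry),
    frequencies_hz = ds$frequencies_hz,
    provenance = ds$provenance,
    n_receivers = n_receivers(ds$geometry),
    keys = keys), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  raw_hdr <- charToRaw(as.character(hdr))
  writeBin(length(raw_hdr), con, size = 4, endian = "little")
  writeBin(raw_hdr, con)
  for (k in keys) {
    v <- ds$data[[k]]
    writeBin(as.vector(rbind(Re(v), Im(v))), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nh <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", nh)),
                            simplifyVector = TRUE)
  if (!identical(hdr$magic, PTX_MAGIC))
    stop_ptx("'%s' is not a paraxtomo dataset file", path)
  g <- hdr$geometry
  geometry <- acquisition_geometry(g$view_angles_deg, g$levels_m,
                                   g$receiver_rows, g$receiver_cols,
                                   g$receiver_pitch, g$row_pitch,
                                   g$propagation_distance, g$aperture)
  ds <- fd_dataset(geometry, hdr$frequencies_hz, hdr$provenance)
  nr <- hdr$n_receivers
  for (k in hdr$keys) {
    buf <- readBin(con, "double", 2 * nr, size = 8, endian = "little")
    ds$data[[k]] <- complex(real = buf[c(TRUE, FALSE)],
                            imaginary = buf[c(FALSE, TRUE)])
  }
  ds
}

#' Canonical geometry serialization
#'
#' Deterministic YAML dump of an acquisition geometry: two geometries that
#' compare equal produce byte-identical dumps.
#'
#' @param geometry an [acquisition_geometry()].
#' @return single YAML string.
#' @export
geometry_to_yaml <- function(geometry) {
  x <- unclass(geometry)
  x <- x[order(names(x))]
  yaml::as.yaml(x, precision = 15)
}

#' Write a volume (with spacing metadata) as NIfTI
#'
#' @param vol numeric array (2D allowed; stored as a one-slice volume).
#' @param spacing per-axis voxel size, m.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, spacing, path) {
  vol <- as.array(vol)
  spacing <- if (length(spacing) == 1L) rep(spacing, length(dim(vol))) else
    spacing[seq_along(dim(vol))]
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing * 1e3        # NIfTI pixdim is in mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return `read_volume_nifti`: list with `vol` (array) and `spacing` (m).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  sp <- RNifti::pixdim(img) * 1e-3
  if (length(d) == 2L) { d <- c(d, 1L); sp <- c(sp, sp[length(sp)]) }
  list(vol = array(as.numeric(img), d), spacing = sp)
}
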