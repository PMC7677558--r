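# Fusion, morphological bone separation, SOS-threshold tissue
# segmentation, ROI statistics and FWHM profiling.

#' Fuse speed-of-sound, attenuation and reflection volumes
#'
#' Voxelwise linear combination
#' `I = alpha * SOS + beta * Atten + gamma_w * Refl` with the typical
#' weights `alpha = 1000, beta = 100, gamma_w = 6`. Volumes are fused in
#' their native units (m/s, dB/m/MHz, normalized reflection envelope), so
#' the weights are unit-dependent and configurable.
#'
#' @param sos,atten,refl co-registered arrays (identical dims).
#' @param alpha,beta,gamma_w fusion weights.
#' @param invert_grayscale if TRUE the fused volume is flipped
#'   (`max - I`), the display convention that highlights connective
#'   tissue.
#' @return fused array.
#' @export
fuse_images <- function(sos, atten, refl, alpha = 1000, beta = 100,
                        gamma_w = 6, invert_grayscale = FALSE) {
  if (!identical(dim(sos), dim(atten)) || !identical(dim(sos), dim(refl)))
    stop_ptx("fusion inputs must share one grid")
  if (alpha == 0 && beta == 0 && gamma_w == 0)
    stop_ptx("at least one fusion weight must be nonzero")
  out <- alpha * sos + beta * atten + gamma_w * refl
  if (invert_grayscale) out <- max(out) - out
  out
}

## structuring-element offsets of a digital ball of given voxel radius
ball_offsets <- function(radius, ndim) {
  r <- ceiling(radius)
  g <- do.call(expand.grid, rep(list(-r:r), ndim))
  g <- as.matrix(g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE])
  unname(g)
}

## shift a logical array by an integer offset, filling with `fill`
shift_mask <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (a in seq_along(d)) {
    s <- off[a]
    src[[a]] <- max(1, 1 - s):min(d[a], d[a] - s)
    dst[[a]] <- src[[a]] + s
  }
  idx_dst <- as.matrix(do.call(expand.grid, dst))
  idx_src <- as.matrix(do.call(expand.grid, src))
  out[idx_dst] <- m[idx_src]
  out
}

#' Binary erosion, dilation and opening with a spherical element
#'
#' n-dimensional morphology via structuring-element shifts: erosion keeps
#' voxels whose whole element fits in the mask (outside the grid counts as
#' background), dilation marks every voxel the element touches, opening is
#' erosion followed by dilation. Opening removes structures smaller than
#' the element and is idempotent.
#'
#' @param mask logical array (2D or 3D).
#' @param radius element radius, voxels.
#' @return logical array.
#' @export
binary_erode <- function(mask, radius = 2) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mask(mask, offs[i, ], fill = FALSE)
  out
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, radius = 2) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(mask, offs[i, ], fill = FALSE)
  out
}

#' @rdname binary_erode
#' @export
binary_opening <- function(mask, radius = 2) {
  binary_dilate(binary_erode(mask, radius), radius)
}

## fill enclosed background cavities: background voxels not face-connected
## to the grid border become foreground (turns a cortical-shell annulus
## into the solid bone region)
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, d)
  ## flood the border-connected background with repeated dilation steps
  border <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  for (a in seq_along(d)) {
    sel <- idx; sel[[a]] <- c(1L, d[a])
    border[as.matrix(do.call(expand.grid, sel))] <- TRUE
  }
  reach <- bg & border
  repeat {
    grown <- reach
    for (a in seq_along(d)) {
      off <- rep(0L, length(d))
      for (s in c(-1L, 1L)) {
        off[a] <- s
        grown <- grown | (shift_mask(reach, off) & bg)
      }
      off[a] <- 0L
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

## largest face-connected component of a logical array
largest_component <- function(mask) {
  d <- dim(mask)
  vox <- which(mask)
  if (length(vox) == 0) return(mask)
  strides <- cumprod(c(1, d[-length(d)]))
  idx_arr <- arrayInd(vox, d)
  edges <- NULL
  for (a in seq_along(d)) {
    nb <- vox + strides[a]
    ok <- idx_arr[, a] < d[a] & (nb %in% vox)
    if (any(ok)) {
      e <- cbind(match(vox[ok], vox), match(nb[ok], vox))
      edges <- rbind(edges, e)
    }
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- array(FALSE, d)
  out[vox[keep]] <- TRUE
  out
}

#' Isolate bone from the attenuation image
#'
#' Threshold (Otsu on the normalized histogram by default, or an explicit
#' value in dB/m/MHz), then morphological opening (erosion followed by
#' dilation) with a spherical element, then optional retention of the
#' largest connected component to suppress disconnected false positives,
#' then optional filling of enclosed cavities. The filling step matters
#' because the trabecular interior attenuates *less* than soft tissue, so
#' thresholding alone keeps only the cortical annulus; the bone as an
#' object is the shell plus what it encloses.
#'
#' @param atten non-negative attenuation volume, dB/m/MHz.
#' @param threshold explicit threshold, or `NULL` for Otsu.
#' @param structuring_radius opening element radius, voxels.
#' @param largest_component_only drop all but the biggest blob.
#' @param fill_interior fill enclosed background cavities.
#' @return logical bone mask.
#' @export
segment_bone_from_attenuation <- function(atten, threshold = NULL,
                                          structuring_radius = 2,
                                          largest_component_only = TRUE,
                                          fill_interior = TRUE) {
  if (any(atten < 0)) stop_ptx("attenuation volume must be non-negative")
  mx <- max(atten)
  if (mx == 0) {
    warning("all-zero attenuation volume: empty bone mask")
    return(array(FALSE, dim(atten)))
  }
  if (is.null(threshold)) {
    norm <- matrix(atten / mx, nrow = dim(atten)[1])
    threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * mx
  }
  mask <- array(atten > threshold, dim(atten))
  mask <- binary_opening(mask, structuring_radius)
  if (largest_component_only && any(mask)) mask <- largest_component(mask)
  if (fill_interior && any(mask)) mask <- fill_holes(mask)
  mask
}

#' Default SOS intervals for tissue segmentation
#'
#' Non-overlapping intervals (m/s) centred on the tabulated tissue values
#' (fat 1437, muscle 1571, cartilage 1655-1664, ligament 1690) with water
#' around the bath speed and the bone shell above 1800 m/s. Skin and the
#' trabecular interior overlap other classes in SOS alone and are not in
#' the default table; pass a custom table to separate them.
#'
#' @return data.frame with columns `label`, `lo`, `hi` (half-open
#'   `[lo, hi)`).
#' @export
default_sos_intervals <- function() {
  data.frame(
    label = c("fat", "water", "muscle", "bone_interior", "cartilage",
              "ligament", "bone_shell"),
    lo = c(1390, 1470, 1535, 1600, 1630, 1675, 1800),
    hi = c(1470, 1535, 1600, 1630, 1675, 1800, Inf),
    stringsAsFactors = FALSE)
}

#' Segment tissues by speed-of-sound intervals
#'
#' Voxelwise interval lookup of the SOS volume; voxels outside every
#' interval are labelled `"other"`.
#'
#' @param sos SOS volume, m/s.
#' @param intervals data.frame(label, lo, hi); intervals must be ordered
#'   and non-overlapping.
#' @return list of class `tissue_label_map`: `labels` (integer array),
#'   `legend` (label per integer code; code 0 = "other"), `intervals`.
#' @export
segment_tissues_by_sos <- function(sos, intervals = default_sos_intervals()) {
  o <- order(intervals$lo)
  intervals <- intervals[o, ]
  if (any(intervals$hi <= intervals$lo) ||
      any(utils::head(intervals$hi, -1) > utils::tail(intervals$lo, -1) + 1e-9))
    stop_ptx("SOS intervals must be non-overlapping and ordered")
  code <- findInterval(as.vector(sos), intervals$lo)
  inside <- code >= 1 & as.vector(sos) < intervals$hi[pmax(code, 1)]
  code[!inside] <- 0L
  structure(list(labels = array(code, dim(sos)),
                 legend = c(other = 0L,
                            stats::setNames(seq_len(nrow(intervals)),
                                            intervals$label)),
                 intervals = intervals),
            class = "tissue_label_map")
}

#' ROI mean, standard deviation and voxel count
#'
#' Cylindrical-disc ROI (default diameter 6 mm) on one slice of a volume;
#' SD is the unbiased sample estimate. `roi_report` evaluates a batch of
#' ROIs (e.g. the same centre on slices 2 mm apart) and aggregates.
#'
#' @param vol numeric array (2D, or 3D with `slice` given).
#' @param spacing voxel size(s), m.
#' @param center ROI centre `(x, y)` in metres, centred coordinates.
#' @param diameter ROI diameter, m.
#' @param slice slice index for 3D volumes.
#' @return list with `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(vol, spacing, center, diameter = 6e-3,
                           slice = NULL) {
  d <- dim(vol)
  if (length(d) == 3) {
    if (is.null(slice)) stop_ptx("3D volume needs a slice index")
    vol <- vol[, , slice]
    d <- dim(vol)
  }
  spacing <- if (length(spacing) == 1L) rep(spacing, 2) else spacing[1:2]
  x <- axis_coords(d[1], spacing[1]) - center[1]
  y <- axis_coords(d[2], spacing[2]) - center[2]
  m <- outer(x^2, y^2, `+`) <= (diameter / 2)^2
  if (!any(m)) stop_ptx("empty ROI at (%g, %g) m", center[1], center[2])
  v <- vol[m]
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' @rdname roi_statistics
#' @param rois list of ROI specs, each `list(name=, center=, diameter=,
#'   slices=)`.
#' @return `roi_report`: data.frame with one row per ROI (mean over its
#'   slices, pooled SD, total voxel count).
#' @export
roi_report <- function(vol, spacing, rois) {
  rows <- lapply(rois, function(r) {
    slices <- r$slices %||% if (length(dim(vol)) == 3) 1L else list(NULL)
    st <- lapply(slices, function(s)
      roi_statistics(vol, spacing, r$center, r$diameter %||% 6e-3,
                     if (is.null(s) || length(dim(vol)) == 2) NULL else s))
    data.frame(name = r$name,
               mean = mean(vapply(st, `[[`, numeric(1), "mean")),
               sd = sqrt(mean(vapply(st, `[[`, numeric(1), "sd")^2)),
               n = sum(vapply(st, `[[`, numeric(1), "n")))
  })
  do.call(rbind, rows)
}

#' Full width at half maximum along a line segment
#'
#' Samples the volume along the segment (bilinear interpolation), locates
#' the unique maximum, finds the two half-maximum crossings by linear
#' interpolation and returns their separation.
#'
#' @param vol 2D array.
#' @param spacing voxel size(s), m.
#' @param p0,p1 segment endpoints, m (centred coordinates).
#' @param n_samples samples along the segment.
#' @return list with `fwhm_mm`, `profile`, `s_mm` (sample positions).
#' @export
fwhm_profile <- function(vol, spacing, p0, p1, n_samples = 400) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 2) else spacing
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  prof <- interp2(vol, spacing, xs, ys)
  L <- sqrt(sum((p1 - p0)^2))
  s <- t * L
  i_max <- which.max(prof)
  if (i_max == 1 || i_max == n_samples)
    stop_ptx("profile has no interior peak (monotone along the segment)")
  half <- (max(prof) + min(prof)) / 2
  cross <- function(idx_range) {
    below <- which(prof[idx_range] < half)
    if (length(below) == 0) return(NA_real_)
    idx_range[if (idx_range[1] < i_max) max(below) else min(below)]
  }
  iL <- cross(seq_len(i_max - 1))
  iR <- cross((i_max + 1):n_samples)
  if (is.na(iL) || is.na(iR))
    stop_ptx("profile does not fall to half maximum on both sides")
  sL <- s[iL] + (half - prof[iL]) / (prof[iL + 1] - prof[iL]) * (s[iL + 1] - s[iL])
  sR <- s[iR] + (half - prof[iR]) / (prof[iR - 1] - prof[iR]) * (s[iR - 1] - s[iR])
  list(fwhm_mm = (sR - sL) * 1e3, profile = prof, s_mm = s * 1e3)
}
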