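# Time-of-flight initialization: straight-ray slowness tomography from the
# unwrapped phase of the lowest-frequency records, solved with a damped
# SART (simultaneous rows-action) sweep. Produces the smooth low-resolution
# speed-of-sound volume that seeds the first frequency-hopping stage.

## separable Gaussian smoothing of a 2D field (reflected borders)
gauss_smooth2 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    mp <- m[idx, , drop = FALSE]
    out <- m
    for (i in seq_len(n))
      out[i, ] <- k %*% mp[i:(i + 2 * r), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(x))))
}

## straight-ray projector for one view: path integrals of a 2D field along
## grid-aligned rays in the rotated frame, interpolated to receiver y
tof_project <- function(field, theta, spacing, recv_y) {
  rot <- rotate_gamma(field + 0i, theta, spacing)
  cols <- Re(colSums(rot)) * spacing[1]
  yc <- axis_coords(ncol(field), spacing[2])
  stats::approx(yc, cols, xout = recv_y, rule = 2)$y
}

tof_backproject <- function(r, theta, spacing, shape, recv_y) {
  yc <- axis_coords(shape[2], spacing[2])
  ## adjoint of the linear interpolation onto receiver positions
  fy <- (recv_y - yc[1]) / spacing[2] + 1
  j0 <- pmin(pmax(floor(fy), 1), shape[2] - 1)
  w <- fy - j0
  colv <- numeric(shape[2])
  for (i in seq_along(r)) {
    colv[j0[i]] <- colv[j0[i]] + (1 - w[i]) * r[i]
    colv[j0[i] + 1] <- colv[j0[i] + 1] + w[i] * r[i]
  }
  rot <- matrix(colv, shape[1], shape[2], byrow = TRUE) * spacing[1]
  Re(rotate_gamma_adjoint(rot + 0i, theta, spacing))
}

## damped SART over all views: solves delays = path integrals of the
## slowness deviation along straight parallel rays, one block per view
tof_sart <- function(delays, spacing, sl_shape, recv_y, n_sweeps = 12,
                     relax = 0.5) {
  views <- as.numeric(names(delays))
  ds <- matrix(0, sl_shape[1], sl_shape[2])
  ones <- matrix(1, sl_shape[1], sl_shape[2])
  row_norm <- col_norm <- list()
  for (th in views) {
    key <- as.character(th)
    row_norm[[key]] <- pmax(tof_project(ones, th, spacing, recv_y), 1e-9)
    col_norm[[key]] <- pmax(tof_backproject(rep(1, length(recv_y)), th,
                                            spacing, sl_shape, recv_y), 1e-9)
  }
  for (sw in seq_len(n_sweeps)) {
    for (th in views) {
      key <- as.character(th)
      r <- delays[[key]] - tof_project(ds, th, spacing, recv_y)
      upd <- tof_backproject(r / row_norm[[key]], th, spacing, sl_shape,
                             recv_y)
      ds <- ds + relax * upd / col_norm[[key]]
    }
  }
  ds
}

#' Time-of-flight straight-ray initialization
#'
#' Derives per-(view, level) arrival delays from the unwrapped phase of
#' the lowest-frequency records relative to the water path, then solves
#' straight-ray slowness tomography (`delays = path integrals of
#' 1/c - 1/c0`) with a damped SART sweep and Gaussian post-smoothing.
#' Returns a smooth low-resolution speed-of-sound medium.
#'
#' @param measured an [fd_dataset()]; the lowest frequency present is used.
#' @param shape,spacing reconstruction grid (2D, or 3D of identical axial
#'   slices) and voxel size, m.
#' @param c0 background speed of sound, m/s.
#' @param n_sweeps SART sweeps over all views.
#' @param relax SART relaxation factor.
#' @param smooth_sigma Gaussian smoothing of the slowness update, voxels.
#' @param config [propagator_config()] for the water-bath reference shot
#'   (the "blank scan" whose phase anchors the delays).
#' @return An [acoustic_medium()] with zero attenuation.
#' @export
tof_initialize <- function(measured, shape, spacing, c0 = 1500,
                           n_sweeps = 12, relax = 0.5, smooth_sigma = 1.5,
                           config = propagator_config()) {
  geometry <- measured$geometry
  views <- geometry$view_angles_deg
  if (length(views) < 8)
    stop_ptx("time-of-flight inversion needs >= 8 views, got %d",
             length(views))
  spacing <- if (length(spacing) == 1L) rep(spacing, length(shape)) else spacing
  f <- min(dataset_keys(measured)$f)
  omega <- 2 * pi * f
  off <- receiver_offsets(geometry)
  nr <- geometry$receiver_rows
  lv <- geometry$levels_m[which.min(abs(geometry$levels_m))]
  ## water-bath reference shot: anchors the delays and removes the
  ## finite-aperture edge-diffraction phase common to every view
  water <- acoustic_medium(array(c0, shape), array(0, shape), spacing, c0)
  ref <- simulate_dataset(water,
                          acquisition_geometry(0, lv, geometry$receiver_rows,
                                               geometry$receiver_cols,
                                               geometry$receiver_pitch,
                                               geometry$row_pitch,
                                               geometry$propagation_distance,
                                               geometry$aperture),
                          f, config)
  dref <- dataset_get(ref, f, 0, lv)
  ## per-view delay profiles over the receiver columns
  delays <- list()
  recv_y <- off$y[seq(1, length(off$y), by = nr)]
  for (th in views) {
    d <- dataset_get(measured, f, th, lv)
    ph <- Arg(d / dref)
    ## average rows, then unwrap across columns
    phm <- matrix(ph, nrow = nr)
    prof <- unwrap_phase(colMeans(phm))
    ## remove any residual whole-cycle offset using the aperture edges
    edge <- mean(c(prof[1:2], prof[length(prof) - 1:0]))
    prof <- prof - 2 * pi * round(edge / (2 * pi))
    delays[[as.character(th)]] <- -prof / omega
  }
  sl_shape <- shape[1:2]
  ds <- tof_sart(delays, spacing, sl_shape, recv_y, n_sweeps, relax)
  ds <- gauss_smooth2(ds, smooth_sigma)
  ds <- pmax(ds, -0.5 / c0)                  # keep c positive and bounded
  sos2 <- 1 / (1 / c0 + ds)
  sos <- if (length(shape) == 3) array(rep(sos2, shape[3]), shape) else sos2
  acoustic_medium(sos, array(0, shape), spacing, c0)
}
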