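# One-way paraxial (split-step Fourier) propagation of a plane wave through
# a heterogeneous object-function volume. Marching along the first grid
# axis: per slab a transverse spectral diffraction operator, then the thin
# phase screen exp(-i k0 gamma dz), then an absorbing raised-cosine taper in
# the zero-padded margin. Slab fields can be stored for the tangent
# (Jacobian) and adjoint (gradient) marches, which reuse the same operators
# so the adjoint identity holds to machine precision.

.ptx_cache <- new.env(parent = emptyenv())

#' Propagator configuration
#'
#' @param pad transverse zero-padding, voxels per side.
#' @param taper raised-cosine absorbing taper width, voxels (<= pad); the
#'   taper lives inside the padded margin so it absorbs outgoing scattered
#'   energy without touching the physical aperture.
#' @param variant `"wide_angle"` (spectral phase
#'   `exp(-i dz sqrt(k0^2 - kt^2))`, evanescent components decayed) or
#'   `"fresnel"` (parabolic phase, kept for oracle comparisons).
#' @param splitting `"symmetric"` (half-screen, diffraction, half-screen;
#'   Strang splitting, second-order accurate in the step, the default) or
#'   `"first_order"` (diffraction then full screen).
#' @param min_ppw minimum points per wavelength in water; coarser grids are
#'   rejected.
#' @return Object of class `propagator_config`.
#' @export
propagator_config <- function(pad = 32L, taper = 16L,
                              variant = c("wide_angle", "fresnel"),
                              splitting = c("symmetric", "first_order"),
                              min_ppw = 4) {
  variant <- match.arg(variant)
  splitting <- match.arg(splitting)
  if (pad < taper) stop_ptx("padding (%d) must be >= taper width (%d)",
                            pad, taper)
  structure(list(pad = as.integer(pad), taper = as.integer(taper),
                 variant = variant, splitting = splitting,
                 min_ppw = min_ppw),
            class = "propagator_config")
}

## ---- rotation resampling (view alignment) ----------------------------------

## Bilinear resampling plan rotating the lab x-y frame by theta so the view
## propagation axis is grid-aligned; exact adjoint via weight scatter.
rotation_plan <- function(nx, ny, hx, hy, theta_deg) {
  key <- sprintf("rot|%d|%d|%.12g|%.12g|%.10f", nx, ny, hx, hy, theta_deg)
  if (!is.null(.ptx_cache[[key]])) return(.ptx_cache[[key]])
  th <- theta_deg * pi / 180
  xc <- axis_coords(nx, hx); yc <- axis_coords(ny, hy)
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  xs <- cos(th) * X - sin(th) * Y
  ys <- sin(th) * X + cos(th) * Y
  fi <- xs / hx + (nx + 1) / 2
  fj <- ys / hy + (ny + 1) / 2
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  ok <- i0 >= 1 & i0 + 1 <= nx & j0 >= 1 & j0 + 1 <= ny
  tgt <- which(ok)
  i0 <- i0[ok]; j0 <- j0[ok]; wi <- wi[ok]; wj <- wj[ok]
  lin <- function(i, j) (j - 1) * nx + i
  plan <- list(
    nx = nx, ny = ny, tgt = tgt,
    src = cbind(lin(i0, j0), lin(i0 + 1, j0), lin(i0, j0 + 1),
                lin(i0 + 1, j0 + 1)),
    w = cbind((1 - wi) * (1 - wj), wi * (1 - wj), (1 - wi) * wj, wi * wj))
  .ptx_cache[[key]] <- plan
  plan
}

## g: (nx, ny) or (nx, ny, nz) complex/numeric array -> rotated array
rotate_gamma <- function(g, theta_deg, spacing, background = 0) {
  d <- dim(g)
  plan <- rotation_plan(d[1], d[2], spacing[1], spacing[2], theta_deg)
  gm <- matrix(g, d[1] * d[2])              # slices as columns (nz = 1 in 2D)
  outm <- matrix(background + 0 * g[1], d[1] * d[2], ncol(gm))
  acc <- plan$w[, 1] * gm[plan$src[, 1], , drop = FALSE]
  for (k in 2:4) acc <- acc + plan$w[, k] * gm[plan$src[, k], , drop = FALSE]
  outm[plan$tgt, ] <- acc
  array(outm, d)
}

## exact adjoint of rotate_gamma (background contribution dropped)
rotate_gamma_adjoint <- function(g_rot, theta_deg, spacing) {
  d <- dim(g_rot)
  plan <- rotation_plan(d[1], d[2], spacing[1], spacing[2], theta_deg)
  gm <- matrix(g_rot, d[1] * d[2])
  nz <- ncol(gm)
  outm <- matrix(0 + 0i, d[1] * d[2], nz)
  idx <- as.vector(plan$src)
  for (z in seq_len(nz)) {
    vals <- as.vector(plan$w * gm[plan$tgt, z])
    sr <- rowsum(Re(vals), idx); si <- rowsum(Im(vals), idx)
    outm[as.integer(rownames(sr)), z] <-
      complex(real = sr[, 1], imaginary = si[, 1])
  }
  array(outm, d)
}

## ---- spectral kernels -------------------------------------------------------

## diffraction symbol over the padded transverse grid for step dz
diffraction_kernel <- function(tdims, tspacing, k0, dz, variant) {
  key <- sprintf("ker|%s|%s|%.12g|%.12g|%s", paste(tdims, collapse = "x"),
                 paste(tspacing, collapse = "x"), k0, dz, variant)
  if (!is.null(.ptx_cache[[key]])) return(.ptx_cache[[key]])
  kt2 <- 0
  for (a in seq_along(tdims)) {
    ka <- 2 * pi * fft_freq(tdims[a], tspacing[a])
    shape <- rep(1L, length(tdims)); shape[a] <- tdims[a]
    kt2 <- kt2 + array(rep(ka^2, each = prod(tdims[seq_len(a - 1)])),
                       tdims)
  }
  if (variant == "fresnel") {
    p <- exp(-1i * k0 * dz + 1i * dz * kt2 / (2 * k0))
  } else {
    kz2 <- k0^2 - kt2
    p <- array(0i, tdims)
    pr <- kz2 >= 0
    p[pr] <- exp(-1i * dz * sqrt(kz2[pr]))
    p[!pr] <- exp(-dz * sqrt(-kz2[!pr]))
  }
  .ptx_cache[[key]] <- p
  p
}

## absorbing boundary layer: a raised-cosine absorption profile sigma(y)
## (1/m) over the taper zone, applied per slab as exp(-sigma dz) so the
## total absorption is a physical quantity independent of the step and
## transverse discretization
TAPER_STRENGTH <- 8      # sigma_max * taper_width, dimensionless

taper_window <- function(n, taper, h_t, dz) {
  w <- rep(1, n)
  if (taper > 0) {
    width <- taper * h_t
    s <- (taper - seq_len(taper) + 0.5) / taper        # 0 inner -> 1 edge
    sigma <- TAPER_STRENGTH / width * 0.5 * (1 - cos(pi * s))
    ramp <- exp(-sigma * dz)                  # ramp[1]: outermost cell
    w[seq_len(taper)] <- ramp
    w[n + 1 - seq_len(taper)] <- ramp
  }
  w
}

## multiplicative per-slab taper over padded transverse dims
taper_mask <- function(tdims, taper, tspace, dz) {
  w <- taper_window(tdims[1], taper, tspace[1], dz)
  if (length(tdims) == 2)
    w <- outer(w, taper_window(tdims[2], taper, tspace[2], dz))
  w
}

fft_fwd <- function(x) stats::fft(x)
fft_inv <- function(x) stats::fft(x, inverse = TRUE) / length(x)

apply_kernel <- function(u, p) fft_inv(p * fft_fwd(u))

## embed interior transverse slab into padded grid (zeros outside)
pad_slab <- function(s, pad) {
  if (is.null(dim(s)) || length(dim(s)) < 2) {
    out <- rep(0 + 0i, length(s) + 2 * pad)
    out[pad + seq_along(s)] <- s
  } else {
    out <- matrix(0 + 0i, nrow(s) + 2 * pad, ncol(s) + 2 * pad)
    out[pad + seq_len(nrow(s)), pad + seq_len(ncol(s))] <- s
  }
  out
}

crop_slab <- function(u, pad, tdims_in) {
  if (length(tdims_in) == 1) u[pad + seq_len(tdims_in)]
  else u[pad + seq_len(tdims_in[1]), pad + seq_len(tdims_in[2]), drop = FALSE]
}

## ---- forward march ----------------------------------------------------------

## internal engine: gamma_rot is the view-aligned complex object function
## (nx, ny[, nz]); returns final padded field and optional per-slab fields.
march_forward <- function(gamma_rot, frequency, c0, spacing, config,
                          keep_slabs = FALSE, extra_distance = 0,
                          input = NULL) {
  d <- dim(gamma_rot)
  ndim <- length(d)
  tdims_in <- d[-1]
  tspace <- spacing[-1]
  lambda0 <- c0 / frequency
  ppw <- lambda0 / max(spacing)
  if (ppw < config$min_ppw)
    stop_ptx("grid supplies %.2f points per wavelength in water; >= %g required",
             ppw, config$min_ppw)
  pad <- config$pad
  tdims <- tdims_in + 2L * pad
  k0 <- 2 * pi * frequency / c0
  dz <- spacing[1]
  p <- diffraction_kernel(tdims, tspace, k0, dz, config$variant)
  tw <- taper_mask(tdims, config$taper, tspace, dz)
  u <- if (is.null(input)) {
    if (ndim == 2) rep(1 + 0i, tdims) else matrix(1 + 0i, tdims[1], tdims[2])
  } else pad_slab(input + 0i, pad)
  slabs <- if (keep_slabs) vector("list", d[1]) else NULL
  half <- config$splitting == "symmetric"
  for (m in seq_len(d[1])) {
    g <- pad_slab(if (ndim == 2) gamma_rot[m, ] else gamma_rot[m, , ], pad)
    if (half) {
      s <- exp(-0.5i * k0 * dz * g)
      a <- s * u
      w <- s * apply_kernel(a, p)               # screened, pre-taper
      if (keep_slabs) slabs[[m]] <- list(w = w, s = s, a = a)
    } else {
      s <- exp(-1i * k0 * dz * g)
      w <- s * apply_kernel(u, p)
      if (keep_slabs) slabs[[m]] <- list(w = w, s = s)
    }
    u <- tw * w
  }
  if (extra_distance > 1e-12) {
    pex <- diffraction_kernel(tdims, tspace, k0, extra_distance,
                              config$variant)
    u <- apply_kernel(u, pex)
  }
  list(u = u, slabs = slabs, p = p, tw = tw, k0 = k0, dz = dz,
       pad = pad, tdims_in = tdims_in, tdims = tdims, tspace = tspace,
       extra_distance = extra_distance)
}

#' Propagate a plane wave through an object function for one view
#'
#' Split-step marching of a unit-amplitude plane wave along the view axis:
#' per slab a transverse spectral diffraction step followed by the thin
#' phase screen `exp(-i k0 gamma dz)`. The medium is rotated into the
#' fixed source-to-receiver frame (bilinear resampling) so the propagation
#' axis stays grid-aligned.
#'
#' @param gamma_obj an `object_function` from [make_object_function()].
#' @param geometry an [acquisition_geometry()]; the receiver plane sits at
#'   `propagation_distance` from the entry face (any excess over the grid
#'   depth is crossed as homogeneous water).
#' @param view_deg azimuthal view angle, degrees.
#' @param config a [propagator_config()].
#' @param input optional complex input field on the unpadded transverse
#'   grid (e.g. an apodized beam); default is the unit plane wave spanning
#'   the padded aperture.
#' @return Object of class `complex_field`: list with `values` (complex
#'   transverse grid at the receiver plane, padding cropped), `spacing`
#'   (transverse), `z` (receiver-plane position, m), `frequency`.
#' @export
propagate <- function(gamma_obj, geometry = NULL, view_deg = 0,
                      config = propagator_config(), input = NULL) {
  stopifnot(inherits(gamma_obj, "object_function"))
  g <- gamma_obj$gamma
  if (view_deg != 0)
    g <- rotate_gamma(g, view_deg, gamma_obj$spacing)
  grid_depth <- dim(g)[1] * gamma_obj$spacing[1]
  extra <- if (is.null(geometry)) 0 else
    max(0, geometry$propagation_distance - grid_depth)
  mres <- march_forward(g, gamma_obj$frequency, gamma_obj$c0,
                        gamma_obj$spacing, config, extra_distance = extra,
                        input = input)
  vals <- crop_slab(mres$u, mres$pad, mres$tdims_in)
  structure(list(values = vals, spacing = gamma_obj$spacing[-1],
                 z = grid_depth + extra, frequency = gamma_obj$frequency),
            class = "complex_field")
}

## ---- receiver sampling ------------------------------------------------------

## interpolation plan from an interior field grid to the element centres;
## row-major (row, col) element order; exact adjoint available
sampler_plan <- function(geometry, tdims_in, tspace, level = 0) {
  off <- receiver_offsets(geometry)
  ny <- tdims_in[1]; hy <- tspace[1]
  fy <- off$y / hy + (ny + 1) / 2
  j0 <- floor(fy); wy <- fy - j0
  ## allow elements exactly on the last node
  at_end <- j0 == ny & abs(wy) < 1e-9
  j0[at_end] <- ny - 1L; wy[at_end] <- 1
  if (any(j0 < 1 | j0 + 1 > ny))
    stop_ptx("receiver footprint outside the field extent (need |y| <= %g m)",
             (ny - 1) / 2 * hy)
  if (length(tdims_in) == 1) {
    if (geometry$receiver_rows != 1)
      stop_ptx("2D field cannot sample a %d-row array", geometry$receiver_rows)
    list(dims = tdims_in,
         src = cbind(j0, j0 + 1), w = cbind(1 - wy, wy))
  } else {
    nz <- tdims_in[2]; hz <- tspace[2]
    fz <- (off$z + level) / hz + (nz + 1) / 2
    k0i <- floor(fz); wz <- fz - k0i
    at_end <- k0i == nz & abs(wz) < 1e-9
    k0i[at_end] <- nz - 1L; wz[at_end] <- 1
    if (any(k0i < 1 | k0i + 1 > nz))
      stop_ptx("receiver rows/level outside the field extent")
    lin <- function(j, k) (k - 1) * ny + j
    list(dims = tdims_in,
         src = cbind(lin(j0, k0i), lin(j0 + 1, k0i),
                     lin(j0, k0i + 1), lin(j0 + 1, k0i + 1)),
         w = cbind((1 - wy) * (1 - wz), wy * (1 - wz),
                   (1 - wy) * wz, wy * wz))
  }
}

sampler_apply <- function(plan, vals) {
  v <- as.vector(vals)
  out <- plan$w[, 1] * v[plan$src[, 1]]
  for (k in 2:ncol(plan$w)) out <- out + plan$w[, k] * v[plan$src[, k]]
  out
}

sampler_adjoint <- function(plan, r) {
  n <- prod(plan$dims)
  idx <- as.vector(plan$src)
  vals <- as.vector(plan$w * r)
  sr <- rowsum(Re(vals), idx); si <- rowsum(Im(vals), idx)
  out <- rep(0 + 0i, n)
  out[as.integer(rownames(sr))] <- complex(real = sr[, 1], imaginary = si[, 1])
  if (length(plan$dims) == 1) out else array(out, plan$dims)
}

#' Sample a receiver-plane field at the array element centres
#'
#' Bilinear interpolation at each element centre, elements ordered
#' row-major (row varies fastest), giving the complex data vector of
#' length `N_R`.
#'
#' @param field a `complex_field` from [propagate()].
#' @param geometry an [acquisition_geometry()].
#' @param level vertical position of the array assembly, m (3D only).
#' @return complex vector of length `N_R`.
#' @export
sample_receivers <- function(field, geometry, level = 0) {
  stopifnot(inherits(field, "complex_field"))
  tdims_in <- if (is.null(dim(field$values))) length(field$values)
              else dim(field$values)
  plan <- sampler_plan(geometry, tdims_in, field$spacing, level)
  sampler_apply(plan, field$values)
}

## ---- dataset simulation -----------------------------------------------------

#' Simulate a frequency-domain dataset over views, levels and frequencies
#'
#' Loops the paraxial forward model over every (frequency, view, level) of
#' the acquisition, tagging the result `"simulated"`. Deterministic;
#' optional additive complex Gaussian noise at a stated SNR with a stated
#' seed. The simulation grid may be finer than the grid later used for
#' inversion (inverse-crime guard).
#'
#' @param medium an [acoustic_medium()].
#' @param geometry an [acquisition_geometry()].
#' @param ladder a [frequency_ladder()] or numeric frequencies, Hz.
#' @param config a [propagator_config()].
#' @param noise_snr_db if non-NULL, per-record SNR of added complex
#'   Gaussian noise, dB.
#' @param seed RNG seed for the noise.
#' @return An [fd_dataset()] tagged `"simulated"`.
#' @export
simulate_dataset <- function(medium, geometry, ladder,
                             config = propagator_config(),
                             noise_snr_db = NULL, seed = 1L) {
  freqs <- as.numeric(ladder)
  ds <- fd_dataset(geometry, freqs, "simulated")
  if (!is.null(noise_snr_db)) set.seed(derive_seed(seed, "simulate-noise"))
  grid_depth <- dim(medium$sos)[1] * medium$spacing[1]
  extra <- max(0, geometry$propagation_distance - grid_depth)
  for (f in freqs) {
    gam <- make_object_function(medium, f)$gamma
    for (th in geometry$view_angles_deg) {
      g_rot <- if (th != 0) rotate_gamma(gam, th, medium$spacing) else gam
      mres <- tryCatch(
        march_forward(g_rot, f, medium$c0, medium$spacing, config,
                      extra_distance = extra),
        error = function(e) stop_ptx("view %g deg, %g Hz: %s", th, f,
                                     conditionMessage(e)))
      vals <- crop_slab(mres$u, mres$pad, mres$tdims_in)
      tdims_in <- if (is.null(dim(vals))) length(vals) else dim(vals)
      for (lv in geometry$levels_m) {
        plan <- sampler_plan(geometry, tdims_in, medium$spacing[-1], lv)
        v <- sampler_apply(plan, vals)
        if (!is.null(noise_snr_db)) {
          sigma <- sqrt(mean(Mod(v)^2)) * 10^(-noise_snr_db / 20)
          v <- v + sigma / sqrt(2) *
            complex(real = stats::rnorm(length(v)),
                    imaginary = stats::rnorm(length(v)))
        }
        ds <- dataset_set(ds, f, th, lv, v)
      }
    }
  }
  ds
}
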