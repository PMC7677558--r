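# Reference desk-scale experiments: the package's standard recovery,
# robustness and resolution studies, shared by the test suite and the
# acceptance script. Conditions (grid, geometry, protocol, ROI sizes) are
# fixed here once; the methods vignette documents the choices.

#' Desk-scale acquisition used by the reference experiments
#' @param shape reconstruction grid.
#' @param h voxel size, m.
#' @param cols receiver columns.
#' @keywords internal
experiment_geometry <- function(shape, h, cols = 56) {
  desk_scale_geometry(views = 36, cols = cols, receiver_pitch = h,
                      propagation_distance = shape[1] * h)
}

## simulation runs on a 2x-finer grid than the inversion; the absorbing
## margin is held at the same physical width on both grids
experiment_sim_config <- function() propagator_config(pad = 64L, taper = 32L)
experiment_protocol <- function() {
  reconstruction_protocol(c(0.35e6, 0.5e6, 0.7e6, 1.0e6),
                          c(15L, 10L, 10L, 10L), init = "tof")
}

#' Soft-tissue parameter-recovery experiment
#'
#' Three 3 mm-radius discs (fat, muscle, articular cartilage at their
#' tabulated speeds 1437 / 1571 / 1664 m/s) in water; noise-free data
#' simulated on a 2x-finer grid; four-stage frequency-hopping inversion
#' (0.35 / 0.5 / 0.7 / 1.0 MHz) from a time-of-flight start; ROI means
#' taken over 2.5 mm discs well inside each tissue.
#'
#' @return data.frame with tissue, true and recovered ROI mean SOS (m/s),
#'   error and ROI SD; attribute `"report"` carries the inversion report.
#' @export
soft_tissue_recovery_experiment <- function() {
  h <- 0.35e-3; shape <- c(64L, 64L)
  layout <- list(
    list(tissue = "fat", center = c(-4.5e-3, -4.5e-3), radius = 3e-3),
    list(tissue = "muscle", center = c(4.5e-3, -4.5e-3), radius = 3e-3),
    list(tissue = "cartilage", center = c(0, 5e-3), radius = 3e-3))
  truth <- make_soft_tissue_phantom(2L * shape, h / 2, layout)
  geom <- experiment_geometry(shape, h)
  protocol <- experiment_protocol()
  ds <- simulate_dataset(truth, geom, protocol$frequencies_hz,
                         experiment_sim_config())
  res <- run_frequency_hopping(ds, protocol, shape, h, tol = 1e-7)
  tab <- tissue_properties()
  rows <- lapply(layout, function(reg) {
    r <- roi_statistics(res$medium$sos, res$medium$spacing, reg$center,
                        2.5e-3)
    true_sos <- tab$sos_mps[tab$name == reg$tissue]
    data.frame(tissue = reg$tissue, true_sos = true_sos,
               recovered_sos = r$mean, error = r$mean - true_sos,
               roi_sd = r$sd)
  })
  out <- do.call(rbind, rows)
  attr(out, "report") <- res$report
  attr(out, "medium") <- res$medium
  out
}

#' High-contrast (bone) robustness experiment
#'
#' A bone-like inclusion (2900 m/s cortical shell, 1600 m/s trabecular
#' interior, shell attenuation 690 dB/m/MHz) embedded in uniform soft
#' tissue at 1570 m/s; the same acquisition and protocol as the
#' soft-tissue experiment. Reports ROI mean SOS in four soft-tissue discs
#' at least two wavelengths (of the final 1 MHz stage) away from the
#' shell; no claim is made inside the bone.
#'
#' @return data.frame with per-ROI recovered SOS and percent error vs the
#'   1570 m/s truth; attributes `"medium"` (reconstruction) and `"truth"`.
#' @export
bone_robustness_experiment <- function() {
  h <- 0.35e-3; shape <- c(64L, 64L)
  truth <- make_bone_phantom(2L * shape, h / 2, bone_radius = 3.5e-3,
                             cortical_thickness = 1.05e-3,
                             tissue_sos = 1570, tissue_atten = 70,
                             tissue_radius = NULL)
  geom <- experiment_geometry(shape, h)
  protocol <- experiment_protocol()
  ds <- simulate_dataset(truth, geom, protocol$frequencies_hz,
                         experiment_sim_config())
  res <- run_frequency_hopping(ds, protocol, shape, h, tol = 1e-7)
  rois <- list(c(8e-3, 0), c(-8e-3, 0), c(0, 8e-3), c(0, -8e-3))
  rows <- lapply(rois, function(p) {
    r <- roi_statistics(res$medium$sos, res$medium$spacing, p, 2.5e-3)
    data.frame(x_mm = p[1] * 1e3, y_mm = p[2] * 1e3, true_sos = 1570,
               recovered_sos = r$mean,
               percent_error = 100 * (r$mean - 1570) / 1570, roi_sd = r$sd)
  })
  out <- do.call(rbind, rows)
  attr(out, "medium") <- res$medium
  attr(out, "truth") <- truth
  out
}

#' Point-spread (resolution) experiment
#'
#' A single-voxel +10 m/s perturbation reconstructed at the final ladder
#' frequency (1 MHz) from a uniform-water start, with a wide receiver
#' aperture so the scattering angles reach the diffraction limit of the
#' method. Returns the reconstructed point-spread FWHM and its ratio to
#' lambda/sqrt(2), the expected contrast/spatial resolution of full-wave
#' inverse scattering.
#'
#' @return list with `fwhm_mm` (mean of the two axis profiles),
#'   `lambda_sqrt2_mm`, `ratio`, `peak_location` (voxel).
#' @export
psf_resolution_experiment <- function() {
  h <- 0.35e-3; shape <- c(64L, 128L)
  f <- 1.0e6
  truth <- make_point_phantom(shape, h, delta_sos = 10)
  geom <- experiment_geometry(shape, h, cols = 116)
  ds <- simulate_dataset(truth, geom, f)
  res <- run_frequency_hopping(
    ds, reconstruction_protocol(f, 30L, init = "uniform"),
    shape, h, tol = 1e-12)
  dsos <- res$medium$sos - truth$c0
  pk <- which(dsos == max(dsos), arr.ind = TRUE)[1, ]
  ctr <- (pk - (shape + 1) / 2) * h
  fx <- fwhm_profile(dsos, h, c(ctr[1] - 4e-3, ctr[2]),
                     c(ctr[1] + 4e-3, ctr[2]))
  fy <- fwhm_profile(dsos, h, c(ctr[1], ctr[2] - 4e-3),
                     c(ctr[1], ctr[2] + 4e-3))
  lam_mm <- truth$c0 / f * 1e3
  fwhm <- (fx$fwhm_mm + fy$fwhm_mm) / 2
  list(fwhm_mm = fwhm, lambda_sqrt2_mm = lam_mm / sqrt(2),
       ratio = fwhm / (lam_mm / sqrt(2)), peak_location = pk,
       true_location = ceiling(shape / 2))
}

#' Refraction-corrected localization experiment
#'
#' A point scatterer under a 6 mm, +10% speed slab, imaged at 4 MHz by a
#' monostatic synthetic-aperture array. Delay-and-sum with eikonal delays
#' through the true speed map localizes the scatterer within a
#' wavelength; water delays through the same traces mislocalize it by
#' more than a wavelength.
#'
#' @return list with `corrected_error_mm`, `water_error_mm`, `lambda_mm`.
#' @export
refraction_correction_experiment <- function() {
  h <- 0.25e-3; shape <- c(96L, 64L)
  sos <- array(1500, shape)
  xs <- axis_coords(shape[1], h)
  sos[xs > -8e-3 & xs < -2e-3, ] <- 1650
  med <- acoustic_medium(sos, spacing = h)
  geom <- echo_geometry(n_elements = 32, pitch = 0.5e-3, x0 = xs[3],
                        center_freq_hz = 4e6, sample_rate_hz = 40e6,
                        n_samples = 1400)
  target <- c(4e-3, 1e-3)
  tr <- simulate_echo_data(data.frame(x = target[1], y = target[2],
                                      refl = 1), med, geom)
  loc <- function(img) {
    p <- which(img == max(img), arr.ind = TRUE)[1, ]
    (p - (shape + 1) / 2) * h
  }
  das_t <- refraction_corrected_das(tr, med, geom)
  das_w <- refraction_corrected_das(
    tr, acoustic_medium(array(1500, shape), spacing = h), geom)
  err <- function(p) sqrt(sum((p - target)^2)) * 1e3
  list(corrected_error_mm = err(loc(das_t$envelope)),
       water_error_mm = err(loc(das_w$envelope)),
       lambda_mm = 1500 / geom$center_freq_hz * 1e3)
}
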