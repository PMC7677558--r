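#' Acoustic medium: speed-of-sound and attenuation grids
#'
#' Container for the object being imaged: voxel grids of compressional speed
#' of sound (m/s) and of attenuation slope (dB m^-1 MHz^-1, attenuation
#' assumed linear in frequency), with per-axis voxel spacing in metres and
#' the background (water-bath) speed of sound `c0`.
#'
#' Grids are 2D matrices (propagation x transverse) or 3D arrays
#' (x, y, z with z vertical). Voxels are cell-centred; the world position of
#' voxel `i` along an axis of `n` voxels with spacing `h` is
#' `(i - (n+1)/2) * h`, so the grid is centred on the origin.
#'
#' @param sos numeric array, speed of sound per voxel, m/s; strictly positive.
#' @param atten numeric array, attenuation slope per voxel, dB m^-1 MHz^-1;
#'   non-negative, same shape as `sos`.
#' @param spacing numeric vector of per-axis voxel sizes, m (length = #dims).
#' @param c0 background (water) speed of sound, m/s. Default 1500.
#' @return An object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(sos, atten = NULL, spacing, c0 = 1500) {
  sos <- as.array(sos)
  if (is.null(atten)) atten <- array(0, dim(sos))
  atten <- as.array(atten)
  if (!identical(dim(sos), dim(atten)))
    stop_ptx("sos grid %s and atten grid %s differ in shape",
             paste(dim(sos), collapse = "x"), paste(dim(atten), collapse = "x"))
  if (any(!is.finite(sos)) || any(sos <= 0)) {
    i <- which(!is.finite(sos) | sos <= 0)[1]
    stop_ptx("non-positive speed of sound %g at voxel %d", sos[i], i)
  }
  if (any(atten < 0)) {
    i <- which(atten < 0)[1]
    stop_ptx("negative attenuation %g at voxel %d", atten[i], i)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, length(dim(sos)))
  if (length(spacing) != length(dim(sos)) || any(spacing <= 0))
    stop_ptx("spacing must give one positive voxel size per axis")
  if (!is_scalar_num(c0) || c0 <= 0) stop_ptx("c0 must be a positive scalar")
  structure(list(sos = sos, atten = atten, spacing = spacing, c0 = c0),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> %s voxels, spacing %s mm, c0 = %g m/s\n",
              paste(dim(x$sos), collapse = " x "),
              paste(signif(x$spacing * 1e3, 4), collapse = " x "), x$c0))
  cat(sprintf("  sos   [%g, %g] m/s\n", min(x$sos), max(x$sos)))
  cat(sprintf("  atten [%g, %g] dB/m/MHz\n", min(x$atten), max(x$atten)))
  invisible(x)
}

#' Complex object function at one frequency
#'
#' The inversion unknown: the dimensionless complex contrast
#' \deqn{\gamma(x) = (c_0/c(x) - 1) - i \frac{\alpha_{dB}(x)}{f_j}
#'   \frac{c_0}{2\pi \cdot 8.686}}
#' whose real part carries the speed-of-sound deviation from the water
#' background and whose (non-positive) imaginary part carries attenuation,
#' under the \eqn{e^{-i\omega t}} time convention. \eqn{\alpha_{dB}(x)} is
#' the attenuation in dB/m at the working frequency `f_j`, i.e. the stored
#' slope times `f_j` in MHz.
#'
#' @param medium an [acoustic_medium()].
#' @param frequency working frequency \eqn{f_j}, Hz; positive.
#' @return Object of class `object_function`: list with complex array
#'   `gamma`, `frequency`, `c0`, `spacing`.
#' @export
make_object_function <- function(medium, frequency) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (!is_scalar_num(frequency) || frequency <= 0)
    stop_ptx("frequency must be positive, got %s", format(frequency))
  alpha_db <- medium$atten * (frequency / 1e6)       # dB/m at f_j
  g <- (medium$c0 / medium$sos - 1) -
    1i * (alpha_db / frequency) * medium$c0 / (2 * pi * NEPER_DB)
  structure(list(gamma = g, frequency = frequency, c0 = medium$c0,
                 spacing = medium$spacing),
            class = "object_function")
}

#' Recover speed of sound and attenuation from an object function
#'
#' Exact algebraic inverse of [make_object_function()]:
#' `c = c0 / (1 + Re gamma)` and the attenuation slope from the imaginary
#' part. Round-trips to relative error below 1e-12.
#'
#' @param gamma_obj an `object_function`.
#' @return An [acoustic_medium()].
#' @export
extract_sos_attenuation <- function(gamma_obj) {
  stopifnot(inherits(gamma_obj, "object_function"))
  re <- Re(gamma_obj$gamma)
  if (any(re <= -1)) {
    i <- which(re <= -1)[1]
    stop_ptx("Re(gamma) = %g <= -1 at voxel %d: non-physical speed of sound",
             re[i], i)
  }
  sos <- gamma_obj$c0 / (1 + re)
  ## invert: Im g = -(slope * f_MHz / f) * c0 / (2 pi * 8.686)
  slope <- -Im(gamma_obj$gamma) * (2 * pi * NEPER_DB) / gamma_obj$c0 * 1e6
  slope[slope < 0 & slope > -1e-9] <- 0   # clip roundoff
  acoustic_medium(sos, slope, gamma_obj$spacing, gamma_obj$c0)
}

#' Tissue acoustic properties table
#'
#' Reference speed of sound and attenuation slope per tissue class, seeded
#' from measured knee-tissue values (6 mm ROI means) plus standard
#' literature values for classes those tables do not cover. Where density
#' and bulk modulus are given they satisfy \eqn{c = \sqrt{K/\rho}}.
#'
#' @return data.frame with columns `name`, `sos_mps`, `atten_db_per_m_mhz`,
#'   `density`, `bulk_modulus`.
#' @export
tissue_properties <- function() {
  path <- system.file("extdata", "tissue_properties.csv",
                      package = "paraxtomo", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ok <- !is.na(tab$density) & !is.na(tab$bulk_modulus)
  if (any(ok)) {
    c_kr <- sqrt(tab$bulk_modulus[ok] / tab$density[ok])
    bad <- abs(c_kr / tab$sos_mps[ok] - 1) > 1e-3
    if (any(bad))
      stop_ptx("tissue '%s': sos inconsistent with sqrt(K/rho)",
               tab$name[ok][bad][1])
  }
  tab
}

tissue_lookup <- function(name) {
  tab <- tissue_properties()
  i <- match(name, tab$name)
  if (is.na(i))
    stop_ptx("unknown tissue '%s'; known tissues: %s", name,
             paste(tab$name, collapse = ", "))
  tab[i, ]
}
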