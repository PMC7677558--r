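# Synthetic phantom generators. All phantoms are centred on the grid origin
# and sit in a water background; shapes are (elliptic) cylinders so that 2D
# slices and 3D volumes share the same layout logic.

## partial-volume coverage fraction of each voxel by an (elliptic)
## cylinder (axis along z in 3D; a disc in 2D), computed on a
## ss x ss subvoxel grid: boundary voxels blend instead of snapping, so
## grids of different resolution discretize the same continuous object
cylinder_coverage <- function(shape, spacing, center, radii, ss = 4L) {
  x <- axis_coords(shape[1], spacing[1]) - center[1]
  y <- axis_coords(shape[2], spacing[2]) - center[2]
  rx <- radii[1]; ry <- if (length(radii) >= 2) radii[2] else radii[1]
  offs <- ((seq_len(ss) - (ss + 1) / 2) / ss)
  f <- matrix(0, shape[1], shape[2])
  for (ox in offs) for (oy in offs)
    f <- f + (outer(((x + ox * spacing[1]) / rx)^2,
                    ((y + oy * spacing[2]) / ry)^2, `+`) <= 1)
  f <- f / ss^2
  if (length(shape) == 3) f <- array(rep(f, shape[3]), dim = shape) else f
}

#' Soft-tissue phantom with tabulated tissue contrasts
#'
#' Places (elliptic-)cylindrical tissue regions in a water background, with
#' speed of sound and attenuation slope looked up per tissue name in
#' [tissue_properties()]. Regions are painted in list order, so later
#' entries overwrite earlier ones (nesting muscle inside fat etc.). Soft
#' tissue contrasts are within roughly +/-10% of water, the regime the
#' transmission inversion is designed around.
#'
#' @param shape integer vector (2D or 3D) of grid dimensions.
#' @param spacing voxel size(s), m.
#' @param layout list of regions, each
#'   `list(tissue = "fat", center = c(x, y), radius = r)` with `center` in
#'   metres relative to the grid centre and `radius` scalar or `c(rx, ry)`.
#'   Empty layout gives a uniform water medium.
#' @param c0 background speed of sound, m/s.
#' @return An [acoustic_medium()]; attribute `"labels"` holds the integer
#'   region label per voxel (0 = water) and `"layout"` the layout used.
#' @export
make_soft_tissue_phantom <- function(shape, spacing, layout = list(),
                                     c0 = 1500) {
  spacing <- if (length(spacing) == 1L) rep(spacing, length(shape)) else spacing
  sos <- array(c0, shape)
  atten <- array(0, shape)
  labels <- array(0L, shape)
  for (i in seq_along(layout)) {
    reg <- layout[[i]]
    prop <- tissue_lookup(reg$tissue)
    f <- cylinder_coverage(shape, spacing, reg$center %||% c(0, 0),
                           reg$radius)
    sos <- sos * (1 - f) + prop$sos_mps * f
    atten <- atten * (1 - f) + prop$atten_db_per_m_mhz * f
    labels[f > 0.5] <- i
  }
  med <- acoustic_medium(sos, atten, spacing, c0)
  attr(med, "labels") <- labels
  attr(med, "layout") <- layout
  med
}

#' Bone-like high-contrast phantom
#'
#' A high speed-of-sound, high-attenuation cortical shell surrounding a
#' slower, low-attenuation (trabecular-like) interior, embedded in a soft
#' tissue cylinder inside the water bath. The shell contrast
#' (about +90% in SOS) far exceeds the +/-10% soft-tissue regime and is the
#' stress case for artifact-free imaging of the surrounding tissue.
#'
#' @param shape,spacing grid dimensions and voxel size(s), m.
#' @param bone_radius outer radius of the bone inclusion, m.
#' @param cortical_thickness shell thickness, m; at least one voxel and
#'   less than `bone_radius`.
#' @param shell_sos,interior_sos cortical and trabecular speed of sound, m/s.
#' @param shell_atten,interior_atten attenuation slopes, dB/m/MHz.
#' @param tissue_sos,tissue_radius surrounding soft-tissue cylinder
#'   (`tissue_radius = NULL` fills the whole grid with soft tissue).
#' @param center bone centre, m, relative to grid centre.
#' @param c0 background speed of sound, m/s.
#' @return An [acoustic_medium()]; attribute `"bone_mask"` marks
#'   shell + interior, `"shell_mask"` the shell alone.
#' @export
make_bone_phantom <- function(shape, spacing,
                              bone_radius = 4e-3,
                              cortical_thickness = 1e-3,
                              shell_sos = 2900, interior_sos = 1600,
                              shell_atten = 690, interior_atten = 40,
                              tissue_sos = 1570, tissue_atten = 70,
                              tissue_radius = NULL, center = c(0, 0),
                              c0 = 1500) {
  spacing <- if (length(spacing) == 1L) rep(spacing, length(shape)) else spacing
  if (cortical_thickness < min(spacing[1:2]))
    stop_ptx("cortical_thickness %g m is below one voxel (%g m)",
             cortical_thickness, min(spacing[1:2]))
  if (cortical_thickness >= bone_radius)
    stop_ptx("cortical shell (%g m) at least as thick as the bone radius (%g m)",
             cortical_thickness, bone_radius)
  sos <- array(c0, shape)
  atten <- array(0, shape)
  if (!is.null(tissue_radius)) {
    f <- cylinder_coverage(shape, spacing, c(0, 0), tissue_radius)
    sos <- sos * (1 - f) + tissue_sos * f
    atten <- atten * (1 - f) + tissue_atten * f
  } else {
    sos[] <- tissue_sos; atten[] <- tissue_atten
  }
  fo <- cylinder_coverage(shape, spacing, center, bone_radius)
  fi <- cylinder_coverage(shape, spacing, center,
                          bone_radius - cortical_thickness)
  sos <- sos * (1 - fo) + shell_sos * fo
  atten <- atten * (1 - fo) + shell_atten * fo
  sos <- sos * (1 - fi) + interior_sos * fi
  atten <- atten * (1 - fi) + interior_atten * fi
  outer_m <- array(fo > 0.5, shape)
  inner_m <- array(fi > 0.5, shape)
  shell <- outer_m & !inner_m
  med <- acoustic_medium(sos, atten, spacing, c0)
  attr(med, "bone_mask") <- outer_m
  attr(med, "shell_mask") <- shell
  med
}

#' Single-voxel point-perturbation phantom
#'
#' Uniform water plus one perturbed voxel, used to measure the
#' point-spread function of the reconstruction chain.
#'
#' @param shape,spacing grid dimensions and voxel size(s), m.
#' @param delta_sos perturbation amplitude, m/s; `|delta_sos|/c0` must not
#'   exceed 1% so the Born/PSF interpretation holds.
#' @param location integer voxel index vector (default: grid centre).
#' @param c0 background speed of sound, m/s.
#' @return An [acoustic_medium()].
#' @export
make_point_phantom <- function(shape, spacing, delta_sos = 10,
                               location = NULL, c0 = 1500) {
  if (abs(delta_sos) / c0 > 0.01)
    stop_ptx("|delta_sos|/c0 = %.3g exceeds the 1%% point-perturbation limit",
             abs(delta_sos) / c0)
  if (is.null(location)) location <- ceiling(shape / 2)
  if (length(location) != length(shape) ||
      any(location < 1) || any(location > shape))
    stop_ptx("location (%s) outside grid (%s)",
             paste(location, collapse = ","), paste(shape, collapse = "x"))
  sos <- array(c0, shape)
  sos[matrix(location, 1)] <- c0 + delta_sos
  spacing <- if (length(spacing) == 1L) rep(spacing, length(shape)) else spacing
  acoustic_medium(sos, array(0, shape), spacing, c0)
}
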