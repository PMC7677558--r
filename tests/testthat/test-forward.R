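test_that("free space and homogeneous loss match closed forms", {
  shape <- c(32L, 48L); h <- 0.3e-3
  f <- 1e6; k0 <- 2 * pi * f / 1500; L <- shape[1] * h
  gob <- make_object_function(
    acoustic_medium(array(1500, shape), spacing = h), f)
  fld <- propagate(gob, config = propagator_config(pad = 16, taper = 0))
  ## plane wave picks up exactly exp(-i k0 L) with unit modulus
  expect_lt(max(Mod(fld$values - exp(-1i * k0 * L))), 1e-12)

  ## Beer-Lambert: slope 50 dB/m/MHz at 1 MHz over L
  lossy <- acoustic_medium(array(1500, shape), array(50, shape), h)
  fld2 <- propagate(make_object_function(lossy, f),
                    config = propagator_config(pad = 0, taper = 0))
  expect_equal(Mod(fld2$values[24]), 10^(-50 * L / 20), tolerance = 1e-10)
})

test_that("apodized Gaussian input diffracts like the analytic beam", {
  ny <- 96L; nx <- 32L; h <- 0.35e-3; f <- 1e6
  w0 <- 3e-3; lam <- 1500 / f
  y <- paraxtomo:::axis_coords(ny, h)
  inp <- exp(-(y / w0)^2)
  gob <- make_object_function(
    acoustic_medium(array(1500, c(nx, ny)), spacing = h), f)
  fld <- propagate(gob, config = propagator_config(pad = 32, taper = 16,
                                                   variant = "fresnel"),
                   input = inp)
  z <- nx * h; zr <- pi * w0^2 / lam
  wz <- w0 * sqrt(1 + (z / zr)^2)
  pred <- sqrt(w0 / wz) * exp(-(y / wz)^2)
  expect_lt(sqrt(mean((Mod(fld$values) - pred)^2)) / max(pred), 0.01)
  expect_gt(wz / w0, 1.1)                     # the waist actually grew
})

test_that("lossless marching conserves transverse power without taper", {
  nx <- 32L; ny <- 96L; h <- 0.35e-3
  y <- paraxtomo:::axis_coords(ny, h)
  inp <- exp(-(y / 3e-3)^2)                   # bandlimited input
  ## water: the spectral operator is exactly unitary for propagating
  ## components and the input carries no evanescent content
  med <- acoustic_medium(array(1500, c(nx, ny)), spacing = h)
  fld <- propagate(make_object_function(med, 1e6),
                   config = propagator_config(pad = 32, taper = 0),
                   input = inp)
  expect_lt(abs(sum(Mod(fld$values)^2) / sum(Mod(inp)^2) - 1), 1e-10)
  ## a weakly scattering lossless medium loses only the trickle of power
  ## scattered beyond the propagating cone
  set.seed(2)
  med2 <- acoustic_medium(
    array(1500 * (1 + 0.01 * matrix(runif(nx * ny), nx)), c(nx, ny)),
    spacing = h)
  fld2 <- propagate(make_object_function(med2, 1e6),
                    config = propagator_config(pad = 32, taper = 0),
                    input = inp)
  expect_lt(abs(sum(Mod(fld2$values)^2) / sum(Mod(inp)^2) - 1), 1e-3)
})

test_that("undersampled grids are rejected with the ppw deficit named", {
  med <- acoustic_medium(array(1500, c(16L, 16L)), spacing = 0.5e-3)
  expect_error(propagate(make_object_function(med, 1.2e6)),
               "points per wavelength")
})

test_that("receiver sampling is bilinear and exact on nodes and ramps", {
  shape <- c(16L, 16L); h <- 0.4e-3
  geom <- desk_scale_geometry(views = 8, cols = 8, receiver_pitch = h,
                              propagation_distance = shape[1] * h)
  fld <- structure(list(values = rep(3 + 2i, 16), spacing = h, z = 0,
                        frequency = 1e6), class = "complex_field")
  expect_true(all(sample_receivers(fld, geom) == 3 + 2i))

  ## element centres coincide with grid nodes: interpolation identity
  y <- paraxtomo:::axis_coords(16L, h)
  fld$values <- complex(real = seq_len(16), imaginary = 16:1)
  v <- sample_receivers(fld, geom)
  node_idx <- match(round(paraxtomo:::receiver_offsets(geom)$y, 12),
                    round(y, 12))
  expect_equal(v, fld$values[node_idx])

  ## linear ramp reproduced exactly by bilinearity, even off-node
  geom2 <- desk_scale_geometry(views = 8, cols = 9,
                               receiver_pitch = 0.37e-3,
                               propagation_distance = shape[1] * h)
  fld$values <- (2 + 1i) * y + 5
  yr <- paraxtomo:::receiver_offsets(geom2)$y
  expect_equal(sample_receivers(fld, geom2), (2 + 1i) * yr + 5,
               tolerance = 1e-13)

  ## footprint outside the field is an error
  geom3 <- desk_scale_geometry(views = 8, cols = 40,
                               receiver_pitch = 0.4e-3,
                               propagation_distance = shape[1] * h)
  expect_error(sample_receivers(fld, geom3), "footprint")
})

test_that("simulated datasets are complete, deterministic and symmetric", {
  shape <- c(32L, 32L); h <- 0.4e-3
  geom <- tiny_geometry(shape, h, views = 8, cols = 16)
  med <- acoustic_medium(array(1500, shape), spacing = h)
  ds <- simulate_dataset(med, geom, c(0.5e6, 0.9e6), tiny_config())
  expect_equal(length(ds$data), 2L * 8L * 1L)
  expect_equal(ds$provenance, "simulated")

  ## water-only: every view equals the view-0 (free-space) record
  ref <- dataset_get(ds, 0.9e6, 0, 0)
  for (th in geom$view_angles_deg)
    expect_equal(dataset_get(ds, 0.9e6, th, 0), ref, tolerance = 1e-12)

  ## centred circularly-symmetric smooth phantom: view-independent data
  ## (to bilinear rotation-resampling accuracy)
  y <- paraxtomo:::axis_coords(32L, h)
  r2 <- outer(y^2, y^2, `+`)
  sos <- 1500 * (1 + 0.03 * exp(-r2 / (3e-3)^2))
  ds2 <- simulate_dataset(acoustic_medium(sos, spacing = h), geom, 0.9e6,
                          tiny_config())
  ref2 <- dataset_get(ds2, 0.9e6, 0, 0)
  for (th in geom$view_angles_deg) {
    rel <- max(Mod(dataset_get(ds2, 0.9e6, th, 0) - ref2)) / max(Mod(ref2))
    expect_lt(rel, 2e-3)                      # bilinear resampling floor
  }

  ## noise injection is seeded and reproducible
  dn1 <- simulate_dataset(med, geom, 0.9e6, tiny_config(),
                          noise_snr_db = 30, seed = 9)
  dn2 <- simulate_dataset(med, geom, 0.9e6, tiny_config(),
                          noise_snr_db = 30, seed = 9)
  expect_identical(dn1$data, dn2$data)
  expect_false(identical(dn1$data[[1]], ds$data[[1]]))
})

test_that("halving the axial step changes receiver data below 0.5% RMS", {
  h <- 0.35e-3; shape <- c(64L, 64L)
  layout <- list(list(tissue = "muscle", center = c(0, 0), radius = 3e-3))
  geom <- desk_scale_geometry(views = 8, cols = 56, receiver_pitch = h,
                              propagation_distance = shape[1] * h)
  coarse <- make_soft_tissue_phantom(shape, h, layout)
  fine_ax <- make_soft_tissue_phantom(c(128L, 64L), c(h / 2, h), layout)
  dc <- simulate_dataset(coarse, geom, 0.5e6)
  df <- simulate_dataset(fine_ax, geom, 0.5e6)
  k <- names(dc$data)[1]
  rel <- sqrt(mean(Mod(dc$data[[k]] - df$data[[k]])^2) /
                mean(Mod(df$data[[k]])^2))
  expect_lt(rel, 0.005)
})
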