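test_that("residuals subtract records elementwise with key checking", {
  geom <- desk_scale_geometry(views = 8, cols = 8)
  mk <- function(vals) {
    ds <- fd_dataset(geom, 1e6)
    for (th in geom$view_angles_deg)
      ds <- dataset_set(ds, 1e6, th, 0, vals)
    ds
  }
  a <- mk(complex(real = 1:8, imaginary = 1:8))
  b <- mk(complex(real = 8:1, imaginary = rep(0, 8)))
  r <- compute_residual(a, b)
  expect_equal(length(r), 8L)
  expect_equal(r[[1]], complex(real = 1:8, imaginary = 1:8) -
                 complex(real = 8:1, imaginary = rep(0, 8)))
  ## identical datasets give exactly zero
  expect_true(all(vapply(compute_residual(a, a), function(v)
    all(v == 0), logical(1))))
  ## zero measured returns the prediction itself
  z <- mk(rep(0 + 0i, 8))
  expect_equal(compute_residual(a, z)[[3]],
               complex(real = 1:8, imaginary = 1:8))
  ## norm computed per key equals the flattened norm
  n_keys <- records_norm2(r)
  n_flat <- sum(Mod(unlist(r))^2)
  expect_equal(n_keys, n_flat, tolerance = 1e-15)
  ## mismatched keys are named
  b2 <- b; names(b2$data)[1] <- "f1e+06|v999|l0"
  expect_error(compute_residual(a, b2), "keys differ")
})

test_that("objective is the half squared misfit and counts one solve", {
  med <- random_soft_medium(c(16L, 16L))
  geom <- tiny_geometry(c(16L, 16L), 0.4e-3)
  cfg <- tiny_config()
  ds <- simulate_dataset(med, geom, 0.9e6, cfg)
  ## perfect-model fit: truth explains its own data to machine precision
  gt <- make_object_function(med, 0.9e6)
  data_norm <- records_norm2(ds$data)
  expect_lt(objective(gt, ds, cfg), 1e-20 * data_norm)
  ## counter +1 per evaluation; equals the brute-force elementwise sum
  ctr <- forward_counter()
  g0 <- make_object_function(
    acoustic_medium(array(1500, c(16L, 16L)), spacing = 0.4e-3), 0.9e6)
  J <- objective(g0, ds, cfg, ctr)
  expect_equal(ctr$n, 1L)
  pred <- paraxtomo:::predict_records(g0, ds, cfg)$records
  brute <- 0
  for (k in names(pred)) for (i in seq_along(pred[[k]]))
    brute <- brute + abs(pred[[k]][i] - ds$data[[k]][i])^2 / 2
  expect_equal(J, brute, tolerance = 1e-12)
  ## quadratic scaling: doubling residual amplitudes quadruples the misfit
  r <- compute_residual(ds, ds)
  expect_equal(records_norm2(lapply(ds$data, function(v) 2 * v)),
               4 * records_norm2(ds$data))
})

test_that("adjoint gradient passes dot-product and finite-difference checks", {
  med <- random_soft_medium(c(16L, 16L))
  geom <- tiny_geometry(c(16L, 16L), 0.4e-3)
  cfg <- tiny_config()
  expect_lt(adjoint_identity_error(med, geom, cfg, 0.9e6), 1e-10)
  expect_lt(fd_gradient_error(med, geom, cfg, 0.9e6, n_voxels = 3), 1e-4)
  ## stationary point: gradient at the truth is negligible against the
  ## water-start gradient
  ds <- simulate_dataset(med, geom, 0.9e6, cfg)
  gt <- make_object_function(med, 0.9e6)
  g0 <- make_object_function(
    acoustic_medium(array(1500, c(16L, 16L)), spacing = 0.4e-3), 0.9e6)
  n_t <- sqrt(sum(Mod(gradient_adjoint(gt, ds, cfg)$g)^2))
  n_0 <- sqrt(sum(Mod(gradient_adjoint(g0, ds, cfg)$g)^2))
  expect_lt(n_t, 1e-8 * n_0)
})

test_that("Jacobian application is linear with first-order secant error", {
  med <- random_soft_medium(c(16L, 16L))
  shape <- c(16L, 16L)
  geom <- tiny_geometry(shape, 0.4e-3)
  cfg <- tiny_config()
  ds <- simulate_dataset(med, geom, 0.9e6, cfg)
  g0 <- make_object_function(
    acoustic_medium(array(1500, shape), spacing = 0.4e-3), 0.9e6)
  set.seed(4)
  dg <- array(complex(real = rnorm(prod(shape)),
                      imaginary = -abs(rnorm(prod(shape)))), shape)
  ## zero perturbation and exact homogeneity
  j0 <- jacobian_apply(g0, 0 * dg, ds, cfg)
  expect_true(all(vapply(j0, function(v) all(v == 0), logical(1))))
  ja <- jacobian_apply(g0, dg, ds, cfg)
  jb <- jacobian_apply(g0, 2.5 * dg, ds, cfg)
  for (k in names(ja))
    expect_equal(jb[[k]], 2.5 * ja[[k]], tolerance = 1e-12)
  expect_error(jacobian_apply(g0, matrix(0i, 4, 4), ds, cfg), "shape")

  ## secant convergence: ||(dhat(g+eps d) - dhat(g))/eps - J d|| = O(eps)
  base <- paraxtomo:::predict_records(g0, ds, cfg)$records
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    gp <- g0; gp$gamma <- g0$gamma + eps * dg
    pp <- paraxtomo:::predict_records(gp, ds, cfg)$records
    sq <- 0
    for (k in names(ja))
      sq <- sq + sum(Mod((pp[[k]] - base[[k]]) / eps - ja[[k]])^2)
    sqrt(sq)
  }, numeric(1))
  expect_lt(errs[2] / errs[1], 0.15)          # about a decade per decade
  expect_lt(errs[3] / errs[2], 0.15)
})

test_that("accepted NCG iterations cost exactly five forward solves and descend", {
  med <- random_soft_medium(c(24L, 24L), seed = 12)
  geom <- tiny_geometry(c(24L, 24L), 0.4e-3, views = 12, cols = 16)
  cfg <- tiny_config()
  ds <- simulate_dataset(med, geom, 0.8e6, cfg)
  g0 <- make_object_function(
    acoustic_medium(array(1500, c(24L, 24L)), spacing = 0.4e-3), 0.8e6)
  st <- inversion_state(g0)
  objs <- numeric(0)
  for (i in 1:5) {
    n0 <- st$counter$n
    st <- ncg_iterate(st, ds, cfg)
    expect_equal(st$counter$n - n0, 5L)       # 2 gradient + 2 Jacobian + 1
    objs <- c(objs, st$objective)
  }
  expect_equal(st$accepted, 5L)
  expect_true(all(diff(objs) < 0))
})

test_that("NCG on a linearized problem matches the dense least-squares solve", {
  shape <- c(5L, 5L); h <- 0.3e-3; f <- 1.2e6
  geom <- acquisition_geometry(seq(0, 360 - 11.25, by = 11.25), 0, 1, 5,
                               receiver_pitch = h,
                               propagation_distance = shape[1] * h)
  cfg <- tiny_config()
  water <- acoustic_medium(array(1500, shape), spacing = h)
  g0 <- make_object_function(water, f)
  base <- simulate_dataset(water, geom, f, cfg)
  dtru <- array(0, shape); dtru[2:4, 2:4] <- 1e-8
  jd <- jacobian_apply(g0, dtru + 0i, base, cfg)
  meas <- base
  for (k in names(jd)) meas$data[[k]] <- base$data[[k]] + jd[[k]]
  ## dense Jacobian column by column -> normal-equations solution
  n <- prod(shape)
  cols <- lapply(seq_len(n), function(v) {
    e <- array(0, shape); e[v] <- 1
    unlist(lapply(jacobian_apply(g0, e + 0i, base, cfg),
                  function(x) c(Re(x), Im(x))))
  })
  J <- do.call(cbind, cols)
  rhs <- unlist(lapply(names(jd), function(k) c(Re(jd[[k]]), Im(jd[[k]]))))
  xls <- solve(crossprod(J), crossprod(J, rhs))[, 1]
  st <- inversion_state(g0, freeze_im = TRUE, restart_every = 1000L)
  for (i in 1:200) {
    st <- ncg_iterate(st, meas, cfg)
    if (st$converged) break
  }
  xncg <- as.vector(Re(st$gamma$gamma))
  expect_lt(sqrt(sum((xncg - xls)^2) / sum(xls^2)), 1e-6)
})

test_that("frequency hopping is guarded, bookkept, and beats one frequency", {
  ## a large high-contrast disc accumulates > pi of phase at 0.9 MHz, so
  ## a water-started single-frequency inversion cycle-skips while the
  ## multiscale ladder walks into the right basin
  shape <- c(48L, 48L); h <- 0.4e-3
  layout <- list(list(tissue = "cartilage", center = c(0, 0),
                      radius = 5e-3))
  truth <- make_soft_tissue_phantom(shape, h, layout)
  geom <- tiny_geometry(shape, h, views = 24, cols = 40)
  freqs <- c(0.35e6, 0.6e6, 0.9e6)            # 0.9 MHz: 4.2 ppw at 0.4 mm
  ds <- simulate_dataset(truth, geom, freqs)

  ## missing frequency fails before any compute
  expect_error(run_frequency_hopping(
    ds, reconstruction_protocol(c(0.35e6, 0.45e6), 2L), shape, h),
    "lacks protocol frequency")

  hop <- run_frequency_hopping(
    ds, reconstruction_protocol(freqs, c(8L, 6L, 6L), init = "uniform"),
    shape, h)
  single <- run_frequency_hopping(
    ds, reconstruction_protocol(0.9e6, 20L, init = "uniform"), shape, h)
  rmse <- function(m) sqrt(mean((m$sos - truth$sos)^2))
  expect_lt(rmse(hop$medium), rmse(single$medium))
  expect_lt(hop$report$stages[[3]]$final_objective,
            single$report$stages[[1]]$final_objective)

  ## ledger: accepted iterations x 5 never exceeds the recorded solves,
  ## and matches exactly when every candidate was accepted first try
  for (s in hop$report$stages) {
    expect_gte(s$forward_solves, 5L * s$accepted_iterations)
  }
  expect_equal(hop$report$total_forward_solves,
               sum(vapply(hop$report$stages, `[[`, numeric(1),
                          "forward_solves")))
})

test_that("a single water stage from water init returns water immediately", {
  shape <- c(24L, 24L); h <- 0.4e-3
  med <- acoustic_medium(array(1500, shape), spacing = h)
  geom <- tiny_geometry(shape, h)
  ds <- simulate_dataset(med, geom, 0.8e6)
  out <- run_frequency_hopping(
    ds, reconstruction_protocol(0.8e6, 3L, init = "uniform"), shape, h)
  expect_equal(out$medium$sos, med$sos, tolerance = 1e-9)
  expect_equal(out$report$stages[[1]]$accepted_iterations, 0L)
})

test_that("time-of-flight initialization matches its straight-ray oracle", {
  h <- 0.35e-3; shape <- c(64L, 64L)
  geom <- desk_scale_geometry(views = 36, cols = 56, receiver_pitch = h,
                              propagation_distance = shape[1] * h)
  ## water data maps to the exact background speed
  dw <- simulate_dataset(acoustic_medium(array(1500, shape), spacing = h),
                         geom, 0.35e6)
  ew <- tof_initialize(dw, shape, h)
  expect_equal(range(ew$sos), c(1500, 1500), tolerance = 1e-9)
  ## too few views rejected
  geom8 <- desk_scale_geometry(views = 8, cols = 56, receiver_pitch = h,
                               propagation_distance = shape[1] * h)
  d8 <- dw; d8$geometry <- geom8
  d8$geometry$view_angles_deg <- c(0, 90)     # degenerate coverage
  expect_error(tof_initialize(d8, shape, h), ">= 8 views")

  ## same-ray-model oracle: SART recovers a cylinder interior within 5%
  recv_y <- paraxtomo:::receiver_offsets(geom)$y
  s_true <- 1 / 1571 - 1 / 1500
  cover <- paraxtomo:::cylinder_coverage(shape, c(h, h), c(0, 0), 5e-3)
  ds_true <- s_true * cover
  delays <- list()
  for (th in geom$view_angles_deg)
    delays[[as.character(th)]] <-
      paraxtomo:::tof_project(ds_true, th, c(h, h), recv_y)
  ## analytic centre chord: delay = D * delta-slowness
  expect_equal(max(abs(delays[["0"]])), abs(10e-3 * s_true),
               tolerance = 0.01)
  sol <- paraxtomo:::tof_sart(delays, c(h, h), shape, recv_y)
  interior <- cover > 0.99
  expect_lt(abs(mean(sol[interior]) - s_true) / abs(s_true), 0.05)
})
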