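# Shared small fixtures: every object is built in code at test time.

## random mildly heterogeneous 2D medium (soft-tissue regime)
random_soft_medium <- function(shape = c(16L, 16L), h = 0.4e-3, seed = 7,
                               atten = 20) {
  set.seed(seed)
  sos <- array(1500 * (1 + 0.02 * (array(stats::runif(prod(shape)),
                                         shape) - 0.5)), shape)
  acoustic_medium(sos, array(atten, shape), h)
}

## small acquisition around a square grid
tiny_geometry <- function(shape, h, views = 8, cols = 12) {
  desk_scale_geometry(views = views, cols = cols, receiver_pitch = h,
                      propagation_distance = shape[1] * h)
}

tiny_config <- function() propagator_config(pad = 8L, taper = 4L)

## real-valued inner product over the (Re, Im) pair of complex arrays
ip_pair <- function(a, b) sum(Re(a) * Re(b) + Im(a) * Im(b))

## data residual norm over a record list
records_norm2 <- function(recs) sum(vapply(recs, function(v)
  sum(Mod(v)^2), numeric(1)))

## adjoint-identity discrepancy for a given medium/geometry/config
adjoint_identity_error <- function(medium, geom, cfg, f, seed = 1) {
  set.seed(seed)
  shape <- dim(medium$sos)
  ds <- simulate_dataset(medium, geom, f, cfg)
  g0 <- make_object_function(
    acoustic_medium(array(medium$c0, shape), spacing = medium$spacing,
                    c0 = medium$c0), f)
  dg <- array(complex(real = stats::rnorm(prod(shape)),
                      imaginary = stats::rnorm(prod(shape))), shape) * 1e-3
  jd <- jacobian_apply(g0, dg, ds, cfg)
  w <- lapply(jd, function(x)
    complex(real = stats::rnorm(length(x)),
            imaginary = stats::rnorm(length(x))))
  names(w) <- names(jd)
  lhs <- sum(vapply(names(jd), function(k)
    sum(Re(Conj(w[[k]]) * jd[[k]])), numeric(1)))
  pr <- paraxtomo:::predict_records(g0, ds, cfg)$records
  pred_ds <- ds
  for (k in names(pr)) pred_ds$data[[k]] <- pr[[k]] - w[[k]]
  gw <- gradient_adjoint(g0, pred_ds, cfg)
  rhs <- sum(Re(dg) * gw$re + Im(dg) * gw$im)
  abs(lhs - rhs) / abs(lhs)
}

## worst finite-difference error of the adjoint gradient over a few voxels
fd_gradient_error <- function(medium, geom, cfg, f, n_voxels = 5,
                              seed = 1) {
  set.seed(seed)
  shape <- dim(medium$sos)
  ds <- simulate_dataset(medium, geom, f, cfg)
  g0 <- make_object_function(
    acoustic_medium(array(medium$c0, shape), spacing = medium$spacing,
                    c0 = medium$c0), f)
  gr <- gradient_adjoint(g0, ds, cfg)
  eps <- 1e-7
  worst <- 0
  for (v in sample(prod(shape), n_voxels)) {
    for (im in c(FALSE, TRUE)) {
      dstep <- if (im) 1i * eps else eps
      gp <- g0; gp$gamma[v] <- gp$gamma[v] + dstep
      gm <- g0; gm$gamma[v] <- gm$gamma[v] - dstep
      fd <- (objective(gp, ds, cfg) - objective(gm, ds, cfg)) / (2 * eps)
      g_adj <- if (im) gr$im[v] else gr$re[v]
      worst <- max(worst, abs(g_adj - fd) / max(abs(fd), 1e-12))
    }
  }
  worst
}
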