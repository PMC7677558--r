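# Frequency-hopping inverse scattering. The objective is the L2 data
# misfit  J(gamma) = 1/2 sum_{f,theta,l} || dhat(gamma) - d ||^2  over the
# complex receiver vectors. Unknowns are Re(gamma) and Im(gamma) jointly,
# stored in one complex array; inner products are the real Euclidean ones
# over the (Re, Im) pair. Gradients come from an adjoint march that reuses
# the forward operators, so the adjoint identity holds to machine
# precision; one accepted Polak-Ribiere NCG iteration costs exactly five
# forward-problem equivalents (2 gradient + 2 Jacobian + 1 residual check).

#' Forward-solve counter
#'
#' Mutable counter of forward-problem-equivalent propagations, shared by
#' [objective()], [gradient_adjoint()], [jacobian_apply()] and
#' [ncg_iterate()] to audit the per-iteration cost budget.
#' @return environment with field `n`.
#' @export
forward_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

count_forward <- function(counter, k = 1L) {
  if (!is.null(counter)) counter$n <- counter$n + as.integer(k)
  invisible(counter)
}

## real inner product over the (Re, Im) unknown pair, complex storage
ip_re <- function(a, b) sum(Re(a) * Re(b) + Im(a) * Im(b))

## all measured records must sit at the working frequency of gamma
check_single_frequency <- function(gamma_obj, measured) {
  f <- gamma_obj$frequency
  ks <- dataset_keys(measured)
  if (any(abs(ks$f - f) > 1e-6))
    stop_ptx("measured data holds frequencies other than the working %g Hz", f)
}

#' Data residual: predicted minus measured
#'
#' Elementwise complex difference per (frequency, view, level) record.
#'
#' @param predicted,measured [fd_dataset()]s with identical keys and
#'   record lengths.
#' @return named list of complex residual vectors, one per record key.
#' @export
compute_residual <- function(predicted, measured) {
  kp <- sort(names(predicted$data)); km <- sort(names(measured$data))
  if (!identical(kp, km))
    stop_ptx("record keys differ (first mismatch: %s)",
             setdiff(union(kp, km), intersect(kp, km))[1])
  out <- vector("list", length(kp)); names(out) <- kp
  for (k in kp) {
    a <- predicted$data[[k]]; b <- measured$data[[k]]
    if (length(a) != length(b))
      stop_ptx("record %s: lengths %d vs %d", k, length(a), length(b))
    out[[k]] <- a - b
  }
  out
}

## internal: predicted records for gamma over the measured keys; optionally
## keeps per-view march state for the adjoint
predict_records <- function(gamma_obj, measured, config,
                            keep = FALSE) {
  geometry <- measured$geometry
  g <- gamma_obj$gamma
  sp <- gamma_obj$spacing
  grid_depth <- dim(g)[1] * sp[1]
  extra <- max(0, geometry$propagation_distance - grid_depth)
  views <- geometry$view_angles_deg
  out <- list(records = list(), marches = if (keep) list() else NULL)
  for (th in views) {
    g_rot <- if (th != 0) rotate_gamma(g, th, sp) else g
    mres <- march_forward(g_rot, gamma_obj$frequency, gamma_obj$c0, sp,
                          config, keep_slabs = keep, extra_distance = extra)
    vals <- crop_slab(mres$u, mres$pad, mres$tdims_in)
    tdims_in <- if (is.null(dim(vals))) length(vals) else dim(vals)
    plans <- list()
    for (lv in geometry$levels_m) {
      plan <- sampler_plan(geometry, tdims_in, sp[-1], lv)
      out$records[[fvl_key(gamma_obj$frequency, th, lv)]] <-
        sampler_apply(plan, vals)
      plans[[as.character(lv)]] <- plan
    }
    if (keep) out$marches[[as.character(th)]] <-
        list(mres = mres, plans = plans, theta = th)
  }
  out
}

#' L2 data-misfit objective
#'
#' `1/2 sum ||dhat(gamma) - d||^2` over every (view, level) record at the
#' working frequency. One call predicts the full dataset once and
#' increments the forward counter by 1.
#'
#' @param gamma_obj current `object_function` estimate.
#' @param measured [fd_dataset()] of measured (simulated) data at the same
#'   frequency.
#' @param config a [propagator_config()].
#' @param counter optional [forward_counter()].
#' @return non-negative scalar.
#' @export
objective <- function(gamma_obj, measured, config = propagator_config(),
                      counter = NULL) {
  check_single_frequency(gamma_obj, measured)
  pred <- predict_records(gamma_obj, measured, config)$records
  count_forward(counter, 1L)
  s <- 0
  for (k in names(pred))
    s <- s + sum(Mod(pred[[k]] - measured$data[[k]])^2)
  s / 2
}

#' Adjoint-state gradient of the objective
#'
#' Gradient with respect to `Re(gamma)` and `Im(gamma)` per voxel, from the
#' stored forward slab fields and a reverse-marched adjoint field whose
#' per-slab correlation accumulates the gradient; the per-view gradients
#' are rotated back to the lab frame with the exact adjoint of the view
#' resampling. Costs 2 forward equivalents (counter +2).
#'
#' @inheritParams objective
#' @return list with numeric arrays `re`, `im` (the two real gradient
#'   fields), the complex packing `g = re + 1i * im`, and `objective` (the
#'   misfit at `gamma_obj`, a by-product of the forward pass).
#' @export
gradient_adjoint <- function(gamma_obj, measured,
                             config = propagator_config(), counter = NULL) {
  check_single_frequency(gamma_obj, measured)
  sp <- gamma_obj$spacing
  symmetric <- config$splitting == "symmetric"
  pr <- predict_records(gamma_obj, measured, config, keep = TRUE)
  count_forward(counter, 2L)
  q_lab <- array(0i, dim(gamma_obj$gamma))
  obj <- 0
  for (vm in pr$marches) {
    mres <- vm$mres
    ## adjoint source: residual scattered back through the samplers
    lam <- NULL
    for (lv_name in names(vm$plans)) {
      lv <- as.numeric(lv_name)
      k <- fvl_key(gamma_obj$frequency, vm$theta, lv)
      r <- pr$records[[k]] - measured$data[[k]]
      obj <- obj + sum(Mod(r)^2) / 2
      sc <- sampler_adjoint(vm$plans[[lv_name]], r)
      lam <- if (is.null(lam)) sc else lam + sc
    }
    lam <- pad_slab(lam, mres$pad)
    if (mres$extra_distance > 1e-12) {
      pex <- diffraction_kernel(mres$tdims, mres$tspace, mres$k0,
                                mres$extra_distance, config$variant)
      lam <- apply_kernel(lam, Conj(pex))
    }
    cfac <- -1i * mres$k0 * mres$dz
    pc <- Conj(mres$p)
    nx <- length(mres$slabs)
    q_rot <- array(0i, dim(gamma_obj$gamma))
    for (m in nx:1) {
      lt <- mres$tw * lam
      sl <- mres$slabs[[m]]
      if (symmetric) {
        mu <- apply_kernel(Conj(sl$s) * lt, pc)
        q <- (cfac / 2) * (Conj(lt) * sl$w + Conj(mu) * sl$a)
        lam <- Conj(sl$s) * mu
      } else {
        q <- Conj(lt) * (cfac * sl$w)
        lam <- apply_kernel(Conj(sl$s) * lt, pc)
      }
      qm <- crop_slab(q, mres$pad, mres$tdims_in)
      if (length(mres$tdims_in) == 1) q_rot[m, ] <- qm else q_rot[m, , ] <- qm
    }
    q_lab <- q_lab + (if (vm$theta != 0)
      rotate_gamma_adjoint(q_rot, vm$theta, sp) else q_rot)
  }
  gre <- Re(q_lab); gim <- -Im(q_lab)
  list(re = gre, im = gim, g = gre + 1i * gim, objective = obj)
}

#' Apply the Jacobian (Frechet derivative) to a model perturbation
#'
#' Linearized change of the predicted data for a perturbation
#' `delta_gamma` of the complex object function, by a tangent march run
#' alongside the forward march. Costs 2 forward equivalents (counter +2).
#'
#' @inheritParams objective
#' @param delta_gamma complex array, same shape as `gamma_obj$gamma`.
#' @return named list of complex data perturbation vectors per record key.
#' @export
jacobian_apply <- function(gamma_obj, delta_gamma, measured,
                           config = propagator_config(), counter = NULL) {
  check_single_frequency(gamma_obj, measured)
  if (!identical(dim(delta_gamma), dim(gamma_obj$gamma)))
    stop_ptx("delta_gamma shape %s does not match gamma %s",
             paste(dim(delta_gamma), collapse = "x"),
             paste(dim(gamma_obj$gamma), collapse = "x"))
  sp <- gamma_obj$spacing
  pr <- predict_records(gamma_obj, measured, config, keep = TRUE)
  count_forward(counter, 2L)
  out <- list()
  for (vm in pr$marches) {
    mres <- vm$mres
    dg_rot <- if (vm$theta != 0)
      rotate_gamma(delta_gamma, vm$theta, sp) else delta_gamma
    cfac <- -1i * mres$k0 * mres$dz
    symmetric <- config$splitting == "symmetric"
    du <- 0 * mres$u
    nd <- length(mres$tdims_in) + 1L
    for (m in seq_along(mres$slabs)) {
      dgm <- pad_slab(if (nd == 2) dg_rot[m, ] else dg_rot[m, , ], mres$pad)
      sl <- mres$slabs[[m]]
      dw <- if (symmetric) {
        (cfac / 2) * dgm * sl$w +
          sl$s * apply_kernel((cfac / 2) * dgm * sl$a + sl$s * du, mres$p)
      } else {
        sl$s * apply_kernel(du, mres$p) + cfac * sl$w * dgm
      }
      du <- mres$tw * dw
    }
    if (mres$extra_distance > 1e-12) {
      pex <- diffraction_kernel(mres$tdims, mres$tspace, mres$k0,
                                mres$extra_distance, config$variant)
      du <- apply_kernel(du, pex)
    }
    dvals <- crop_slab(du, mres$pad, mres$tdims_in)
    for (lv_name in names(vm$plans))
      out[[fvl_key(gamma_obj$frequency, vm$theta, as.numeric(lv_name))]] <-
        sampler_apply(vm$plans[[lv_name]], dvals)
  }
  out
}

## ---- nonlinear conjugate gradients -----------------------------------------

#' Initialize the inversion state for one frequency stage
#'
#' @param gamma_obj starting `object_function` at the stage frequency.
#' @param freeze_im if TRUE the imaginary part (attenuation) is frozen at
#'   its starting value and only `Re(gamma)` is updated.
#' @param counter a [forward_counter()] (created if NULL).
#' @param restart_every steepest-descent restart period (standard
#'   safeguard for nonlinear problems; raise it for near-quadratic ones).
#' @return list of class `inversion_state`.
#' @export
inversion_state <- function(gamma_obj, freeze_im = FALSE, counter = NULL,
                            restart_every = 20L) {
  structure(list(gamma = gamma_obj, grad_prev = NULL, dir_prev = NULL,
                 objective = NA_real_, history = numeric(0),
                 iter = 0L, accepted = 0L, freeze_im = freeze_im,
                 counter = counter %||% forward_counter(),
                 restart_every = as.integer(restart_every),
                 converged = FALSE),
            class = "inversion_state")
}

## keep the candidate physical: Re(gamma) > -1, Im(gamma) <= 0
project_gamma <- function(g) {
  re <- pmax(Re(g), -0.9)
  im <- pmin(Im(g), 0)
  array(complex(real = re, imaginary = im), dim(g))
}

#' One Polak-Ribiere nonlinear CG iteration
#'
#' Computes the adjoint gradient (+2 forward equivalents), a
#' Polak-Ribiere+ conjugate direction (beta clipped at 0, periodic
#' steepest-descent restarts), an exact step length from the quadratic
#' model via one Jacobian application (+2), and a residual check of the
#' candidate (+1): exactly 5 forward-problem equivalents per accepted
#' iteration. A candidate that fails to decrease the objective is
#' backtracked by halving (each re-check +1); repeated failure flags the
#' state `converged`.
#'
#' @param state an [inversion_state()].
#' @param measured measured [fd_dataset()] at the stage frequency.
#' @param config a [propagator_config()].
#' @param max_backtracks halvings before giving up.
#' @return updated `inversion_state`.
#' @export
ncg_iterate <- function(state, measured, config = propagator_config(),
                        max_backtracks = 8L) {
  gr <- gradient_adjoint(state$gamma, measured, config, state$counter)
  G <- gr$g
  if (state$freeze_im) G <- complex(real = Re(G), imaginary = 0)
  if (is.na(state$objective)) state$objective <- gr$objective
  gnorm2 <- ip_re(G, G)
  if (gnorm2 == 0) { state$converged <- TRUE; return(state) }
  beta <- 0
  if (!is.null(state$grad_prev) && state$iter %% state$restart_every != 0) {
    denom <- ip_re(state$grad_prev, state$grad_prev)
    beta <- max(0, ip_re(G, G - state$grad_prev) / denom)
  }
  dir <- -G + beta * (state$dir_prev %||% (0 * G))
  if (ip_re(dir, -G) <= 0) dir <- -G          # safeguard: ensure descent
  jd <- jacobian_apply(state$gamma, array(dir, dim(state$gamma$gamma)),
                       measured, config, state$counter)
  jd2 <- sum(vapply(jd, function(v) sum(Mod(v)^2), numeric(1)))
  gd <- ip_re(G, dir)
  alpha <- if (jd2 > 0) -gd / jd2 else 0
  if (!is.finite(alpha) || alpha <= 0) { dir <- -G
    jd <- jacobian_apply(state$gamma, array(dir, dim(state$gamma$gamma)),
                         measured, config, state$counter)
    jd2 <- sum(vapply(jd, function(v) sum(Mod(v)^2), numeric(1)))
    alpha <- -ip_re(G, dir) / jd2
  }
  accepted <- FALSE
  for (bt in 0:max_backtracks) {
    cand <- state$gamma
    cand$gamma <- project_gamma(state$gamma$gamma +
                                  alpha * array(dir, dim(state$gamma$gamma)))
    obj_c <- objective(cand, measured, config, state$counter)
    if (is.finite(obj_c) && obj_c < state$objective) {
      state$gamma <- cand
      state$objective <- obj_c
      accepted <- TRUE
      break
    }
    alpha <- alpha / 2
  }
  state$iter <- state$iter + 1L
  if (accepted) {
    state$accepted <- state$accepted + 1L
    state$history <- c(state$history, state$objective)
    state$grad_prev <- G
    state$dir_prev <- dir
  } else {
    state$converged <- TRUE                   # stage exhausted at this freq
  }
  state
}

## ---- frequency hopping ------------------------------------------------------

#' Run the full frequency-hopping reconstruction
#'
#' Executes the protocol stages in order. Each stage encodes the running
#' (speed of sound, attenuation) volumes into the object function at its
#' frequency, runs NCG for the stage's iteration budget (early exit when
#' the relative objective decrease falls below `tol`), and decodes the
#' result back into physical volumes, which warm-start the next stage.
#' Carrying the state as physical volumes makes the attenuation slope
#' frequency-consistent across stages without any ad hoc rescaling.
#'
#' @param measured [fd_dataset()] holding every protocol frequency.
#' @param protocol a [reconstruction_protocol()].
#' @param shape,spacing reconstruction grid (2D or 3D) and voxel size, m.
#' @param c0 background speed of sound, m/s.
#' @param config a [propagator_config()].
#' @param init_medium starting [acoustic_medium()] when
#'   `protocol$init == "provided"`.
#' @param freeze_im freeze the attenuation (imaginary) unknowns.
#' @param tol relative objective-decrease early-exit threshold.
#' @param verbose print per-stage progress.
#' @return list with `medium` (reconstructed [acoustic_medium()]) and
#'   `report` (per-stage objective curves, accepted iteration and forward
#'   counts).
#' @export
run_frequency_hopping <- function(measured, protocol, shape, spacing,
                                  c0 = 1500, config = propagator_config(),
                                  init_medium = NULL, freeze_im = FALSE,
                                  tol = 1e-6, verbose = FALSE) {
  stopifnot(inherits(protocol, "reconstruction_protocol"))
  have <- unique(dataset_keys(measured)$f)
  missing_f <- setdiff(protocol$frequencies_hz, have)
  if (length(missing_f) > 0)
    stop_ptx("measured data lacks protocol frequency %g Hz", missing_f[1])
  spacing <- if (length(spacing) == 1L) rep(spacing, length(shape)) else spacing
  medium <- switch(protocol$init,
    uniform = acoustic_medium(array(c0, shape), array(0, shape), spacing, c0),
    provided = {
      if (is.null(init_medium)) stop_ptx("init = 'provided' needs init_medium")
      init_medium
    },
    tof = tof_initialize(measured, shape = shape, spacing = spacing, c0 = c0,
                         config = config))
  counter <- forward_counter()
  stages <- list()
  for (s in seq_along(protocol$frequencies_hz)) {
    f <- protocol$frequencies_hz[s]
    sub <- dataset_subset(measured, f)
    gam <- make_object_function(medium, f)
    st <- inversion_state(gam, freeze_im = freeze_im, counter = counter)
    n0 <- counter$n
    for (it in seq_len(protocol$iterations[s])) {
      obj_before <- st$objective
      st <- ncg_iterate(st, sub, config)
      if (verbose)
        message(sprintf("stage %d (%.2f MHz) iter %d: J = %.6g", s, f / 1e6,
                        it, st$objective))
      if (st$converged) break
      if (is.finite(obj_before) &&
          (obj_before - st$objective) < tol * obj_before) break
    }
    medium <- extract_sos_attenuation(st$gamma)
    stages[[s]] <- list(frequency_hz = f, objective = st$history,
                        final_objective = st$objective,
                        accepted_iterations = st$accepted,
                        forward_solves = counter$n - n0)
  }
  list(medium = medium,
       report = list(stages = stages, total_forward_solves = counter$n,
                     protocol = unclass(protocol)))
}

#' Restrict a dataset to one frequency
#' @param ds an [fd_dataset()].
#' @param f frequency, Hz.
#' @export
dataset_subset <- function(ds, f) {
  out <- fd_dataset(ds$geometry, f, ds$provenance)
  pref <- sprintf("f%.8g|", f)
  keep <- startsWith(names(ds$data), pref)
  if (!any(keep)) stop_ptx("dataset has no records at %g Hz", f)
  out$data <- ds$data[keep]
  out
}
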