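# Refractive-index fields, first-arrival travel-time solutions of the
# eikonal equation |grad(phi)| = n, and ray tracing through the index
# gradient. phi has units of length (optical path); travel time is phi/c0.

#' Refractive index field
#'
#' `n(x) = c0 / c(x)`, dimensionless, on a voxel grid.
#'
#' @param n positive numeric array (2D or 3D).
#' @param spacing per-axis voxel size, m.
#' @return object of class `index_field`.
#' @export
index_field <- function(n, spacing) {
  n <- as.array(n)
  if (any(!is.finite(n)) || any(n <= 0))
    stop_ptx("refractive index must be positive and finite everywhere")
  spacing <- if (length(spacing) == 1L) rep(spacing, length(dim(n))) else
    as.numeric(spacing)
  structure(list(n = n, spacing = spacing), class = "index_field")
}

#' @rdname index_field
#' @param medium an [acoustic_medium()].
#' @export
index_from_medium <- function(medium) {
  index_field(medium$c0 / medium$sos, medium$spacing)
}

#' First-arrival travel-time field by fast sweeping
#'
#' Solves the eikonal equation `|grad(phi)| = n` for the first-arrival
#' phase/travel function `phi` (units of length; time = `phi / c0`) from a
#' point source, using Gauss-Seidel fast sweeping with first-order upwind
#' differences. `phi` is exact (`n_src * distance`) in a small seeded
#' neighbourhood of the source to reduce the point-source singularity
#' error.
#'
#' @param index an [index_field()].
#' @param source voxel index vector of the source (length = #dims).
#' @param tol sweep convergence tolerance on `phi`, m.
#' @param max_iter maximum full sweep passes.
#' @return object of class `travel_time_field`: list with `phi` array,
#'   `source`, `spacing`.
#' @export
solve_eikonal <- function(index, source, tol = 1e-10, max_iter = 50L) {
  stopifnot(inherits(index, "index_field"))
  d <- dim(index$n)
  source <- as.integer(round(source))
  if (length(source) != length(d) || any(source < 1) || any(source > d))
    stop_ptx("source voxel (%s) outside grid (%s)",
             paste(source, collapse = ","), paste(d, collapse = "x"))
  phi <- array(Inf, d)
  ## seed the exact solution in a 2-voxel ball around the source
  n_src <- index$n[matrix(source, 1)]
  seed_r <- 2L
  rng <- lapply(seq_along(d), function(a)
    max(1, source[a] - seed_r):min(d[a], source[a] + seed_r))
  idx <- as.matrix(expand.grid(rng))
  dist <- sqrt(rowSums((sweep(idx, 2, source) *
                          rep(index$spacing, each = nrow(idx)))^2))
  phi[idx] <- n_src * dist
  out <- fast_sweep_eikonal(as.vector(phi), as.vector(index$n),
                            as.integer(d), index$spacing, tol,
                            as.integer(max_iter))
  structure(list(phi = array(out, d), source = source,
                 spacing = index$spacing),
            class = "travel_time_field")
}

## bilinear interpolation of a 2D array at physical points (centred coords)
interp2 <- function(arr, spacing, x, y, rule_clip = TRUE) {
  nx <- nrow(arr); ny <- ncol(arr)
  fi <- x / spacing[1] + (nx + 1) / 2
  fj <- y / spacing[2] + (ny + 1) / 2
  if (rule_clip) {
    fi <- pmin(pmax(fi, 1), nx - 1e-9)
    fj <- pmin(pmax(fj, 1), ny - 1e-9)
  }
  i0 <- pmin(floor(fi), nx - 1); j0 <- pmin(floor(fj), ny - 1)
  wi <- fi - i0; wj <- fj - j0
  arr[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    arr[cbind(i0 + 1, j0)] * wi * (1 - wj) +
    arr[cbind(i0, j0 + 1)] * (1 - wi) * wj +
    arr[cbind(i0 + 1, j0 + 1)] * wi * wj
}

#' Trace a ray through the index gradient
#'
#' Integrates the ray system `d/ds (n dr/ds) = grad(n)` (with
#' `p = n dr/ds`, so `dr/ds = p/n`, `dp/ds = grad(n)`) by classical
#' fourth-order Runge-Kutta steps of arclength `step`, from `start` in
#' unit direction `direction`, until the ray leaves the grid or
#' `max_length` is reached. 2D index fields only.
#'
#' @param index an [index_field()] (2D).
#' @param start physical start point, m (centred coordinates).
#' @param direction initial direction (normalized internally; must be
#'   nonzero).
#' @param step arclength step, m; at most one voxel.
#' @param max_length maximum path length, m.
#' @return object of class `ray_path`: list with `points` (k x 2 matrix),
#'   `optical_path` (accumulated `integral n ds`), `length`.
#' @export
trace_ray <- function(index, start, direction, step = NULL,
                      max_length = NULL) {
  stopifnot(inherits(index, "index_field"))
  if (length(dim(index$n)) != 2)
    stop_ptx("trace_ray operates on 2D index fields")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_ptx("zero ray direction")
  direction <- direction / nrm
  h <- index$spacing
  step <- step %||% (0.5 * min(h))
  if (step > min(h) + 1e-12)
    stop_ptx("step %g m exceeds the voxel spacing %g m", step, min(h))
  d <- dim(index$n)
  extent <- d * h / 2
  max_length <- max_length %||% (4 * sum(extent))
  ## centred-difference index gradient, interpolated bilinearly
  n_arr <- index$n
  gx <- n_arr; gx[] <- 0
  gx[2:(d[1] - 1), ] <- (n_arr[3:d[1], ] - n_arr[1:(d[1] - 2), ]) / (2 * h[1])
  gy <- n_arr; gy[] <- 0
  gy[, 2:(d[2] - 1)] <- (n_arr[, 3:d[2]] - n_arr[, 1:(d[2] - 2)]) / (2 * h[2])
  n_at <- function(p) interp2(n_arr, h, p[1], p[2])
  g_at <- function(p) c(interp2(gx, h, p[1], p[2]),
                        interp2(gy, h, p[1], p[2]))
  deriv <- function(state) {
    r <- state[1:2]; p <- state[3:4]
    c(p / n_at(r), g_at(r))
  }
  r <- start
  p <- direction * n_at(start)
  n_steps <- ceiling(max_length / step)
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- r
  opl <- 0
  k <- 1L
  inside <- function(r) all(abs(r) <= extent - h / 2)
  state <- c(r, p)
  while (k <= n_steps && inside(state[1:2])) {
    opl <- opl + n_at(state[1:2]) * step   # midpoint-free running integral
    k1 <- deriv(state)
    k2 <- deriv(state + step / 2 * k1)
    k3 <- deriv(state + step / 2 * k2)
    k4 <- deriv(state + step * k3)
    state <- state + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    k <- k + 1L
    pts[k, ] <- state[1:2]
  }
  pts <- pts[seq_len(k), , drop = FALSE]
  structure(list(points = pts, optical_path = opl,
                 length = (k - 1) * step, final_momentum = state[3:4]),
            class = "ray_path")
}
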