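# Acquisition geometry, frequency ladder/protocol, chirp emulation and the
# frequency-domain dataset container.

#' Rotating plane-wave acquisition geometry
#'
#' A plane-wave source and an opposing receiver array rotate around the
#' object in a water bath; a view is one azimuthal shot. Receiver elements
#' form a `receiver_rows` x `receiver_cols` grid (rows stacked vertically),
#' and the assembly is repeated at each vertical `level`.
#'
#' @param view_angles_deg azimuthal view angles, degrees, strictly
#'   increasing within `[0, 360)`.
#' @param levels_m vertical positions of the array, m.
#' @param receiver_rows,receiver_cols element grid size; `N_R = rows * cols`.
#' @param receiver_pitch element spacing along the columns (transverse), m.
#' @param row_pitch element spacing along the rows (vertical), m.
#' @param propagation_distance source-to-receiver distance, m.
#' @param aperture transverse extent of the array, m (defaults to
#'   `receiver_pitch * (receiver_cols - 1)`).
#' @return Object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(view_angles_deg, levels_m = 0,
                                 receiver_rows, receiver_cols,
                                 receiver_pitch = 0.8e-3,
                                 row_pitch = 2e-3,
                                 propagation_distance = 0.2,
                                 aperture = NULL) {
  v <- as.numeric(view_angles_deg)
  if (any(diff(v) <= 0) || any(v < 0) || any(v >= 360))
    stop_ptx("view angles must be strictly increasing within [0, 360)")
  if (receiver_rows < 1 || receiver_cols < 1)
    stop_ptx("degenerate receiver grid %dx%d", receiver_rows, receiver_cols)
  aperture <- aperture %||% (receiver_pitch * (receiver_cols - 1))
  if (receiver_pitch * (receiver_cols - 1) > aperture + 1e-12)
    stop_ptx("element span %g m exceeds stated aperture %g m",
             receiver_pitch * (receiver_cols - 1), aperture)
  structure(list(view_angles_deg = v, levels_m = as.numeric(levels_m),
                 receiver_rows = as.integer(receiver_rows),
                 receiver_cols = as.integer(receiver_cols),
                 receiver_pitch = receiver_pitch, row_pitch = row_pitch,
                 propagation_distance = propagation_distance,
                 aperture = aperture),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> %d views, %d level(s), %dx%d = %d receivers\n",
    length(x$view_angles_deg), length(x$levels_m), x$receiver_rows,
    x$receiver_cols, n_receivers(x)))
  invisible(x)
}

#' Number of receiver elements N_R
#' @param geometry an [acquisition_geometry()].
#' @export
n_receivers <- function(geometry) {
  geometry$receiver_rows * geometry$receiver_cols
}

## transverse (y) and vertical (z) element-centre offsets, row-major order
receiver_offsets <- function(geometry) {
  y <- axis_coords(geometry$receiver_cols, geometry$receiver_pitch)
  z <- axis_coords(geometry$receiver_rows, geometry$row_pitch)
  list(y = rep(y, each = geometry$receiver_rows),
       z = rep(z, times = geometry$receiver_cols))
}

#' Full-scale clinical acquisition geometry
#'
#' The full-scale configuration: the array rotates through 360 degrees
#' shooting a pseudo-plane wave every 2 degrees (180 views), receiver array
#' of 2048 elements in 8 rows and 256 columns, vertical steps of 2 mm.
#'
#' @param n_levels number of 2 mm-spaced vertical levels (default 1).
#' @return An [acquisition_geometry()] with `N_R = 2048`.
#' @export
default_full_scale_geometry <- function(n_levels = 1) {
  levels <- (seq_len(n_levels) - (n_levels + 1) / 2) * 2e-3
  acquisition_geometry(view_angles_deg = seq(0, 358, by = 2),
                       levels_m = levels,
                       receiver_rows = 8, receiver_cols = 256,
                       receiver_pitch = 0.8e-3, row_pitch = 2e-3,
                       propagation_distance = 0.2)
}

#' Reduced desk-scale geometry for fast experiments
#'
#' Self-consistent scaled-down geometry preserving the structure of the
#' full-scale scan (uniform azimuthal coverage of 360 degrees, rectangular
#' receiver grid).
#'
#' @param views number of views over 360 degrees (>= 8).
#' @param rows,cols receiver grid (rows >= 1, cols >= 8).
#' @param receiver_pitch,row_pitch element spacings, m.
#' @param propagation_distance source-to-receiver distance, m.
#' @param levels_m vertical positions, m.
#' @return An [acquisition_geometry()].
#' @export
desk_scale_geometry <- function(views = 36, rows = 1, cols = 64,
                                receiver_pitch = 0.35e-3, row_pitch = 2e-3,
                                propagation_distance = 22.4e-3,
                                levels_m = 0) {
  if (views < 8 || rows < 1 || cols < 8)
    stop_ptx("degenerate desk geometry (need views >= 8, rows >= 1, cols >= 8)")
  acquisition_geometry(view_angles_deg = seq(0, 360 - 360 / views,
                                             by = 360 / views),
                       levels_m = levels_m,
                       receiver_rows = rows, receiver_cols = cols,
                       receiver_pitch = receiver_pitch, row_pitch = row_pitch,
                       propagation_distance = propagation_distance)
}

#' Frequency ladder
#'
#' Strictly increasing working frequencies for the multiscale inversion,
#' Hz. The clinical ladder runs 0.35, 0.4, 0.5, ..., 1.3 MHz.
#'
#' @param frequencies_hz numeric vector, Hz.
#' @return Object of class `frequency_ladder` (numeric vector).
#' @export
frequency_ladder <- function(frequencies_hz) {
  f <- as.numeric(frequencies_hz)
  if (any(f <= 0) || any(diff(f) <= 0))
    stop_ptx("ladder frequencies must be positive and strictly increasing")
  structure(f, class = "frequency_ladder")
}

#' Reconstruction protocol (frequency hopping schedule)
#'
#' Ordered stages of (frequency, iteration count) plus the initialization
#' mode. Reconstruction starts from a time-of-flight estimate at the lowest
#' frequency and warm-starts each higher frequency from the previous image.
#'
#' @param frequencies_hz non-decreasing stage frequencies, Hz.
#' @param iterations per-stage NCG iteration budgets (recycled).
#' @param init one of `"tof"`, `"uniform"`, `"provided"`.
#' @return Object of class `reconstruction_protocol`.
#' @export
reconstruction_protocol <- function(frequencies_hz, iterations,
                                    init = c("tof", "uniform", "provided")) {
  init <- match.arg(init)
  f <- as.numeric(frequencies_hz)
  it <- as.integer(rep_len(iterations, length(f)))
  if (any(diff(f) < 0)) stop_ptx("protocol frequencies must be non-decreasing")
  if (any(it < 1)) stop_ptx("iteration counts must be >= 1")
  structure(list(frequencies_hz = f, iterations = it, init = init),
            class = "reconstruction_protocol")
}

#' Default frequency-hopping protocol
#'
#' Ladder 0.35, 0.4, 0.5, ..., 1.3 MHz with per-frequency iteration budgets
#' weighted toward the low frequencies (15 at 0.35 MHz, 10 at 0.4-0.8 MHz,
#' 5 at 0.9-1.3 MHz), starting from a time-of-flight inversion. The exact
#' counts are a tunable protocol choice, not a fixed property of the method.
#'
#' @param init initialization mode, see [reconstruction_protocol()].
#' @return A `reconstruction_protocol`.
#' @export
default_frequency_protocol <- function(init = "tof") {
  f <- c(0.35, seq(0.4, 1.3, by = 0.1)) * 1e6
  it <- ifelse(f <= 0.36e6, 15L, ifelse(f <= 0.85e6, 10L, 5L))
  reconstruction_protocol(f, it, init = init)
}

#' Linear FM chirp waveform
#'
#' The time-domain excitation: a linear frequency-modulated chirp, default
#' duration 50 microseconds, sweeping a band with fractional bandwidth
#' about 1.2 around its centre.
#'
#' @param duration_s chirp length, s.
#' @param f_lo,f_hi band edges, Hz.
#' @param sample_rate_hz sampling rate, Hz; must satisfy Nyquist for `f_hi`.
#' @return list with `t` (s), `x` (waveform), `sample_rate_hz`,
#'   `f_lo`, `f_hi`.
#' @export
synthesize_chirp <- function(duration_s = 50e-6, f_lo = 0.2e6, f_hi = 1.4e6,
                             sample_rate_hz = 10e6) {
  if (duration_s <= 0) stop_ptx("duration must be positive")
  if (f_hi <= f_lo || f_lo < 0) stop_ptx("need 0 <= f_lo < f_hi")
  if (f_hi > sample_rate_hz / 2)
    stop_ptx("band edge %g Hz violates Nyquist at sample rate %g Hz",
             f_hi, sample_rate_hz)
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  k <- (f_hi - f_lo) / duration_s            # sweep rate, Hz/s
  x <- sin(2 * pi * (f_lo * t + 0.5 * k * t^2))
  list(t = t, x = x, sample_rate_hz = sample_rate_hz,
       f_lo = f_lo, f_hi = f_hi)
}

## key for one (frequency, view, level) record
fvl_key <- function(f, v, l) sprintf("f%.8g|v%.8g|l%.8g", f, v, l)

#' Frequency-domain receiver dataset
#'
#' Complex receiver vectors of length `N_R` indexed by
#' (frequency, view angle, level) — the "measured" (simulated) or predicted
#' data the inversion fits.
#'
#' @param geometry an [acquisition_geometry()].
#' @param frequencies_hz the frequencies present.
#' @param provenance `"simulated"` or `"predicted"`.
#' @return Object of class `fd_dataset` with an (initially empty) record
#'   store; use [dataset_set()] / [dataset_get()].
#' @export
fd_dataset <- function(geometry, frequencies_hz,
                       provenance = c("simulated", "predicted")) {
  provenance <- match.arg(provenance)
  structure(list(geometry = geometry,
                 frequencies_hz = as.numeric(frequencies_hz),
                 provenance = provenance, data = list()),
            class = "fd_dataset")
}

#' @rdname fd_dataset
#' @param ds an `fd_dataset`.
#' @param f,view_deg,level record coordinates.
#' @param value complex vector of length `N_R`.
#' @export
dataset_set <- function(ds, f, view_deg, level, value) {
  if (length(value) != n_receivers(ds$geometry))
    stop_ptx("record %s: length %d != N_R = %d", fvl_key(f, view_deg, level),
             length(value), n_receivers(ds$geometry))
  ds$data[[fvl_key(f, view_deg, level)]] <- as.complex(value)
  ds
}

#' @rdname fd_dataset
#' @export
dataset_get <- function(ds, f, view_deg, level) {
  k <- fvl_key(f, view_deg, level)
  v <- ds$data[[k]]
  if (is.null(v)) stop_ptx("dataset has no record %s", k)
  v
}

#' @rdname fd_dataset
#' @export
dataset_keys <- function(ds) {
  expand.grid(f = ds$frequencies_hz,
              view_deg = ds$geometry$view_angles_deg,
              level = ds$geometry$levels_m, KEEP.OUT.ATTRS = FALSE)
}

#' @export
print.fd_dataset <- function(x, ...) {
  cat(sprintf("<fd_dataset> %s: %d records, N_R = %d, %d frequencies\n",
              x$provenance, length(x$data), n_receivers(x$geometry),
              length(x$frequencies_hz)))
  invisible(x)
}

#' Extract single-frequency ladder records into the frequency domain
#'
#' Fourier transforms per-(view, level) time traces and samples the DFT at
#' each ladder frequency. The trace length and sampling rate must place
#' every ladder frequency exactly on a DFT bin; a mismatch is an error,
#' never silent rounding.
#'
#' @param time_traces named list keyed by `"v<angle>|l<level>"`, each an
#'   `n_samples x N_R` real matrix.
#' @param ladder a [frequency_ladder()].
#' @param sample_rate_hz sampling rate of the traces, Hz.
#' @param geometry an [acquisition_geometry()].
#' @return An `fd_dataset` tagged `"simulated"`.
#' @export
time_to_frequency_data <- function(time_traces, ladder, sample_rate_hz,
                                   geometry) {
  first <- time_traces[[1]]
  n <- nrow(first)
  if (sample_rate_hz / n > min(ladder) + 1e-9)
    stop_ptx("trace length %d too short to resolve %g Hz", n, min(ladder))
  df <- sample_rate_hz / n
  bins <- ladder / df
  off <- abs(bins - round(bins))
  if (any(off > 1e-6))
    stop_ptx("ladder frequency %g Hz lies %.4g bins off the DFT grid",
             ladder[which.max(off)][1], max(off))
  bins <- round(bins)
  ds <- fd_dataset(geometry, as.numeric(ladder), "simulated")
  for (nm in names(time_traces)) {
    tr <- time_traces[[nm]]
    sp <- stats::mvfft(tr)
    parts <- as.numeric(sub("^v", "", strsplit(nm, "\\|l")[[1]]))
    for (j in seq_along(ladder))
      ds <- dataset_set(ds, as.numeric(ladder)[j], parts[1], parts[2],
                        sp[bins[j] + 1L, ])
  }
  ds
}
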