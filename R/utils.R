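# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib paraxtomo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

NEPER_DB <- 20 / log(10)  # 8.6859 dB per neper

stop_ptx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## FFT frequencies in cycles per unit, matching stats::fft bin layout
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

## centered voxel coordinates along one axis: (i - (n+1)/2) * h
axis_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## 1D linear phase unwrap (radians)
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

## deterministic child seed derivation (stays below 2^31)
derive_seed <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v))
  as.integer((as.double(seed) + h * 1009) %% 2147483647)
}
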