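#' Design a Butterworth band-pass filter for the ripple band
#'
#' Returns normalized coefficients of a 4th-order (two pole pairs)
#' Butterworth band-pass, the standard choice for ripple-band isolation.
#'
#' @param band numeric length-2, pass band in Hz.
#' @param fs sampling rate in samples/s. Must exceed twice the upper edge.
#' @return list with `b`, `a` coefficient vectors.
#' @export
ripple_filter_design <- function(band = c(150, 250), fs = 1500) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop("band edge at or above Nyquist frequency")
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

#' Causal band-pass filtering with carry-over state
#'
#' Single-pass IIR filtering as run in the real-time loop. The returned
#' state makes chunked filtering bit-identical to filtering the whole
#' trace at once.
#'
#' @param x numeric vector or matrix (samples x tetrodes).
#' @param filt list with `b`, `a` from [ripple_filter_design()].
#' @param state optional list of per-column filter states from a previous
#'   call.
#' @return list with `y` (filtered, same shape as `x`) and `state`.
#' @export
causal_bandpass <- function(x, filt, state = NULL) {
  xm <- as.matrix(x)
  nz <- max(length(filt$a), length(filt$b)) - 1L
  if (is.null(state)) {
    state <- replicate(ncol(xm), numeric(nz), simplify = FALSE)
  }
  y <- xm
  for (j in seq_len(ncol(xm))) {
    r <- .iir_filter_cpp(xm[, j], filt$b, filt$a, state[[j]])
    y[, j] <- r$y
    state[[j]] <- r$zf
  }
  if (is.vector(x)) y <- drop(y)
  list(y = y, state = state)
}

#' Zero-phase band-pass filtering
#'
#' Forward-backward filtering for offline analyses, where unbiased event
#' boundaries matter and causality does not.
#'
#' @inheritParams causal_bandpass
#' @return filtered signal, same shape as `x`.
#' @export
zerophase_bandpass <- function(x, filt) {
  f <- function(v) signal::filtfilt(filt$b, filt$a, v)
  if (is.matrix(x)) apply(x, 2, f) else f(x)
}

#' Gaussian smoothing by direct convolution
#'
#' Kernel truncated at 4 standard deviations; edges handled by reflection
#' so a constant input maps to itself.
#'
#' @param x numeric vector.
#' @param sd_samples kernel standard deviation in samples.
#' @return smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sd_samples) {
  stopifnot(sd_samples > 0)
  n <- length(x)
  if (n == 0) return(x)
  h <- ceiling(4 * sd_samples)
  k <- stats::dnorm(seq(-h, h), sd = sd_samples)
  k <- k / sum(k)
  pre_idx <- pmin(n, pmax(1L, (h + 1L):2L))   # reflect about the first sample
  post_idx <- pmax(1L, pmin(n, (n - 1L):(n - h)))
  xp <- c(x[pre_idx], x, x[post_idx])
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(h + 1):(h + n)])
}
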