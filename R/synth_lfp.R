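#' Session generator configuration
#'
#' Collects the knobs of the synthetic session generator. Defaults encode
#' the conditions the analyses assume: 1500 Hz sampling, a 150--250 Hz
#' ripple band, state-dependent SWR occurrence rates concentrated in
#' immobility, and a long-tailed (shifted-lognormal) event-size
#' distribution in which larger events occur less often than smaller
#' ones.
#'
#' @param n_tetrodes tetrode count.
#' @param fs sampling rate, samples/s.
#' @param duration session length, s.
#' @param swr_rate_by_state named numeric, events/s per behavioral state
#'   (`moving`, `still_pre_reward`, `still_post_reward`, `rest`).
#' @param size_shift,size_meanlog,size_sdlog shifted-lognormal size
#'   distribution in SD units: `size = size_shift + rlnorm(...)`.
#' @param ripple_freq_range ripple oscillation band, Hz.
#' @param swr_duration_range event duration range, ms.
#' @param min_gap_ms minimum inter-event gap enforced by thinning.
#' @param n_cells place cell count.
#' @param replay_compression replay speed-up factor relative to run speed.
#' @param background_snr ratio of 1/f-noise SD to white-noise SD.
#' @param rng_seed integer seed; fully determines the session.
#' @export
session_config <- function(n_tetrodes = 4, fs = 1500, duration = 600,
                           swr_rate_by_state = c(moving = 0.02,
                                                 still_pre_reward = 0.3,
                                                 still_post_reward = 0.3,
                                                 rest = 0.25),
                           size_shift = 2, size_meanlog = 1.6,
                           size_sdlog = 0.7,
                           ripple_freq_range = c(150, 250),
                           swr_duration_range = c(40, 120),
                           min_gap_ms = 100,
                           n_cells = 30, replay_compression = 20,
                           background_snr = 1, rng_seed = 1L) {
  stopifnot(fs > 2 * ripple_freq_range[2], all(swr_rate_by_state >= 0),
            duration >= 0, n_tetrodes >= 1)
  structure(as.list(environment()), class = "session_config")
}

#' Generate background multi-tetrode LFP
#'
#' 1/f ("pink") noise plus white noise, independent across tetrodes,
#' standing in for movement/rest CA1 LFP with a nonzero ripple-band
#' floor so SD-unit thresholds are meaningful.
#'
#' @param config a [session_config()].
#' @return numeric matrix, samples x tetrodes (uV scale).
#' @export
gen_background_lfp <- function(config) {
  if (config$duration < 0 || config$fs <= 0) stop("invalid duration or fs")
  n <- round(config$duration * config$fs)
  ntet <- config$n_tetrodes
  if (n == 0) return(matrix(numeric(0), 0, ntet))
  out <- matrix(0, n, ntet)
  for (j in seq_len(ntet)) {
    white <- stats::rnorm(n)
    pink <- pink_noise(n)
    out[, j] <- 10 * (config$background_snr * pink + white)
  }
  out
}

# 1/f-amplitude noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- c(1, seq_len(n - 1))           # avoid dividing DC by zero
  freq <- pmin(freq, n - freq + 1)       # symmetric |frequency| index
  f <- f / sqrt(freq)
  p <- Re(stats::fft(f, inverse = TRUE)) / n
  as.numeric(scale(p))
}

#' Construct a ripple-like waveform
#'
#' A sinusoid at `freq` under a Gaussian envelope whose SD is a quarter
#' of the nominal duration; support is truncated at +-2 durations.
#'
#' @param fs sampling rate.
#' @param duration_ms nominal event duration, ms.
#' @param freq oscillation frequency, Hz.
#' @param phase carrier phase, radians.
#' @return list with `wave` (unit peak envelope) and `half_width`
#'   (samples on each side of the center).
#' @export
ripple_waveform <- function(fs, duration_ms, freq, phase = 0) {
  dur <- duration_ms / 1000
  sd_t <- dur / 4
  half <- ceiling(2 * dur * fs)
  t <- seq(-half, half) / fs
  env <- exp(-t^2 / (2 * sd_t^2))
  list(wave = env * sin(2 * pi * freq * t + phase), half_width = half)
}

#' Inject a calibrated ripple event into raw LFP
#'
#' Adds a Gaussian-windowed sinusoid to every selected tetrode, scaled so
#' that the event's peak on the offline consensus trace of the otherwise
#' clean background sits at the requested size (epoch-SD units). The
#' calibration is numeric: the clean background's ripple filtrate and
#' epoch statistics are computed (or passed in), the unit waveform is
#' filtered, and the scale is solved for by root finding on a local
#' window. Calibrating every event against the clean background makes
#' injections additive and order-independent.
#'
#' @param traces raw LFP matrix, samples x tetrodes.
#' @param time event center, s.
#' @param amplitude requested size in epoch-SD units (0 leaves the trace
#'   unchanged).
#' @param duration_ms,freq waveform parameters.
#' @param fs sampling rate.
#' @param phase carrier phase, radians.
#' @param tetrodes column indices receiving the event (default all).
#' @param calib optional precomputed [injection_calib()] of the clean
#'   background (strongly recommended when injecting many events).
#' @return list with `traces` (modified) and `truth` (one-row data.frame:
#'   `time`, `amplitude`, `duration_ms`, `freq`, `scale`).
#' @export
inject_ripple <- function(traces, time, amplitude, duration_ms, freq,
                          fs = 1500, phase = 0, tetrodes = NULL,
                          calib = NULL) {
  traces <- as.matrix(traces)
  if (is.null(tetrodes)) tetrodes <- seq_len(ncol(traces))
  truth <- data.frame(time = time, amplitude = amplitude,
                      duration_ms = duration_ms, freq = freq, scale = 0)
  if (amplitude == 0) return(list(traces = traces, truth = truth))
  if (amplitude < 0) stop("amplitude must be non-negative")
  w <- ripple_waveform(fs, duration_ms, freq, phase)
  ic <- round(time * fs) + 1L
  idx <- (ic - w$half_width):(ic + w$half_width)
  if (idx[1] < 1 || idx[length(idx)] > nrow(traces)) {
    stop("event extends past trace bounds")
  }
  if (is.null(calib)) calib <- injection_calib(traces, fs)
  if (calib$epoch_sd == 0) stop("degenerate background (flat trace)")
  # zero-phase filtrate of the unit waveform, padded to kill edge effects
  pad <- 5 * w$half_width
  wp <- c(numeric(pad), w$wave, numeric(pad))
  wf <- zerophase_bandpass(wp, calib$filt)[pad + seq_along(w$wave)]
  # Quadrature calibration: the consensus peak of background + event is
  # approximately sqrt(mean background power + k a^2 smooth(wf^2)), the
  # cross term averaging to zero. Solve for the scale a that puts the
  # peak at epoch_mean + amplitude * epoch_sd.
  q_peak <- length(tetrodes) * max(gaussian_smooth(wf^2, 0.004 * fs))
  target_val <- calib$epoch_mean + amplitude * calib$epoch_sd
  a <- sqrt(max(0, target_val^2 - calib$power_mean) / q_peak)
  # Refine against the realized local consensus maximum so the offline
  # measure of this event on the otherwise-clean background hits the
  # requested size. Window: event center +- nominal duration.
  half_win <- ceiling(duration_ms / 1000 * fs)
  lo <- max(1L, ic - w$half_width - half_win)
  hi <- min(nrow(traces), ic + w$half_width + half_win)
  bg <- calib$filtered[lo:hi, tetrodes, drop = FALSE]
  wloc <- numeric(hi - lo + 1)
  wloc[idx - lo + 1] <- wf
  win <- (max(lo, ic - half_win):min(hi, ic + half_win)) - lo + 1L
  size_of <- function(s) {
    power <- rowSums((bg + s * wloc)^2)
    sm <- gaussian_smooth(power, 0.004 * fs)
    (max(sqrt(pmax(sm[win], 0))) - calib$epoch_mean) / calib$epoch_sd
  }
  if (size_of(0) < amplitude) {
    a_hi <- max(a * 2, calib$epoch_sd)
    while (size_of(a_hi) < amplitude) a_hi <- a_hi * 2
    a <- stats::uniroot(function(s) size_of(s) - amplitude, c(0, a_hi),
                        tol = 1e-5 * a_hi)$root
  }
  # else: the clean background already peaks above the target locally;
  # keep the quadrature scale so the event still exists.
  for (j in tetrodes) traces[idx, j] <- traces[idx, j] + a * w$wave
  truth$scale <- a
  list(traces = traces, truth = truth)
}

#' Precompute injection calibration quantities for a clean background
#'
#' Ripple filtrate, consensus epoch statistics, and the filter object,
#' shared by all [inject_ripple()] calls on the same background.
#'
#' @param traces clean background LFP matrix.
#' @param fs sampling rate.
#' @param band ripple band, Hz.
#' @export
injection_calib <- function(traces, fs = 1500, band = c(150, 250)) {
  filt <- ripple_filter_design(band, fs)
  filtered <- as.matrix(zerophase_bandpass(as.matrix(traces), filt))
  cons <- build_consensus(filtered, fs)
  list(filt = filt, filtered = filtered, epoch_mean = cons$epoch_mean,
       epoch_sd = cons$epoch_sd, power_mean = mean(cons$values^2),
       fs = fs)
}

#' Draw state-dependent SWR event times
#'
#' Inhomogeneous Poisson sampling with a piecewise-constant rate given by
#' the behavioral state of each interval, followed by thinning to enforce
#' a minimum inter-event gap.
#'
#' @param state_intervals data.frame with `t0`, `t1`, `state`
#'   (non-overlapping).
#' @param rate_by_state named numeric, events/s.
#' @param min_gap_ms minimum gap between successive events.
#' @return sorted numeric vector of event times (s).
#' @export
gen_event_times <- function(state_intervals, rate_by_state,
                            min_gap_ms = 100) {
  if (any(rate_by_state < 0)) stop("negative rate")
  times <- numeric(0)
  for (i in seq_len(nrow(state_intervals))) {
    st <- as.character(state_intervals$state[i])
    rate <- rate_by_state[[st]]
    if (is.null(rate)) stop("no rate for state ", st)
    len <- state_intervals$t1[i] - state_intervals$t0[i]
    if (rate > 0 && len > 0) {
      k <- stats::rpois(1, rate * len)
      times <- c(times, state_intervals$t0[i] + sort(stats::runif(k)) * len)
    }
  }
  times <- sort(times)
  gap <- min_gap_ms / 1000
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= gap) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Draw event sizes from the shifted-lognormal size distribution
#'
#' @param n number of draws.
#' @param config a [session_config()].
#' @return sizes in SD units.
#' @export
gen_event_sizes <- function(n, config) {
  config$size_shift + stats::rlnorm(n, config$size_meanlog,
                                    config$size_sdlog)
}

#' Tail probability of the event-size distribution
#'
#' P(size >= s) under the configured shifted lognormal; used for
#' renewal-process wait-time predictions.
#'
#' @param s size threshold, SD units.
#' @param config a [session_config()].
#' @export
size_tail_prob <- function(s, config) {
  stats::plnorm(pmax(s - config$size_shift, 0), config$size_meanlog,
                config$size_sdlog, lower.tail = FALSE)
}
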