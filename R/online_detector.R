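#' Online detector configuration
#'
#' Parameters of the real-time SWR detector: the causal ripple band, the
#' detection threshold in baseline SD units, the tetrode-coincidence
#' requirement, and the feedback delay applied between trigger and cue.
#'
#' @param band causal ripple band in Hz.
#' @param threshold_sd detection threshold in units of the frozen baseline
#'   sigma.
#' @param min_coincident minimum number of tetrodes whose envelope must be
#'   above threshold at the same sample.
#' @param feedback_delay_ms delay between trigger and feedback delivery,
#'   a per-subject constant in 50--100 ms.
#' @param lockout_ms refractory period after a trigger. The task ends the
#'   trial at the trigger, so the default is 0; free-running use should set
#'   a lockout.
#' @param literal_gain if `TRUE`, the envelope update uses the previous
#'   step's gain rather than the gain computed from the current sample.
#' @param fs sampling rate, samples/s.
#' @return an `online_config` list.
#' @export
online_config <- function(band = c(100, 400), threshold_sd = 4,
                          min_coincident = 2, feedback_delay_ms = 75,
                          lockout_ms = 0, literal_gain = FALSE, fs = 1500) {
  stopifnot(threshold_sd > 0, min_coincident >= 1, fs > 2 * band[2])
  structure(list(band = band, threshold_sd = threshold_sd,
                 min_coincident = min_coincident,
                 feedback_delay_ms = feedback_delay_ms,
                 lockout_ms = lockout_ms, literal_gain = literal_gain,
                 fs = fs),
            class = "online_config")
}

#' Initialize an iterative baseline estimate
#'
#' @param mu,sigma starting values (uV). The streaming path seeds `mu` from
#'   the first sample; an explicit zero state is useful for analysis of the
#'   recursion itself.
#' @param n_smooth smoothing constant in samples.
#' @export
baseline_init <- function(mu = 0, sigma = 0, n_smooth = 10000) {
  stopifnot(n_smooth > 0, sigma >= 0)
  list(mu = mu, sigma = sigma, n_smooth = n_smooth, n_seen = 0L)
}

#' One step of the iterative baseline estimator
#'
#' Applies, to the absolute value of the sample,
#' \deqn{\mu' = \mu (N-1)/N + |x|/N}
#' \deqn{\sigma' = (||x| - \mu| - \sigma)/N + \sigma}
#' where the sigma update uses the *previous* mu.
#'
#' @param state a [baseline_init()] list.
#' @param x one ripple-filtered sample (uV).
#' @export
update_baseline <- function(state, x) {
  if (!is.finite(x)) stop("non-finite sample")
  ax <- abs(x)
  n <- state$n_smooth
  mu_prev <- state$mu
  state$mu <- mu_prev * (n - 1) / n + ax / n
  state$sigma <- (abs(ax - mu_prev) - state$sigma) / n + state$sigma
  state$n_seen <- state$n_seen + 1L
  state
}

#' Run the baseline estimator over a vector of samples
#'
#' Compiled equivalent of iterating [update_baseline()].
#'
#' @inheritParams update_baseline
#' @param x ripple-filtered samples.
#' @param keep_path if `TRUE`, also return the per-sample mu/sigma paths.
#' @export
run_baseline <- function(state, x, keep_path = FALSE) {
  if (any(!is.finite(x))) stop("non-finite sample")
  r <- .baseline_run_cpp(as.numeric(x), state$mu, state$sigma,
                         state$n_smooth, keep_path)
  out <- baseline_init(r$mu, r$sigma, state$n_smooth)
  out$n_seen <- state$n_seen + length(x)
  if (keep_path) {
    out$mu_path <- r$mu_path
    out$sigma_path <- r$sigma_path
  }
  out
}

#' Initialize the asymmetric envelope estimator state
#'
#' The gain history is seeded full of the decreasing-branch gain 0.2 and
#' the envelope itself is seeded from the first observed sample, so
#' startup transients do not dominate calibration.
#'
#' @param n_tetrodes number of tetrodes tracked in parallel.
#' @param v optional starting envelope values (uV); by default the first
#'   streamed sample seeds the envelope.
#' @param g_history optional numeric vector (length <= 19) used for every
#'   tetrode's initial gain history.
#' @export
envelope_init <- function(n_tetrodes = 1, v = NULL, g_history = NULL) {
  if (is.null(g_history)) g_history <- rep(0.2, 19)
  stopifnot(length(g_history) <= 19)
  gh <- matrix(0, 19, n_tetrodes)
  gh[seq_along(g_history), ] <- g_history
  list(v = if (is.null(v)) rep(0, n_tetrodes) else rep_len(v, n_tetrodes),
       ghist = gh,
       gn = rep(length(g_history), n_tetrodes),
       gpos = rep(0L, n_tetrodes),
       glast = rep(0.2, n_tetrodes),
       started = rep(!is.null(v), n_tetrodes))
}

#' One step of the asymmetric envelope estimator (single tetrode)
#'
#' If `|x| <= v` the gain is 0.2 (decreasing branch); otherwise the gain is
#' the mean of 1.2 and the last (up to) 19 gains. The update is
#' `v' = v + g (|x| - v)` and the gain is appended to the history.
#'
#' @param state an [envelope_init()] state with `n_tetrodes = 1`.
#' @param x one ripple-filtered sample (uV).
#' @return updated state with an extra element `g` (the gain just used).
#' @export
update_envelope <- function(state, x, literal_gain = FALSE) {
  if (!is.finite(x)) stop("non-finite sample")
  r <- .detector_run_cpp(matrix(abs(x), 1, 1), state,
                         thr = Inf, min_coincident = 1L,
                         lockout_samples = 0, since_last = 0,
                         literal_gain = literal_gain, stop_at_first = FALSE,
                         keep_env = TRUE)
  st <- r$state
  st$g <- st$glast[1]
  st
}

#' Calibrate and freeze the per-tetrode baselines
#'
#' Runs the causal ripple filter and the iterative baseline estimator over
#' a calibration recording (the rest-box period preceding the behavioral
#' epoch), then freezes the resulting mu/sigma. Downstream detection
#' thresholds are `mu + threshold_sd * sigma`.
#'
#' @param traces numeric matrix, samples x tetrodes, raw LFP (uV).
#' @param config an [online_config()].
#' @param settle minimum calibration duration in seconds (default 60).
#' @return list with per-tetrode `mu`, `sigma`, plus `n_smooth`, `fs`, and
#'   `degenerate` flags where sigma is zero.
#' @export
calibrate_baseline <- function(traces, config, settle = 60) {
  traces <- as.matrix(traces)
  if (nrow(traces) < settle * config$fs) {
    stop("calibration traces shorter than the settle period")
  }
  filt <- ripple_filter_design(config$band, config$fs)
  xf <- causal_bandpass(traces, filt)$y
  xf <- as.matrix(xf)
  mu <- sigma <- numeric(ncol(xf))
  for (j in seq_len(ncol(xf))) {
    st <- baseline_init(mu = abs(xf[1, j]), sigma = 0)
    r <- run_baseline(st, xf[, j])
    mu[j] <- r$mu
    sigma[j] <- r$sigma
  }
  list(mu = mu, sigma = sigma, n_smooth = 10000, fs = config$fs,
       degenerate = sigma == 0)
}

#' One coincidence-detection step
#'
#' Updates every tetrode's envelope with the current (filtered) sample and
#' reports whether at least `min_coincident` envelopes exceed their frozen
#' thresholds at this sample.
#'
#' @param states an [envelope_init()] state for all tetrodes.
#' @param frozen frozen baselines from [calibrate_baseline()].
#' @param config an [online_config()].
#' @param samples one ripple-filtered value per tetrode (uV).
#' @param since_last samples elapsed since the previous trigger (for the
#'   lockout); `Inf` means free.
#' @return list with `states`, `triggered`, `since_last`.
#' @export
step_detector <- function(states, frozen, config, samples,
                          since_last = Inf) {
  if (length(samples) != length(frozen$mu)) {
    stop("tetrode count mismatch")
  }
  thr <- frozen$mu + config$threshold_sd * frozen$sigma
  r <- .detector_run_cpp(matrix(samples, 1), states, thr,
                         as.integer(config$min_coincident),
                         config$lockout_ms / 1000 * config$fs,
                         since_last, config$literal_gain,
                         stop_at_first = FALSE, keep_env = FALSE)
  list(states = r$state, triggered = length(r$triggers) > 0,
       since_last = r$since_last)
}

#' Initialize a full streaming-detector state
#'
#' Bundles the causal filter state, the envelope states, and the lockout
#' clock, so [run_stream()] can be invoked on arbitrary chunks with
#' bit-identical results.
#'
#' @param n_tetrodes tetrode count.
#' @param config an [online_config()].
#' @export
stream_state_init <- function(n_tetrodes, config) {
  filt <- ripple_filter_design(config$band, config$fs)
  nz <- max(length(filt$a), length(filt$b)) - 1L
  list(filt = filt,
       filter_state = replicate(n_tetrodes, numeric(nz), simplify = FALSE),
       env = envelope_init(n_tetrodes),
       since_last = Inf,
       n_seen = 0L)
}

#' Stream raw LFP through the online detector
#'
#' Applies the causal band-pass and the per-sample envelope/coincidence
#' logic. Trigger times are sample-index / fs, relative to the start of the
#' whole stream (chunk offsets are tracked in the state).
#'
#' @param traces numeric matrix, samples x tetrodes, raw LFP (uV).
#' @param frozen frozen baselines from [calibrate_baseline()].
#' @param config an [online_config()].
#' @param state optional state from a previous chunk
#'   ([stream_state_init()] is used otherwise).
#' @param stop_at_first stop processing at the first trigger (closed-loop
#'   use); remaining samples are not consumed.
#' @return list with `triggers` (times in s), `state`, and `n_processed`
#'   (samples of this chunk consumed).
#' @export
run_stream <- function(traces, frozen, config, state = NULL,
                       stop_at_first = FALSE) {
  traces <- as.matrix(traces)
  ntet <- ncol(traces)
  if (ntet != length(frozen$mu)) stop("tetrode count mismatch")
  if (is.null(state)) state <- stream_state_init(ntet, config)
  if (nrow(traces) == 0) {
    return(list(triggers = numeric(0), state = state, n_processed = 0L))
  }
  f <- causal_bandpass(traces, state$filt, state$filter_state)
  thr <- frozen$mu + config$threshold_sd * frozen$sigma
  r <- .detector_run_cpp(as.matrix(f$y), state$env, thr,
                         as.integer(config$min_coincident),
                         config$lockout_ms / 1000 * config$fs,
                         state$since_last, config$literal_gain,
                         stop_at_first, keep_env = FALSE)
  n_used <- r$n_processed
  if (stop_at_first && n_used < nrow(traces)) {
    # re-run the filter only over the consumed samples so the carried
    # state matches a sample-by-sample invocation
    f <- causal_bandpass(traces[seq_len(n_used), , drop = FALSE],
                         state$filt, state$filter_state)
  }
  state$filter_state <- f$state
  state$env <- r$state
  state$since_last <- r$since_last
  triggers <- (state$n_seen + r$triggers) / config$fs
  state$n_seen <- state$n_seen + n_used
  list(triggers = triggers, state = state, n_processed = n_used)
}
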