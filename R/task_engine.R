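#' Task configuration
#'
#' Parameters of the neurofeedback task: threshold ramp across days and
#' within epochs, yoked-delay bookkeeping, reward sizes, goal-block
#' repeat quotas, and timeout behavior.
#'
#' @param threshold_start starting detection threshold, SD.
#' @param threshold_max maximum threshold reached by the ramp, SD.
#' @param ramp_days days over which the day-maximum ramps up.
#' @param within_epoch_ramp_trials NF trials over which each epoch ramps
#'   from `threshold_start` to the day maximum.
#' @param yoke_window number of prior NF latencies delays are drawn from.
#' @param feedback_delay_ms trigger-to-reward delay, ms.
#' @param reward_small_ul,reward_large_ul reward volumes, uL.
#' @param repeats_range rewarded repeat visits per goal block (range).
#' @param timeout_range timeout duration range, s.
#' @param immobility_cutoff speed cutoff, cm/s.
#' @param bootstrap_delay_range delay range used before any NF history
#'   exists, s.
#' @param nf_cap trial abort cap for the closed loop, s.
#' @export
task_config <- function(threshold_start = 4, threshold_max = 16,
                        ramp_days = 14, within_epoch_ramp_trials = 10,
                        yoke_window = 8, feedback_delay_ms = 75,
                        reward_small_ul = 50, reward_large_ul = 150,
                        repeats_range = c(4, 12),
                        timeout_range = c(30, 45),
                        immobility_cutoff = 4,
                        bootstrap_delay_range = c(2, 10),
                        nf_cap = 300) {
  stopifnot(threshold_start <= threshold_max, yoke_window >= 1)
  structure(as.list(environment()), class = "task_config")
}

#' Detection threshold for a given day and NF trial
#'
#' The day maximum ramps linearly from `threshold_start` to
#' `threshold_max` across `ramp_days` and is clamped thereafter (the
#' stable period). Within an epoch the threshold steps linearly from
#' `threshold_start` to the day maximum over the first
#' `within_epoch_ramp_trials` NF trials and is constant afterwards.
#'
#' @param day training day (1-based).
#' @param nf_trial_index index of the NF trial within the epoch
#'   (1-based).
#' @param config a [task_config()].
#' @return threshold in SD units.
#' @export
threshold_schedule <- function(day, nf_trial_index, config) {
  stopifnot(day >= 1, nf_trial_index >= 1)
  frac_day <- min(1, (day - 1) / max(1, config$ramp_days - 1))
  day_max <- config$threshold_start +
    frac_day * (config$threshold_max - config$threshold_start)
  m <- config$within_epoch_ramp_trials
  if (nf_trial_index >= m) return(day_max)
  config$threshold_start +
    (day_max - config$threshold_start) * nf_trial_index / m
}

#' Draw a yoked delay from recent NF latencies
#'
#' Uniform draw from the most recent `min(yoke_window, available)` NF
#' pre-reward latencies; before any NF history exists, a uniform draw
#' from the bootstrap delay range.
#'
#' @param history numeric vector of prior NF latencies, oldest first.
#' @param config a [task_config()].
#' @return delay in seconds.
#' @export
sample_yoked_delay <- function(history, config) {
  if (!length(history)) {
    return(stats::runif(1, config$bootstrap_delay_range[1],
                        config$bootstrap_delay_range[2]))
  }
  recent <- utils::tail(history, config$yoke_window)
  recent[sample.int(length(recent), 1)]
}

#' Initialize goal-block bookkeeping
#'
#' @param n_arms arm count.
#' @param config a [task_config()].
#' @export
goal_state_init <- function(n_arms = 8, config = task_config()) {
  list(goal_arm = sample.int(n_arms, 1),
       block = 1L,
       quota = sample(seq(config$repeats_range[1],
                          config$repeats_range[2]), 1),
       rewarded_in_block = 0L,
       phase = "search",
       n_arms = n_arms,
       config = config)
}

#' Apply one arm choice to the goal controller
#'
#' Reward iff the chosen arm is the goal; after the block's quota of
#' rewarded visits the goal is redrawn from the other arms and the
#' block counter increments. Phase is search until the first rewarded
#' visit of a block, repeat thereafter.
#'
#' @param state a [goal_state_init()] list.
#' @param arm_choice chosen arm (1..n_arms).
#' @return list with `rewarded`, `phase` (phase the trial was in), and
#'   the updated `state`.
#' @export
goal_controller <- function(state, arm_choice) {
  if (arm_choice < 1 || arm_choice > state$n_arms) stop("invalid arm")
  phase <- state$phase
  rewarded <- arm_choice == state$goal_arm
  if (rewarded) {
    state$rewarded_in_block <- state$rewarded_in_block + 1L
    state$phase <- "repeat"
    if (state$rewarded_in_block >= state$quota) {
      state$goal_arm <- sample(setdiff(seq_len(state$n_arms),
                                       state$goal_arm), 1)
      state$block <- state$block + 1L
      state$quota <- sample(seq(state$config$repeats_range[1],
                                state$config$repeats_range[2]), 1)
      state$rewarded_in_block <- 0L
      state$phase <- "search"
    }
  }
  list(rewarded = rewarded, phase = phase, state = state)
}

#' Agent behavior policy
#'
#' Parametric stand-in for the animal: arm-choice probabilities and
#' dwell/travel distributions. These knobs give the behavioral metrics
#' controllable ground truth.
#'
#' @param p_return_goal probability a repeat-phase trial returns to the
#'   known goal arm.
#' @param p_repeat_sample probability a search-phase trial revisits an
#'   already-sampled arm.
#' @param post_dwell_range post-reward dwell at the center port, s.
#' @param travel_range inter-port travel time, s.
#' @param p_violation probability of a trial-order violation (an arm
#'   poke without a center poke), which earns a timeout instead of a
#'   reward.
#' @export
agent_policy <- function(p_return_goal = 0.8, p_repeat_sample = 0.3,
                         post_dwell_range = c(2, 6),
                         travel_range = c(2, 5), p_violation = 0) {
  structure(as.list(environment()), class = "agent_policy")
}

# choose an arm given phase, goal, and arms sampled this block
policy_choose_arm <- function(policy, phase, goal_arm, sampled, n_arms) {
  if (phase == "repeat" && stats::runif(1) < policy$p_return_goal) {
    return(goal_arm)
  }
  unsampled <- setdiff(seq_len(n_arms), sampled)
  if (phase == "search" && length(unsampled) &&
      stats::runif(1) >= policy$p_repeat_sample) {
    return(unsampled[sample.int(length(unsampled), 1)])
  }
  sample.int(n_arms, 1)
}

#' Map injected amplitude to online envelope size
#'
#' The online detector expresses its threshold in units of the frozen
#' baseline sigma of the causal envelope, which differ from the offline
#' consensus SD units the generator is calibrated in. This routine
#' measures, on clean background, the online envelope peak size (the
#' second-largest tetrode peak, the coincidence-relevant statistic)
#' produced by injections over a grid of amplitudes, and returns a
#' monotone interpolator from amplitude to online size.
#'
#' @param cfg a [session_config()].
#' @param ocfg an [online_config()].
#' @param frozen frozen baselines from [calibrate_baseline()].
#' @param calib an [injection_calib()] for backgrounds drawn from `cfg`.
#' @param amplitudes amplitude grid, SD units.
#' @param reps repeats per grid point.
#' @return function(amplitude) -> online size (and the reverse map as
#'   attribute `inverse`).
#' @export
online_size_map <- function(cfg, ocfg, frozen, calib,
                            amplitudes = seq(2, 26, by = 2), reps = 8) {
  filt <- ripple_filter_design(ocfg$band, ocfg$fs)
  ntet <- cfg$n_tetrodes
  seg_dur <- 2
  amp_all <- rep(amplitudes, each = reps)
  val_all <- numeric(length(amp_all))
  k <- 0
  for (ai in seq_along(amplitudes)) {
    vals <- numeric(reps)
    for (r in seq_len(reps)) {
      seg_cfg <- cfg
      seg_cfg$duration <- seg_dur
      bg <- gen_background_lfp(seg_cfg)
      lc <- calib
      lc$filtered <- as.matrix(zerophase_bandpass(bg, calib$filt))
      inj <- inject_ripple(bg, seg_dur / 2, amplitudes[ai],
                           duration_ms = stats::runif(
                             1, cfg$swr_duration_range[1],
                             cfg$swr_duration_range[2]),
                           freq = stats::runif(1,
                                               cfg$ripple_freq_range[1],
                                               cfg$ripple_freq_range[2]),
                           fs = cfg$fs, calib = lc)
      xf <- causal_bandpass(inj$traces, filt)$y
      rr <- .detector_run_cpp(as.matrix(xf), envelope_init(ntet),
                              rep(Inf, ntet), 1L, 0, Inf, FALSE, FALSE,
                              TRUE)
      win <- round(seg_dur / 2 * cfg$fs) + seq(-150, 300)
      env_sd <- sweep(sweep(rr$env[win, , drop = FALSE], 2, frozen$mu),
                      2, frozen$sigma, `/`)
      # per-sample second-largest envelope: the statistic the
      # same-sample coincidence trigger actually thresholds
      k2 <- min(2, ntet)
      v2 <- apply(env_sd, 1, function(v) sort(v, decreasing = TRUE)[k2])
      vals[r] <- max(v2)
      k <- k + 1
      val_all[k] <- vals[r]
    }
  }
  # per-amplitude medians, made monotone; medians center the trigger
  # sigmoid on each amplitude without cross-amplitude pooling bias
  fitted_at <- vapply(amplitudes, function(a) {
    stats::median(val_all[amp_all == a])
  }, numeric(1))
  fitted_at <- cummax(fitted_at)
  f <- stats::approxfun(amplitudes, fitted_at, rule = 2)
  inv <- stats::approxfun(fitted_at, amplitudes, rule = 2,
                          ties = "ordered")
  attr(f, "inverse") <- inv
  attr(f, "samples") <- data.frame(amplitude = amp_all,
                                   online_size = val_all)
  f
}

#' Probability that an event of given amplitude triggers at a threshold
#'
#' An event's size on the online scale is its realized envelope
#' response, which varies around the median map with the background.
#' This estimates P(online size >= threshold | amplitude) from the
#' calibration repeats stored in an [online_size_map()], interpolated
#' over amplitude and made monotone.
#'
#' @param size_map an [online_size_map()] function.
#' @param amplitudes event amplitudes, SD units.
#' @param threshold online threshold, frozen-baseline SD units.
#' @return vector of trigger probabilities.
#' @export
online_trigger_prob <- function(size_map, amplitudes, threshold) {
  smp <- attr(size_map, "samples")
  grid <- sort(unique(smp$amplitude))
  p_at <- vapply(grid, function(a) {
    mean(smp$online_size[smp$amplitude == a] >= threshold)
  }, numeric(1))
  p_at <- cummax(p_at)
  fn <- stats::approxfun(grid, p_at, rule = 2)
  p <- fn(amplitudes)
  p[amplitudes <= grid[1]] <- ifelse(p_at[1] > 0,
                                     p[amplitudes <= grid[1]], 0)
  p
}

# Generate a background segment with injected events drawn at `rate`.
# The background is generated with hidden padding on both ends so the
# event process runs at full rate over the entire visible window
# (waveforms near the edges spill into the padding, which is sliced
# off). Returns traces, truth table (times relative to the visible
# segment start), and the updated last-event time for cross-segment
# gap enforcement.
segment_with_events <- function(cfg, duration, rate, calib,
                                last_event = -Inf, pad = 0.3,
                                sizes = NULL) {
  segment_piecewise(cfg, data.frame(t0 = 0, t1 = duration, rate = rate),
                    calib, last_event = last_event, pad = pad,
                    sizes = sizes)
}

#' Simulate the closed-loop wait until an online trigger
#'
#' Streams synthetic background with state-rate event injections
#' through the online detector until the coincidence trigger fires.
#' The online threshold is the task threshold (offline consensus SD
#' units) mapped through [online_size_map()].
#'
#' @param threshold_sd task threshold, SD units.
#' @param cfg a [session_config()].
#' @param ocfg an [online_config()].
#' @param frozen frozen baselines.
#' @param size_map an [online_size_map()] function.
#' @param calib an [injection_calib()] for `cfg` backgrounds.
#' @param rate event rate during the wait, ev/s.
#' @param cap abort cap, s.
#' @param chunk generation chunk length, s.
#' @param threshold_units `"size"` (threshold in offline consensus SD
#'   units, mapped through `size_map`) or `"online"` (threshold applied
#'   directly in frozen-baseline envelope units, as the real-time
#'   system expresses it).
#' @param post_trigger_s extra seconds of the stream kept after the
#'   trigger (the feedback-delay continuation), so the triggering
#'   event's waveform stays in the recording.
#' @return list: `latency` (s, NA if aborted), `triggered`,
#'   `trigger_size` (ground-truth amplitude of the triggering event, NA
#'   if unmatched), `events` (ground truth injected so far), `lfp`
#'   (traces up to the consumed sample), `n_samples`.
#' @export
simulate_nf_wait <- function(threshold_sd, cfg, ocfg, frozen, size_map,
                             calib, rate, cap = 300, chunk = 10,
                             threshold_units = c("size", "online"),
                             post_trigger_s = 0) {
  threshold_units <- match.arg(threshold_units)
  ocfg$threshold_sd <- if (threshold_units == "size") {
    size_map(threshold_sd)
  } else {
    threshold_sd
  }
  # warm up the causal filter and envelope estimators on 1 s of
  # event-free background (the real loop runs continuously; a cold
  # start spikes the envelope and fires spurious triggers)
  warm_cfg <- cfg
  warm_cfg$duration <- 1
  warm <- gen_background_lfp(warm_cfg)
  state <- stream_state_init(ncol(warm), ocfg)
  wr <- run_stream(warm, frozen, ocfg, state)
  state <- wr$state
  state$since_last <- Inf
  state$n_seen <- 0L   # trigger times count from the post-warmup start
  t_off <- 0
  last_event <- -Inf
  events <- NULL
  lfp <- list()
  latency <- NA_real_
  trig_size <- NA_real_
  while (t_off < cap) {
    seg <- segment_with_events(cfg, chunk, rate, calib, last_event)
    last_event <- seg$last_event
    tru <- seg$truth
    tru$time <- tru$time + t_off
    r <- run_stream(seg$traces, frozen, ocfg, state, stop_at_first = TRUE)
    state <- r$state
    if (length(r$triggers)) {
      latency <- r$triggers[1]
      # attribute the trigger to the nearest preceding injected event
      cand <- rbind(events, tru)
      if (!is.null(cand) && nrow(cand)) {
        dt <- latency - cand$time
        ok <- which(abs(dt) < 0.25)
        if (length(ok)) trig_size <- cand$amplitude[ok[which.min(
          abs(dt[ok]))]]
      }
      events <- rbind(events, tru)
      # keep the feedback-delay continuation so the triggering event's
      # waveform (cut mid-rise by the trigger) stays in the recording
      n_keep <- min(nrow(seg$traces),
                    r$n_processed + round(post_trigger_s * cfg$fs))
      lfp[[length(lfp) + 1]] <-
        seg$traces[seq_len(n_keep), , drop = FALSE]
      break
    }
    events <- rbind(events, tru)
    lfp[[length(lfp) + 1]] <- seg$traces
    t_off <- t_off + chunk
  }
  list(latency = latency, triggered = is.finite(latency),
       trigger_size = trig_size,
       events = if (is.null(events)) data.frame() else events,
       lfp = do.call(rbind, lfp))
}

#' Closed-loop trigger-latency experiment over detection thresholds
#'
#' Runs the full closed loop (calibration, amplitude-to-online-size
#' map, streamed detection) on a stationary event generator at a set
#' of online detection thresholds, and compares the resulting trigger
#' latencies with the renewal-process prediction
#' `1 / (rate * P(size >= threshold))`, where event size is expressed
#' on the online envelope scale through the inverse calibration map.
#'
#' @param thresholds online detection thresholds, frozen-baseline SD
#'   units.
#' @param n_trials trials per threshold (scalar or vector).
#' @param rate stationary event rate, ev/s.
#' @param cfg a [session_config()]; its size distribution should span
#'   the tested thresholds on the online scale.
#' @param ocfg an [online_config()].
#' @param map_amplitudes amplitude grid for the calibration map.
#' @param map_reps repeats per grid point.
#' @return data.frame: `threshold`, `n`, `median_latency`,
#'   `mean_latency`, `prediction`, `ratio`.
#' @export
closed_loop_latency_experiment <- function(
    thresholds = c(4, 8, 12, 16), n_trials = 100, rate = 0.5,
    cfg = session_config(size_shift = 2, size_meanlog = 3.66,
                         size_sdlog = 0.63,
                         swr_duration_range = c(100, 100),
                         ripple_freq_range = c(200, 200)),
    ocfg = online_config(),
    map_amplitudes = c(5, 10, 15, 20, 28, 38, 50, 66, 85, 110),
    map_reps = 20) {
  cal <- subject_calibration(cfg, ocfg, with_size_map = FALSE)
  size_map <- online_size_map(cfg, ocfg, cal$frozen, cal$calib,
                              amplitudes = map_amplitudes,
                              reps = map_reps)
  inv <- attr(size_map, "inverse")
  n_trials <- rep_len(n_trials, length(thresholds))
  # the minimum inter-event gap makes the generator a dead-time renewal
  # process: realized event rate = rate / (1 + rate * gap)
  rate_eff <- rate / (1 + rate * cfg$min_gap_ms / 1000)
  rows <- lapply(seq_along(thresholds), function(i) {
    thr <- thresholds[i]
    lat <- vapply(seq_len(n_trials[i]), function(j) {
      simulate_nf_wait(thr, cfg, ocfg, cal$frozen, size_map,
                       cal$calib, rate,
                       threshold_units = "online")$latency
    }, numeric(1))
    pred <- 1 / (rate_eff * size_tail_prob(inv(thr), cfg))
    data.frame(threshold = thr, n = n_trials[i],
               median_latency = stats::median(lat),
               mean_latency = mean(lat), prediction = pred,
               ratio = mean(lat) / pred)
  })
  do.call(rbind, rows)
}

#' Size-binned SWR occurrence rates
#'
#' Bins events by size and divides each bin's count by the total time
#' spent at the center port; bins with fewer than `min_count` events
#' are omitted.
#'
#' @param sizes event sizes, SD units.
#' @param total_port_time total center-port time, s.
#' @param bin_width size bin width, SD.
#' @param min_count minimum events per tabulated bin.
#' @return data.frame: `bin_lo`, `bin_hi`, `n`, `rate` (ev/s).
#' @export
size_rate_table <- function(sizes, total_port_time, bin_width = 1,
                            min_count = 10) {
  if (bin_width <= 0) stop("non-positive bin width")
  if (total_port_time <= 0) stop("non-positive port time")
  b <- floor(sizes / bin_width)
  tab <- table(b)
  out <- data.frame(bin_lo = as.numeric(names(tab)) * bin_width,
                    n = as.integer(tab))
  out$bin_hi <- out$bin_lo + bin_width
  out$rate <- out$n / total_port_time
  out <- out[out$n >= min_count, c("bin_lo", "bin_hi", "n", "rate")]
  rownames(out) <- NULL
  out
}

#' Predicted wait time for a trigger event
#'
#' The predicted wait is the reciprocal of the cumulative occurrence
#' rate of all tabulated bins at or above the trigger's size bin (a
#' threshold trigger fires on the first event at or above threshold).
#' `mode = "bin"` uses the event's own bin rate instead. Events whose
#' size falls in no tabulated bin are excluded (NA).
#'
#' @param trigger_size trigger event size, SD.
#' @param table a [size_rate_table()].
#' @param mode `"cumulative"` (default) or `"bin"`.
#' @return predicted wait in seconds, or NA if excluded.
#' @export
predicted_wait <- function(trigger_size, table,
                           mode = c("cumulative", "bin")) {
  mode <- match.arg(mode)
  row <- which(trigger_size >= table$bin_lo & trigger_size < table$bin_hi)
  if (!length(row)) return(NA_real_)
  rate <- if (mode == "bin") table$rate[row] else
    sum(table$rate[table$bin_lo >= table$bin_lo[row]])
  if (rate <= 0) return(NA_real_)
  1 / rate
}

#' Trailing moving average
#'
#' @param x numeric vector.
#' @param k window length in trials (default 200); shorter prefixes use
#'   all available values.
#' @export
moving_average <- function(x, k = 200) {
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    j <- max(1, i - k + 1)
    out[i] <- (cs[i + 1] - cs[j]) / (i - j + 1)
  }
  out
}
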