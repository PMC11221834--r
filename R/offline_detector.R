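#' Zero-phase ripple-band filtrate of raw LFP
#'
#' @param traces numeric vector or matrix (samples x tetrodes), raw LFP.
#' @param band pass band in Hz (default 150--250).
#' @param fs sampling rate, samples/s.
#' @return filtrate, same shape.
#' @export
bandpass_ripple <- function(traces, band = c(150, 250), fs = 1500) {
  filt <- ripple_filter_design(band, fs)
  zerophase_bandpass(traces, filt)
}

#' Build the multi-tetrode consensus ripple-power trace
#'
#' The filtrates are squared, summed over tetrodes, smoothed with a
#' Gaussian kernel (SD 4 ms), and square-rooted. Epoch statistics (mean
#' and SD over all samples) are attached; SWR sizes and thresholds are
#' expressed in units of the epoch SD above the epoch mean.
#'
#' @param filtered numeric matrix, samples x tetrodes, ripple-band
#'   filtrate.
#' @param fs sampling rate, samples/s.
#' @param smooth_sd_ms Gaussian kernel SD in ms.
#' @return a `consensus_trace` list: `values`, `fs`, `epoch_mean`,
#'   `epoch_sd`.
#' @export
build_consensus <- function(filtered, fs = 1500, smooth_sd_ms = 4) {
  filtered <- as.matrix(filtered)
  power <- rowSums(filtered^2)
  sm <- gaussian_smooth(power, smooth_sd_ms / 1000 * fs)
  values <- sqrt(pmax(sm, 0))
  structure(list(values = values, fs = fs,
                 epoch_mean = mean(values),
                 epoch_sd = stats::sd(values)),
            class = "consensus_trace")
}

#' Detect SWR events on a consensus trace
#'
#' Candidate intervals are runs where the consensus exceeds
#' `epoch_mean + threshold_sd * epoch_sd` for at least `min_dur_ms`.
#' Each candidate is extended backward and forward to the nearest
#' crossings of the epoch mean (the baseline); extended events that
#' overlap are merged. Events are returned time-ordered with their size
#' (peak height in epoch-SD units), peak time, and length.
#'
#' @param consensus a [build_consensus()] object.
#' @param threshold_sd detection threshold in epoch-SD units (default 2).
#' @param min_dur_ms minimum suprathreshold duration in ms (default 15).
#' @return data.frame with `t_start`, `t_end`, `t_peak`, `size`, `length`,
#'   `source`.
#' @export
detect_events <- function(consensus, threshold_sd = 2, min_dur_ms = 15) {
  fs <- consensus$fs
  if (min_dur_ms / 1000 < 1 / fs) stop("min_dur below one sample")
  v <- consensus$values
  n <- length(v)
  mu <- consensus$epoch_mean
  thr <- mu + threshold_sd * consensus$epoch_sd
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      t_peak = numeric(0), size = numeric(0),
                      length = numeric(0), source = character(0))
  if (n == 0) return(empty)
  above <- v > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- ceiling(min_dur_ms / 1000 * fs)
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  cand <- cbind(starts[keep], ends[keep])
  below <- v <= mu
  # extend each candidate to the nearest epoch-mean crossings
  ext <- t(apply(cand, 1, function(se) {
    i0 <- se[1]
    while (i0 > 1 && !below[i0]) i0 <- i0 - 1L
    i1 <- se[2]
    while (i1 < n && !below[i1]) i1 <- i1 + 1L
    c(i0, i1)
  }))
  # merge overlapping extended spans
  o <- order(ext[, 1])
  ext <- ext[o, , drop = FALSE]
  merged <- list(ext[1, ])
  if (nrow(ext) > 1) {
    for (i in 2:nrow(ext)) {
      last <- merged[[length(merged)]]
      if (ext[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], ext[i, 2]))
      } else {
        merged[[length(merged) + 1]] <- ext[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  out <- data.frame(t_start = (m[, 1] - 1) / fs, t_end = (m[, 2] - 1) / fs)
  out$t_peak <- NA_real_
  out$size <- NA_real_
  for (i in seq_len(nrow(out))) {
    idx <- m[i, 1]:m[i, 2]
    pk <- idx[which.max(v[idx])]
    out$t_peak[i] <- (pk - 1) / fs
    out$size[i] <- (v[pk] - mu) / consensus$epoch_sd
  }
  out$length <- out$t_end - out$t_start
  out$source <- "offline"
  out[order(out$t_start), , drop = FALSE]
}

#' Measure the size and length of one event
#'
#' Size is the maximum threshold (in epoch-SD units) at which the event
#' would still have been detected, i.e. the peak consensus height above
#' the epoch mean in units of the epoch SD.
#'
#' @param consensus a [build_consensus()] object.
#' @param t_start,t_end event boundaries in seconds.
#' @return list with `t_start`, `t_end`, `t_peak`, `size`, `length`.
#' @export
measure_event <- function(consensus, t_start, t_end) {
  if (consensus$epoch_sd == 0) stop("degenerate epoch SD")
  fs <- consensus$fs
  i0 <- max(1L, floor(t_start * fs) + 1L)
  i1 <- min(length(consensus$values), ceiling(t_end * fs) + 1L)
  if (i1 < i0) stop("event outside trace")
  idx <- i0:i1
  v <- consensus$values[idx]
  pk <- idx[which.max(v)]
  list(t_start = t_start, t_end = t_end, t_peak = (pk - 1) / fs,
       size = (max(v) - consensus$epoch_mean) / consensus$epoch_sd,
       length = t_end - t_start)
}

#' Offline SWR detection on raw multi-tetrode LFP
#'
#' Convenience driver: ripple filtrate, consensus trace, event detection
#' in one call.
#'
#' @param traces numeric matrix, samples x tetrodes, raw LFP.
#' @param fs sampling rate.
#' @param band ripple band in Hz.
#' @param threshold_sd,min_dur_ms see [detect_events()].
#' @param exclude_events_iteration recompute the epoch statistics with
#'   first-pass event samples excluded, then detect again (the epoch
#'   statistics otherwise include event samples).
#' @return list with `events` (data.frame) and `consensus`.
#' @export
detect_swr_offline <- function(traces, fs = 1500, band = c(150, 250),
                               threshold_sd = 2, min_dur_ms = 15,
                               exclude_events_iteration = FALSE) {
  filtered <- bandpass_ripple(traces, band, fs)
  consensus <- build_consensus(filtered, fs)
  events <- detect_events(consensus, threshold_sd, min_dur_ms)
  if (exclude_events_iteration && nrow(events)) {
    keep <- rep(TRUE, length(consensus$values))
    for (i in seq_len(nrow(events))) {
      i0 <- max(1L, floor(events$t_start[i] * fs) + 1L)
      i1 <- min(length(keep), ceiling(events$t_end[i] * fs) + 1L)
      keep[i0:i1] <- FALSE
    }
    consensus$epoch_mean <- mean(consensus$values[keep])
    consensus$epoch_sd <- stats::sd(consensus$values[keep])
    events <- detect_events(consensus, threshold_sd, min_dur_ms)
  }
  list(events = events, consensus = consensus)
}
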