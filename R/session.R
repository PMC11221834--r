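#' Per-subject detector calibration bundle
#'
#' Generates a rest-box calibration recording, freezes the online
#' baselines on it, precomputes the injection calibration of the
#' background process, and (optionally) the amplitude-to-online-size
#' map used to set closed-loop thresholds.
#'
#' @param cfg a [session_config()].
#' @param ocfg an [online_config()].
#' @param settle calibration duration, s.
#' @param with_size_map build the [online_size_map()] (needed for NF
#'   trials).
#' @return list with `frozen`, `calib`, `size_map`.
#' @export
subject_calibration <- function(cfg, ocfg, settle = 60,
                                with_size_map = TRUE) {
  ccfg <- cfg
  ccfg$duration <- settle
  rest <- gen_background_lfp(ccfg)
  frozen <- calibrate_baseline(rest, ocfg, settle = settle)
  calib <- injection_calib(rest, cfg$fs)
  calib$filtered <- NULL  # per-segment filtrates are supplied locally
  size_map <- if (with_size_map) {
    online_size_map(cfg, ocfg, frozen, calib)
  } else NULL
  list(frozen = frozen, calib = calib, size_map = size_map)
}

# Background segment with piecewise-constant event rates; interval
# times are relative to the visible segment start. The background is
# generated with `pad` seconds of hidden margin on each side so events
# can occur at full rate right up to the segment edges (their
# waveforms spill into the padding, which is sliced off). Returns
# traces + truth (+ realized last event relative to the segment end).
segment_piecewise <- function(cfg, intervals, calib, last_event = -Inf,
                              pad = 0.3, sizes = NULL) {
  total <- max(intervals$t1)
  seg_cfg <- cfg
  seg_cfg$duration <- total + 2 * pad
  bg <- gen_background_lfp(seg_cfg)
  rates <- stats::setNames(intervals$rate,
                           paste0("iv", seq_len(nrow(intervals))))
  iv <- data.frame(t0 = intervals$t0 + pad, t1 = intervals$t1 + pad,
                   state = names(rates))
  iv <- iv[iv$t1 > iv$t0, , drop = FALSE]
  times <- gen_event_times(iv, rates, cfg$min_gap_ms)
  times <- times[(times - pad) - last_event >= cfg$min_gap_ms / 1000]
  truth <- data.frame(time = numeric(0), amplitude = numeric(0),
                      duration_ms = numeric(0), freq = numeric(0),
                      scale = numeric(0))
  if (length(times)) {
    lc <- calib
    lc$filtered <- as.matrix(zerophase_bandpass(bg, calib$filt))
    if (is.null(sizes)) sizes <- gen_event_sizes(length(times), cfg)
    for (i in seq_along(times)) {
      dur_ms <- stats::runif(1, cfg$swr_duration_range[1],
                             cfg$swr_duration_range[2])
      freq <- stats::runif(1, cfg$ripple_freq_range[1],
                           cfg$ripple_freq_range[2])
      inj <- inject_ripple(bg, times[i], sizes[i], dur_ms, freq,
                           fs = cfg$fs,
                           phase = stats::runif(1, 0, 2 * pi), calib = lc)
      bg <- inj$traces
      truth <- rbind(truth, inj$truth)
    }
    last_event <- max(times) - pad
  }
  vis <- round(pad * cfg$fs) + seq_len(round(total * cfg$fs))
  truth$time <- truth$time - pad
  list(traces = bg[vis, , drop = FALSE], truth = truth,
       last_event = last_event - total)
}

#' Simulate one behavioral epoch
#'
#' Runs the trial state machine: home poke, travel, center poke, a
#' pre-reward period that for neurofeedback trials runs the online
#' detector closed-loop on streamed synthetic LFP and for delay trials
#' draws a yoked duration from recent NF latencies, reward, post-reward
#' dwell, arm choice, and goal-block bookkeeping. Control-cohort trials
#' use a pretraining-style random delay.
#'
#' @param cfg a [session_config()].
#' @param tcfg a [task_config()].
#' @param policy an [agent_policy()].
#' @param cal a [subject_calibration()] bundle.
#' @param day training day (sets the threshold schedule).
#' @param n_trials trials to simulate.
#' @param cohort `"manipulation"` (interleaved NF/delay) or
#'   `"control"`.
#' @param rates list with named vectors `pre` and `post` (events/s for
#'   `nf`, `delay`, `control`) and scalar `travel`.
#' @param ocfg an [online_config()] (threshold is set per trial from
#'   the schedule).
#' @param collect_lfp keep the composed session LFP (memory-heavy).
#' @return list with `trials`, `events` (ground truth),
#'   `nf_latencies`, `lfp` (matrix or NULL), `duration`, `fs`.
#' @export
simulate_epoch <- function(cfg, tcfg, policy, cal, day = 20,
                           n_trials = 40,
                           cohort = c("manipulation", "control"),
                           rates = list(pre = c(nf = 0.3, delay = 0.3,
                                                control = 0.3),
                                        post = c(nf = 0.3, delay = 0.3,
                                                 control = 0.3),
                                        travel = 0.02),
                           ocfg = online_config(), collect_lfp = FALSE,
                           n_arms = 8) {
  cohort <- match.arg(cohort)
  fs <- cfg$fs
  fd <- tcfg$feedback_delay_ms / 1000
  gstate <- goal_state_init(n_arms, tcfg)
  sampled_this_block <- integer(0)
  cur_block <- gstate$block
  nf_latencies <- numeric(0)
  trials <- list()
  events <- list()
  lfp <- list()
  gsample <- 0L   # global sample counter
  nf_count <- 0L
  pair <- character(0)
  add_seg <- function(seg_traces) {
    if (collect_lfp) lfp[[length(lfp) + 1]] <<- seg_traces
    gsample <<- gsample + nrow(seg_traces)
  }
  add_events <- function(truth, t0, trial, period, type) {
    if (!nrow(truth)) return(invisible())
    truth$time <- truth$time + t0
    truth$trial <- trial
    truth$period <- period
    truth$type <- type
    truth$is_trigger <- FALSE
    events[[length(events) + 1]] <<- truth
  }
  for (i in seq_len(n_trials)) {
    type <- if (cohort == "control") "control" else {
      if (!length(pair)) pair <- sample(c("neurofeedback", "delay"))
      tp <- pair[1]
      pair <- pair[-1]
      tp
    }
    t_home <- gsample / fs
    # travel to the center port
    travel <- round(stats::runif(1, policy$travel_range[1],
                                 policy$travel_range[2]) * fs) / fs
    seg <- segment_piecewise(cfg, data.frame(t0 = 0, t1 = travel,
                                             rate = rates$travel),
                             cal$calib)
    add_events(seg$truth, t_home, i, "travel", type)
    add_seg(seg$traces)
    if (stats::runif(1) < policy$p_violation) {
      # trial-order violation: arm poke without a center poke earns a
      # timeout instead of a reward
      t_arm <- gsample / fs
      to_dur <- round(stats::runif(1, tcfg$timeout_range[1],
                                   tcfg$timeout_range[2]) * fs) / fs
      seg <- segment_piecewise(cfg, data.frame(t0 = 0, t1 = to_dur,
                                               rate = rates$travel),
                               cal$calib)
      add_events(seg$truth, t_arm, i, "travel", type)
      add_seg(seg$traces)
      trials[[i]] <- data.frame(
        trial = i, type = type, day = day,
        t_home_poke = t_home, t_center_poke = NA_real_,
        t_reward = NA_real_, t_center_exit = NA_real_,
        t_arm_poke = t_arm, center_port = NA_integer_,
        pre_dur = NA_real_, post_dur = NA_real_,
        arm_choice = sample.int(n_arms, 1),
        goal_arm = gstate$goal_arm, rewarded = FALSE,
        phase = gstate$phase, goal_block = gstate$block,
        threshold_sd = NA_real_, trigger_size = NA_real_,
        aborted = FALSE, timeout = TRUE, timeout_dur = to_dur)
      next
    }
    t_poke <- gsample / fs
    thr <- threshold_schedule(day, max(1L, nf_count + (type ==
                                                         "neurofeedback")),
                              tcfg)
    aborted <- FALSE
    trig_size <- NA_real_
    if (type == "neurofeedback") {
      nf_count <- nf_count + 1L
      w <- simulate_nf_wait(thr, cfg, ocfg, cal$frozen, cal$size_map,
                            cal$calib, rate = rates$pre[["nf"]],
                            cap = tcfg$nf_cap, post_trigger_s = fd)
      if (!w$triggered) {
        aborted <- TRUE
        latency <- tcfg$nf_cap
      } else {
        latency <- w$latency
        trig_size <- w$trigger_size
        nf_latencies <- c(nf_latencies, latency)
      }
      ev <- w$events[w$events$time <= latency + 0.25, , drop = FALSE]
      if (nrow(ev) && w$triggered) {
        # the last injected event before the trigger is the trigger SWR
        k <- which.min(abs(latency - ev$time))
        ev$is_trigger <- FALSE
        others <- ev[-k, , drop = FALSE]
        others <- others[others$time <= latency, , drop = FALSE]
        add_events(others, t_poke, i, "pre", type)
        evk <- ev[k, , drop = FALSE]
        evk$time <- evk$time + t_poke
        evk$trial <- i
        evk$period <- "pre"
        evk$type <- type
        evk$is_trigger <- TRUE
        events[[length(events) + 1]] <- evk
      } else {
        add_events(ev, t_poke, i, "pre", type)
      }
      # the consumed stream already includes the feedback-delay
      # continuation after the trigger
      add_seg(w$lfp)
      pre_dur <- gsample / fs - t_poke
    } else {
      pre_dur <- if (type == "delay") {
        sample_yoked_delay(nf_latencies, tcfg)
      } else {
        stats::runif(1, tcfg$bootstrap_delay_range[1],
                     tcfg$bootstrap_delay_range[2])
      }
      pre_dur <- round(pre_dur * fs) / fs
    }
    # the whole pre period (delay/control) plus the post-reward dwell
    # in one segment; NF pre LFP was consumed by the closed loop above
    dwell <- round(stats::runif(1, policy$post_dwell_range[1],
                                policy$post_dwell_range[2]) * fs) / fs
    lead <- if (type == "neurofeedback") 0 else pre_dur
    iv <- data.frame(
      t0 = c(0, lead),
      t1 = c(lead, lead + dwell),
      rate = c(if (type == "neurofeedback") 0 else
        rates$pre[[switch(type, delay = "delay", control = "control")]],
        rates$post[[switch(type, neurofeedback = "nf", delay = "delay",
                           control = "control")]]))
    seg_start <- gsample / fs
    seg <- segment_piecewise(cfg, iv, cal$calib)
    pre_events <- seg$truth[seg$truth$time < lead, , drop = FALSE]
    post_events <- seg$truth[seg$truth$time >= lead, , drop = FALSE]
    if (type != "neurofeedback") {
      add_events(pre_events, seg_start, i, "pre", type)
    }
    t_reward <- t_poke + pre_dur
    add_events(post_events, seg_start, i, "post", type)
    add_seg(seg$traces)
    t_exit <- gsample / fs
    # arm run
    run <- round(stats::runif(1, policy$travel_range[1],
                              policy$travel_range[2]) * fs) / fs
    seg <- segment_piecewise(cfg, data.frame(t0 = 0, t1 = run,
                                             rate = rates$travel),
                             cal$calib)
    add_events(seg$truth, t_exit, i, "travel", type)
    add_seg(seg$traces)
    t_arm <- gsample / fs
    if (gstate$block != cur_block) {
      sampled_this_block <- integer(0)
      cur_block <- gstate$block
    }
    arm <- policy_choose_arm(policy, gstate$phase, gstate$goal_arm,
                             sampled_this_block, n_arms)
    sampled_this_block <- union(sampled_this_block, arm)
    gc_res <- goal_controller(gstate, arm)
    trials[[i]] <- data.frame(
      trial = i, type = type, day = day,
      t_home_poke = t_home, t_center_poke = t_poke,
      t_reward = t_reward, t_center_exit = t_exit, t_arm_poke = t_arm,
      center_port = sample(1:2, 1),
      pre_dur = pre_dur, post_dur = t_exit - t_reward,
      arm_choice = arm, goal_arm = gstate$goal_arm,
      rewarded = gc_res$rewarded, phase = gc_res$phase,
      goal_block = gstate$block, threshold_sd = thr,
      trigger_size = trig_size, aborted = aborted, timeout = FALSE,
      timeout_dur = NA_real_)
    gstate <- gc_res$state
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), amplitude = numeric(0),
               duration_ms = numeric(0), freq = numeric(0),
               scale = numeric(0), trial = integer(0),
               period = character(0), type = character(0),
               is_trigger = logical(0))
  rownames(ev) <- NULL
  list(trials = do.call(rbind, trials), events = ev,
       nf_latencies = nf_latencies,
       lfp = if (collect_lfp) do.call(rbind, lfp) else NULL,
       duration = gsample / fs, fs = fs)
}

# trajectory tied to the trial structure: home -> center -> arm -> home
session_trajectory <- function(trials, graph, duration, fs_pos = 25) {
  dt <- 1 / fs_pos
  n <- ceiling(duration * fs_pos)
  home_bin <- 1L
  center_bin <- max(which(graph$bins$seg_id == 2))
  arm_end <- vapply(seq_len(graph$n_arms), function(a) {
    max(which(graph$bins$seg_id == 2 + a))
  }, integer(1))
  bins <- rep(home_bin, n)
  t <- (seq_len(n) - 1) * dt
  fill_path <- function(t0, t1, from, to) {
    sel <- which(t >= t0 & t < t1)
    if (!length(sel)) return(invisible())
    lin <- seq(0, 1, length.out = length(sel))
    # linear interpolation in graph distance via straight bin walk
    p <- bin_walk(graph, from, to)
    bins[sel] <<- p[pmax(1, ceiling(lin * length(p)))]
  }
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    fill_path(tr$t_home_poke, tr$t_center_poke, home_bin, center_bin)
    sel <- which(t >= tr$t_center_poke & t < tr$t_center_exit)
    bins[sel] <- center_bin
    fill_path(tr$t_center_exit, tr$t_arm_poke, center_bin,
              arm_end[tr$arm_choice])
    t_next <- if (i < nrow(trials)) trials$t_home_poke[i + 1] else
      duration
    fill_path(tr$t_arm_poke, t_next, arm_end[tr$arm_choice], home_bin)
  }
  b <- graph$bins[bins, ]
  step_cm <- c(0, graph$dist[cbind(bins[-n], bins[-1])])
  speed <- gaussian_smooth(step_cm / dt, 0.25 * fs_pos)
  data.frame(t = t, bin = bins, x = b$x, y = b$y, lin_pos = b$lin_pos,
             segment = as.character(b$segment), speed = speed)
}

# BFS bin path between two bins
bin_walk <- function(graph, from, to) {
  if (from == to) return(from)
  prev <- integer(nrow(graph$bins))
  seen <- logical(nrow(graph$bins))
  seen[from] <- TRUE
  frontier <- from
  while (!seen[to] && length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in graph$adjacency[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  p <- to
  while (p[1] != from) p <- c(prev[p[1]], p)
  p
}

#' Generate a complete ground-truthed synthetic session
#'
#' Composes the behavioral epoch simulator with the track, place-cell,
#' and replay generators: multi-tetrode LFP with injected SWRs, a
#' trial table, a trial-locked trajectory, movement spiking, and
#' replay spiking during injected SWRs with known content labels.
#'
#' @param cfg a [session_config()].
#' @param tcfg a [task_config()].
#' @param policy an [agent_policy()].
#' @param day,n_trials,cohort,rates,ocfg passed to [simulate_epoch()].
#' @param replay_probs probabilities of (local, remote, none) content
#'   for each injected port-period SWR.
#' @param include_spikes generate trajectory + spikes (movement and
#'   replay).
#' @param seed integer; fully determines the session.
#' @return a `swr_session` list.
#' @export
gen_session <- function(cfg, tcfg = task_config(),
                        policy = agent_policy(), day = 20,
                        n_trials = 20, cohort = "manipulation",
                        rates = list(pre = c(nf = 0.3, delay = 0.3,
                                             control = 0.3),
                                     post = c(nf = 0.3, delay = 0.3,
                                              control = 0.3),
                                     travel = 0.02),
                        ocfg = online_config(),
                        replay_probs = c(local = 0.3, remote = 0.5,
                                         none = 0.2),
                        include_spikes = TRUE, seed = cfg$rng_seed) {
  set.seed(seed)
  graph <- make_track_graph()
  model <- gen_place_model(cfg$n_cells, graph, cfg$n_tetrodes)
  # pre-task encoding block: free running with full arm coverage, on
  # its own clock (encoding epochs precede the task)
  encoding <- NULL
  if (include_spikes) {
    enc_traj <- gen_trajectory(graph, 180)
    encoding <- list(trajectory = enc_traj,
                     spikes = gen_movement_spikes(enc_traj, model,
                                                  graph))
  }
  cal <- subject_calibration(cfg, ocfg,
                             with_size_map = cohort == "manipulation")
  ep <- simulate_epoch(cfg, tcfg, policy, cal, day = day,
                       n_trials = n_trials, cohort = cohort,
                       rates = rates, ocfg = ocfg, collect_lfp = TRUE)
  ev <- ep$events
  ev$replay_kind <- "none"
  ev$replay_segment <- NA_character_
  spikes <- NULL
  traj <- NULL
  if (include_spikes) {
    traj <- session_trajectory(ep$trials, graph, ep$duration)
    spikes <- gen_movement_spikes(traj, model, graph)
    center_bin <- max(which(graph$bins$seg_id == 2))
    arm_first <- vapply(seq_len(graph$n_arms), function(a) {
      min(which(graph$bins$seg_id == 2 + a))
    }, integer(1))
    port_ev <- which(ev$period %in% c("pre", "post"))
    kinds <- sample(names(replay_probs), length(port_ev), replace = TRUE,
                    prob = replay_probs)
    for (k in seq_along(port_ev)) {
      e <- port_ev[k]
      if (kinds[k] == "none") next
      if (kinds[k] == "local") {
        # replay within the animal's segment (center)
        path <- bin_walk(graph, min(which(graph$bins$seg_id == 2)),
                         center_bin)
        seg_name <- "center"
      } else {
        arm <- sample.int(graph$n_arms, 1)
        a0 <- arm_first[arm]
        path <- bin_walk(graph, a0,
                         max(which(graph$bins$seg_id == 2 + arm)))
        seg_name <- paste0("arm", arm)
      }
      if (stats::runif(1) < 0.5) path <- rev(path)
      rs <- gen_replay_spikes(ev$time[e], ev$duration_ms[e], path,
                              model, graph,
                              compression = cfg$replay_compression)
      ev$replay_kind[e] <- kinds[k]
      ev$replay_segment[e] <- seg_name
      if (nrow(rs)) spikes <- rbind(spikes, rs)
    }
    if (!is.null(spikes)) spikes <- spikes[order(spikes$t), ]
  }
  structure(list(config = cfg, task_config = tcfg, fs = cfg$fs,
                 lfp = ep$lfp, trials = ep$trials, events = ev,
                 spikes = spikes, trajectory = traj,
                 encoding = encoding, graph = graph,
                 place_model = model, nf_latencies = ep$nf_latencies,
                 duration = ep$duration, seed = seed),
            class = "swr_session")
}

#' Write a session to a directory
#'
#' LFP as one flat binary float32 file per tetrode with a plain-text
#' header; spikes, trials, events, and trajectory as tab-separated
#' tables.
#'
#' @param session a [gen_session()] object.
#' @param dir output directory (created).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ntet <- ncol(session$lfp)
  writeLines(c(paste("fs", session$fs),
               paste("n_samples", nrow(session$lfp)),
               paste("n_tetrodes", ntet),
               paste("units", "uV"),
               paste("seed", session$seed)),
             file.path(dir, "header.txt"))
  for (j in seq_len(ntet)) {
    con <- file(file.path(dir, sprintf("lfp_tt%02d.f32", j)), "wb")
    writeBin(as.numeric(session$lfp[, j]), con, size = 4,
             endian = "little")
    close(con)
  }
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(session$trials, "trials.tsv")
  wt(session$events, "events.tsv")
  if (!is.null(session$spikes)) wt(session$spikes, "spikes.tsv")
  if (!is.null(session$trajectory)) wt(session$trajectory,
                                       "trajectory.tsv")
  if (!is.null(session$encoding)) {
    wt(session$encoding$trajectory, "encoding_trajectory.tsv")
    wt(session$encoding$spikes, "encoding_spikes.tsv")
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return list with `lfp`, `fs`, `trials`, `events`, and (if present)
#'   `spikes`, `trajectory`.
#' @export
read_session <- function(dir) {
  hdr <- utils::read.table(file.path(dir, "header.txt"),
                           col.names = c("key", "value"),
                           colClasses = "character")
  h <- stats::setNames(hdr$value, hdr$key)
  fs <- as.numeric(h["fs"])
  n <- as.integer(h["n_samples"])
  ntet <- as.integer(h["n_tetrodes"])
  lfp <- matrix(0, n, ntet)
  for (j in seq_len(ntet)) {
    con <- file(file.path(dir, sprintf("lfp_tt%02d.f32", j)), "rb")
    lfp[, j] <- readBin(con, numeric(), n, size = 4, endian = "little")
    close(con)
  }
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.table(p, header = TRUE, sep = "\t")
    else NULL
  }
  enc_t <- rd("encoding_trajectory.tsv")
  list(lfp = lfp, fs = fs, trials = rd("trials.tsv"),
       events = rd("events.tsv"), spikes = rd("spikes.tsv"),
       trajectory = rd("trajectory.tsv"),
       encoding = if (!is.null(enc_t)) {
         list(trajectory = enc_t, spikes = rd("encoding_spikes.tsv"))
       })
}
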