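#' Classify the decoded content of one SWR event
#'
#' An event is interpretable if the time-averaged probability of the
#' continuous movement state exceeds 0.8 and at least 30% of the
#' time-averaged position posterior falls in a single maze segment.
#' Interpretable events are local when the dominant segment is the
#' animal's current segment, remote otherwise.
#'
#' @param posterior a [decode()] grid covering the event.
#' @param graph a [make_track_graph()].
#' @param animal_segment segment name of the animal's position during
#'   the event.
#' @param p_cont_rule `"mean"` (time-average, default) or `"min"`
#'   (pointwise) application of the 0.8 rule.
#' @param p_cont_threshold,density_threshold classification thresholds.
#' @return a one-row data.frame: `interpretable`, `kind`
#'   (local/remote/none), `dominant_segment`, `p_continuous`, plus the
#'   per-segment posterior fractions as attribute `segment_density`.
#' @export
classify_event <- function(posterior, graph, animal_segment,
                           p_cont_rule = c("mean", "min"),
                           p_cont_threshold = 0.8,
                           density_threshold = 0.30) {
  p_cont_rule <- match.arg(p_cont_rule)
  if (!length(posterior$t)) stop("empty posterior")
  p_cont_t <- apply(posterior$post[, , 1, drop = FALSE], 1, sum)
  p_cont <- if (p_cont_rule == "mean") mean(p_cont_t) else min(p_cont_t)
  pos_marg <- apply(posterior$post, 2, sum)
  pos_marg <- pos_marg / sum(pos_marg)
  seg <- bin_segments(graph)
  seg_density <- tapply(pos_marg, seg, sum)
  dominant <- names(seg_density)[which.max(seg_density)]
  interpretable <- (p_cont > p_cont_threshold) &&
    (max(seg_density) >= density_threshold)
  kind <- if (!interpretable) "none" else
    if (identical(dominant, as.character(animal_segment))) "local" else
      "remote"
  out <- data.frame(interpretable = interpretable, kind = kind,
                    dominant_segment = if (interpretable) dominant else
                      NA_character_,
                    p_continuous = p_cont)
  attr(out, "segment_density") <- seg_density
  out
}

#' Per-trial remote replay rates and per-epoch interpretable fraction
#'
#' @param labels data.frame of [classify_event()] rows with an added
#'   `t_peak` column (event peak time, s) and optionally `is_trigger`.
#' @param trials trial table with `t_center_poke`, `t_reward`,
#'   `t_center_exit`, `trial`.
#' @param period `"pre"`, `"post"`, or `"total"` (center-port period).
#' @param exclude_trigger drop events flagged `is_trigger` from the rate
#'   numerator (default TRUE, consistent with timewise rate rules).
#' @return list with `per_trial` (data.frame: trial, duration, n_remote,
#'   remote_rate) and `interpretable_fraction`.
#' @export
replay_rates <- function(labels, trials, period = c("pre", "post", "total"),
                         exclude_trigger = TRUE) {
  period <- match.arg(period)
  stopifnot(!is.null(labels$t_peak))
  n <- nrow(trials)
  out <- data.frame(trial = trials$trial, duration = NA_real_,
                    n_remote = 0L, remote_rate = NA_real_,
                    skipped = FALSE)
  ev <- labels
  if (exclude_trigger && !is.null(ev$is_trigger)) {
    ev <- ev[!ev$is_trigger, , drop = FALSE]
  }
  for (i in seq_len(n)) {
    lim <- switch(period,
                  pre = c(trials$t_center_poke[i], trials$t_reward[i]),
                  post = c(trials$t_reward[i], trials$t_center_exit[i]),
                  total = c(trials$t_center_poke[i],
                            trials$t_center_exit[i]))
    dur <- lim[2] - lim[1]
    if (!is.finite(dur) || dur <= 0) {
      out$skipped[i] <- TRUE
      next
    }
    inwin <- ev$t_peak >= lim[1] & ev$t_peak < lim[2]
    out$duration[i] <- dur
    out$n_remote[i] <- sum(inwin & ev$kind == "remote")
    out$remote_rate[i] <- out$n_remote[i] / dur
  }
  list(per_trial = out,
       interpretable_fraction = mean(labels$interpretable))
}

#' Build the arm-category design for the replay GLM
#'
#' Each trial contributes one row per maze arm; binary predictors mark
#' whether the arm is the previous trial's arm, the current (future)
#' choice, or the previous goal block's goal arm; the response is the
#' number of remote replays of that arm during the trial's analysis
#' period. Search and repeat trials from the second goal block onward
#' are used, so every trial has a valid previous goal.
#'
#' @param trials trial table with `trial`, `arm_choice`, `goal_block`,
#'   and goal bookkeeping (`goal_arm`).
#' @param replay_arms list (by trial index) of integer vectors: the arm
#'   replayed by each counted replay event of that trial.
#' @param n_arms number of arms.
#' @return data.frame: `trial`, `arm`, `previous_arm`, `future_arm`,
#'   `previous_goal_arm`, `count`.
#' @export
build_arm_design <- function(trials, replay_arms, n_arms = 8) {
  rows <- list()
  prev_goal_of_block <- function(block) {
    b <- trials$goal_arm[trials$goal_block == block - 1]
    if (length(b)) b[length(b)] else NA_integer_
  }
  for (i in seq_len(nrow(trials))) {
    if (trials$goal_block[i] < 2 || i == 1) next
    prev_arm <- trials$arm_choice[i - 1]
    prev_goal <- prev_goal_of_block(trials$goal_block[i])
    counts <- tabulate(replay_arms[[i]], n_arms)
    rows[[length(rows) + 1]] <- data.frame(
      trial = trials$trial[i], arm = seq_len(n_arms),
      previous_arm = as.integer(seq_len(n_arms) == prev_arm),
      future_arm = as.integer(seq_len(n_arms) == trials$arm_choice[i]),
      previous_goal_arm = as.integer(seq_len(n_arms) == prev_goal),
      count = counts)
  }
  if (!length(rows)) stop("no eligible trials for the arm design")
  do.call(rbind, rows)
}

#' Fit the arm-category Poisson GLM
#'
#' Poisson regression of per-arm replay counts on the three binary arm
#' categories; coefficients are converted to fold changes by
#' exponentiation, with exponentiated Wald confidence intervals.
#'
#' @param design a [build_arm_design()] data.frame.
#' @param conf_level confidence level for the Wald intervals.
#' @return data.frame: `term`, `estimate` (log scale), `fold_change`,
#'   `ci_lo`, `ci_hi`, `p_value`, `estimable`.
#' @export
fit_replay_glm <- function(design, conf_level = 0.95) {
  preds <- c("previous_arm", "future_arm", "previous_goal_arm")
  fit <- stats::glm(count ~ previous_arm + future_arm + previous_goal_arm,
                    family = stats::poisson(), data = design)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- rownames(sm)
  out <- data.frame(term = terms, estimate = sm[, 1],
                    fold_change = exp(sm[, 1]),
                    ci_lo = exp(sm[, 1] - z * sm[, 2]),
                    ci_hi = exp(sm[, 1] + z * sm[, 2]),
                    p_value = sm[, 4], estimable = TRUE,
                    row.names = NULL)
  # flag non-estimable categories: predictor constant, or no events at
  # a level needed to identify the coefficient
  for (p in preds) {
    degenerate <- length(unique(design[[p]])) < 2 ||
      !is.finite(sm[match(p, terms), 2]) ||
      sm[match(p, terms), 2] > 10
    if (!(p %in% terms)) {
      out <- rbind(out, data.frame(term = p, estimate = NA, fold_change = NA,
                                   ci_lo = NA, ci_hi = NA, p_value = NA,
                                   estimable = FALSE))
    } else if (degenerate) {
      out$estimable[out$term == p] <- FALSE
    }
  }
  out
}
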