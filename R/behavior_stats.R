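#' Reward-aligned timewise SWR rate curve
#'
#' Counts events in 0.5 s bins between center-port entry and exit for
#' each trial, indexes bins relative to reward delivery (negative =
#' pre-reward), and averages across trials. Bins with fewer than
#' `min_trials` contributing trials are omitted; neurofeedback trigger
#' events are excluded when flagged.
#'
#' @param trials trial table with `t_center_poke`, `t_reward`,
#'   `t_center_exit`.
#' @param events event table with `t_peak` and optionally `is_trigger`.
#' @param bin bin width, s.
#' @param min_trials minimum contributing trials per bin.
#' @param exclude_trigger drop trigger-flagged events.
#' @return data.frame: `bin_start` (s rel. reward), `rate` (ev/s),
#'   `sem`, `n_trials`.
#' @export
timewise_rate <- function(trials, events, bin = 0.5, min_trials = 100,
                          exclude_trigger = TRUE) {
  stopifnot(!is.null(events$t_peak))
  ev <- events
  if (exclude_trigger && !is.null(ev$is_trigger)) {
    ev <- ev[!ev$is_trigger, , drop = FALSE]
  }
  ok <- is.finite(trials$t_reward)
  trials <- trials[ok, , drop = FALSE]
  per_trial <- list()
  for (i in seq_len(nrow(trials))) {
    lo <- trials$t_center_poke[i] - trials$t_reward[i]
    hi <- trials$t_center_exit[i] - trials$t_reward[i]
    b0 <- floor(lo / bin)
    b1 <- ceiling(hi / bin) - 1
    bins <- b0:b1
    # only bins fully inside the port interval contribute
    full <- (bins * bin >= lo) & ((bins + 1) * bin <= hi)
    if (!any(full)) next
    bins <- bins[full]
    tev <- ev$t_peak - trials$t_reward[i]
    counts <- vapply(bins, function(b) {
      sum(tev >= b * bin & tev < (b + 1) * bin)
    }, numeric(1))
    per_trial[[length(per_trial) + 1]] <-
      data.frame(bin_idx = bins, count = counts)
  }
  if (!length(per_trial)) {
    return(data.frame(bin_start = numeric(0), rate = numeric(0),
                      sem = numeric(0), n_trials = integer(0)))
  }
  dd <- do.call(rbind, per_trial)
  agg <- stats::aggregate(count ~ bin_idx, dd,
                          function(v) c(m = mean(v),
                                        sem = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  res <- data.frame(bin_start = agg$bin_idx * bin,
                    rate = agg$count[, "m"] / bin,
                    sem = agg$count[, "sem"] / bin,
                    n_trials = as.integer(agg$count[, "n"]))
  res[res$n_trials >= min_trials, , drop = FALSE]
}

#' Per-trial period metrics
#'
#' Event counts/rates and dwell for the pre-reward (center poke to
#' reward) and post-reward (reward to exit) periods, with optional
#' exclusion of suprathreshold events (events at or above the trial's
#' online threshold, including the trigger), plus smoothed mean head
#' speed per period when a trajectory is supplied.
#'
#' @param trials trial table with `trial`, `t_center_poke`, `t_reward`,
#'   `t_center_exit`, optionally `threshold_sd`.
#' @param events event table with `t_peak`, `size`, optionally
#'   `is_trigger`.
#' @param exclude_suprathreshold drop events with
#'   `size >= threshold_sd` of their trial (both NF and delay trials).
#' @param exclude_trigger drop trigger-flagged events only.
#' @param trajectory optional data.frame (`t`, `speed`) for per-period
#'   smoothed mean speed.
#' @return data.frame of per-trial metrics.
#' @export
period_metrics <- function(trials, events,
                           exclude_suprathreshold = FALSE,
                           exclude_trigger = FALSE,
                           trajectory = NULL) {
  stopifnot(!is.null(events$t_peak))
  n <- nrow(trials)
  out <- data.frame(trial = trials$trial,
                    pre_dur = trials$t_reward - trials$t_center_poke,
                    post_dur = trials$t_center_exit - trials$t_reward)
  if (any(stats::na.omit(c(out$pre_dur, out$post_dur)) < 0)) {
    stop("negative period duration")
  }
  out$pre_count <- out$post_count <- 0L
  out$pre_size <- out$post_size <- NA_real_
  out$pre_speed <- out$post_speed <- NA_real_
  for (i in seq_len(n)) {
    ev <- events
    if (exclude_trigger && !is.null(ev$is_trigger)) {
      ev <- ev[!ev$is_trigger, , drop = FALSE]
    }
    if (exclude_suprathreshold && !is.null(trials$threshold_sd)) {
      ev <- ev[ev$size < trials$threshold_sd[i], , drop = FALSE]
    }
    pre <- ev$t_peak >= trials$t_center_poke[i] &
      ev$t_peak < trials$t_reward[i]
    post <- ev$t_peak >= trials$t_reward[i] &
      ev$t_peak < trials$t_center_exit[i]
    out$pre_count[i] <- sum(pre)
    out$post_count[i] <- sum(post)
    out$pre_size[i] <- if (any(pre)) mean(ev$size[pre]) else NA_real_
    out$post_size[i] <- if (any(post)) mean(ev$size[post]) else NA_real_
    if (!is.null(trajectory)) {
      sel_pre <- trajectory$t >= trials$t_center_poke[i] &
        trajectory$t < trials$t_reward[i]
      sel_post <- trajectory$t >= trials$t_reward[i] &
        trajectory$t < trials$t_center_exit[i]
      if (any(sel_pre)) out$pre_speed[i] <- mean(trajectory$speed[sel_pre])
      if (any(sel_post)) out$post_speed[i] <-
          mean(trajectory$speed[sel_post])
    }
  }
  out$pre_rate <- ifelse(out$pre_dur > 0, out$pre_count / out$pre_dur, NA)
  out$post_rate <- ifelse(out$post_dur > 0, out$post_count / out$post_dur,
                          NA)
  out$total_rate <- ifelse(out$pre_dur + out$post_dur > 0,
                           (out$pre_count + out$post_count) /
                             (out$pre_dur + out$post_dur), NA)
  out$post_dwell <- out$post_dur
  out
}

#' Speed-matched quartile subsets
#'
#' Selects, per group, the quartile of neurofeedback trials with the
#' highest mean pre-reward head speed and the quartiles of delay and
#' control trials with the lowest, for speed-controlled rate
#' comparisons. Ties are broken by trial index.
#'
#' @param metrics a [period_metrics()] data.frame with a `group` column
#'   (`nf`, `delay`, or `control`) and `pre_speed`.
#' @return list of data.frames by group (the selected subsets).
#' @export
speed_quartile_analysis <- function(metrics) {
  pick <- function(df, highest) {
    if (nrow(df) < 4) {
      return(df[0, , drop = FALSE])
    }
    k <- floor(nrow(df) / 4)
    o <- order(df$pre_speed, seq_len(nrow(df)),
               decreasing = highest)
    df[sort(o[seq_len(k)]), , drop = FALSE]
  }
  split_g <- split(metrics, metrics$group)
  out <- list()
  for (g in names(split_g)) {
    out[[g]] <- pick(split_g[[g]], highest = identical(g, "nf"))
  }
  out
}

#' Task-performance metrics per epoch
#'
#' Search efficiency (fraction of search trials choosing a not-yet-
#' sampled arm; the sampling history resets at each goal switch),
#' the NF fraction of redundant search trials, the fraction of repeat
#' trials visiting the goal, and the NF fraction of error repeat
#' trials.
#'
#' @param trials trial table with `phase` (search/repeat), `arm_choice`,
#'   `goal_arm`, `goal_block`, `type` (neurofeedback/delay/control),
#'   `rewarded`.
#' @return one-row data.frame of the four metrics plus counts.
#' @export
performance_metrics <- function(trials) {
  search <- trials$phase == "search"
  if (!any(search)) {
    return(data.frame(search_efficiency = NA, redundant_nf_fraction = NA,
                      correct_repeat_fraction = NA,
                      error_nf_fraction = NA, n_search = 0L,
                      n_repeat = sum(trials$phase == "repeat")))
  }
  novel <- logical(nrow(trials))
  sampled <- integer(0)
  cur_block <- trials$goal_block[1]
  for (i in seq_len(nrow(trials))) {
    if (trials$goal_block[i] != cur_block) {
      sampled <- integer(0)
      cur_block <- trials$goal_block[i]
    }
    if (search[i]) {
      novel[i] <- !(trials$arm_choice[i] %in% sampled)
      sampled <- union(sampled, trials$arm_choice[i])
    }
  }
  redundant <- search & !novel
  rep_tr <- trials$phase == "repeat"
  correct_rep <- rep_tr & trials$arm_choice == trials$goal_arm
  error_rep <- rep_tr & !correct_rep
  is_nf <- trials$type == "neurofeedback"
  data.frame(
    search_efficiency = mean(novel[search]),
    redundant_nf_fraction = if (any(redundant)) mean(is_nf[redundant])
      else NA_real_,
    correct_repeat_fraction = if (any(rep_tr)) mean(correct_rep[rep_tr])
      else NA_real_,
    error_nf_fraction = if (any(error_rep)) mean(is_nf[error_rep])
      else NA_real_,
    n_search = sum(search), n_repeat = sum(rep_tr))
}

#' Within-subject rank-sum comparisons with BH correction
#'
#' Two-sided Wilcoxon rank-sum per comparison; Benjamini-Hochberg
#' step-up adjustment across the family.
#'
#' @param pairs named list; each element is a list with numeric `nf`
#'   and `delay` samples.
#' @return data.frame: `comparison`, `p_raw`, `p_adj`, `skipped`.
#' @export
within_subject_compare <- function(pairs) {
  p <- vapply(pairs, function(pr) {
    if (!length(pr$nf) || !length(pr$delay)) return(NA_real_)
    stats::wilcox.test(pr$nf, pr$delay, exact = FALSE)$p.value
  }, numeric(1))
  data.frame(comparison = names(pairs), p_raw = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             skipped = is.na(p), row.names = NULL)
}

#' Groupwise mixed-effects comparison
#'
#' Fixed group effect (control cohort trials as reference vs
#' manipulation-cohort NF and delay trials) with a subject-level random
#' intercept. Linear family for rates, dwell, size, and proportions;
#' Poisson family for counts.
#'
#' @param data data.frame with `value`, `subject`, `group` (factor with
#'   levels control, nf, delay).
#' @param family `"linear"` or `"poisson"`.
#' @return list with `coefficients` (data.frame: contrast, estimate,
#'   se, p_value) and the fitted model.
#' @export
groupwise_model <- function(data, family = c("linear", "poisson")) {
  family <- match.arg(family)
  if (family == "poisson" && any(data$value %% 1 != 0)) {
    stop("poisson family requires count outcomes")
  }
  data$group <- stats::relevel(factor(data$group), ref = "control")
  tab <- table(unique(data[, c("subject", "group")])$group)
  if (any(tab < 2)) stop("need at least two subjects per cohort")
  if (family == "linear") {
    fit <- lmerTest::lmer(value ~ group + (1 | subject), data = data)
    sm <- stats::coef(summary(fit))
    pcol <- "Pr(>|t|)"
  } else {
    fit <- lme4::glmer(value ~ group + (1 | subject), data = data,
                       family = stats::poisson())
    sm <- stats::coef(summary(fit))
    pcol <- "Pr(>|z|)"
  }
  rows <- grep("^group", rownames(sm))
  list(coefficients = data.frame(
         contrast = sub("^group", "", rownames(sm)[rows]),
         estimate = sm[rows, "Estimate"],
         se = sm[rows, "Std. Error"],
         p_value = sm[rows, pcol], row.names = NULL),
       model = fit)
}

#' Exact two-sided sign test against 0.5
#'
#' @param successes,n counts.
#' @return two-sided binomial p-value.
#' @export
sign_test_fraction <- function(successes, n) {
  if (n == 0) return(NA_real_)
  stats::binom.test(successes, n, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Pre/post correlation per subject
#'
#' Pearson correlation between pre- and post-reward values across a
#' subject's trials, with the standard t-based p-value.
#'
#' @param pre,post numeric vectors (same length, one value per trial).
#' @return list with `r`, `p`, `n`, `defined`.
#' @export
prepost_correlation <- function(pre, post) {
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 3 || stats::sd(pre) == 0 || stats::sd(post) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(pre),
                defined = FALSE))
  }
  ct <- stats::cor.test(pre, post)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(pre),
       defined = TRUE)
}
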