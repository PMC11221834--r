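test_that("timewise rate bins align to reward and enforce the trial
           minimum", {
  # 200 identical trials, one event in the bin [-1.0, -0.5) s
  trials <- data.frame(t_center_poke = seq(0, by = 50,
                                           length.out = 200))
  trials$t_reward <- trials$t_center_poke + 5
  trials$t_center_exit <- trials$t_reward + 5
  ev <- data.frame(t_peak = trials$t_reward[1:3] - 0.75)
  r <- timewise_rate(trials, ev, min_trials = 100)
  row <- r[r$bin_start == -1.0, ]
  expect_equal(row$rate, 3 / (200 * 0.5))
  expect_equal(row$n_trials, 200)
  # bins contributed by fewer than min_trials are dropped
  trials2 <- trials
  trials2$t_center_poke[1:150] <- trials2$t_reward[1:150] - 1.2
  r2 <- timewise_rate(trials2, ev, min_trials = 100)
  expect_false(any(r2$bin_start <= -2))
  # constant-rate generator: curve flat within SEM bands
  set.seed(90)
  evs <- data.frame(t_peak = sort(runif(3000, 0, max(trials$t_center_exit))))
  r3 <- timewise_rate(trials, evs, min_trials = 100)
  grand <- mean(r3$rate)
  expect_true(all(abs(r3$rate - grand) < 4 * r3$sem))
})

test_that("period metrics count, rate, and apply exclusions
           consistently", {
  trials <- data.frame(trial = 1:2, type = c("neurofeedback", "delay"),
                       t_center_poke = c(0, 100),
                       t_reward = c(8, 104),
                       t_center_exit = c(12, 108),
                       threshold_sd = c(6, 6))
  ev <- data.frame(
    t_peak = c(2, 5, 7.9, 101, 103, 106),
    size = c(3, 4, 9, 3, 8, 2),
    is_trigger = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  pm <- period_metrics(trials, ev)
  expect_equal(pm$pre_count, c(3L, 2L))
  expect_equal(pm$pre_rate, c(3 / 8, 2 / 4))
  # conservation: pre + post = all events in the port interval
  expect_equal(pm$pre_count + pm$post_count, c(3L, 3L))
  # trigger exclusion removes exactly one event per completed NF trial
  pm_t <- period_metrics(trials, ev, exclude_trigger = TRUE)
  expect_equal(pm$pre_count - pm_t$pre_count, c(1L, 0L))
  # suprathreshold exclusion drops events >= the trial threshold on
  # both NF and delay trials
  pm_s <- period_metrics(trials, ev, exclude_suprathreshold = TRUE)
  expect_equal(pm_s$pre_count, c(2L, 1L))
  expect_error(period_metrics(
    data.frame(trial = 1, t_center_poke = 5, t_reward = 3,
               t_center_exit = 10), ev), "negative")
})

test_that("speed quartiles select the documented extremes with index
           tie-breaks", {
  m <- data.frame(trial = 1:8, group = "nf",
                  pre_speed = c(3, 9, 5, 7, 1, 8, 2, 6))
  sel <- speed_quartile_analysis(m)
  expect_equal(sort(sel$nf$pre_speed), c(8, 9))   # top quartile of 8 = 2
  m2 <- m
  m2$group <- "delay"
  sel2 <- speed_quartile_analysis(m2)
  expect_equal(sort(sel2$delay$pre_speed), c(1, 2))
  # all-equal speeds: ties broken by trial index
  m3 <- data.frame(trial = 1:8, group = "control", pre_speed = 5)
  sel3 <- speed_quartile_analysis(m3)
  expect_equal(sel3$control$trial, 1:2)
  # too few trials: empty with no error
  expect_equal(nrow(speed_quartile_analysis(
    data.frame(trial = 1:3, group = "nf", pre_speed = 1:3))$nf), 0)
})

test_that("performance metrics follow the goal-block bookkeeping", {
  trials <- data.frame(
    trial = 1:10,
    phase = c("search", "search", "search", "repeat", "repeat",
              "search", "search", "repeat", "repeat", "repeat"),
    arm_choice = c(1, 2, 2, 3, 3, 4, 5, 6, 7, 6),
    goal_arm = c(3, 3, 3, 3, 3, 6, 6, 6, 6, 6),
    goal_block = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
    type = c("neurofeedback", "delay", "neurofeedback", "delay",
             "neurofeedback", "delay", "neurofeedback", "delay",
             "neurofeedback", "delay"),
    rewarded = FALSE)
  p <- performance_metrics(trials)
  # searches: arms 1,2,2 (block1), 4,5 (block2): one redundant (trial 3)
  expect_equal(p$search_efficiency, 4 / 5)
  expect_equal(p$redundant_nf_fraction, 1)   # trial 3 is NF
  # repeats: choices 3,3 (goal 3) and 6,7,6 (goal 6): correct 4 of 5
  expect_equal(p$correct_repeat_fraction, 4 / 5)
  expect_equal(p$error_nf_fraction, 1)       # trial 9 (choice 7) is NF
  # policy limit: no repeat-sampling -> efficiency 1
  trials$arm_choice <- c(1, 2, 3, 3, 3, 4, 5, 6, 6, 6)
  expect_equal(performance_metrics(trials)$search_efficiency, 1)
})

test_that("BH adjustment equals the hand-computed step-up and orders
           correctly", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  res <- within_subject_compare(list(
    a = list(nf = 1, delay = 2), b = list(nf = 1, delay = 2),
    c = list(nf = 1, delay = 2), d = list(nf = 1, delay = 2)))
  # direct check of the documented example via p.adjust semantics
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  # brute-force step-up oracle over random vectors
  set.seed(91)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  for (r in 1:50) {
    p <- runif(sample(2:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
  # adjusted >= raw always, and skipped comparisons flagged
  res2 <- within_subject_compare(list(
    x = list(nf = rnorm(20), delay = rnorm(20)),
    y = list(nf = rnorm(20), delay = rnorm(20, 2)),
    z = list(nf = numeric(0), delay = rnorm(5))))
  ok <- !res2$skipped
  expect_true(all(res2$p_adj[ok] >= res2$p_raw[ok] - 1e-12))
  expect_true(res2$skipped[3])
})

test_that("rank-sum p-values are calibrated under the null", {
  set.seed(92)
  ps <- replicate(200, stats::wilcox.test(rnorm(30), rnorm(30),
                                          exact = FALSE)$p.value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value,
            0.01)
})

test_that("sign test gives exact binomial two-sided p-values", {
  expect_equal(sign_test_fraction(5, 10), 1.0)
  expect_equal(sign_test_fraction(0, 10), 2 * 0.5^10,
               tolerance = 1e-12)
  expect_equal(sign_test_fraction(10, 10), sign_test_fraction(0, 10))
  expect_true(is.na(sign_test_fraction(0, 0)))
})

test_that("pre/post correlations behave at the sign limits and under
           independence", {
  set.seed(93)
  x <- rnorm(50)
  expect_equal(prepost_correlation(x, x)$r, 1)
  r_neg <- prepost_correlation(x, -x + rnorm(50, 0, 0.1))$r
  expect_lt(r_neg, -0.9)
  rs <- replicate(50, prepost_correlation(rnorm(40), rnorm(40))$r)
  expect_gt(mean(abs(rs) < 3 / sqrt(40)), 0.8)
  expect_false(prepost_correlation(rep(1, 10), rnorm(10))$defined)
})

test_that("groupwise mixed model recovers effects and refuses degenerate
           cohorts", {
  set.seed(94)
  make_data <- function(effect_nf = 0, n_sub = 4, n_per = 60) {
    rows <- list()
    for (g in c("control", "nf", "delay")) {
      for (s in seq_len(n_sub)) {
        mu <- 1 + rnorm(1, 0, 0.2) + (g == "nf") * effect_nf
        rows[[length(rows) + 1]] <- data.frame(
          value = rnorm(n_per, mu, 0.5),
          subject = paste0(g, s), group = g)
      }
    }
    do.call(rbind, rows)
  }
  fit <- groupwise_model(make_data(effect_nf = 0.6), family = "linear")
  est <- fit$coefficients
  nf_row <- est[est$contrast == "nf", ]
  expect_lt(abs(nf_row$estimate - 0.6), 3 * nf_row$se)
  expect_lt(nf_row$p_value, 0.05)
  # poisson family on counts
  d <- make_data()
  d$value <- rpois(nrow(d), 3)
  fitp <- groupwise_model(d, family = "poisson")
  expect_equal(nrow(fitp$coefficients), 2)
  # family mismatch
  dd <- make_data()
  expect_error(groupwise_model(dd, family = "poisson"), "count")
  # single subject in a cohort refused
  d1 <- make_data(n_sub = 1)
  expect_error(groupwise_model(d1, family = "linear"), "two subjects")
})
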