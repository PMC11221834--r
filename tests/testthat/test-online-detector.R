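test_that("baseline recursion matches its closed form and single steps", {
  # one step from zero state
  st <- update_baseline(baseline_init(0, 0, 10000), 1)
  expect_equal(st$mu, 1e-4)
  expect_equal(st$sigma, 1e-4)
  # fixed point: mu = |x|, sigma = 0
  st <- update_baseline(baseline_init(5, 0, 10000), 5)
  expect_equal(st$mu, 5)
  expect_equal(st$sigma, 0)
  # geometric closed form for constant unit input
  r <- run_baseline(baseline_init(0, 0, 10000), rep(1, 10000))
  expect_equal(r$mu, 1 - (1 - 1e-4)^10000, tolerance = 1e-12)
  # compiled path equals the plain-R recursion on noise
  set.seed(1)
  x <- rnorm(500, 0, 3)
  r2 <- run_baseline(baseline_init(0.5, 0.1, 100), x)
  o <- baseline_oracle(x, 0.5, 0.1, 100)
  expect_equal(r2$mu, unname(o["mu"]), tolerance = 1e-12)
  expect_equal(r2$sigma, unname(o["sigma"]), tolerance = 1e-12)
  expect_error(update_baseline(baseline_init(), NaN), "non-finite")
})

test_that("envelope estimator applies asymmetric gains as specified", {
  # decreasing branch: g = 0.2
  st <- update_envelope(envelope_init(1, v = 10), 4)
  expect_equal(st$v[1], 8.8)
  expect_equal(st$g, 0.2)
  # increasing branch with a 0.2-filled history:
  # g = (1.2 + 19 * 0.2) / 20 = 0.25
  st <- update_envelope(envelope_init(1, v = 1), 5)
  expect_equal(st$v[1], 2.0)
  expect_equal(st$g, 0.25)
  # sustained increases drive the gain toward 1.2 monotonically; the
  # 19-gain moving average converges slowly (~0.85 by step 200)
  st <- envelope_init(1, v = 0)
  gains <- numeric(400)
  for (k in 1:400) {
    st <- update_envelope(st, k)          # ramp: always increasing
    gains[k] <- st$g
  }
  expect_true(all(diff(gains) >= -1e-12))
  expect_gt(gains[400], 1.0)
  expect_lt(gains[400], 1.2)
  # compiled path equals the plain-R recursion on noise
  set.seed(2)
  x <- abs(rnorm(200, 5, 2))
  st <- envelope_init(1, v = x[1])
  for (xi in x[-1]) st <- update_envelope(st, xi)
  expect_equal(st$v[1], envelope_oracle(x[-1], x[1]), tolerance = 1e-12)
})

test_that("envelope rises faster than it falls (asymmetry)", {
  for (b in c(1, 5, 20)) {
    st <- envelope_init(1, v = b)
    up <- 0
    while (st$v[1] < b + 0.9 * 2 * b) {   # rise to 90% of a step to 3b
      st <- update_envelope(st, 3 * b)
      up <- up + 1
    }
    down <- 0
    while (st$v[1] > 1.1 * b) {           # fall back to 110% of b
      st <- update_envelope(st, b)
      down <- down + 1
    }
    expect_lt(up, down)
  }
})

test_that("calibration freezes baselines near the filtrate envelope mean", {
  set.seed(3)
  cfg <- session_config(duration = 60)
  bg <- gen_background_lfp(cfg)
  ocfg <- online_config()
  frozen <- calibrate_baseline(bg, ocfg, settle = 60)
  # Monte-Carlo oracle: mean |filtrate| over the trace
  filt <- ripple_filter_design(ocfg$band, cfg$fs)
  xf <- causal_bandpass(bg, filt)$y
  m <- colMeans(abs(xf))
  expect_equal(frozen$mu, m, tolerance = 0.05)
  expect_true(all(frozen$sigma > 0))
  # determinism
  frozen2 <- calibrate_baseline(bg, ocfg, settle = 60)
  expect_identical(frozen, frozen2)
  # zero trace: degenerate, flagged
  z <- calibrate_baseline(matrix(0, 90000, 2), ocfg, settle = 60)
  expect_equal(z$mu, c(0, 0))
  expect_true(all(z$degenerate))
  expect_error(calibrate_baseline(bg[1:100, ], ocfg), "shorter")
})

test_that("coincidence trigger needs the configured tetrode count", {
  frozen <- list(mu = c(0, 0, 0), sigma = c(1, 1, 1))
  cfg <- online_config(threshold_sd = 4, min_coincident = 2)
  # drive envelopes directly with filtered samples
  states <- envelope_init(3, v = c(10, 0, 0))  # one tetrode above (thr 4)
  r <- step_detector(states, frozen, cfg, c(10, 0, 0))
  expect_false(r$triggered)
  states <- envelope_init(3, v = c(10, 10, 0))
  r <- step_detector(states, frozen, cfg, c(10, 10, 0))
  expect_true(r$triggered)
  # threshold -> infinity never triggers
  cfg_inf <- online_config(threshold_sd = 1e12)
  r <- step_detector(envelope_init(3, v = c(10, 10, 10)), frozen,
                     cfg_inf, c(10, 10, 10))
  expect_false(r$triggered)
  expect_error(step_detector(envelope_init(2), frozen, cfg, c(1, 1)),
               "mismatch")
})

test_that("streamed detection is bit-identical under arbitrary chunking", {
  set.seed(4)
  cfg <- session_config(duration = 10, n_tetrodes = 3)
  bg <- gen_background_lfp(cfg)
  calib <- injection_calib(bg, cfg$fs)
  inj <- inject_ripple(bg, 5, 12, 80, 200, fs = cfg$fs, calib = calib)
  ocfg <- online_config(threshold_sd = 3)
  frozen <- calibrate_baseline(gen_background_lfp(
    session_config(duration = 60, n_tetrodes = 3)), ocfg)
  whole <- run_stream(inj$traces, frozen, ocfg)
  for (chunks in list(c(3000, 12000), c(1, 7499, 5000, 2500),
                      rep(1500, 10))) {
    state <- NULL
    triggers <- numeric(0)
    off <- 0
    for (ck in chunks) {
      r <- run_stream(inj$traces[off + seq_len(ck), , drop = FALSE],
                      frozen, ocfg, state)
      triggers <- c(triggers, r$triggers)
      state <- r$state
      off <- off + ck
    }
    expect_identical(triggers, whole$triggers)
  }
  # flat traces: no triggers
  flat <- run_stream(matrix(0, 1000, 3), frozen, ocfg)
  expect_length(flat$triggers, 0)
})

test_that("raising the threshold never adds triggers, and a strong event
           triggers exactly once under a long lockout", {
  set.seed(5)
  cfg <- session_config(duration = 20, n_tetrodes = 2)
  bg <- gen_background_lfp(cfg)
  calib <- injection_calib(bg, cfg$fs)
  inj <- inject_ripple(bg, 10, 20, 80, 200, fs = cfg$fs, calib = calib)
  frozen <- calibrate_baseline(gen_background_lfp(
    session_config(duration = 60, n_tetrodes = 2)),
    online_config())
  # with no lockout, trigger samples are exactly the suprathreshold
  # coincidence samples: raising the threshold keeps a subset
  trig_sets <- lapply(c(1.5, 2, 2.5, 3), function(th) {
    ocfg <- online_config(threshold_sd = th, lockout_ms = 0)
    run_stream(inj$traces, frozen, ocfg)$triggers
  })
  for (i in 1:3) {
    expect_true(all(trig_sets[[i + 1]] %in% trig_sets[[i]]))
  }
  # a strong injected event with a lockout longer than the event
  # triggers exactly once near its center
  ocfg <- online_config(threshold_sd = 3, lockout_ms = 1000)
  tr <- run_stream(inj$traces, frozen, ocfg)$triggers
  near <- tr[abs(tr - 10) < 0.3]
  expect_length(near, 1)
})
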