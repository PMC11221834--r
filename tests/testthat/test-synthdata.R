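test_that("background generation is deterministic, sized, and handles
           the empty case", {
  cfg <- session_config(duration = 10, n_tetrodes = 3)
  set.seed(7)
  a <- gen_background_lfp(cfg)
  expect_equal(dim(a), c(15000, 3))
  set.seed(7)
  b <- gen_background_lfp(cfg)
  expect_identical(a, b)
  cfg0 <- session_config(duration = 0)
  expect_equal(nrow(gen_background_lfp(cfg0)), 0)
  expect_error(session_config(fs = 300), "fs")
})

test_that("ripple injection is calibrated, additive, and bounded", {
  bgf <- background_fixture()
  # amplitude 0 leaves the trace unchanged
  inj0 <- inject_ripple(bgf$bg, 30, 0, 80, 200, fs = bgf$cfg$fs,
                        calib = bgf$calib)
  expect_identical(inj0$traces, bgf$bg)
  # two disjoint injections are sample-wise additive, order-independent
  i1 <- inject_ripple(bgf$bg, 20, 6, 80, 200, fs = bgf$cfg$fs,
                      calib = bgf$calib)
  i12 <- inject_ripple(i1$traces, 40, 9, 60, 180, fs = bgf$cfg$fs,
                       calib = bgf$calib)
  i2 <- inject_ripple(bgf$bg, 40, 9, 60, 180, fs = bgf$cfg$fs,
                      calib = bgf$calib)
  i21 <- inject_ripple(i2$traces, 20, 6, 80, 200, fs = bgf$cfg$fs,
                       calib = bgf$calib)
  expect_equal(i12$traces, i21$traces, tolerance = 1e-12)
  delta <- i12$traces - bgf$bg - (i1$traces - bgf$bg) -
    (i2$traces - bgf$bg)
  expect_lt(max(abs(delta)), 1e-9)
  # out-of-bounds event
  expect_error(inject_ripple(bgf$bg, 59.99, 6, 80, 200,
                             fs = bgf$cfg$fs, calib = bgf$calib),
               "bounds")
})

test_that("injected amplitude and offline-measured size agree tightly", {
  bgf <- background_fixture(duration = 120, seed = 406)
  set.seed(60)
  amps <- seq(2, 20, length.out = 50)
  times <- seq(3, 117, length.out = 50)
  meas <- numeric(50)
  for (i in seq_along(amps)) {
    inj <- inject_ripple(bgf$bg, times[i], amps[i], 80, 200,
                         fs = bgf$cfg$fs, calib = bgf$calib)
    f <- bandpass_ripple(inj$traces[round((times[i] - 1.5) *
      1500):round((times[i] + 1.5) * 1500), ], fs = bgf$cfg$fs)
    cons_v <- sqrt(pmax(gaussian_smooth(rowSums(f^2), 6), 0))
    pk <- max(cons_v[(1.42 * 1500):(1.58 * 1500)])
    meas[i] <- (pk - bgf$calib$epoch_mean) / bgf$calib$epoch_sd
  }
  expect_gt(cor(amps, meas, method = "spearman"), 0.95)
})

test_that("state-dependent event times follow the configured rates and
           respect the minimum gap", {
  set.seed(61)
  iv <- data.frame(t0 = 0, t1 = 2000, state = "still_pre_reward")
  times <- gen_event_times(iv, c(still_pre_reward = 0.5), min_gap_ms = 100)
  # Poisson oracle: thinning by the 100 ms gap removes ~ rate*gap of
  # events; allow 3 SD around the thinned expectation
  expect_lt(abs(length(times) - 1000 * (1 - 0.5 * 0.1)), 3 * sqrt(1000))
  expect_true(all(diff(times) >= 0.1 - 1e-12))
  # zero rate -> empty
  expect_length(gen_event_times(iv, c(still_pre_reward = 0)), 0)
  expect_error(gen_event_times(iv, c(still_pre_reward = -1)), "negative")
})

test_that("event counts per state stay within Poisson 99% bands", {
  set.seed(62)
  iv <- data.frame(t0 = c(0, 600, 1200), t1 = c(600, 1200, 1800),
                   state = c("moving", "still_pre_reward", "rest"))
  rates <- c(moving = 0.02, still_pre_reward = 0.3, rest = 0.15)
  times <- gen_event_times(iv, rates, min_gap_ms = 100)
  for (i in 1:3) {
    n <- sum(times >= iv$t0[i] & times < iv$t1[i])
    lambda <- rates[[as.character(iv$state[i])]] * 600
    lambda_eff <- lambda * (1 - rates[[as.character(iv$state[i])]] * 0.1)
    expect_gte(n, qpois(0.005, lambda_eff))
    expect_lte(n, qpois(0.995, lambda))
  }
})

test_that("place models tile the track with separated marks", {
  set.seed(63)
  graph <- make_track_graph()
  m <- gen_place_model(30, graph, 4)
  expect_true(all(m$cells$center_bin >= 1 &
                    m$cells$center_bin <= nrow(graph$bins)))
  # mean nearest-center spacing ~ track length / n_cells
  pos <- sort(graph$bins$lin_pos[m$cells$center_bin])
  expect_equal(mean(diff(pos)), graph$total_length / 30,
               tolerance = 0.35)
  # marks pairwise separated (Mahalanobis w.r.t. isotropic cov)
  mm <- as.matrix(m$cells[, paste0("mark_mean", 1:4)])
  d <- as.matrix(dist(mm / m$mark_sd))
  expect_gte(min(d[upper.tri(d)]), 6 - 1e-9)
  # single cell
  m1 <- gen_place_model(1, graph, 4)
  expect_equal(nrow(m1$cells), 1)
  expect_error(gen_place_model(0, graph), "positive")
})

test_that("movement spiking matches Poisson tuning and mark statistics", {
  set.seed(64)
  graph <- make_track_graph()
  m <- gen_place_model(5, graph, 2)
  # park the animal at cell 1's field center for 10 s
  cb <- m$cells$center_bin[1]
  traj <- data.frame(t = seq(0, 10, by = 0.04), bin = cb,
                     speed = 10)
  m$cells$peak_rate <- 20
  spk <- gen_movement_spikes(traj, m, graph)
  n1 <- sum(spk$cell == 1)
  expect_lt(abs(n1 - 200), 3 * sqrt(200))
  # far cells stay silent: any cell >= 5 field widths away
  far <- which(graph$dist[cb, m$cells$center_bin] >=
                 5 * m$cells$field_width)
  expect_equal(sum(spk$cell %in% far), 0)
  # marks: sample mean of cell 1's marks within 3 SE of its mark mean
  mk <- as.matrix(spk[spk$cell == 1, paste0("m", 1:4)])
  mu <- as.numeric(m$cells[1, paste0("mark_mean", 1:4)])
  se <- m$mark_sd / sqrt(nrow(mk))
  expect_true(all(abs(colMeans(mk) - mu) < 3 * se))
})

test_that("replay spiking is time-compressed and order-reverses with
           the path", {
  set.seed(65)
  graph <- make_track_graph()
  m <- gen_place_model(30, graph, 4)
  arm_bins <- which(graph$bins$seg_id == 3)
  # long path (home -> center -> arm1) so many fields participate;
  # forward vs reversed paths flip the spike-time/field-position rank
  # correlation
  long_path <- c(which(graph$bins$seg_id == 1),
                 which(graph$bins$seg_id == 2), arm_bins)
  rs_f <- gen_replay_spikes(10, 100, long_path, m, graph)
  rs_r <- gen_replay_spikes(10, 100, rev(long_path), m, graph)
  rho <- function(rs) {
    cb <- m$cells$center_bin[rs$cell]
    cor(rs$t, graph$bins$lin_pos[cb], method = "spearman")
  }
  expect_gt(rho(rs_f), 0.5)
  expect_lt(rho(rs_r), -0.5)
  # single-bin path: only cells with fields near that bin fire
  rs1 <- gen_replay_spikes(10, 100, arm_bins[1], m, graph)
  if (nrow(rs1)) {
    d <- graph$dist[arm_bins[1], m$cells$center_bin[rs1$cell]]
    expect_true(all(d < 5 * m$cells$field_width[1]))
  }
  expect_error(gen_replay_spikes(10, 100, integer(0), m, graph),
               "empty")
})
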