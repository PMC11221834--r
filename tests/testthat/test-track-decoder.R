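test_that("track graph bins partition segments and adjacency is
           symmetric", {
  graph <- make_track_graph()
  expect_equal(nrow(graph$bins),
               sum(round(graph$segments$length / graph$bin_size)))
  for (i in seq_along(graph$adjacency)) {
    for (j in graph$adjacency[[i]]) {
      expect_true(i %in% graph$adjacency[[j]])
    }
  }
  # geodesic distance symmetric, zero diagonal
  expect_equal(graph$dist, t(graph$dist))
  expect_true(all(diag(graph$dist) == 0))
})

test_that("linearization projects onto the skeleton with documented
           tie-breaks", {
  graph <- make_track_graph()
  # a point exactly on arm 3, 10 cm from its junction end
  seg <- graph$segments[graph$segments$name == "arm3", ]
  u <- 10 / seg$length
  p <- c(seg$x0 + u * (seg$x1 - seg$x0), seg$y0 + u * (seg$y1 - seg$y0))
  lin <- linearize(matrix(p, 1), graph)
  expect_equal(lin$segment, "arm3")
  expect_equal(lin$along, 10, tolerance = 1e-9)
  expect_lt(lin$proj_error, 1e-9)
  # round trip: skeleton points map back with zero error
  set.seed(70)
  traj <- gen_trajectory(graph, 20)
  lin2 <- linearize(cbind(traj$x, traj$y), graph)
  expect_lt(max(lin2$proj_error), 1e-9)
  expect_true(all(lin2$bin == traj$bin))
  # equidistant point between home (segment 1) start side and nothing
  # else: far point flagged off-track
  lin3 <- linearize(matrix(c(500, 500), 1), graph)
  expect_true(lin3$off_track)
})

test_that("posterior columns are normalized and continuous mass stays
           local", {
  fx <- encoding_fixture()
  set.seed(71)
  arm_bins <- which(fx$graph$bins$seg_id == 4)
  rs <- gen_replay_spikes(50, 100, arm_bins, fx$model, fx$graph)
  g <- decode(rs, fx$enc, min(rs$t) - 0.004, max(rs$t) + 0.004)
  sums <- apply(g$post, 1, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # pure continuous state moves at most 1 bin per step
  kern <- movement_kernels(fx$graph)
  p0 <- numeric(nrow(fx$graph$bins))
  p0[arm_bins[5]] <- 1
  p1 <- as.numeric(p0 %*% kern$continuous)
  moved <- which(p1 > 0)
  expect_true(all(fx$graph$dist[arm_bins[5], moved] <=
                    fx$graph$bin_size))
})

test_that("forward-backward matches exhaustive path enumeration", {
  # small synthetic HMM instance on a 10-bin track, 3 time bins,
  # using the package's exact kernels and emissions
  graph <- make_track_graph(home_length = 25, center_length = 15,
                            arm_length = 5, bin_size = 5, n_arms = 2)
  expect_equal(nrow(graph$bins), 10)
  set.seed(72)
  traj <- gen_trajectory(graph, 60, run_speed = 10)
  model <- gen_place_model(6, graph, 2)
  spk <- gen_movement_spikes(traj, model, graph)
  enc <- fit_encoding(spk, traj, graph)
  rs <- gen_replay_spikes(30, 40, seq_len(5), model, graph,
                          compression = 5)
  t0 <- 30 - 0.003
  t1 <- 30 + 0.003
  g <- decode(rs, enc, t0, t1)
  expect_equal(length(g$t), 3)
  # brute force: enumerate all (state, bin) paths
  nb <- 10
  kern <- movement_kernels(graph)
  S <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2)
  Tj <- list(kern$continuous, kern$fragmented)
  edges <- seq(t0, t1, by = 0.002)
  spk_in <- rs[rs$t >= t0 & rs$t < t1, , drop = FALSE]
  kidx <- findInterval(spk_in$t, edges, rightmost.closed = TRUE)
  L <- matrix(1, 3, nb)
  base_ll <- -0.002 * Reduce(`+`, lapply(enc$tetrodes, `[[`, "ground"))
  for (k in 1:3) {
    ll <- base_ll
    sp <- spk_in[kidx == k, , drop = FALSE]
    if (nrow(sp)) ll <- ll + swrloop:::spike_loglik(enc, sp)
    L[k, ] <- exp(ll - max(ll))
  }
  joint <- array(0, c(3, nb, 2))
  for (s1 in 1:2) for (b1 in 1:nb) {
    for (s2 in 1:2) for (b2 in 1:nb) {
      for (s3 in 1:2) for (b3 in 1:nb) {
        w <- (1 / (2 * nb)) * L[1, b1] *
          S[s1, s2] * Tj[[s2]][b1, b2] * L[2, b2] *
          S[s2, s3] * Tj[[s3]][b2, b3] * L[3, b3]
        joint[1, b1, s1] <- joint[1, b1, s1] + w
        joint[2, b2, s2] <- joint[2, b2, s2] + w
        joint[3, b3, s3] <- joint[3, b3, s3] + w
      }
    }
  }
  total <- sum(joint[1, , ])
  for (k in 1:3) {
    expect_equal(g$post[k, , ], joint[k, , ] / total, tolerance = 1e-10)
  }
})

test_that("decoding recovers position from spikes of a single cell", {
  fx <- encoding_fixture()
  set.seed(73)
  # pick two far-separated cells; emit spikes only from cell A
  cells <- fx$model$cells
  d <- fx$graph$dist[cells$center_bin, cells$center_bin]
  pick <- which(d == max(d), arr.ind = TRUE)[1, ]
  a <- unname(pick[1])
  n <- 25
  tt <- seq(0.001, 0.049, length.out = n)
  mk <- matrix(rep(unname(as.numeric(cells[a, paste0("mark_mean",
                                                     1:4)])), n),
               n, 4, byrow = TRUE)
  dimnames(mk) <- NULL
  spk <- data.frame(t = tt, tetrode = cells$tetrode[a], cell = a,
                    m1 = mk[, 1], m2 = mk[, 2], m3 = mk[, 3],
                    m4 = mk[, 4])
  g <- decode(spk, fx$enc, 0, 0.05)
  marg <- apply(g$post, c(1, 2), sum)
  map_bin <- max.col(marg)
  err <- fx$graph$dist[cbind(map_bin, cells$center_bin[a])]
  expect_gte(mean(err <= 2 * fx$graph$bin_size), 0.9)
})

test_that("leave-one-spike-out decoding is accurate and collapses under
           mark-position shuffling", {
  fx <- encoding_fixture()
  loo <- decode_movement_loo(fx$spikes, fx$enc, fx$traj, t0 = 20,
                             t1 = 45)
  expect_lte(loo$median_error, 10)
  expect_false(loo$low_n)
  # removing the decoded spike lowers its own likelihood
  set.seed(74)
  sp1 <- fx$spikes[500, , drop = FALSE]
  te <- fx$enc$tetrodes[[as.character(sp1$tetrode)]]
  sp1$train_idx <- match(round(sp1$t, 9), round(te$t, 9))
  ll_with <- swrloop:::spike_loglik(fx$enc, sp1, loo = FALSE)
  ll_without <- swrloop:::spike_loglik(fx$enc, sp1, loo = TRUE)
  expect_true(all(ll_without <= ll_with + 1e-12))
  # shuffled mark-position pairing: error near the random-guess level
  set.seed(75)
  shuf <- fx$spikes
  shuf[, paste0("m", 1:4)] <-
    shuf[sample(nrow(shuf)), paste0("m", 1:4)]
  enc_shuf <- fit_encoding(shuf, fx$traj, fx$graph)
  loo_shuf <- decode_movement_loo(shuf, enc_shuf, fx$traj, t0 = 20,
                                  t1 = 35)
  # random-guess expectation: mean graph distance between two random
  # bins, a scale the shuffled decode should approach (>= half)
  rand_err <- mean(fx$graph$dist)
  expect_gt(loo_shuf$median_error, 0.4 * rand_err)
})

test_that("spike-free windows relax toward the transition stationary
           distribution while staying normalized", {
  fx <- encoding_fixture()
  empty <- fx$spikes[0, , drop = FALSE]
  g <- decode(empty, fx$enc, 0, 0.06)
  sums <- apply(g$post, 1, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # position marginal approaches near-uniformity mid-window
  marg <- apply(g$post, c(1, 2), sum)
  k <- nrow(marg) %/% 2
  expect_lt(max(marg[k, ]) / mean(marg[k, ]), 30)
})
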