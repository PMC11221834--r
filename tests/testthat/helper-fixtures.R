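# Shared fixtures, built once per test run. Sizes are kept small; the
# heavier end-to-end checks live in test-acceptance.R.

fixture_env <- new.env()

# encoding fixture: track, trajectory, place model, spikes, fitted model
encoding_fixture <- function(duration = 180, n_cells = 30, seed = 401) {
  key <- paste("enc", duration, n_cells, seed, sep = "_")
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  set.seed(seed)
  graph <- make_track_graph()
  traj <- gen_trajectory(graph, duration)
  model <- gen_place_model(n_cells, graph, 4)
  spikes <- gen_movement_spikes(traj, model, graph)
  enc <- fit_encoding(spikes, traj, graph)
  out <- list(graph = graph, traj = traj, model = model,
              spikes = spikes, enc = enc)
  fixture_env[[key]] <- out
  out
}

# clean background + its injection calibration
background_fixture <- function(duration = 60, seed = 402) {
  key <- paste("bg", duration, seed, sep = "_")
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  set.seed(seed)
  cfg <- session_config(duration = duration)
  bg <- gen_background_lfp(cfg)
  out <- list(cfg = cfg, bg = bg, calib = injection_calib(bg, cfg$fs))
  fixture_env[[key]] <- out
  out
}

# reference (plain-R) baseline recursion, used as the oracle for the
# compiled path
baseline_oracle <- function(x, mu0 = 0, sigma0 = 0, n = 10000) {
  mu <- mu0; sigma <- sigma0
  for (xi in abs(x)) {
    mu_prev <- mu
    mu <- mu_prev * (n - 1) / n + xi / n
    sigma <- (abs(xi - mu_prev) - sigma) / n + sigma
  }
  c(mu = mu, sigma = sigma)
}

# reference (plain-R) envelope recursion with explicit gain history
envelope_oracle <- function(x, v0, ghist = rep(0.2, 19)) {
  v <- v0
  for (xi in abs(x)) {
    if (xi <= v) g <- 0.2 else g <- mean(c(1.2, ghist))
    v <- v + g * (xi - v)
    ghist <- c(utils::tail(ghist, 18), g)
  }
  v
}
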