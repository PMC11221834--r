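#' Fit the clusterless encoding model
#'
#' Kernel-density joint mark-position intensity per tetrode, built only
#' from samples collected while the animal moved faster than the speed
#' cutoff. Position kernels use graph (geodesic) distance on the track;
#' mark kernels are product Gaussians over the four channel amplitudes.
#' The ground intensity is the spike density divided by occupancy.
#'
#' @param spikes data.frame with `t`, `tetrode`, `m1`..`m4`.
#' @param positions data.frame with `t`, `bin`, `speed` (the trajectory,
#'   regularly sampled).
#' @param graph a [make_track_graph()].
#' @param mark_bw mark kernel bandwidth, uV.
#' @param pos_bw position kernel bandwidth, cm.
#' @param speed_cutoff movement threshold, cm/s (samples at or below are
#'   excluded).
#' @return an `encoding_model` list.
#' @export
fit_encoding <- function(spikes, positions, graph, mark_bw = 20,
                         pos_bw = 5, speed_cutoff = 4) {
  moving <- positions$speed > speed_cutoff
  if (!any(moving)) stop("no movement samples above the speed cutoff")
  dt_pos <- stats::median(diff(positions$t))
  nb <- nrow(graph$bins)
  # occupancy density over bins (kernel-smoothed, in seconds)
  Kbin <- exp(-graph$dist^2 / (2 * pos_bw^2))
  occ_counts <- tabulate(positions$bin[moving], nb)
  occ_dens <- as.numeric(Kbin %*% occ_counts) * dt_pos
  occ_dens <- pmax(occ_dens, 1e-12)
  # spike position at spike time: nearest position sample
  sp_bin_all <- positions$bin[findInterval(spikes$t, positions$t,
                                           all.inside = TRUE)]
  sp_speed <- positions$speed[findInterval(spikes$t, positions$t,
                                           all.inside = TRUE)]
  enc <- spikes[sp_speed > speed_cutoff, , drop = FALSE]
  if (!nrow(enc)) stop("no spikes during movement")
  sp_bin <- sp_bin_all[sp_speed > speed_cutoff]
  tets <- sort(unique(enc$tetrode))
  per_tet <- lapply(tets, function(tt) {
    sel <- enc$tetrode == tt
    marks <- as.matrix(enc[sel, paste0("m", 1:4)])
    bins <- sp_bin[sel]
    kpos <- Kbin[bins, , drop = FALSE]          # n_spikes x n_bins
    ground <- colSums(kpos) / occ_dens          # spikes/s over bins
    list(tetrode = tt, marks = marks, bins = bins, kpos = kpos,
         ground = ground, t = enc$t[sel])
  })
  names(per_tet) <- as.character(tets)
  structure(list(tetrodes = per_tet, occ_dens = occ_dens,
                 mark_bw = mark_bw, pos_bw = pos_bw,
                 speed_cutoff = speed_cutoff, n_bins = nb,
                 graph = graph),
            class = "encoding_model")
}

# Gaussian product mark kernel between one mark vector and a matrix of
# training marks (rows), bandwidth bw per channel.
mark_kernel <- function(m, marks, bw) {
  d2 <- (marks[, 1] - m[1])^2 + (marks[, 2] - m[2])^2 +
    (marks[, 3] - m[3])^2 + (marks[, 4] - m[4])^2
  exp(-d2 / (2 * bw^2)) / (2 * pi * bw^2)^2
}

# log-likelihood contribution of one set of spikes over position bins
# (added to the no-spike base); each spike's own training contribution
# can be removed via its `train_idx` (leave-one-spike-out).
spike_loglik <- function(model, spk, floor = 1e-10, loo = FALSE) {
  ll <- 0
  for (i in seq_len(nrow(spk))) {
    te <- model$tetrodes[[as.character(spk$tetrode[i])]]
    if (is.null(te)) next
    m <- as.numeric(spk[i, paste0("m", 1:4)])
    w <- mark_kernel(m, te$marks, model$mark_bw)
    if (loo && !is.na(spk$train_idx[i])) {
      w[spk$train_idx[i]] <- 0
    }
    joint <- as.numeric(w %*% te$kpos) / model$occ_dens
    ll <- ll + log(joint + floor)
  }
  ll
}

#' Movement-state transition kernels
#'
#' Continuous state: equal probability over the current bin and its
#' graph neighbors (junction bins include all their neighbors).
#' Fragmented state: equal probability over all other bins.
#'
#' @param graph a [make_track_graph()].
#' @return list with matrices `continuous` and `fragmented` (row =
#'   source bin).
#' @export
movement_kernels <- function(graph) {
  nb <- nrow(graph$bins)
  Tc <- matrix(0, nb, nb)
  for (i in seq_len(nb)) {
    tgt <- c(i, graph$adjacency[[i]])
    Tc[i, tgt] <- 1 / length(tgt)
  }
  Tf <- matrix(1 / (nb - 1), nb, nb)
  diag(Tf) <- 0
  list(continuous = Tc, fragmented = Tf)
}

#' Decode position and movement state from marked spikes
#'
#' Poisson marked-point-process likelihood in 2 ms bins over position,
#' combined with a two-state (continuous/fragmented) state-space model
#' by HMM forward filtering and backward smoothing. The discrete state
#' matrix is diagonally dominant by default (stay 0.98) so sustained-
#' state classification is meaningful; `state_stay = 0.5` gives the
#' uniform alternative.
#'
#' @param spikes data.frame with `t`, `tetrode`, `m1`..`m4` (optionally
#'   `train_idx` for leave-one-out).
#' @param model an [fit_encoding()] model.
#' @param t0,t1 decoding window, s.
#' @param dt time bin, s (default 0.002).
#' @param state_stay diagonal of the 2x2 discrete state matrix.
#' @param smooth if `FALSE`, return the causal (filtered) posterior.
#' @param loo remove each spike's own contribution from the encoding
#'   kernel sums (requires `train_idx`).
#' @param floor small uniform intensity floor.
#' @return a `posterior_grid` list: `post` (time x bins x 2 array,
#'   normalized per time bin), `t` (bin centers), plus bookkeeping.
#' @export
decode <- function(spikes, model, t0, t1, dt = 0.002, state_stay = 0.98,
                   smooth = TRUE, loo = FALSE, floor = 1e-10) {
  nb <- model$n_bins
  edges <- seq(t0, t1, by = dt)
  if (length(edges) < 2) stop("window shorter than one time bin")
  nt <- length(edges) - 1
  keep <- spikes$t >= t0 & spikes$t < edges[nt + 1]
  spk <- spikes[keep, , drop = FALSE]
  spk_bin <- if (nrow(spk)) findInterval(spk$t, edges,
                                         rightmost.closed = TRUE) else
    integer(0)
  kern <- movement_kernels(model$graph)
  S <- matrix(c(state_stay, 1 - state_stay,
                1 - state_stay, state_stay), 2, 2, byrow = TRUE)
  # emission likelihoods (time x bins), shared by the two states
  base_ll <- -dt * Reduce(`+`, lapply(model$tetrodes, `[[`, "ground"))
  L <- matrix(exp(base_ll - max(base_ll)), nt, nb, byrow = TRUE)
  for (k in unique(spk_bin)) {
    ll <- base_ll + spike_loglik(model, spk[spk_bin == k, , drop = FALSE],
                                 floor = floor, loo = loo)
    L[k, ] <- exp(ll - max(ll))
  }
  predict_step <- function(p) {
    # p: 2 x nb (rows: continuous, fragmented), returns predicted p
    mixed <- t(S) %*% p                 # state mixing
    rbind(as.numeric(mixed[1, ] %*% kern$continuous),
          as.numeric(mixed[2, ] %*% kern$fragmented))
  }
  alpha <- array(0, c(nt, 2, nb))
  p <- matrix(1 / (2 * nb), 2, nb)
  for (k in seq_len(nt)) {
    pred <- if (k == 1) p else predict_step(p)
    up <- sweep(pred, 2, L[k, ], `*`)
    up <- up / sum(up)
    alpha[k, , ] <- up
    p <- up
  }
  post <- alpha
  if (smooth && nt > 1) {
    beta <- matrix(1, 2, nb)
    for (k in (nt - 1):1) {
      lb <- sweep(beta, 2, L[k + 1, ], `*`)
      nxt <- rbind(as.numeric(kern$continuous %*% lb[1, ]),
                   as.numeric(kern$fragmented %*% lb[2, ]))
      beta <- S %*% nxt
      beta <- beta / max(beta)
      sm <- alpha[k, , ] * beta
      post[k, , ] <- sm / sum(sm)
    }
  }
  structure(list(post = aperm(post, c(1, 3, 2)),
                 t = (edges[-1] + edges[-(nt + 1)]) / 2,
                 dt = dt, n_spikes = nrow(spk),
                 states = c("continuous", "fragmented")),
            class = "posterior_grid")
}

#' Leave-one-spike-out movement decoding error
#'
#' Decodes a movement interval with each spike's own contribution
#' removed from the encoding model, and reports the distribution of
#' graph-distance errors between the MAP position and the true position
#' at spike-containing time bins.
#'
#' @param spikes encoding spikes (`t`, `tetrode`, `m1`..`m4`).
#' @param model an [fit_encoding()] model fitted from `spikes`.
#' @param positions the trajectory data.frame (`t`, `bin`, `speed`).
#' @param t0,t1 window to decode (defaults: full trajectory range).
#' @param dt time bin, s.
#' @return list with `errors` (cm, one per evaluated time bin),
#'   `median_error`, `n_spikes`, `low_n` flag.
#' @export
decode_movement_loo <- function(spikes, model, positions,
                                t0 = min(positions$t),
                                t1 = max(positions$t), dt = 0.002) {
  # map each decoded spike to its row in the tetrode training set
  spikes$train_idx <- NA_integer_
  for (tt in names(model$tetrodes)) {
    te <- model$tetrodes[[tt]]
    sel <- which(spikes$tetrode == as.integer(tt))
    idx <- match(round(spikes$t[sel], 9), round(te$t, 9))
    spikes$train_idx[sel] <- idx
  }
  g <- decode(spikes, model, t0, t1, dt = dt, loo = TRUE)
  marg <- apply(g$post, c(1, 2), sum)    # time x bins
  map_bin <- max.col(marg)
  pos_idx <- findInterval(g$t, positions$t, all.inside = TRUE)
  true_bin <- positions$bin[pos_idx]
  moving <- positions$speed[pos_idx] > model$speed_cutoff
  has_spike <- tabulate(findInterval(
    spikes$t[spikes$t >= t0 & spikes$t <= t1],
    seq(t0, t1, by = dt), rightmost.closed = TRUE), length(g$t)) > 0
  eval_bins <- which(moving & has_spike)
  errors <- model$graph$dist[cbind(map_bin[eval_bins],
                                   true_bin[eval_bins])]
  n_spk <- sum(!is.na(spikes$train_idx))
  list(errors = errors, median_error = stats::median(errors),
       n_spikes = n_spk, low_n = n_spk < 100)
}
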