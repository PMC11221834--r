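#' Generate a ground-truth place-cell encoding model
#'
#' Field centers tile the 1-D track (even spacing over bins with jitter
#' at most half a spacing), each cell has Gaussian positional tuning and
#' a 4-D Gaussian mark distribution. Mark means are redrawn until all
#' pairs are separated by at least `min_mark_sep` Mahalanobis units so
#' clusterless decoding is feasible. Cells are assigned to tetrodes
#' round-robin.
#'
#' @param n_cells number of place cells.
#' @param graph a [make_track_graph()].
#' @param n_tetrodes tetrode count.
#' @param field_width Gaussian tuning SD, cm.
#' @param peak_rate_range in-field peak rate range, spikes/s.
#' @param mark_mean_range range of mark means per channel, uV.
#' @param mark_sd mark SD per channel, uV (isotropic covariance).
#' @param min_mark_sep minimum pairwise Mahalanobis distance of mark
#'   means.
#' @return a `place_model` list with `cells` (data.frame) and `mark_cov`.
#' @export
gen_place_model <- function(n_cells, graph, n_tetrodes = 4,
                            field_width = 8,
                            peak_rate_range = c(15, 25),
                            mark_mean_range = c(100, 350),
                            mark_sd = 20, min_mark_sep = 6) {
  if (n_cells <= 0) stop("n_cells must be positive")
  nb <- nrow(graph$bins)
  centers_lin <- (seq_len(n_cells) - 0.5) / n_cells * nb
  center_bin <- pmax(1L, pmin(nb, round(centers_lin)))
  jit <- round(stats::runif(n_cells, -0.4, 0.4) * nb / n_cells)
  center_bin <- pmax(1L, pmin(nb, center_bin + jit))
  # mark means on a randomized lattice whose spacing guarantees the
  # minimum Mahalanobis separation (rejection sampling is hopeless in
  # 4-D at realistic cell counts)
  spacing <- min_mark_sep * mark_sd
  levels <- seq(mark_mean_range[1], by = spacing,
                length.out = max(2, ceiling(diff(mark_mean_range) /
                                              spacing) + 1))
  n_grid <- length(levels)^4
  while (n_grid < n_cells) {
    levels <- c(levels, levels[length(levels)] + spacing)
    n_grid <- length(levels)^4
  }
  pick <- sample.int(n_grid, n_cells)
  L <- length(levels)
  mm <- cbind(levels[(pick - 1) %% L + 1],
              levels[((pick - 1) %/% L) %% L + 1],
              levels[((pick - 1) %/% L^2) %% L + 1],
              levels[((pick - 1) %/% L^3) %% L + 1])
  cells <- data.frame(
    cell = seq_len(n_cells),
    tetrode = ((seq_len(n_cells) - 1) %% n_tetrodes) + 1L,
    center_bin = center_bin,
    field_width = field_width,
    peak_rate = stats::runif(n_cells, peak_rate_range[1],
                             peak_rate_range[2]))
  cells <- cbind(cells, stats::setNames(as.data.frame(mm),
                                        paste0("mark_mean", 1:4)))
  structure(list(cells = cells, mark_cov = diag(mark_sd^2, 4),
                 mark_sd = mark_sd, n_tetrodes = n_tetrodes),
            class = "place_model")
}

#' Generate a movement trajectory on the track
#'
#' The simulated animal makes journeys between randomly chosen segment
#' endpoints along graph geodesics at approximately `run_speed`, with
#' brief dwells between journeys. Sampled at `fs_pos`.
#'
#' @param graph a [make_track_graph()].
#' @param duration trajectory length, s.
#' @param fs_pos position sampling rate, Hz (>= 25).
#' @param run_speed mean running speed, cm/s.
#' @param dwell_range pause duration range between journeys, s.
#' @return data.frame: `t`, `bin`, `x`, `y`, `lin_pos`, `segment`,
#'   `speed` (graph speed, cm/s).
#' @export
gen_trajectory <- function(graph, duration, fs_pos = 25, run_speed = 20,
                           dwell_range = c(0.5, 2)) {
  stopifnot(fs_pos >= 25)
  dt <- 1 / fs_pos
  n <- ceiling(duration * fs_pos)
  endpoints <- c(1L, sapply(3:(2 + graph$n_arms), function(s) {
    max(which(graph$bins$seg_id == s))
  }))
  path_to <- function(from, to) {
    # BFS shortest bin path
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
  bins <- integer(n)
  i <- 1
  cur <- endpoints[1]
  queue <- integer(0)   # shuffled endpoint blocks -> even arm coverage
  while (i <= n) {
    if (!length(queue)) queue <- sample(endpoints)
    queue <- setdiff(queue, cur)
    if (!length(queue)) queue <- sample(setdiff(endpoints, cur))
    target <- queue[1]
    queue <- queue[-1]
    path <- path_to(cur, target)
    per_bin <- max(1L, round(graph$bin_size / run_speed / dt))
    run <- rep(path, each = per_bin)
    take <- min(length(run), n - i + 1)
    bins[i:(i + take - 1)] <- run[seq_len(take)]
    i <- i + take
    cur <- target
    dwell <- round(stats::runif(1, dwell_range[1], dwell_range[2]) / dt)
    if (i <= n && dwell > 0) {
      take <- min(dwell, n - i + 1)
      bins[i:(i + take - 1)] <- cur
      i <- i + take
    }
  }
  b <- graph$bins[bins, ]
  step_cm <- c(0, graph$dist[cbind(bins[-n], bins[-1])])
  speed <- gaussian_smooth(step_cm / dt, 0.25 * fs_pos)
  data.frame(t = (seq_len(n) - 1) * dt, bin = bins, x = b$x, y = b$y,
             lin_pos = b$lin_pos, segment = as.character(b$segment),
             speed = speed)
}

# spike marks for a set of cells: mark_mean + isotropic Gaussian noise
draw_marks <- function(model, cell_idx) {
  mm <- as.matrix(model$cells[cell_idx, paste0("mark_mean", 1:4)])
  mm + matrix(stats::rnorm(length(cell_idx) * 4, 0, model$mark_sd),
              ncol = 4)
}

#' Generate place-field spiking along a trajectory
#'
#' Each cell fires as an inhomogeneous Poisson process with Gaussian
#' tuning in graph distance around its field center; marks are drawn
#' from the cell's 4-D mark distribution and spikes are assigned to the
#' cell's tetrode.
#'
#' @param trajectory a [gen_trajectory()] data.frame (sampled >= 25 Hz).
#' @param model a [gen_place_model()].
#' @param graph a [make_track_graph()].
#' @return data.frame: `t`, `tetrode`, `cell`, `m1`..`m4`.
#' @export
gen_movement_spikes <- function(trajectory, model, graph) {
  dt <- stats::median(diff(trajectory$t))
  if (1 / dt < 25 - 1e-9) stop("trajectory sampled below 25 Hz")
  out <- list()
  for (ci in seq_len(nrow(model$cells))) {
    cell <- model$cells[ci, ]
    d <- graph$dist[cell$center_bin, trajectory$bin]
    rate <- cell$peak_rate * exp(-d^2 / (2 * cell$field_width^2))
    k <- stats::rpois(length(rate), rate * dt)
    idx <- rep(seq_along(k), k)
    if (!length(idx)) next
    t_sp <- trajectory$t[idx] + stats::runif(length(idx), 0, dt)
    out[[length(out) + 1]] <- data.frame(
      t = t_sp, tetrode = cell$tetrode, cell = cell$cell,
      stats::setNames(as.data.frame(draw_marks(model,
                                               rep(ci, length(idx)))),
                      paste0("m", 1:4)))
  }
  if (!length(out)) {
    return(data.frame(t = numeric(0), tetrode = integer(0),
                      cell = integer(0), m1 = numeric(0), m2 = numeric(0),
                      m3 = numeric(0), m4 = numeric(0)))
  }
  sp <- do.call(rbind, out)
  sp[order(sp$t), , drop = FALSE]
}

#' Generate time-compressed replay spiking for one SWR
#'
#' Spikes are drawn as if the animal traversed `path` (ordered bins,
#' connected on the graph) at `compression` times the typical run speed,
#' within the event window. Poisson rates are the place-field tuning
#' curves scaled by `compression`, preserving spikes-per-distance.
#'
#' @param t_center event center time, s.
#' @param duration_ms event duration, ms.
#' @param path ordered vector of bin indices.
#' @param model a [gen_place_model()].
#' @param graph a [make_track_graph()].
#' @param compression replay speed-up factor.
#' @param run_speed typical run speed, cm/s.
#' @param dt_virtual virtual time step for rate evaluation, s.
#' @return data.frame like [gen_movement_spikes()].
#' @export
gen_replay_spikes <- function(t_center, duration_ms, path, model, graph,
                              compression = 20, run_speed = 20,
                              dt_virtual = 0.001) {
  if (!length(path)) stop("empty replay path")
  v <- compression * run_speed
  # position along the path as a function of time within the event
  path_cm <- c(0, cumsum(graph$dist[cbind(path[-length(path)],
                                          path[-1])]))
  span <- max(path_cm)
  dur_needed <- if (span > 0) span / v else duration_ms / 1000
  t0 <- t_center - dur_needed / 2
  tt <- seq(0, dur_needed, by = dt_virtual)
  pos_cm <- pmin(span, v * tt)
  pos_bin <- path[findInterval(pos_cm, path_cm, rightmost.closed = TRUE)]
  out <- list()
  for (ci in seq_len(nrow(model$cells))) {
    cell <- model$cells[ci, ]
    d <- graph$dist[cell$center_bin, pos_bin]
    rate <- compression * cell$peak_rate *
      exp(-d^2 / (2 * cell$field_width^2))
    k <- stats::rpois(length(rate), rate * dt_virtual)
    idx <- rep(seq_along(k), k)
    if (!length(idx)) next
    t_sp <- t0 + tt[idx] + stats::runif(length(idx), 0, dt_virtual)
    out[[length(out) + 1]] <- data.frame(
      t = t_sp, tetrode = cell$tetrode, cell = cell$cell,
      stats::setNames(as.data.frame(draw_marks(model,
                                               rep(ci, length(idx)))),
                      paste0("m", 1:4)))
  }
  if (!length(out)) {
    return(data.frame(t = numeric(0), tetrode = integer(0),
                      cell = integer(0), m1 = numeric(0), m2 = numeric(0),
                      m3 = numeric(0), m4 = numeric(0)))
  }
  sp <- do.call(rbind, out)
  sp[order(sp$t), , drop = FALSE]
}
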