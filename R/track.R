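#' Build the 8-arm maze track graph
#'
#' A linearized skeleton of the task maze: a home segment, a central
#' segment, and eight arms fanning out from the central junction. The 2-D
#' central area collapses onto a single line from the home well to the
#' arm junction; each segment is divided into ordered 1-D bins.
#'
#' @param home_length,center_length,arm_length segment lengths, cm.
#' @param bin_size linear bin size, cm (default 5).
#' @param n_arms number of arms.
#' @return a `track_graph` list: `segments` (data.frame: id, name, length,
#'   x0, y0, x1, y1), `bins` (data.frame: bin, segment, along, lin_pos,
#'   x, y), `adjacency` (list of neighbor bin indices), `dist` (bin-to-bin
#'   graph distance matrix, cm), `bin_size`.
#' @export
make_track_graph <- function(home_length = 60, center_length = 30,
                             arm_length = 80, bin_size = 5, n_arms = 8) {
  stopifnot(bin_size > 0, n_arms >= 1)
  junction <- c(0, center_length)
  segs <- data.frame(
    id = seq_len(2 + n_arms),
    name = c("home", "center", paste0("arm", seq_len(n_arms))),
    length = c(home_length, center_length, rep(arm_length, n_arms)))
  ang <- pi * (0.125 + 0.75 * (seq_len(n_arms) - 1) / (n_arms - 1))
  segs$x0 <- c(0, 0, rep(junction[1], n_arms))
  segs$y0 <- c(-home_length, 0, rep(junction[2], n_arms))
  segs$x1 <- c(0, junction[1], junction[1] + arm_length * cos(ang))
  segs$y1 <- c(0, junction[2], junction[2] + arm_length * sin(ang))

  bins <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    nb <- max(1L, round(segs$length[i] / bin_size))
    along <- (seq_len(nb) - 0.5) * segs$length[i] / nb
    u <- along / segs$length[i]
    data.frame(segment = segs$name[i], seg_id = i, along = along,
               x = segs$x0[i] + u * (segs$x1[i] - segs$x0[i]),
               y = segs$y0[i] + u * (segs$y1[i] - segs$y0[i]))
  }))
  bins$bin <- seq_len(nrow(bins))
  offs <- c(0, cumsum(segs$length))
  bins$lin_pos <- offs[bins$seg_id] + bins$along

  nb_per_seg <- tapply(bins$bin, bins$seg_id, range)
  adjacency <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins) - 1)) {
    if (bins$seg_id[i] == bins$seg_id[i + 1]) {
      adjacency[[i]] <- c(adjacency[[i]], i + 1L)
      adjacency[[i + 1]] <- c(adjacency[[i + 1]], i)
    }
  }
  link <- function(a, b) {
    adjacency[[a]] <<- c(adjacency[[a]], b)
    adjacency[[b]] <<- c(adjacency[[b]], a)
  }
  home_end <- nb_per_seg[[1]][2]
  center_first <- nb_per_seg[[2]][1]
  center_last <- nb_per_seg[[2]][2]
  link(home_end, center_first)
  for (a in seq_len(n_arms)) link(center_last, nb_per_seg[[2 + a]][1])

  # bin-to-bin geodesic distances (BFS on the uniform-bin lattice)
  n <- nrow(bins)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adjacency[[v]]) {
          if (d[w] > d[v] + 1) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- d * bin_size
  }
  structure(list(segments = segs, bins = bins, adjacency = adjacency,
                 dist = D, bin_size = bin_size, n_arms = n_arms,
                 total_length = sum(segs$length)),
            class = "track_graph")
}

#' Project 2-D positions onto the track skeleton
#'
#' Each sample is projected onto the nearest point of the nearest
#' segment; ties go to the lower-indexed segment. Samples farther than
#' `gate` from every segment are flagged off-track.
#'
#' @param xy numeric matrix or data.frame with columns x, y (cm).
#' @param graph a [make_track_graph()].
#' @param gate off-track gate, cm.
#' @return data.frame: `segment`, `seg_id`, `along` (cm from segment
#'   start), `lin_pos`, `bin`, `proj_error` (perpendicular distance, cm),
#'   `off_track`.
#' @export
linearize <- function(xy, graph, gate = 20) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  segs <- graph$segments
  n <- nrow(xy)
  best_d <- rep(Inf, n)
  best_seg <- integer(n)
  best_along <- numeric(n)
  for (i in seq_len(nrow(segs))) {
    p0 <- c(segs$x0[i], segs$y0[i])
    dvec <- c(segs$x1[i] - p0[1], segs$y1[i] - p0[2])
    len2 <- sum(dvec^2)
    t_par <- ((xy[, 1] - p0[1]) * dvec[1] + (xy[, 2] - p0[2]) * dvec[2]) /
      len2
    t_par <- pmin(1, pmax(0, t_par))
    px <- p0[1] + t_par * dvec[1]
    py <- p0[2] + t_par * dvec[2]
    d <- sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
    upd <- d < best_d - 1e-12    # strict: ties keep the lower segment id
    best_d[upd] <- d[upd]
    best_seg[upd] <- i
    best_along[upd] <- t_par[upd] * segs$length[i]
  }
  offs <- c(0, cumsum(segs$length))
  lin <- offs[best_seg] + best_along
  bin <- bin_at(graph, best_seg, best_along)
  data.frame(segment = segs$name[best_seg], seg_id = best_seg,
             along = best_along, lin_pos = lin, bin = bin,
             proj_error = best_d, off_track = best_d > gate)
}

# bin index for (segment id, distance along segment)
bin_at <- function(graph, seg_id, along) {
  out <- integer(length(seg_id))
  for (i in seq_along(seg_id)) {
    cand <- which(graph$bins$seg_id == seg_id[i])
    out[i] <- cand[which.min(abs(graph$bins$along[cand] - along[i]))]
  }
  out
}

#' Segment id of each bin
#' @param graph a [make_track_graph()].
#' @export
bin_segments <- function(graph) as.character(graph$bins$segment)
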