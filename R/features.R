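#' Canonical feature names
#'
#' The 27 per-agent summary observables, in the fixed column order used by
#' [build_feature_matrix()]: for each neighbour rank 1-3 the mean and
#' variance of aheadness, mean and variance of leftness, mean distance and
#' mean adjacent angle (18 columns); mean and variance of the k-step angle
#' difference for k in 1, 5, 10, 20 (8 columns); and the mean 20-step travel
#' distance (1 column).
#'
#' @return character vector of length 27.
#' @export
feature_names <- function() {
  nn <- unlist(lapply(1:3, function(j) {
    sprintf(c("aheadness_nn%d_mean", "aheadness_nn%d_var",
              "leftness_nn%d_mean", "leftness_nn%d_var",
              "distance_nn%d_mean", "adjacent_angle_nn%d_mean"), j)
  }))
  ks <- unlist(lapply(c(1, 5, 10, 20), function(k) {
    sprintf(c("angle_diff_k%d_mean", "angle_diff_k%d_var"), k)
  }))
  c(nn, ks, "travel_dist_k20_mean")
}

# per-frame observable streams from which the 27 summaries derive
.stream_names <- function() {
  c(t(outer(c("h", "l", "d", "g"), 1:3, paste0)),
    paste0("a", c(1, 5, 10, 20)), "s20")
}

#' Signed ahead/behind offset of a neighbour
#'
#' Projection of the displacement to a neighbour onto the focal agent's
#' heading: positive when the neighbour is ahead, negative behind.
#'
#' @param c_i,c_j positions (length-2 numeric) of the focal agent and the
#'   neighbour, in metres.
#' @param v_i focal agent's heading vector (non-zero).
#' @return metres.
#' @export
aheadness <- function(c_i, v_i, c_j) {
  nv <- vec_norm(v_i)
  if (nv == 0) stop("zero heading vector", call. = FALSE)
  sum((c_j - c_i) * v_i) / nv
}

#' Signed left/right offset of a neighbour
#'
#' Projection of the displacement to a neighbour onto the focal agent's
#' heading rotated 90 degrees counter-clockwise (in a right-handed x-y
#' frame): positive when the neighbour is to the agent's left.
#'
#' @inheritParams aheadness
#' @return metres.
#' @export
leftness <- function(c_i, v_i, c_j) {
  nv <- vec_norm(v_i)
  if (nv == 0) stop("zero heading vector", call. = FALSE)
  d <- c_j - c_i
  (d[1L] * (-v_i[2L]) + d[2L] * v_i[1L]) / nv
}

#' Angle between two heading vectors
#'
#' @param v_i,v_j non-zero heading vectors.
#' @return radians in \[0, pi\].
#' @export
adjacent_angle <- function(v_i, v_j) {
  ni <- vec_norm(v_i); nj <- vec_norm(v_j)
  if (ni == 0 || nj == 0) stop("zero heading vector", call. = FALSE)
  acos(clamp_cos(sum(v_i * v_j) / (ni * nj)))
}

# one agent's records, sorted by frame, with headings present
agent_records <- function(table, run_id, agent_id, require_directions = FALSE) {
  rows <- table$run_id == run_id & table$agent_id == agent_id
  if (!any(rows)) {
    stop(sprintf("agent '%s' not found in run '%s'", agent_id, run_id),
         call. = FALSE)
  }
  tr <- as.data.frame(table)[rows, , drop = FALSE]
  tr <- tr[order(tr$frame), , drop = FALSE]
  if (require_directions && !all(c("dx", "dy") %in% names(tr))) {
    stop("directions absent; run derive_directions() first", call. = FALSE)
  }
  tr
}

#' Turning measure: angle between headings k frames apart
#'
#' @param traj one agent's records (a data frame with `frame`, `dx`, `dy`),
#'   e.g. a single-agent subset of a [trajectory_table()].
#' @param frame frame at which to evaluate.
#' @param k lag in frames.
#' @return radians, or `NA` when `frame - k` precedes the trajectory.
#' @export
angle_difference <- function(traj, frame, k) {
  i1 <- match(frame, traj$frame)
  i0 <- match(frame - k, traj$frame)
  if (is.na(i1)) stop("frame not in trajectory", call. = FALSE)
  if (is.na(i0)) return(NA_real_)
  adjacent_angle(c(traj$dx[i1], traj$dy[i1]), c(traj$dx[i0], traj$dy[i0]))
}

#' Path length travelled over the last k frames
#'
#' Sum of per-frame step lengths (path length, not net displacement).
#'
#' @param traj one agent's records (a data frame with `frame`, `x`, `y`).
#' @param frame frame at which to evaluate.
#' @param k window length in frames (default 20).
#' @return metres, or `NA` when `frame - k` precedes the trajectory.
#' @export
travel_distance <- function(traj, frame, k = 20) {
  i1 <- match(frame, traj$frame)
  i0 <- match(frame - k, traj$frame)
  if (is.na(i1)) stop("frame not in trajectory", call. = FALSE)
  if (is.na(i0)) return(NA_real_)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  if (i1 == i0) 0 else sum(steps[i0:(i1 - 1L)])
}

#' Three nearest co-present neighbours of an agent at a frame
#'
#' Neighbours are drawn from agents present at the same frame of the same
#' run, excluding the focal agent, ordered by ascending Euclidean distance
#' with ties broken by agent id (ascending). Missing ranks (fewer than three
#' co-present agents) are `NA`.
#'
#' @param table a [trajectory_table()].
#' @param run_id,agent_id,frame identify the focal agent-frame.
#' @return character vector of length 3 (`NA` for absent ranks).
#' @export
nearest_neighbours <- function(table, run_id, agent_id, frame) {
  rows <- table$run_id == run_id & table$frame == frame
  ids <- table$agent_id[rows]
  if (!agent_id %in% ids) {
    stop(sprintf("agent '%s' not present at frame %d of run '%s'",
                 agent_id, frame, run_id), call. = FALSE)
  }
  xs <- table$x[rows]; ys <- table$y[rows]
  self <- which(ids == agent_id)
  others <- which(ids != agent_id)
  out <- rep(NA_character_, 3L)
  if (length(others) > 0L) {
    d <- sqrt((xs[others] - xs[self])^2 + (ys[others] - ys[self])^2)
    ord <- others[order(d, ids[others])]
    n <- min(3L, length(ord))
    out[seq_len(n)] <- ids[ord[seq_len(n)]]
  }
  out
}

#' Per-frame observables for one agent
#'
#' Returns the defined/undefined pattern of every per-frame observable the
#' 27 summaries are built from: neighbour-rank aheadness (`h1`-`h3`),
#' leftness (`l1`-`l3`), distance (`d1`-`d3`) and adjacent angle
#' (`g1`-`g3`); k-step angle differences (`a1`, `a5`, `a10`, `a20`); and the
#' 20-step travel distance (`s20`). Undefined entries (missing neighbour
#' rank, or fewer than k preceding frames) are `NA`. Mainly useful for
#' inspecting why an agent was summarised the way it was;
#' [build_feature_matrix()] computes the same quantities in bulk.
#'
#' @inheritParams nearest_neighbours
#' @return data frame with one row per frame of the agent.
#' @export
per_frame_features <- function(table, run_id, agent_id) {
  if (!all(c("dx", "dy") %in% names(table))) {
    table <- derive_directions(table)
  }
  tr <- agent_records(table, run_id, agent_id, require_directions = TRUE)
  frames <- tr$frame
  n <- length(frames)
  out <- as.data.frame(matrix(NA_real_, n, 17L,
                              dimnames = list(NULL, .stream_names())))
  out <- cbind(frame = frames, out)
  for (i in seq_len(n)) {
    f <- frames[i]
    ci <- c(tr$x[i], tr$y[i]); vi <- c(tr$dx[i], tr$dy[i])
    nn <- nearest_neighbours(table, run_id, agent_id, f)
    for (j in 1:3) {
      if (is.na(nn[j])) next
      rowj <- which(table$run_id == run_id & table$frame == f &
                      table$agent_id == nn[j])
      cj <- c(table$x[rowj], table$y[rowj])
      vj <- c(table$dx[rowj], table$dy[rowj])
      out[[paste0("h", j)]][i] <- aheadness(ci, vi, cj)
      out[[paste0("l", j)]][i] <- leftness(ci, vi, cj)
      out[[paste0("d", j)]][i] <- vec_norm(cj - ci)
      out[[paste0("g", j)]][i] <- adjacent_angle(vi, vj)
    }
    for (k in c(1, 5, 10, 20)) {
      out[[paste0("a", k)]][i] <- angle_difference(tr, f, k)
    }
    out$s20[i] <- travel_distance(tr, f, k = 20)
  }
  out
}

#' Summarise one agent's per-frame observables into a feature row
#'
#' Means and variances are taken over each observable's defined frames only;
#' variances use the population convention (divide by the count of defined
#' frames). An observable with no defined frame at all makes the agent
#' unsummarisable and raises an error naming it.
#'
#' @param pff per-frame observables from [per_frame_features()].
#' @return named numeric vector of length 27 in [feature_names()] order.
#' @export
summarise_features <- function(pff) {
  streams <- .stream_names()
  counts <- vapply(streams, function(s) sum(!is.na(pff[[s]])), integer(1))
  if (any(counts == 0L)) {
    stop("no defined frames for observable(s): ",
         paste(streams[counts == 0L], collapse = ", "), call. = FALSE)
  }
  m <- vapply(streams, function(s) mean(pff[[s]], na.rm = TRUE), numeric(1))
  v <- vapply(streams, function(s) {
    x <- pff[[s]][!is.na(pff[[s]])]
    mean(x^2) - mean(x)^2
  }, numeric(1))
  v <- pmax(v, 0)
  out <- numeric(27L)
  names(out) <- feature_names()
  for (j in 1:3) {
    out[sprintf("aheadness_nn%d_mean", j)] <- m[paste0("h", j)]
    out[sprintf("aheadness_nn%d_var", j)] <- v[paste0("h", j)]
    out[sprintf("leftness_nn%d_mean", j)] <- m[paste0("l", j)]
    out[sprintf("leftness_nn%d_var", j)] <- v[paste0("l", j)]
    out[sprintf("distance_nn%d_mean", j)] <- m[paste0("d", j)]
    out[sprintf("adjacent_angle_nn%d_mean", j)] <- m[paste0("g", j)]
  }
  for (k in c(1, 5, 10, 20)) {
    out[sprintf("angle_diff_k%d_mean", k)] <- m[paste0("a", k)]
    out[sprintf("angle_diff_k%d_var", k)] <- v[paste0("a", k)]
  }
  out["travel_dist_k20_mean"] <- m["s20"]
  out
}
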