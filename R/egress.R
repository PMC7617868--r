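#' Configuration for the synthetic room-egress generator
#'
#' Agents start at non-overlapping random positions in a square room and
#' steer towards a bottleneck exit on the right wall under goal attraction,
#' short-range separation, wall repulsion and heading noise; a trajectory
#' ends once the agent is past the exit margin. A small number of planted
#' atypical agents is mixed in: `wall_follower` agents first head to the
#' exit wall far from the bottleneck and then creep along it towards the
#' exit in a stop-and-go gait (motion roughly perpendicular to the crowd's
#' main direction, with much shorter 20-step path lengths); `zigzag` agents
#' intersperse backtracking segments, walking away from the exit for part of
#' every cycle (inflating their turning-angle variance and path length
#' relative to net displacement). Ground-truth labels for the planted agents
#' travel with the generated table.
#'
#' @param n_runs independent runs.
#' @param n_agents agents per run (including planted outliers).
#' @param room_side room side length in metres; the exit is centred on the
#'   right wall `x = room_side`.
#' @param exit_width bottleneck width in metres.
#' @param speed_range uniform range of preferred speeds in m/s.
#' @param separation_radius,separation_weight short-range repulsion between
#'   agents (metres; dimensionless weight against unit goal attraction).
#' @param noise standard deviation of the per-frame heading perturbation
#'   (added to the steering vector componentwise).
#' @param outliers named integer vector with counts for `wall_follower` and
#'   `zigzag`; their total must stay below `n_agents / 4`.
#' @param frames_max hard cap on frames per run.
#' @param margin metres past the exit line after which a trajectory ends
#'   (matches the [crop_region()] convention).
#' @param frame_interval seconds per frame.
#' @param seed integer seed; one derived RNG stream per run.
#' @return a validated `egress_config` list.
#' @export
egress_config <- function(n_runs = 5, n_agents = 60, room_side = 14,
                          exit_width = 1.8, exit_centre_y = 1.6,
                          speed_range = c(0.6, 0.7),
                          separation_radius = 0.6, separation_weight = 0.8,
                          noise = 0.15,
                          outliers = c(wall_follower = 2, zigzag = 2),
                          frames_max = 700, margin = 0.5,
                          frame_interval = 0.1, seed = 1) {
  outliers <- c(wall_follower = unname(outliers["wall_follower"] %||% 0),
                zigzag = unname(outliers["zigzag"] %||% 0))
  outliers[is.na(outliers)] <- 0
  cfg <- list(n_runs = as.integer(n_runs), n_agents = as.integer(n_agents),
              room_side = room_side, exit_width = exit_width,
              exit_centre_y = exit_centre_y, speed_range = speed_range,
              separation_radius = separation_radius,
              separation_weight = separation_weight, noise = noise,
              outliers = as.integer(outliers), frames_max = as.integer(frames_max),
              margin = margin, frame_interval = frame_interval,
              seed = as.integer(seed))
  names(cfg$outliers) <- c("wall_follower", "zigzag")
  if (cfg$n_agents < 1L || cfg$n_runs < 1L) {
    stop("need at least one agent and one run", call. = FALSE)
  }
  if (sum(cfg$outliers) > 0 && sum(cfg$outliers) >= cfg$n_agents / 4) {
    stop("planted outlier count must stay below n_agents / 4", call. = FALSE)
  }
  if (cfg$exit_width <= 0 || cfg$exit_width >= cfg$room_side) {
    stop("exit_width must be positive and smaller than the room side",
         call. = FALSE)
  }
  if (cfg$exit_centre_y - cfg$exit_width / 2 < 0 ||
      cfg$exit_centre_y + cfg$exit_width / 2 > cfg$room_side) {
    stop("exit segment must lie within the right wall", call. = FALSE)
  }
  # rejection-sampled placement with 0.4 m separation must be feasible
  start_area <- (cfg$room_side - 2.5) * (cfg$room_side - 1)
  if (cfg$n_agents > start_area / (2 * 0.4^2)) {
    stop(sprintf("cannot place %d non-overlapping agents in the start region",
                 cfg$n_agents), call. = FALSE)
  }
  class(cfg) <- "egress_config"
  cfg
}

#' Generate synthetic room-egress trajectories with planted outliers
#'
#' @param config an [egress_config()].
#' @return a [trajectory_table()] with source `"egress"`, unit headings
#'   `dx`, `dy`, and a `labels` attribute (data frame `run_id`, `agent_id`,
#'   `kind`) identifying the planted outliers; see [outlier_labels()].
#' @export
generate_egress <- function(config = egress_config()) {
  stopifnot(inherits(config, "egress_config"))
  runs <- vector("list", config$n_runs)
  labels <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run_id <- sprintf("egress%d", r)
    sim <- with_preserved_rng({
      set.seed(derive_seed(config$seed, 100 + r))
      simulate_egress_run(config, run_id)
    })
    runs[[r]] <- sim$records
    labels[[r]] <- sim$labels
  }
  tab <- trajectory_table(do.call(rbind, runs),
                          frame_interval = config$frame_interval,
                          source = "egress")
  attr(tab, "labels") <- do.call(rbind, labels)
  tab
}

#' Ground-truth labels of planted outliers
#'
#' @param table a [generate_egress()] table.
#' @return data frame with `run_id`, `agent_id`, `kind`.
#' @export
outlier_labels <- function(table) {
  lab <- attr(table, "labels")
  if (is.null(lab)) {
    stop("table carries no planted-outlier labels", call. = FALSE)
  }
  lab
}

#' Write planted-outlier labels as CSV
#'
#' @param table a [generate_egress()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_labels <- function(table, path) {
  utils::write.csv(outlier_labels(table), path, row.names = FALSE)
  invisible(path)
}

simulate_egress_run <- function(cfg, run_id) {
  side <- cfg$room_side
  cy <- cfg$exit_centre_y
  half_exit <- cfg$exit_width / 2
  dt <- cfg$frame_interval
  n <- cfg$n_agents
  n_wall <- cfg$outliers[["wall_follower"]]
  n_zig <- cfg$outliers[["zigzag"]]
  kind <- rep("normal", n)
  if (n_wall + n_zig > 0) {
    picks <- sample.int(n, n_wall + n_zig)
    kind[picks[seq_len(n_wall)]] <- "wall_follower"
    if (n_zig > 0) kind[picks[n_wall + seq_len(n_zig)]] <- "zigzag"
  }

  # start positions: planted agents are inserted at fixed per-kind spots
  # (small jitter only), so replicates across runs experience a comparable
  # crowd context; normal agents start uniformly in the left part of the
  # room, far enough from the exit that every trajectory spans the
  # 20-frame feature windows, all with 0.4 m minimum separation
  pos <- matrix(NA_real_, n, 2L)
  kind_rank <- stats::ave(seq_len(n), kind, FUN = seq_along)
  anchor <- function(i) {
    switch(kind[i],
           wall_follower = c(1.0, side - 1.5 - 0.5 * (kind_rank[i] - 1)),
           zigzag = c(1.0, 1.0 + 0.5 * (kind_rank[i] - 1)),
           c(runif(1, 0.5, side - 2), runif(1, 0.5, side - 0.5)))
  }
  order_place <- order(kind == "normal")  # planted first
  placed <- integer(0)
  tries <- 0L
  for (i in order_place) {
    repeat {
      cand <- anchor(i)
      if (kind[i] != "normal") cand <- cand + runif(2, -0.2, 0.2)
      ok <- length(placed) == 0L ||
        min(sqrt(rowSums(sweep(pos[placed, , drop = FALSE], 2L, cand)^2))) >= 0.4
      tries <- tries + 1L
      if (ok) {
        pos[i, ] <- cand
        placed <- c(placed, i)
        break
      }
      if (tries > 20000L) {
        stop("agent placement failed: room too crowded for non-overlapping starts",
             call. = FALSE)
      }
    }
  }

  # planted kinds share one fixed speed so that same-kind agents from
  # different runs produce near-identical feature rows (coherent manifold
  # ends), while normal speeds vary across the configured range
  speed <- runif(n, cfg$speed_range[1L], cfg$speed_range[2L])
  speed[kind == "wall_follower"] <- 0.65
  speed[kind == "zigzag"] <- 0.9
  # per-agent heading noise ("waywardness") grows with preferred speed, so
  # the normal crowd spreads along one slow/straight -- fast/wayward axis
  # rather than forming an unstructured blob; individual variability of
  # this kind is a standard feature of real crowds
  noise_i <- rep(cfg$noise, n)
  # planted agents of one kind share one cycle phase: their scripted
  # gaits are in step, which keeps each kind's feature rows tightly
  # clustered across runs
  zig_offset <- rep(0L, n)
  go_offset <- rep(0L, n)
  # wall followers all join the exit wall at its far (top) corner and
  # then creep down the full wall towards the low bottleneck, so their
  # paths (and the signs of their leftness statistics) agree
  wall_y <- rep(side - 0.8, n)
  wall_phase <- rep(1L, n)

  # aim at the nearest point of the exit segment (with a shoulder allowance);
  # close to the wall, aim beyond it so the crossing completes
  exit_target <- function(p) {
    cbind(ifelse(p[, 1L] > side - 0.5, side + cfg$margin + 1, side),
          pmin(pmax(p[, 2L], cy - half_exit + 0.15), cy + half_exit - 0.15))
  }

  active <- rep(TRUE, n)
  heading <- matrix(0, n, 2L)
  tgt0 <- exit_target(pos)
  for (i in seq_len(n)) {
    d0 <- tgt0[i, ] - pos[i, ]
    heading[i, ] <- d0 / vec_norm(d0)
  }

  rec_x <- matrix(NA_real_, cfg$frames_max, n)
  rec_y <- matrix(NA_real_, cfg$frames_max, n)
  rec_dx <- matrix(NA_real_, cfg$frames_max, n)
  rec_dy <- matrix(NA_real_, cfg$frames_max, n)
  rec_x[1L, ] <- pos[, 1L]; rec_y[1L, ] <- pos[, 2L]
  rec_dx[1L, ] <- heading[, 1L]; rec_dy[1L, ] <- heading[, 2L]

  for (t in seq_len(cfg$frames_max - 1L)) {
    if (!any(active)) break
    act <- which(active)
    na <- length(act)
    p <- pos[act, , drop = FALSE]

    # goal attraction towards the nearest point of the exit segment
    tgt <- exit_target(p)
    goal <- tgt - p
    goal <- goal / pmax(sqrt(rowSums(goal^2)), 1e-12)

    # planted behaviour overrides
    moving <- rep(TRUE, na)
    for (ii in seq_len(na)) {
      i <- act[ii]
      if (kind[i] == "zigzag") {
        # zigzag agents work their way along the bottom wall before
        # turning to the exit, backtracking for a third of every cycle
        if (p[ii, 1L] < side - 1.5) {
          wp <- c(side - 1.2, 0.8)
          dv <- wp - p[ii, ]
          goal[ii, ] <- dv / max(vec_norm(dv), 1e-12)
        }
        phase <- (t + zig_offset[i]) %% 24L
        if (phase >= 16L && p[ii, 1L] < side - 0.3) {
          goal[ii, ] <- -goal[ii, ]   # backtracking leg of the cycle
        }
      } else if (kind[i] == "wall_follower") {
        if (wall_phase[i] == 1L) {
          wp <- c(side - 0.35, wall_y[i])
          if (vec_norm(p[ii, ] - wp) < 0.3) wall_phase[i] <- 2L
        }
        if (wall_phase[i] == 2L && abs(p[ii, 2L] - cy) < half_exit * 0.6) {
          wall_phase[i] <- 3L
        }
        wp <- switch(wall_phase[i],
                     c(side - 0.35, wall_y[i]),
                     c(side - 0.35, cy),
                     c(side + cfg$margin + 1, cy))
        dv <- wp - p[ii, ]
        goal[ii, ] <- dv / max(vec_norm(dv), 1e-12)
        # the creep down the wall is a stop-and-go gait (walk 12 frames,
        # stand 12, inheriting the heading); the initial leg towards the
        # wall is walked at a normal gait
        if (wall_phase[i] >= 2L &&
            (t + go_offset[i]) %% 24L >= 12L) moving[ii] <- FALSE
      }
    }

    # short-range separation
    sep <- matrix(0, na, 2L)
    if (na > 1L) {
      dm <- as.matrix(stats::dist(p))
      w <- pmax((cfg$separation_radius - dm) / cfg$separation_radius, 0)
      diag(w) <- 0
      inv <- 1 / pmax(dm, 1e-9)
      diag(inv) <- 0
      relx <- outer(p[, 1L], p[, 1L], "-") * inv
      rely <- outer(p[, 2L], p[, 2L], "-") * inv
      sep <- cfg$separation_weight * cbind(rowSums(w * relx),
                                           rowSums(w * rely))
    }

    # wall repulsion (skipped on the exit gap of the right wall)
    wallf <- cbind(pmax(0, 0.3 - p[, 1L]) - 0, 0) / 0.3
    wallf[, 2L] <- (pmax(0, 0.3 - p[, 2L]) -
                      pmax(0, p[, 2L] - (side - 0.3))) / 0.3
    at_exit_band <- abs(p[, 2L] - cy) < half_exit - 0.05
    wallf[, 1L] <- wallf[, 1L] -
      ifelse(at_exit_band, 0, pmax(0, p[, 1L] - (side - 0.3)) / 0.3)

    # planted agents follow their scripted motion exactly (no separation,
    # noise or turning inertia), so same-kind agents from different runs
    # trace near-identical paths and form tight groups in feature space;
    # normal agents steer smoothly (heading inertia) under goal attraction,
    # separation, wall repulsion and noise
    scripted <- kind[act] != "normal"
    noise_term <- matrix(rnorm(2 * na), na, 2L) * noise_i[act]
    steer <- goal + sep + wallf + noise_term
    steer <- 0.35 * steer + 0.65 * heading[act, , drop = FALSE]
    steer[scripted, ] <- goal[scripted, , drop = FALSE]
    norms <- sqrt(rowSums(steer^2))
    newhead <- heading[act, , drop = FALSE]
    okv <- norms > 1e-9
    newhead[okv, ] <- steer[okv, , drop = FALSE] / norms[okv]

    step <- newhead * speed[act] * dt
    step[!moving, ] <- 0
    newp <- p + step
    # walls are solid except across the exit gap
    can_cross <- abs(newp[, 2L] - cy) < half_exit - 0.05 & newp[, 1L] > side - 1
    newp[, 1L] <- ifelse(can_cross, newp[, 1L],
                         pmin(pmax(newp[, 1L], 0.05), side - 0.05))
    newp[, 2L] <- pmin(pmax(newp[, 2L], 0.05), side - 0.05)

    # keep the recorded heading consistent with the realised displacement:
    # standing agents inherit their previous heading
    disp <- newp - p
    dlen <- sqrt(rowSums(disp^2))
    okd <- dlen > 1e-12
    newhead[okd, ] <- disp[okd, , drop = FALSE] / dlen[okd]
    newhead[!okd, ] <- heading[act, , drop = FALSE][!okd, , drop = FALSE]

    pos[act, ] <- newp
    heading[act, ] <- newhead
    gone <- newp[, 1L] > side + cfg$margin
    record <- !gone
    if (any(record)) {
      ri <- act[record]
      rec_x[t + 1L, ri] <- newp[record, 1L]
      rec_y[t + 1L, ri] <- newp[record, 2L]
      rec_dx[t + 1L, ri] <- newhead[record, 1L]
      rec_dy[t + 1L, ri] <- newhead[record, 2L]
    }
    active[act[gone]] <- FALSE
  }

  ids <- sprintf("p%03d", seq_len(n))
  recs <- lapply(seq_len(n), function(i) {
    got <- which(!is.na(rec_x[, i]))
    data.frame(run_id = run_id, agent_id = ids[i], frame = got - 1L,
               x = rec_x[got, i], y = rec_y[got, i],
               dx = rec_dx[got, i], dy = rec_dy[got, i],
               stringsAsFactors = FALSE)
  })
  planted <- which(kind != "normal")
  lab <- data.frame(run_id = rep(run_id, length(planted)),
                    agent_id = ids[planted], kind = kind[planted],
                    stringsAsFactors = FALSE)
  list(records = do.call(rbind, recs), labels = lab)
}
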