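#' Build the M x 27 feature matrix from a trajectory table
#'
#' Maps every agent's trajectory to the 27 summary observables of
#' [feature_names()]: per-frame nearest-neighbour geometry (aheadness,
#' leftness, distance, adjacent angle for ranks 1-3), k-step turning angles
#' (k = 1, 5, 10, 20) and the 20-step travel distance, summarised as means
#' and (population) variances over each observable's defined frames.
#' Neighbours are drawn only from agents co-present at the same frame of the
#' same run; ranks are ordered by distance with ties broken by agent id.
#'
#' Agents for which any observable has no defined frame (e.g. trajectories
#' shorter than 21 frames, for which the 20-step features never exist, or
#' agents never co-present with three others) are excluded rather than
#' imputed; the exclusions and their reasons are recorded in the result.
#'
#' @param table a [trajectory_table()]; headings are derived from positions
#'   with [derive_directions()] if absent.
#' @param source label stored with every row (defaults to the table's
#'   `source` attribute, else `"data"`).
#' @return an object of class `feature_matrix`: a list with `values`
#'   (M x 27 numeric matrix), `meta` (data frame with `run_id`, `agent_id`,
#'   `source`) and `exclusions` (data frame of dropped agents and reasons).
#' @export
build_feature_matrix <- function(table, source = NULL) {
  stopifnot(inherits(table, "trajectory_table"))
  source <- source %||% attr(table, "source") %||% "data"
  exclusions <- data.frame(run_id = character(0), agent_id = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  if (!all(c("dx", "dy") %in% names(table))) {
    degen <- character(0)
    withCallingHandlers(
      table <- derive_directions(table),
      warning = function(w) {
        invokeRestart("muffleWarning")
      })
    degen <- attr(table, "degenerate_agents") %||% character(0)
    if (length(degen) > 0L) {
      parts <- strsplit(degen, "/", fixed = TRUE)
      exclusions <- rbind(exclusions, data.frame(
        run_id = vapply(parts, `[[`, "", 1L),
        agent_id = vapply(parts, `[[`, "", 2L),
        reason = "degenerate trajectory (never moves)",
        stringsAsFactors = FALSE))
    }
  }

  streams <- .stream_names()
  rows <- list()
  meta <- list()
  for (run in unique(table$run_id)) {
    rs <- run_streams(table[table$run_id == run, , drop = FALSE])
    agents <- rownames(rs$count)
    for (ai in seq_along(agents)) {
      cnt <- rs$count[ai, ]
      if (any(cnt == 0L)) {
        missing <- streams[cnt == 0L]
        exclusions <- rbind(exclusions, data.frame(
          run_id = run, agent_id = agents[ai],
          reason = paste0("no defined frames for: ",
                          paste(missing, collapse = ", ")),
          stringsAsFactors = FALSE))
        next
      }
      m <- rs$sum[ai, ] / cnt
      v <- pmax(rs$sumsq[ai, ] / cnt - m^2, 0)
      row <- numeric(27L)
      names(row) <- feature_names()
      for (j in 1:3) {
        row[sprintf("aheadness_nn%d_mean", j)] <- m[paste0("h", j)]
        row[sprintf("aheadness_nn%d_var", j)] <- v[paste0("h", j)]
        row[sprintf("leftness_nn%d_mean", j)] <- m[paste0("l", j)]
        row[sprintf("leftness_nn%d_var", j)] <- v[paste0("l", j)]
        row[sprintf("distance_nn%d_mean", j)] <- m[paste0("d", j)]
        row[sprintf("adjacent_angle_nn%d_mean", j)] <- m[paste0("g", j)]
      }
      for (k in c(1, 5, 10, 20)) {
        row[sprintf("angle_diff_k%d_mean", k)] <- m[paste0("a", k)]
        row[sprintf("angle_diff_k%d_var", k)] <- v[paste0("a", k)]
      }
      row["travel_dist_k20_mean"] <- m["s20"]
      rows[[length(rows) + 1L]] <- row
      meta[[length(meta) + 1L]] <- c(run, agents[ai])
    }
  }
  if (length(rows) == 0L) {
    stop("no agents retained: every agent has at least one observable with ",
         "no defined frames (see trajectory lengths and co-presence); ",
         "first reasons: ",
         paste(utils::head(unique(exclusions$reason), 3L), collapse = "; "),
         call. = FALSE)
  }
  values <- do.call(rbind, rows)
  md <- do.call(rbind, meta)
  structure(list(
    values = values,
    meta = data.frame(run_id = md[, 1L], agent_id = md[, 2L],
                      source = source, stringsAsFactors = FALSE),
    exclusions = exclusions),
    class = "feature_matrix")
}

# accumulate count/sum/sumsq of the 17 per-frame streams for one run.
# neighbour geometry is vectorised within each frame; the only per-agent
# work is the distance ordering.
run_streams <- function(run_tab) {
  agents <- sort(unique(run_tab$agent_id))
  na <- length(agents)
  streams <- .stream_names()
  ns <- length(streams)
  count <- matrix(0L, na, ns, dimnames = list(agents, streams))
  ssum <- matrix(0, na, ns, dimnames = list(agents, streams))
  ssq <- matrix(0, na, ns, dimnames = list(agents, streams))

  # aggregate by agent before indexing: subscript assignment with repeated
  # index rows would silently drop all but the last contribution
  add <- function(aidx, stream, vals) {
    ok <- !is.na(vals)
    if (!any(ok)) return()
    si <- match(stream, streams)
    agg <- rowsum(cbind(1, vals[ok], vals[ok]^2), group = aidx[ok])
    idx <- cbind(as.integer(rownames(agg)), si)
    count[idx] <<- count[idx] + as.integer(agg[, 1L])
    ssum[idx] <<- ssum[idx] + agg[, 2L]
    ssq[idx] <<- ssq[idx] + agg[, 3L]
  }

  # neighbour-rank streams, frame by frame
  by_frame <- split(seq_len(nrow(run_tab)), run_tab$frame)
  for (rows in by_frame) {
    n <- length(rows)
    if (n < 2L) next
    ids <- run_tab$agent_id[rows]
    aidx <- match(ids, agents)
    pos <- cbind(run_tab$x[rows], run_tab$y[rows])
    dir <- cbind(run_tab$dx[rows], run_tab$dy[rows])
    dm <- as.matrix(stats::dist(pos))
    diag(dm) <- Inf
    # rank matrix: nn[i, j] = index of i's j-th nearest neighbour
    nn <- matrix(NA_integer_, n, 3L)
    for (i in seq_len(n)) {
      ord <- order(dm[i, ], ids)
      nn[i, seq_len(min(3L, n - 1L))] <- ord[seq_len(min(3L, n - 1L))]
    }
    perp <- cbind(-dir[, 2L], dir[, 1L])
    for (j in seq_len(min(3L, n - 1L))) {
      tgt <- nn[, j]
      ok <- !is.na(tgt)
      rel <- pos[tgt[ok], , drop = FALSE] - pos[ok, , drop = FALSE]
      h <- rowSums(rel * dir[ok, , drop = FALSE])
      l <- rowSums(rel * perp[ok, , drop = FALSE])
      d <- dm[cbind(which(ok), tgt[ok])]
      g <- acos(clamp_cos(rowSums(dir[ok, , drop = FALSE] *
                                    dir[tgt[ok], , drop = FALSE])))
      add(aidx[ok], paste0("h", j), h)
      add(aidx[ok], paste0("l", j), l)
      add(aidx[ok], paste0("d", j), d)
      add(aidx[ok], paste0("g", j), g)
    }
  }

  # turning and path-length streams, agent by agent
  by_agent <- split(seq_len(nrow(run_tab)), run_tab$agent_id)
  for (id in names(by_agent)) {
    rows <- by_agent[[id]]
    rows <- rows[order(run_tab$frame[rows])]
    ai <- match(id, agents)
    nfr <- length(rows)
    v <- cbind(run_tab$dx[rows], run_tab$dy[rows])
    for (k in c(1, 5, 10, 20)) {
      if (nfr > k) {
        ang <- acos(clamp_cos(rowSums(v[(k + 1):nfr, , drop = FALSE] *
                                        v[1:(nfr - k), , drop = FALSE])))
        add(rep(ai, nfr - k), paste0("a", k), ang)
      }
    }
    if (nfr > 20L) {
      steps <- sqrt(diff(run_tab$x[rows])^2 + diff(run_tab$y[rows])^2)
      cum <- c(0, cumsum(steps))
      s20 <- cum[21:nfr] - cum[1:(nfr - 20L)]
      add(rep(ai, nfr - 20L), "s20", s20)
    }
  }
  list(count = count, sum = ssum, sumsq = ssq)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d agents x %d features (%d excluded)\n",
              nrow(x$values), ncol(x$values), nrow(x$exclusions)))
  cat("runs:", paste(unique(x$meta$run_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$values))
}

#' Write a feature matrix as CSV
#'
#' Metadata columns `run_id`, `agent_id`, `source` followed by the 27
#' feature columns in canonical order.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}
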