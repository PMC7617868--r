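#' Construct a trajectory table
#'
#' A trajectory table is the package's central container: one row per agent
#' per frame, holding 2-D positions in metres and (optionally) unit heading
#' vectors. Rows are grouped into runs (independent recordings); frames are
#' 0-based integers that must be contiguous within each agent's trajectory.
#'
#' @param records data frame with columns `run_id`, `agent_id`, `frame`,
#'   `x`, `y` and optionally `dx`, `dy` (unit heading components).
#' @param frame_interval optional seconds per frame, kept as metadata; all
#'   downstream k-step features count frames, not seconds.
#' @param source optional label describing where the data came from (e.g. a
#'   generator name); carried into feature-matrix metadata.
#' @return an object of class `trajectory_table` (a validated data frame
#'   sorted by run, agent, frame).
#' @export
trajectory_table <- function(records, frame_interval = NULL, source = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("run_id", "agent_id", "frame", "x", "y")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c(need, "dx", "dy"), names(records))
  tab <- as.data.frame(records)[keep]
  tab$run_id <- as.character(tab$run_id)
  tab$agent_id <- as.character(tab$agent_id)
  tab$frame <- as.integer(tab$frame)
  tab <- tab[order(tab$run_id, tab$agent_id, tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "frame_interval") <- frame_interval
  attr(tab, "source") <- source
  class(tab) <- c("trajectory_table", "data.frame")
  validate_trajectories(tab)
  tab
}

# invariant checks shared by the constructor, the readers and crop_region
validate_trajectories <- function(tab) {
  key <- paste(tab$run_id, tab$agent_id, tab$frame, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1L]
    stop(sprintf(
      "duplicate record for (run '%s', agent '%s', frame %d)",
      tab$run_id[first], tab$agent_id[first], tab$frame[first]),
      call. = FALSE)
  }
  grp <- paste(tab$run_id, tab$agent_id, sep = "\r")
  for (g in split(seq_len(nrow(tab)), grp)) {
    fr <- tab$frame[g]
    if (length(fr) > 1L && any(diff(fr) != 1L)) {
      stop(sprintf(
        "non-contiguous frames for agent '%s' in run '%s'",
        tab$agent_id[g[1L]], tab$run_id[g[1L]]),
        call. = FALSE)
    }
  }
  if (all(c("dx", "dy") %in% names(tab))) {
    n2 <- tab$dx^2 + tab$dy^2
    bad <- which(abs(sqrt(n2) - 1) > 1e-6)
    if (length(bad) > 0L) {
      b <- bad[1L]
      stop(sprintf(
        "direction vector is not unit length (||v|| = %.8f) for agent '%s' in run '%s' at frame %d; drop dx/dy and use derive_directions()",
        sqrt(n2[b]), tab$agent_id[b], tab$run_id[b], tab$frame[b]),
        call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.trajectory_table <- function(x, ...) {
  n_run <- length(unique(x$run_id))
  n_agent <- nrow(unique(as.data.frame(x)[c("run_id", "agent_id")]))
  cat(sprintf(
    "<trajectory_table> %d records, %d agents, %d run(s)%s%s\n",
    nrow(x), n_agent, n_run,
    if (all(c("dx", "dy") %in% names(x))) ", with directions" else "",
    if (!is.null(attr(x, "frame_interval")))
      sprintf(", frame interval %gs", attr(x, "frame_interval")) else ""))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

resolve_column <- function(nms, aliases) {
  hit <- which(tolower(nms) %in% aliases)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Read multi-agent trajectories from a file
#'
#' Two dialects are supported. `csv` expects a header with columns
#' resolvable to run, agent, frame, x, y (aliases such as `run`, `ped`,
#' `id`, `t` are accepted) and optional `dx`, `dy`. `whitespace` reads the
#' headerless `agent frame x y [z]` layout used by public pedestrian
#' trajectory archives; any z column is discarded and the run id is taken
#' from the file name unless given explicitly.
#'
#' @param path path to the file.
#' @param dialect `"csv"` or `"whitespace"`.
#' @param run_id run label used when the file carries no run column.
#' @param frame_interval optional seconds per frame (metadata).
#' @param source optional source label (metadata).
#' @return a [trajectory_table()].
#' @export
read_trajectories <- function(path, dialect = c("csv", "whitespace"),
                              run_id = NULL, frame_interval = NULL,
                              source = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  default_run <- run_id %||% sub("\\.[^.]*$", "", basename(path))

  if (dialect == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
    nms <- names(raw)
    idx <- c(
      run   = resolve_column(nms, c("run_id", "run")),
      agent = resolve_column(nms, c("agent_id", "agent", "ped", "ped_id", "id")),
      frame = resolve_column(nms, c("frame", "t", "step", "time_step")),
      x     = resolve_column(nms, "x"),
      y     = resolve_column(nms, "y"),
      dx    = resolve_column(nms, "dx"),
      dy    = resolve_column(nms, "dy"))
    for (col in c("agent", "frame", "x", "y")) {
      if (is.na(idx[[col]])) {
        stop(sprintf("cannot resolve mandatory column '%s' in %s", col, path),
             call. = FALSE)
      }
    }
    header_lines <- 1L
    rec <- data.frame(
      run_id = if (is.na(idx[["run"]])) default_run else raw[[idx[["run"]]]],
      agent_id = raw[[idx[["agent"]]]],
      frame = parse_numeric(raw[[idx[["frame"]]]], "frame", header_lines),
      x = parse_numeric(raw[[idx[["x"]]]], "x", header_lines),
      y = parse_numeric(raw[[idx[["y"]]]], "y", header_lines),
      stringsAsFactors = FALSE)
    if (!is.na(idx[["dx"]]) && !is.na(idx[["dy"]])) {
      rec$dx <- parse_numeric(raw[[idx[["dx"]]]], "dx", header_lines)
      rec$dy <- parse_numeric(raw[[idx[["dy"]]]], "dy", header_lines)
    }
  } else {
    raw <- utils::read.table(path, colClasses = "character", header = FALSE)
    if (ncol(raw) < 4L) {
      stop(sprintf(
        "whitespace dialect needs at least 4 columns (agent frame x y), got %d in %s",
        ncol(raw), path), call. = FALSE)
    }
    rec <- data.frame(
      run_id = default_run,
      agent_id = raw[[1L]],
      frame = parse_numeric(raw[[2L]], "frame", 0L),
      x = parse_numeric(raw[[3L]], "x", 0L),
      y = parse_numeric(raw[[4L]], "y", 0L),
      stringsAsFactors = FALSE)
    # a 5th (z) column, present in some archives, is ignored
  }
  if (any(rec$frame != floor(rec$frame))) {
    bad <- which(rec$frame != floor(rec$frame))[1L]
    stop(sprintf("frame index is not an integer at data row %d", bad),
         call. = FALSE)
  }
  trajectory_table(rec, frame_interval = frame_interval, source = source)
}

parse_numeric <- function(chr, column, header_lines) {
  num <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(num) & !is.na(chr))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                 chr[bad[1L]], column, bad[1L] + header_lines),
         call. = FALSE)
  }
  num
}

#' Write a trajectory table as CSV
#'
#' Numbers are written with 17 significant digits so that
#' `read_trajectories()` recovers the table bit-identically.
#'
#' @param table a [trajectory_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(table, path) {
  stopifnot(inherits(table, "trajectory_table"))
  has_dir <- all(c("dx", "dy") %in% names(table))
  cols <- c("run_id", "agent_id", "frame", "x", "y",
            if (has_dir) c("dx", "dy"))
  lines <- paste(cols, collapse = ",")
  body <- paste(table$run_id, table$agent_id, table$frame,
                fmt_num(table$x), fmt_num(table$y), sep = ",")
  if (has_dir) {
    body <- paste(body, fmt_num(table$dx), fmt_num(table$dy), sep = ",")
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Derive unit heading vectors from positions
#'
#' Headings are backward finite differences: `v(t)` is the normalised
#' displacement from frame `t-1` to `t`. A zero displacement inherits the
#' previous frame's heading, so stationary spells keep the last direction of
#' motion. The first frame uses the forward difference; if that is also zero
#' the first subsequent non-zero step direction is carried backwards. Agents
#' that never move (including single-frame trajectories) are dropped with a
#' warning and recorded in the `degenerate_agents` attribute.
#'
#' @param table a [trajectory_table()]; any existing `dx`/`dy` columns are
#'   recomputed from positions (which makes the operation idempotent).
#' @return the table with unit `dx`, `dy` columns.
#' @export
derive_directions <- function(table) {
  stopifnot(inherits(table, "trajectory_table"))
  tab <- as.data.frame(table)
  grp <- paste(tab$run_id, tab$agent_id, sep = "\r")
  dx <- numeric(nrow(tab))
  dy <- numeric(nrow(tab))
  drop_rows <- integer(0)
  degenerate <- character(0)
  for (g in split(seq_len(nrow(tab)), grp)) {
    n <- length(g)
    sx <- diff(tab$x[g])
    sy <- diff(tab$y[g])
    len <- sqrt(sx^2 + sy^2)
    nz <- which(len > 0)
    if (n == 1L || length(nz) == 0L) {
      drop_rows <- c(drop_rows, g)
      degenerate <- c(degenerate,
                      paste0(tab$run_id[g[1L]], "/", tab$agent_id[g[1L]]))
      next
    }
    d <- matrix(0, n, 2L)
    d[1L, ] <- c(sx[nz[1L]], sy[nz[1L]]) / len[nz[1L]]
    for (t in 2:n) {
      d[t, ] <- if (len[t - 1L] > 0) {
        c(sx[t - 1L], sy[t - 1L]) / len[t - 1L]
      } else {
        d[t - 1L, ]
      }
    }
    dx[g] <- d[, 1L]
    dy[g] <- d[, 2L]
  }
  if (length(degenerate) > 0L) {
    warning("dropping degenerate (never-moving) agent(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  tab$dx <- dx
  tab$dy <- dy
  if (length(drop_rows) > 0L) tab <- tab[-drop_rows, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("all agents are degenerate; no trajectories left", call. = FALSE)
  }
  out <- trajectory_table(tab, frame_interval = attr(table, "frame_interval"),
                          source = attr(table, "source"))
  attr(out, "degenerate_agents") <- degenerate
  out
}

#' Crop trajectories to a rectangular region and an exit margin
#'
#' Removes records outside the retained region. The `exit` argument mirrors
#' the common bottleneck convention of keeping trajectories inside the room
#' plus a short margin beyond the exit line (default 0.5 m): for an exit on
#' the line `x = at` crossed in the `+` direction, records with
#' `x > at + margin` are dropped. If cropping splits an agent's trajectory,
#' only the first contiguous in-region segment is kept (and the truncation is
#' reported in the `crop_log` attribute).
#'
#' @param table a [trajectory_table()].
#' @param xlim,ylim optional numeric length-2 retained intervals.
#' @param exit optional list `list(axis = "x"|"y", at = <metres>,
#'   direction = "+"|"-")` describing the exit line and crossing direction.
#' @param margin metres retained beyond the exit line (default 0.5).
#' @return the cropped [trajectory_table()].
#' @export
crop_region <- function(table, xlim = NULL, ylim = NULL, exit = NULL,
                        margin = 0.5) {
  stopifnot(inherits(table, "trajectory_table"))
  if (is.null(xlim) && is.null(ylim) && is.null(exit)) {
    stop("no region given: supply xlim, ylim and/or exit", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  if (!is.null(xlim)) {
    stopifnot(length(xlim) == 2L, xlim[1L] <= xlim[2L])
    keep <- keep & table$x >= xlim[1L] & table$x <= xlim[2L]
  }
  if (!is.null(ylim)) {
    stopifnot(length(ylim) == 2L, ylim[1L] <= ylim[2L])
    keep <- keep & table$y >= ylim[1L] & table$y <= ylim[2L]
  }
  if (!is.null(exit)) {
    stopifnot(is.list(exit), exit$axis %in% c("x", "y"),
              is.numeric(exit$at), exit$direction %in% c("+", "-"))
    coord <- if (exit$axis == "x") table$x else table$y
    keep <- keep & if (exit$direction == "+") {
      coord <= exit$at + margin
    } else {
      coord >= exit$at - margin
    }
  }
  tab <- as.data.frame(table)
  grp <- paste(tab$run_id, tab$agent_id, sep = "\r")
  keep_rows <- integer(0)
  truncated <- character(0)
  for (g in split(seq_len(nrow(tab)), grp)) {
    r <- rle(keep[g])
    segs <- which(r$values)
    if (length(segs) == 0L) next
    first <- segs[1L]
    start <- if (first == 1L) 1L else sum(r$lengths[seq_len(first - 1L)]) + 1L
    keep_rows <- c(keep_rows, g[start:(start + r$lengths[first] - 1L)])
    if (length(segs) > 1L) {
      truncated <- c(truncated,
                     paste0(tab$run_id[g[1L]], "/", tab$agent_id[g[1L]]))
    }
  }
  if (length(keep_rows) == 0L) {
    stop("no records remain after cropping; check the region specification",
         call. = FALSE)
  }
  if (length(truncated) > 0L) {
    message("crop_region: kept only the first in-region segment for ",
            length(truncated), " agent(s) that re-entered")
  }
  out <- trajectory_table(tab[sort(keep_rows), , drop = FALSE],
                          frame_interval = attr(table, "frame_interval"),
                          source = attr(table, "source"))
  attr(out, "crop_log") <- truncated
  out
}
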