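#' Detect behavioural outliers at eigenvector extremes
#'
#' Agents whose entries in a chosen embedding coordinate are the most
#' extreme sit at the ends or boundaries of the manifold and correspond to
#' behaviour distinct from the bulk. This returns the `k` agents with the
#' largest (`side = "max"`) or smallest (`side = "min"`) entries in the
#' chosen eigenvector, over the pooled embedding (all runs and sources
#' together). Note the eigenvector sign is a convention (fixed here so the
#' largest-magnitude entry is positive), so `max` under one sign equals
#' `min` under the other; the report records the side used.
#'
#' @param embedding a [embed()] result.
#' @param ev_index which eigenvector to use, 1-based (default 1).
#' @param side `"max"` or `"min"`.
#' @param k number of outliers to report (default 10, a purely pragmatic
#'   choice; no automatic threshold on "how many outliers exist" is
#'   attempted).
#' @return an `outlier_report` data frame (`rank`, `run_id`, `agent_id`,
#'   `source`, `value`) sorted descending for `max`, ascending for `min`,
#'   with attributes `ev_index`, `side`, `k` and `sign_convention`.
#' @export
detect_outliers <- function(embedding, ev_index = 1, side = c("max", "min"),
                            k = 10) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  side <- match.arg(side)
  M <- nrow(embedding$vectors)
  if (ev_index < 1 || ev_index > embedding$K) {
    stop(sprintf("ev_index must be in 1..%d", embedding$K), call. = FALSE)
  }
  if (k < 1 || k > M) {
    stop(sprintf("k must be in 1..%d (got %d)", M, k), call. = FALSE)
  }
  v <- embedding$vectors[, ev_index]
  ord <- order(v, decreasing = (side == "max"))[seq_len(k)]
  out <- data.frame(rank = seq_len(k),
                    run_id = embedding$meta$run_id[ord],
                    agent_id = embedding$meta$agent_id[ord],
                    source = embedding$meta$source[ord],
                    value = v[ord],
                    stringsAsFactors = FALSE)
  structure(out, ev_index = ev_index, side = side, k = k,
            sign_convention = "largest-magnitude entry positive",
            class = c("outlier_report", "data.frame"))
}

#' Seeded random baseline selection
#'
#' Draws `k` agents uniformly without replacement, as a null comparison for
#' [detect_outliers()]: trajectories picked this way should show none of the
#' shared atypical structure of the eigenvector extremes. The draw is
#' reproducible from `seed` and leaves the caller's RNG state untouched.
#'
#' @param embedding a [embed()] result.
#' @param k number of agents to sample.
#' @param seed integer seed.
#' @return an `outlier_report`-shaped data frame with `side = "random"`.
#' @export
sample_baseline <- function(embedding, k, seed) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  M <- nrow(embedding$vectors)
  if (k < 1 || k > M) {
    stop(sprintf("k must be in 1..%d (got %d)", M, k), call. = FALSE)
  }
  idx <- with_preserved_rng({
    set.seed(as.integer(seed))
    sample.int(M, k)
  })
  out <- data.frame(rank = seq_len(k),
                    run_id = embedding$meta$run_id[idx],
                    agent_id = embedding$meta$agent_id[idx],
                    source = embedding$meta$source[idx],
                    value = embedding$vectors[idx, 1L],
                    stringsAsFactors = FALSE)
  structure(out, ev_index = NA_integer_, side = "random", k = k, seed = seed,
            class = c("outlier_report", "data.frame"))
}

#' Fetch the trajectories behind an outlier report
#'
#' @param report a [detect_outliers()] or [sample_baseline()] report.
#' @param table the [trajectory_table()] the embedding was built from.
#' @return a [trajectory_table()] restricted to the reported agents.
#' @export
outlier_trajectories <- function(report, table) {
  stopifnot(inherits(report, "outlier_report"),
            inherits(table, "trajectory_table"))
  key <- paste(table$run_id, table$agent_id, sep = "\r")
  want <- paste(report$run_id, report$agent_id, sep = "\r")
  rows <- key %in% want
  if (!any(rows)) stop("no reported agent found in the table", call. = FALSE)
  trajectory_table(as.data.frame(table)[rows, , drop = FALSE],
                   frame_interval = attr(table, "frame_interval"),
                   source = attr(table, "source"))
}

#' Write an outlier report as CSV
#'
#' @param report an `outlier_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  stopifnot(inherits(report, "outlier_report"))
  df <- as.data.frame(report)
  df$side <- attr(report, "side")
  df$ev_index <- attr(report, "ev_index")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
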