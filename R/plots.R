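#' Plot trajectories, optionally highlighting reported agents
#'
#' Draws every trajectory of the selected run(s) in light grey and overlays
#' the highlighted agents (e.g. an outlier report) in colour, mirroring the
#' usual way detected outliers are inspected against the rest of their run.
#'
#' @param table a [trajectory_table()].
#' @param runs run ids to draw (default: all).
#' @param highlight optional `outlier_report` or character vector of agent
#'   ids to emphasise.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the table.
#' @export
plot_trajectories <- function(table, runs = NULL, highlight = NULL, ...) {
  stopifnot(inherits(table, "trajectory_table"))
  tab <- as.data.frame(table)
  if (!is.null(runs)) tab <- tab[tab$run_id %in% runs, , drop = FALSE]
  if (nrow(tab) == 0L) stop("nothing to plot", call. = FALSE)
  hi_key <- character(0)
  if (inherits(highlight, "outlier_report")) {
    hi_key <- paste(highlight$run_id, highlight$agent_id, sep = "\r")
  } else if (!is.null(highlight)) {
    hi_key <- paste(rep(unique(tab$run_id), each = length(highlight)),
                    highlight, sep = "\r")
  }
  graphics::plot(range(tab$x), range(tab$y), type = "n", asp = 1,
                 xlab = "x [m]", ylab = "y [m]", ...)
  key <- paste(tab$run_id, tab$agent_id, sep = "\r")
  for (g in split(seq_len(nrow(tab)), key)) {
    graphics::lines(tab$x[g], tab$y[g], col = "grey70", lwd = 0.5)
  }
  if (length(hi_key) > 0L) {
    cols <- grDevices::hcl.colors(max(2L, length(unique(hi_key))), "Dark 3")
    for (i in seq_along(unique(hi_key))) {
      g <- which(key == unique(hi_key)[i])
      if (length(g) > 0L) graphics::lines(tab$x[g], tab$y[g],
                                          col = cols[i], lwd = 2)
    }
  }
  invisible(table)
}

#' Scatter plot of an embedding
#'
#' @param x a `diffusion_embedding`.
#' @param dims which two coordinates to draw (default 1 and 2).
#' @param colour_by optional numeric or factor per agent (e.g. the planted
#'   group size) used for point colours.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the embedding.
#' @export
plot.diffusion_embedding <- function(x, dims = c(1, 2), colour_by = NULL,
                                     ...) {
  v <- x$vectors
  stopifnot(all(dims %in% seq_len(ncol(v))))
  col <- "grey30"
  if (!is.null(colour_by)) {
    f <- as.integer(factor(colour_by))
    col <- grDevices::hcl.colors(max(f), "Viridis")[f]
  }
  graphics::plot(v[, dims[1L]], v[, dims[2L]], col = col, pch = 16,
                 xlab = paste0("ev", dims[1L]), ylab = paste0("ev", dims[2L]),
                 ...)
  invisible(x)
}
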