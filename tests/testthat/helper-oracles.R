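# independent brute-force oracles: plain nested loops, no spatial shortcuts,
# no reuse of the package's accumulation code

# per-agent summary rows recomputed naively from a table that already
# carries unit headings; returns rows in (run in appearance order, agent id
# sorted) order to match build_feature_matrix()
naive_feature_matrix <- function(table) {
  stopifnot(all(c("dx", "dy") %in% names(table)))
  ks <- c(1, 5, 10, 20)
  out <- list()
  meta <- list()
  for (run in unique(table$run_id)) {
    rt <- table[table$run_id == run, , drop = FALSE]
    for (id in sort(unique(rt$agent_id))) {
      at <- rt[rt$agent_id == id, , drop = FALSE]
      at <- at[order(at$frame), , drop = FALSE]
      streams <- list()
      for (i in seq_len(nrow(at))) {
        f <- at$frame[i]
        ci <- c(at$x[i], at$y[i]); vi <- c(at$dx[i], at$dy[i])
        co <- rt[rt$frame == f & rt$agent_id != id, , drop = FALSE]
        if (nrow(co) > 0) {
          d <- sqrt((co$x - ci[1])^2 + (co$y - ci[2])^2)
          co <- co[order(d, co$agent_id), , drop = FALSE]
          for (j in seq_len(min(3, nrow(co)))) {
            cj <- c(co$x[j], co$y[j]); vj <- c(co$dx[j], co$dy[j])
            rel <- cj - ci
            streams[[paste0("h", j)]] <- c(streams[[paste0("h", j)]],
                                           sum(rel * vi))
            streams[[paste0("l", j)]] <- c(streams[[paste0("l", j)]],
                                           -rel[1] * vi[2] + rel[2] * vi[1])
            streams[[paste0("d", j)]] <- c(streams[[paste0("d", j)]],
                                           sqrt(sum(rel^2)))
            streams[[paste0("g", j)]] <- c(streams[[paste0("g", j)]],
                                           acos(min(1, max(-1, sum(vi * vj)))))
          }
        }
        for (k in ks) {
          i0 <- which(at$frame == f - k)
          if (length(i0) == 1) {
            v0 <- c(at$dx[i0], at$dy[i0])
            streams[[paste0("a", k)]] <- c(streams[[paste0("a", k)]],
                                           acos(min(1, max(-1, sum(vi * v0)))))
          }
        }
        if (any(at$frame == f - 20)) {
          i0 <- which(at$frame == f - 20)
          seg <- i0:(i - 1)
          streams$s20 <- c(streams$s20,
                           sum(sqrt(diff(at$x[i0:i])^2 + diff(at$y[i0:i])^2)))
        }
      }
      need <- c(paste0(rep(c("h", "l", "d", "g"), 3),
                       rep(1:3, each = 4)), paste0("a", ks), "s20")
      if (!all(need %in% names(streams))) next
      pm <- function(x) mean(x)
      pv <- function(x) mean(x^2) - mean(x)^2
      row <- numeric(0)
      for (j in 1:3) {
        row <- c(row,
                 pm(streams[[paste0("h", j)]]), pv(streams[[paste0("h", j)]]),
                 pm(streams[[paste0("l", j)]]), pv(streams[[paste0("l", j)]]),
                 pm(streams[[paste0("d", j)]]), pm(streams[[paste0("g", j)]]))
      }
      for (k in ks) {
        row <- c(row, pm(streams[[paste0("a", k)]]),
                 pv(streams[[paste0("a", k)]]))
      }
      row <- c(row, pm(streams$s20))
      out[[length(out) + 1]] <- row
      meta[[length(meta) + 1]] <- c(run, id)
    }
  }
  values <- do.call(rbind, out)
  colnames(values) <- feature_names()
  md <- do.call(rbind, meta)
  list(values = values,
       meta = data.frame(run_id = md[, 1], agent_id = md[, 2],
                         stringsAsFactors = FALSE))
}

# dense eigendecomposition of the random-walk Laplacian taken directly as
# the (non-symmetric) matrix I - D^-1 C
dense_rw_oracle <- function(C) {
  C <- as.matrix(C)
  d <- colSums(C)
  L <- diag(nrow(C)) - diag(1 / d) %*% C
  e <- eigen(L)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}
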