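# small constructors used across the test files

make_traj <- function(run_id, agent_id, frame, x, y, dx = NULL, dy = NULL,
                      ...) {
  rec <- data.frame(run_id = run_id, agent_id = agent_id, frame = frame,
                    x = x, y = y, stringsAsFactors = FALSE)
  if (!is.null(dx)) {
    rec$dx <- dx
    rec$dy <- dy
  }
  trajectory_table(rec, ...)
}

# one agent walking a straight line along +x at constant step
straight_walker <- function(n = 30, step = 0.1, id = "a1", run = "r1") {
  make_traj(run, id, 0:(n - 1), (0:(n - 1)) * step, rep(0, n))
}

# small two-run ring table reused by several feature tests
small_ring <- function(seed = 7) {
  generate_ring(ring_config(group_sizes = c(6, 8), frames = 60, seed = seed))
}

# memoised heavier fixtures for the acceptance suite
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ring_fm <- function(seed) {
  cached(paste0("ring_fm_", seed), {
    build_feature_matrix(generate_ring(ring_config(seed = seed)))
  })
}

egress_embedding <- function(seed) {
  cached(paste0("egress_", seed), {
    tab <- generate_egress(egress_config(seed = seed))
    fm <- build_feature_matrix(tab)
    list(labels = outlier_labels(tab), fm = fm,
         emb = diffusion_map(fm, p = 10, K = 3, mode = "per_run"))
  })
}
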