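# hand-built feature_matrix-shaped object for unit tests
fm_of <- function(values, runs = rep("r1", nrow(values))) {
  colnames(values) <- feature_names()[seq_len(ncol(values))]
  structure(list(values = values,
                 meta = data.frame(run_id = runs,
                                   agent_id = sprintf("a%d", seq_len(nrow(values))),
                                   source = "test",
                                   stringsAsFactors = FALSE),
                 exclusions = data.frame()),
            class = "feature_matrix")
}

# a full-width feature matrix from two well-separated gaussian blobs
blob_fm <- function(n1, n2, gap = 60, seed = 1, runs = NULL) {
  set.seed(seed)
  v <- rbind(matrix(rnorm(n1 * 27), n1, 27),
             matrix(rnorm(n2 * 27), n2, 27) + gap)
  fm_of(v, runs = runs %||% rep("r1", n1 + n2))
}

test_that("standardisation yields per-group zero mean and unit sd", {
  fm <- fm_of(cbind(c(1, 3), c(5, 9)))
  sf <- standardise(fm, "global")
  expect_equal(sf$values[, 1], c(-1, 1))  # population sd of (1,3) is 1
  expect_equal(sf$values[, 2], c(-1, 1))

  fm <- ring_fm(1)
  for (mode in c("global", "per_run")) {
    sf <- standardise(fm, mode)
    groups <- if (mode == "global") rep("g", nrow(sf$values)) else
      sf$meta$run_id
    for (g in unique(groups)) {
      block <- sf$values[groups == g, , drop = FALSE]
      expect_lt(max(abs(colMeans(block))), 1e-10)
      expect_lt(max(abs(sqrt(colMeans(sweep(block, 2,
                                            colMeans(block))^2)) - 1)),
                1e-10)
    }
  }

  # standardising an already standardised matrix changes nothing
  sf <- standardise(fm, "global")
  sf2 <- standardise(structure(list(values = sf$values, meta = fm$meta,
                                    exclusions = fm$exclusions),
                               class = "feature_matrix"), "global")
  expect_equal(sf2$values, sf$values, tolerance = 1e-10)
})

test_that("constant columns and tiny groups are rejected by name", {
  v <- cbind(c(1, 2, 3), c(4, 4, 4))
  expect_error(standardise(fm_of(v), "global"), "aheadness_nn1_var")
  v <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_error(standardise(fm_of(v, runs = c("r1", "r1", "r2")), "per_run"),
               "fewer than 2 rows")
})

test_that("distance matrix matches the naive double loop", {
  fm <- fm_of(cbind(c(0, 3), c(0, 4)))
  D <- distance_matrix(fm$values)
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), c(0, 0))

  set.seed(3)
  v <- matrix(rnorm(3 * 27), 3, 27)
  D <- distance_matrix(v)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(D[i, j], sqrt(sum((v[i, ] - v[j, ])^2)), tolerance = 1e-12)
  }
  # identical rows have distance zero
  expect_equal(distance_matrix(v[c(1, 1), ])[1, 2], 0)
})

test_that("affinity is 1/d with symmetric top-p thresholding", {
  # 4 points on a line at 0, 1, 2, 10; p = 1 keeps the union of per-row bests
  D <- as.matrix(dist(c(0, 1, 2, 10)))
  net <- similarity(D, p = 1)
  C <- as.matrix(net$C)
  expect_equal(C[1, 2], 1)      # 1/d with d = 1
  expect_equal(C[3, 4], 1 / 8)
  expect_equal(C[2, 3], 1)
  expect_equal(C[1, 3], 0)      # not in either endpoint's top 1
  expect_equal(C[1, 4], 0)
  expect_equal(C[2, 4], 0)
  expect_true(Matrix::isSymmetric(net$C))
  expect_equal(unname(diag(C)), rep(0, 4))

  # duplicate rows hit the eps clamp instead of dividing by zero
  D2 <- as.matrix(dist(c(0, 0, 5)))
  net2 <- similarity(D2, p = 1)
  expect_equal(as.matrix(net2$C)[1, 2], 1e12)

  expect_error(similarity(D, p = 4), "degenerate")
  expect_error(similarity(D, p = 0), "positive")
})

test_that("every node keeps at least min(p, M-1) links", {
  set.seed(8)
  for (rep in 1:4) {
    M <- sample(30:80, 1)
    p <- sample(c(3, 10, 20), 1)
    D <- as.matrix(dist(matrix(rnorm(M * 5), M, 5)))
    net <- similarity(D, p = p)
    expect_gte(min(net$degrees), min(p, M - 1))
  }
})

test_that("the Laplacian is row-normalised with known small-graph spectra", {
  # path graph on 3 nodes, unit weights: eigenvalues 0, 1, 2
  C <- Matrix::Matrix(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                      sparse = TRUE)
  L <- laplacian(C)
  expect_equal(as.vector(L %*% rep(1, 3)), rep(0, 3), tolerance = 1e-14)
  expect_equal(sort(Re(eigen(as.matrix(L))$values)), c(0, 1, 2),
               tolerance = 1e-12)

  # single edge: closed form [[1,-1],[-1,1]]
  C2 <- Matrix::Matrix(rbind(c(0, 2), c(2, 0)), sparse = TRUE)
  L2 <- as.matrix(laplacian(C2))
  expect_equal(L2, rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)

  # isolated node is an error
  C3 <- Matrix::Matrix(diag(0, 3), sparse = TRUE)
  C3[1, 2] <- C3[2, 1] <- 1
  expect_error(laplacian(C3), "isolated")
})

test_that("embedding eigenpairs match the dense non-symmetric oracle", {
  fm <- ring_fm(1)
  net <- similarity(distance_matrix(standardise(fm, "global")), p = 20)
  emb <- embed(net, K = 3)
  oracle <- dense_rw_oracle(net$C)
  M <- nrow(net$C)
  expect_equal(emb$eigenvalues, oracle$values, tolerance = 1e-8)
  expect_equal(emb$zero_multiplicity, 1L)
  for (j in 1:3) {
    u <- oracle$vectors[, 1 + j]
    u <- u / sqrt(sum(u^2))
    if (u[which.max(abs(u))] < 0) u <- -u
    expect_equal(emb$vectors[, j], u, tolerance = 1e-8)
  }
  # spectrum bounds and unit-norm sign-fixed coordinates
  expect_true(all(emb$eigenvalues >= 0 & emb$eigenvalues <= 2 + 1e-8))
  expect_equal(colSums(emb$vectors^2), c(ev1 = 1, ev2 = 1, ev3 = 1))
  for (j in 1:3) {
    expect_gt(emb$vectors[which.max(abs(emb$vectors[, j])), j], 0)
  }
})

test_that("a disconnected network raises the advisory error with multiplicity", {
  fm <- blob_fm(30, 30)
  net <- similarity(distance_matrix(standardise(fm, "global")), p = 20)
  err <- tryCatch(embed(net, K = 3), pedmap_disconnected_error = identity)
  expect_s3_class(err, "pedmap_disconnected_error")
  expect_equal(err$zero_multiplicity, 2L)
  expect_match(conditionMessage(err), "larger p")
})

test_that("embedding is equivariant under row permutation", {
  fm <- blob_fm(25, 15, gap = 1, seed = 4)
  emb <- diffusion_map(fm, p = 8, K = 3)
  set.seed(99)
  perm <- sample(40)
  fmp <- fm_of(fm$values[perm, ])
  fmp$meta <- fm$meta[perm, ]
  emb_p <- diffusion_map(fmp, p = 8, K = 3)
  expect_equal(emb_p$eigenvalues, emb$eigenvalues, tolerance = 1e-9)
  expect_equal(emb_p$vectors, emb$vectors[perm, ], tolerance = 1e-8)
})

test_that("embedding csv/json export round-trips the coordinates", {
  fm <- blob_fm(20, 10, gap = 1, seed = 6)
  emb <- diffusion_map(fm, p = 5, K = 2)
  f <- tempfile(fileext = ".csv")
  write_embedding(emb, f)
  back <- utils::read.csv(f)
  expect_equal(back$ev1, unname(emb$vectors[, 1]), tolerance = 1e-12)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(side$p, 5)
  expect_equal(side$zero_multiplicity, 1)
  expect_equal(side$eigenvalues[1], 0, tolerance = 1e-10)
})
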