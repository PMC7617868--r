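test_that("aheadness and leftness are signed projections on the heading frame", {
  expect_equal(aheadness(c(0, 0), c(1, 0), c(2, 3)), 2)
  expect_equal(aheadness(c(0, 0), c(1, 0), c(-1, 0)), -1)
  expect_equal(aheadness(c(0, 0), c(0.6, 0.8), c(1, 1)), 1.4)
  expect_equal(leftness(c(0, 0), c(1, 0), c(2, 3)), 3)
  expect_equal(leftness(c(0, 0), c(0, 1), c(2, 3)), -2)
  expect_equal(leftness(c(0, 0), c(1, 1), c(2, 2)), 0)
  expect_error(aheadness(c(0, 0), c(0, 0), c(1, 1)), "zero heading")
})

test_that("adjacent angle is the clamped arccos of the heading cosine", {
  expect_equal(adjacent_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(adjacent_angle(c(2, 0), c(3, 0)), 0)
  expect_equal(adjacent_angle(c(1, 0), c(-1, 0)), pi)
  # numerically out-of-range cosines are clamped, not NaN
  v <- c(0.6, 0.8)
  expect_false(is.nan(adjacent_angle(v, v * (1 + 1e-16))))
})

test_that("angle difference matches the analytic value for a constant turn", {
  # heading rotates by 0.1 rad per frame; k-step difference is 0.1 * k
  n <- 40
  theta <- 0.1 * (0:(n - 1))
  traj <- data.frame(frame = 0:(n - 1), dx = cos(theta), dy = sin(theta))
  expect_equal(angle_difference(traj, frame = 20, k = 5), 0.5,
               tolerance = 1e-12)
  expect_equal(angle_difference(traj, frame = 30, k = 20), 2.0,
               tolerance = 1e-12)
  # straight walker turns by 0
  s <- derive_directions(straight_walker())
  st <- as.data.frame(s)[s$agent_id == "a1", ]
  expect_equal(angle_difference(st, frame = 10, k = 5), 0)
  # undefined before k frames have elapsed
  expect_true(is.na(angle_difference(st, frame = 3, k = 5)))
})

test_that("travel distance sums path length, not displacement", {
  s <- straight_walker(n = 30, step = 0.05)
  st <- as.data.frame(derive_directions(s))
  expect_equal(travel_distance(st, frame = 25, k = 20), 1.0)
  expect_true(is.na(travel_distance(st, frame = 10, k = 20)))
  # back-and-forth between two points 1 m apart: path length 20, not 0
  n <- 41
  bf <- data.frame(frame = 0:(n - 1), x = rep(c(0, 1), length.out = n),
                   y = 0)
  expect_equal(travel_distance(bf, frame = 40, k = 20), 20)
  # stationary spell contributes zero
  still <- data.frame(frame = 0:25, x = rep(3, 26), y = rep(4, 26))
  expect_equal(travel_distance(still, frame = 25, k = 20), 0)
})

test_that("nearest neighbours are distance-ordered with id tie-breaks", {
  tab <- make_traj("r", c("i", "b", "c", "d", "e"), 0,
                   c(0, 1, 2, 3, 4), rep(0, 5))
  expect_equal(nearest_neighbours(tab, "r", "i", 0), c("b", "c", "d"))

  # equidistant neighbours: lower agent id wins
  tab <- make_traj("r", c("i", "q", "b"), 0, c(0, 1, -1), rep(0, 3))
  expect_equal(nearest_neighbours(tab, "r", "i", 0)[1:2], c("b", "q"))

  # fewer than three co-present agents leaves ranks absent
  tab <- make_traj("r", c("i", "b"), 0, c(0, 1), c(0, 0))
  expect_equal(nearest_neighbours(tab, "r", "i", 0), c("b", NA, NA))

  # random configurations agree with a brute-force sort
  set.seed(5)
  for (rep in 1:5) {
    m <- 7
    xy <- matrix(sample(0:3, 2 * m, replace = TRUE), m, 2) # forced ties
    ids <- sprintf("a%d", 1:m)
    tab <- make_traj("r", ids, 0, xy[, 1], xy[, 2])
    got <- nearest_neighbours(tab, "r", "a1", 0)
    d <- sqrt((xy[-1, 1] - xy[1, 1])^2 + (xy[-1, 2] - xy[1, 2])^2)
    want <- ids[-1][order(d, ids[-1])][1:3]
    expect_equal(got, want)
  }
})

test_that("per-frame features respect the neighbour distance ordering", {
  tab <- derive_directions(small_ring())
  pff <- per_frame_features(tab, tab$run_id[1], tab$agent_id[1])
  ok <- !is.na(pff$d1) & !is.na(pff$d2) & !is.na(pff$d3)
  expect_true(any(ok))
  expect_true(all(pff$d1[ok] <= pff$d2[ok]))
  expect_true(all(pff$d2[ok] <= pff$d3[ok]))
  expect_true(all(pff$g1[!is.na(pff$g1)] >= 0 &
                    pff$g1[!is.na(pff$g1)] <= pi))
  expect_true(all(pff$s20[!is.na(pff$s20)] >= 0))
})

test_that("summaries use population variance over defined frames", {
  pff <- data.frame(frame = 0:1)
  for (s in c(t(outer(c("h", "l", "d", "g"), 1:3, paste0)),
              paste0("a", c(1, 5, 10, 20)), "s20")) {
    pff[[s]] <- c(1, 3)
  }
  row <- summarise_features(pff)
  expect_equal(unname(row["aheadness_nn1_mean"]), 2)
  expect_equal(unname(row["aheadness_nn1_var"]), 1)   # population: /n
  expect_equal(unname(row["travel_dist_k20_mean"]), 2)
  expect_named(row, feature_names())

  pff$s20 <- NA_real_
  expect_error(summarise_features(pff), "s20")
})

test_that("feature matrix has the canonical 27 columns and excludes short tracks", {
  tab <- small_ring()
  fm <- build_feature_matrix(tab)
  expect_identical(colnames(fm$values), feature_names())
  expect_equal(ncol(fm$values), 27L)
  expect_equal(nrow(fm$values), 14L)  # 6 + 8 agents, all eligible
  expect_false(anyNA(fm$values))

  # a 10-frame trajectory can never define the 20-step features
  short <- make_traj("r", rep(c("a", "b", "c", "d"), each = 10),
                     rep(0:9, 4), rep(1:4, each = 10) + rep(0:9, 4) * 0.1,
                     rep(1:4, each = 10))
  expect_error(build_feature_matrix(short), "no agents retained")

  # three co-present agents leave rank-3 features undefined for everyone
  three <- make_traj("r", rep(c("a", "b", "c"), each = 25), rep(0:24, 3),
                     rep(c(0, 1, 2), each = 25) + rep(0:24, 3) * 0.1,
                     rep(c(0, 1, 2), each = 25))
  expect_error(build_feature_matrix(three), "no agents retained")
})

test_that("bulk feature extraction equals the naive all-pairs oracle", {
  tab <- derive_directions(small_ring(seed = 3))
  fm <- build_feature_matrix(tab)
  oracle <- naive_feature_matrix(as.data.frame(tab))
  expect_equal(fm$meta$run_id, oracle$meta$run_id)
  expect_equal(fm$meta$agent_id, oracle$meta$agent_id)
  expect_equal(fm$values, oracle$values, tolerance = 1e-12)
})

test_that("features are invariant under translation and rotation, and leftness flips under reflection", {
  tab <- derive_directions(small_ring(seed = 9))
  fm0 <- build_feature_matrix(tab)

  # global translation
  tr <- tab
  tr$x <- tr$x + 13.7
  tr$y <- tr$y - 4.2
  fm_t <- build_feature_matrix(derive_directions(tr))
  expect_equal(fm_t$values, fm0$values, tolerance = 1e-9)

  # global rotation
  th <- 0.83
  ro <- tab
  ro$x <- cos(th) * tab$x - sin(th) * tab$y
  ro$y <- sin(th) * tab$x + cos(th) * tab$y
  fm_r <- build_feature_matrix(derive_directions(ro))
  expect_equal(fm_r$values, fm0$values, tolerance = 1e-9)

  # reflection: every leftness column changes sign, everything else is fixed
  rf <- tab
  rf$y <- -tab$y
  fm_m <- build_feature_matrix(derive_directions(rf))
  left_mean <- grep("^leftness_nn[123]_mean$", feature_names())
  left_var <- grep("^leftness_nn[123]_var$", feature_names())
  expect_equal(fm_m$values[, left_mean], -fm0$values[, left_mean],
               tolerance = 1e-9)
  expect_equal(fm_m$values[, left_var], fm0$values[, left_var],
               tolerance = 1e-9)
  other <- setdiff(seq_len(27), left_mean)
  expect_equal(fm_m$values[, other], fm0$values[, other], tolerance = 1e-9)
})
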