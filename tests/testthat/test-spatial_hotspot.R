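test_that("queen and rook contiguity counts match hand enumeration", {
  w <- grid_weights(2, 2, "queen")
  expect_equal(vapply(w$neighbors, length, integer(1)), rep(3L, 4))
  w2 <- grid_weights(1, 3, "rook")
  expect_equal(vapply(w2$neighbors, length, integer(1)), c(1L, 2L, 1L))
  # symmetry
  for (i in seq_len(w$n)) {
    for (j in w$neighbors[[i]]) expect_true(i %in% w$neighbors[[j]])
  }
})

test_that("polygon-derived and explicit edge-list weights coincide", {
  ids <- sprintf("g%02d", 1:12)
  feats <- grid_features(3, 4, ids)
  for (rule in c("queen", "rook")) {
    from_geom <- geometry_adjacency(feats, rule)
    from_list <- grid_adjacency(3, 4, ids, rule)
    key <- function(a) sort(paste(pmin(a$from, a$to), pmax(a$from, a$to)))
    expect_equal(key(from_geom), key(from_list))
  }
})

test_that("raw Gi* shares match a dense-matrix summation oracle", {
  w <- grid_weights(3, 3)
  set.seed(8)
  x <- rlnorm(9)
  x[5] <- x[5] + 10                    # spiked centre
  expect_equal(gi_star(x, w), gi_star_dense(x, w))
  # literal self-exclusive variant too
  w0 <- grid_weights(3, 3, include_self = FALSE)
  expect_equal(gi_star(x, w0), gi_star_dense(x, w0))
})

test_that("complete self-inclusive graph yields share 1 everywhere", {
  ids <- letters[1:5]
  pairs <- t(utils::combn(ids, 2))
  w <- contiguity_weights(data.frame(from = pairs[, 1], to = pairs[, 2]),
                          ids = ids)
  expect_equal(gi_star(runif(5), w), rep(1, 5))
})

test_that("an isolated unit's share is its own value over the total", {
  ids <- c("a", "b", "c")
  expect_warning(
    w <- contiguity_weights(data.frame(from = "a", to = "b"), ids = ids),
    "isolated")
  x <- c(1, 2, 3)
  expect_equal(gi_star(x, w)[3], 3 / 6)
  expect_error(gi_star(c(0, 0, 0), w), "zero")
})

test_that("z-scores are location-invariant and label-equivariant", {
  w <- grid_weights(4, 4)
  set.seed(9)
  x <- rnorm(16)
  z <- gi_star_z(x, w)
  expect_equal(gi_star_z(x + 100, w), z)
  # permute unit labels together with the weights: z permutes alongside
  perm <- sample(16)
  ids <- w$ids
  adj <- grid_adjacency(4, 4, ids)
  adj_p <- data.frame(from = ids[perm][match(adj$from, ids)],
                      to = ids[perm][match(adj$to, ids)])
  w_p <- contiguity_weights(adj_p, ids = ids)
  x_p <- numeric(16)
  x_p[perm] <- x
  expect_equal(gi_star_z(x_p, w_p)[perm], z)
})

test_that("a constant surface gives all-zero z with a warning", {
  w <- grid_weights(3, 3)
  expect_warning(z <- gi_star_z(rep(2, 9), w), "constant")
  expect_equal(z, rep(0, 9))
  expect_equal(permutation_test(rep(2, 9), w, 99, seed = 1), rep(1, 9))
})

test_that("permutation p-values are deterministic given the seed", {
  w <- grid_weights(4, 4)
  set.seed(10)
  x <- rlnorm(16)
  p1 <- permutation_test(x, w, 199, seed = 77)
  p2 <- permutation_test(x, w, 199, seed = 77)
  expect_identical(p1, p2)
  expect_error(permutation_test(x, w, 50, seed = 1), ">= 99")
})

test_that("a planted hot cluster is significant for its neighbourhood", {
  # a strong signal for conditional permutation inference is a spiked
  # neighbourhood (a lone spiked cell re-enters the conditional null
  # through the resampled values and so can never be extreme)
  w <- grid_weights(5, 5)
  set.seed(11)
  x <- rnorm(25, mean = 10, sd = 0.5)
  nbhd <- c(13, w$neighbors[[13]])     # centre cell plus its 8 neighbours
  x[nbhd] <- x[nbhd] + 25
  p <- permutation_test(x, w, 999, seed = 3)
  z <- gi_star_z(x, w)
  # the centre's whole neighbourhood is elevated: minimal attainable p
  expect_equal(p[13], 1 / 1000)
  expect_true(all(z[nbhd] > 0))
  expect_equal(which.max(z), 13L)      # the fully-elevated neighbourhood
})

test_that("analytic z agrees with the permutation null on a 3x3 spike", {
  w <- grid_weights(3, 3)
  set.seed(12)
  x <- rnorm(9, 5, 0.5)
  x[1] <- 15
  z <- gi_star_z(x, w)
  p <- permutation_test(x, w, 9999, seed = 4)
  p_norm <- 2 * stats::pnorm(-abs(z))
  # same significance direction on every unit at the 10% level, and the
  # permutation rank reproduces the analytic tail within Monte-Carlo error
  for (i in seq_len(9)) {
    if (abs(z[i]) > 2) expect_lt(p[i], 0.1)
    if (abs(z[i]) < 0.5) expect_gt(p[i], 0.1)
  }
})

test_that("four-class hotspot labels follow the z ordering", {
  z <- c(-3, -2.9, -0.1, 0.1, 2.9, 3)
  lab <- classify_hotspots(z)
  expect_equal(as.character(lab),
               c("cold", "cold", "sub_cold", "sub_hot", "hot", "hot"))
  # order invariance
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(as.character(classify_hotspots(z[perm])),
               as.character(lab)[perm])
  # 4 distinct values -> each its own class
  expect_equal(as.integer(classify_hotspots(c(-2, -1, 1, 2))), 1:4)
  expect_error(classify_hotspots(c(1, 1, 2, 2)), "distinct")
  # fixed-cutoff mode
  expect_equal(as.character(classify_hotspots(c(-2, -1, 1, 2),
                                              method = "cutoff")),
               c("cold", "sub_cold", "sub_hot", "hot"))
})
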