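test_that("identical normalized systems give unit coefficients throughout", {
  k <- 8
  set.seed(13)
  X <- matrix(minmax_normalize(runif(k)), ncol = 1)
  expect_message(R <- relation_coefficients(X, X), "identical")
  expect_equal(R, array(1, c(1, 1, k)), ignore_attr = TRUE)
  gamma <- relation_grades(R)
  expect_equal(unname(gamma[1, 1]), 1)
  expect_equal(system_coupling_degree(gamma), 1)
})

test_that("the two-city hand case gives R = (1, 1/3) and gamma = 2/3", {
  X <- matrix(c(0, 1), ncol = 1)
  Y <- matrix(c(0, 0.5), ncol = 1)
  R <- relation_coefficients(X, Y, rho = 0.5)
  expect_equal(as.vector(R), c(1, 1 / 3))
  expect_equal(unname(relation_grades(R)[1, 1]), 2 / 3)
})

test_that("coefficients respect the rho/(1+rho) floor when dmin = 0", {
  set.seed(14)
  for (rep in 1:50) {
    k <- sample(3:15, 1); l <- sample(1:3, 1); m <- sample(1:4, 1)
    X <- matrix(runif(k * l), k, l)
    Y <- matrix(runif(k * m), k, m)
    # pin the global minimum difference at zero
    Y[1, 1] <- X[1, 1]
    X <- apply(X, 2, minmax_normalize)
    Y <- apply(Y, 2, minmax_normalize)
    # re-pin after normalization (columns rescale independently)
    Y[, 1] <- X[, 1]
    R <- suppressMessages(relation_coefficients(X, Y, rho = 0.5))
    expect_true(all(R >= 1 / 3 - 1e-12 & R <= 1 + 1e-12))
    # brute-force scan oracle for the normalizing constants
    dl <- array(0, c(l, m, k))
    for (i in seq_len(l)) for (j in seq_len(m)) for (c in seq_len(k)) {
      dl[i, j, c] <- abs(X[c, i] - Y[c, j])
    }
    if (max(dl) == 0) {
      expect_true(all(R == 1))         # identical systems convention
    } else {
      expect_equal(unname(R),
                   (min(dl) + 0.5 * max(dl)) / (dl + 0.5 * max(dl)))
    }
  }
})

test_that("grade aggregation means match hand computation", {
  gamma <- matrix(c(0.5, 0.6, 0.7, 0.8, 0.55, 0.65, 0.75, 0.85),
                  nrow = 2, byrow = TRUE)
  d <- indicator_mean_grades(gamma)
  expect_equal(unname(d$d_demand), c(mean(gamma[1, ]), mean(gamma[2, ])))
  expect_equal(unname(d$d_supply), colMeans(gamma))
  expect_equal(system_coupling_degree(matrix(c(0.5, 0.6, 0.7, 0.8), 2)),
               0.65)
  # grand-mean consistency
  expect_equal(mean(d$d_demand), system_coupling_degree(gamma),
               tolerance = 1e-12)
  expect_equal(mean(d$d_supply), system_coupling_degree(gamma),
               tolerance = 1e-12)
  # constant gamma propagates
  expect_equal(unname(indicator_mean_grades(matrix(0.4, 3, 2))$d_demand),
               rep(0.4, 3))
})

test_that("correlation categories follow the defined intervals", {
  expect_equal(as.character(classify_correlation(0.6661)),
               "relatively_high")
  expect_equal(as.character(classify_correlation(0.85)), "relatively_high")
  expect_equal(as.character(classify_correlation(0.2)), "low")
  expect_equal(as.character(classify_correlation(0.9)), "high")
  expect_equal(as.character(classify_correlation(0.35)), "low")
  expect_equal(as.character(classify_correlation(1)), "high")
  expect_error(classify_correlation(0), "\\(0, 1\\]")
  expect_error(classify_correlation(1.2), "\\(0, 1\\]")
})

test_that("coupling degree is monotone non-decreasing in rho", {
  set.seed(15)
  X <- matrix(runif(20 * 2), 20, 2)
  Y <- matrix(runif(20 * 4), 20, 4)
  X <- apply(X, 2, minmax_normalize)
  Y <- apply(Y, 2, minmax_normalize)
  Cs <- vapply(seq(0.05, 1, by = 0.05), function(rho) {
    system_coupling_degree(relation_grades(
      relation_coefficients(X, Y, rho)))
  }, numeric(1))
  expect_true(all(diff(Cs) >= -1e-12))
})

test_that("coupling rises to 1 as supply converges onto demand", {
  set.seed(16)
  k <- 15
  X <- matrix(runif(k), ncol = 1)
  E <- matrix(runif(2 * k, -0.3, 0.3), ncol = 2)
  Y0 <- pmin(pmax(cbind(X[, 1], X[, 1]) + E, 0), 1)
  resid <- apply(abs(Y0 - cbind(X[, 1], X[, 1])), 1, max)
  ord <- order(resid)
  Y0[ord[1], ] <- X[ord[1], 1]         # pin dmin at 0 from the start
  Cs <- vapply(0:k, function(s) {
    Y <- Y0
    if (s > 0) Y[ord[seq_len(s)], ] <- X[ord[seq_len(s)], 1]
    suppressMessages(system_coupling_degree(
      relation_grades(relation_coefficients(X, Y))))
  }, numeric(1))
  expect_true(all(diff(Cs) >= -1e-12))
  expect_equal(Cs[k + 1], 1)
})

test_that("the full grey analysis is indicator-relabel invariant", {
  ind <- build_indicators(default_yrd_like(4))
  g <- grey_coupling(ind)
  # reordering supply indicators permutes gamma columns, leaves C fixed
  ind2 <- ind[c("id", "X1", "X2", "Y3", "Y1", "Y4", "Y2")]
  names(ind2) <- c("id", "X1", "X2", "Y1", "Y2", "Y3", "Y4")
  g2 <- grey_coupling(ind2)
  expect_equal(g2$C, g$C)
  expect_equal(unname(g2$gamma[, c(2, 4, 1, 3)]), unname(g$gamma))
  # structure invariants
  expect_true(all(g$R > 0 & g$R <= 1))
  expect_equal(mean(g$gamma), g$C)
  expect_equal(mean(g$d_demand), g$C)
  expect_equal(mean(g$d_supply), g$C)
  expect_equal(nrow(g$per_city), 41)
  expect_equal(mean(g$per_city$coupling), g$C, tolerance = 1e-12)
})
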