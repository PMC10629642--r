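test_that("coordination closed forms hold", {
  expect_equal(coupling_coordination(0.5, 0.5), 1)
  expect_equal(coupling_coordination(0, 0.7), 0)
  expect_equal(coupling_coordination(0.2, 0.8), 0.8)
  expect_equal(coupling_coordination(0, 0), 1)   # balanced degenerate pair
  expect_error(coupling_coordination(-0.1, 0.5), "non-negative")
})

test_that("coordination is symmetric, bounded, and unimodal in y", {
  set.seed(17)
  x <- runif(2000); y <- runif(2000)
  C <- coupling_coordination(x, y)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(coupling_coordination(y, x), C)
  expect_equal(coupling_coordination(x, x), rep(1, 2000))
  # for fixed x, strictly increasing below x, strictly decreasing above
  for (x0 in c(0.2, 0.5, 0.9)) {
    below <- coupling_coordination(rep(x0, 50), seq(0.001, x0, length = 50))
    above <- coupling_coordination(rep(x0, 50), seq(x0, 3, length = 50))
    expect_true(all(diff(below) > 0))
    expect_true(all(diff(above) < 0))
  }
})

test_that("the coordination matrix matches a spreadsheet-style oracle", {
  ind <- data.frame(
    id = sprintf("c%02d", 1:6),
    X1 = c(8, 12, 14, 17, 20, 22),
    X2 = c(10, 15, 18, 22, 26, 29),
    Y1 = c(0.6, 1.1, 0.9, 1.5, 0.7, 2.0),
    Y2 = c(50, 120, 90, 300, 60, 400),
    Y3 = c(900, 2100, 1500, 3800, 1200, 5000),
    Y4 = c(200, 320, 260, 450, 210, 560))
  m <- suppressWarnings(match_resources(ind))
  # independent recomputation with plain arithmetic
  nrm <- function(v) (v - min(v)) / (max(v) - min(v))
  x <- nrm(ind$X1)
  for (col in c("Y1", "Y2", "Y3", "Y4")) {
    y <- nrm(ind[[col]])
    s <- x + y
    expected <- ifelse(s > 0, 2 * sqrt(x * y) / s, 1)
    expect_equal(unname(m$C_matrix[, col]), pmin(expected, 1))
  }
})

test_that("city order does not affect per-city results", {
  ind <- build_indicators(default_yrd_like(6))
  m1 <- match_resources(ind)
  perm <- sample(nrow(ind))
  m2 <- match_resources(ind[perm, ])
  expect_equal(m2$C_matrix[ind$id, ], m1$C_matrix[ind$id, ])
})

test_that("five-class matching matches the exhaustive breaks oracle", {
  v <- c(0.05, 0.1, 0.3, 0.35, 0.6, 0.65, 0.85, 0.9, 0.99, 1.0)
  lab <- classify_matching(v)
  ex <- exhaustive_jenks(v, 5)
  expect_equal(jenks_breaks(v, 5)$ssd, ex$ssd)
  # the two highest values share the top class
  expect_equal(as.character(lab[v >= 0.99]),
               c("high_match", "high_match"))
  # monotone: sorting input ascending yields non-decreasing labels
  expect_false(is.unsorted(lab[order(v)]))
})

test_that("five tight clusters fill all five classes", {
  set.seed(18)
  v <- pmin(pmax(rep(c(0.05, 0.3, 0.55, 0.8, 0.98), each = 6) +
                   rnorm(30, sd = 0.01), 0), 1)
  lab <- classify_matching(v)
  expect_equal(sort(unique(as.character(lab))),
               sort(c("severe_mismatch", "general_mismatch",
                      "barely_matched", "intermediate_match",
                      "high_match")))
})

test_that("degenerate columns fall back to absolute-scale labels", {
  expect_warning(hi <- classify_matching(rep(1, 8)), "distinct")
  expect_true(all(hi == "high_match"))
  expect_warning(lo <- classify_matching(rep(0.02, 8)), "distinct")
  expect_true(all(lo == "severe_mismatch"))
  # sub-precision jitter is treated as ties, not classes
  expect_warning(j <- classify_matching(1 - abs(rnorm(8, sd = 1e-8))),
                 "distinct")
  expect_true(all(j == "high_match"))
})

test_that("proportional supply is uniformly high-matched", {
  ind <- build_indicators(default_yrd_like(8, beta = rep(1, 4),
                                           sigma = rep(0, 4),
                                           integer_counts = FALSE))
  m <- suppressWarnings(match_resources(ind))
  expect_equal(unname(m$C_matrix), matrix(1, 41, 4), tolerance = 1e-9)
  expect_true(all(vapply(m$match_class,
                         function(x) all(x == "high_match"), logical(1))))
})

test_that("noisier supply yields more severely mismatched cities", {
  count_severe <- function(sigma) {
    mean(vapply(1:20, function(seed) {
      ind <- build_indicators(default_yrd_like(seed, beta = rep(1, 4),
                                               sigma = rep(sigma, 4)))
      m <- suppressWarnings(match_resources(ind))
      sum(vapply(m$match_class, function(x) sum(x == "severe_mismatch"),
                 numeric(1)))
    }, numeric(1)))
  }
  expect_gt(count_severe(0.8), count_severe(0.05))
})
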