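# shared fixtures and independent oracles used across test files

make_city <- function(id = "c01", name = "A", land_area = 100,
                      pop_total = 10000, pop_65plus = 1500,
                      pop_15_64 = 6000, facilities = 2, green_space = 30,
                      insured = 400, beds = 50) {
  data.frame(id = id, name = name, land_area = land_area,
             pop_total = pop_total, pop_65plus = pop_65plus,
             pop_15_64 = pop_15_64, facilities = facilities,
             green_space = green_space, insured = insured, beds = beds,
             stringsAsFactors = FALSE)
}

make_cities3 <- function() {
  rbind(make_city("c01", "A"),
        make_city("c02", "B", pop_total = 20000, pop_65plus = 4000,
                  pop_15_64 = 12000, beds = 120),
        make_city("c03", "C", pop_total = 5000, pop_65plus = 400,
                  pop_15_64 = 3500, facilities = 1))
}

adj3 <- function() data.frame(from = c("c01", "c02"), to = c("c02", "c03"))

# exhaustive natural-breaks oracle: enumerate every placement of k - 1
# interior breaks over the sorted values and minimize total within-class SSD
ssd_of <- function(g) sum((g - mean(g))^2)

exhaustive_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  if (k == 1) return(list(ssd = ssd_of(x), ends = n))
  best <- Inf
  best_ends <- NULL
  combos <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(combos))) {
    ends <- c(combos[, ci], n)
    starts <- c(1, head(ends, -1) + 1)
    tot <- sum(mapply(function(a, b) ssd_of(x[a:b]), starts, ends))
    if (tot < best - 1e-12) {          # ties toward lowest-index break
      best <- tot
      best_ends <- ends
    }
  }
  list(ssd = best, ends = best_ends)
}

grid_weights <- function(rows, cols, rule = "queen", include_self = TRUE) {
  ids <- sprintf("g%02d", seq_len(rows * cols))
  contiguity_weights(grid_adjacency(rows, cols, ids, rule), ids = ids,
                     include_self = include_self)
}

# dense-matrix Gi* oracle: explicit W matrix and direct summation
gi_star_dense <- function(values, w) {
  n <- w$n
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, w$neighbors[[i]]] <- 1
  if (w$include_self) diag(W) <- 1
  num <- as.vector(W %*% values)
  den <- if (w$include_self) sum(values) else sum(values) - values
  num / den
}
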