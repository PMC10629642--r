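#' Range-method (min-max) normalization
#'
#' Rescales each column of an indicator matrix to \code{[0, 1]} by the range
#' method: positive-oriented columns map \code{v -> (v - min) / (max - min)},
#' negative-oriented columns map \code{v -> (max - v) / (max - min)}.  All
#' indicators in the aging/elderly-care coupling system are positive-oriented
#' (more is "larger"); the orientation argument exists for reuse.
#'
#' @param x numeric vector, matrix, or data frame of indicator columns.
#' @param orientation character vector, one of \code{"positive"} or
#'   \code{"negative"} per column (recycled if length 1).
#' @param constant character; what to do with a zero-range column:
#'   \code{"error"} (default) or \code{"half"} which emits 0.5 for every
#'   entry of that column.
#' @return object of the same shape as \code{x} with every column in
#'   \code{[0, 1]}; column minima map to 0 and maxima to 1 exactly.
#' @examples
#' minmax_normalize(c(2, 4, 6))              # 0, 0.5, 1
#' minmax_normalize(cbind(a = 1:3, b = c(10, 0, 5)))
#' @export
minmax_normalize <- function(x, orientation = "positive",
                             constant = c("error", "half")) {
  constant <- match.arg(constant)
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("`x` must be numeric", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("`x` contains non-finite values", call. = FALSE)
  }
  orientation <- rep_len(orientation, ncol(m))
  if (!all(orientation %in% c("positive", "negative"))) {
    stop("orientation must be \"positive\" or \"negative\"", call. = FALSE)
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    if (hi == lo) {
      if (constant == "error") {
        stop("column ", colnames(m)[j] %||% j,
             " is constant; range normalization is degenerate", call. = FALSE)
      }
      out[, j] <- 0.5
    } else if (orientation[j] == "positive") {
      out[, j] <- (m[, j] - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - m[, j]) / (hi - lo)
    }
  }
  if (vec) out[, 1L, drop = TRUE] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Jenks natural-breaks classification
#'
#' Computes the optimal partition of a numeric vector into \code{k} ordered
#' classes minimizing the total within-class sum of squared deviations from
#' the class means (Fisher's optimal partition, the exact form of Jenks
#' natural breaks).  The dynamic program is exact and deterministic: when two
#' break placements achieve the same objective, the one with the lower break
#' index is kept.
#'
#' @param values numeric vector; the number of distinct values must be at
#'   least \code{k}.
#' @param k number of classes (>= 1).
#' @param labels optional character vector of \code{k} ordered class labels
#'   (lowest class first); defaults to \code{"class_1" ... "class_k"}.
#' @return an object of class \code{class_breaks}: a list with \code{k},
#'   \code{breaks} (the \code{k - 1} interior boundary values, each the
#'   maximum of its lower class), \code{labels}, \code{range} (data min and
#'   max), \code{interval_convention} (\code{"left_open_right_closed"}:
#'   intervals reported in the form \code{(a < v <= b]}), \code{ssd} (the
#'   optimal objective) and \code{gvf} (goodness of variance fit).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
#' @export
jenks_breaks <- function(values, k, labels = NULL) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  n_distinct <- length(unique(values))
  if (k > n_distinct) {
    stop("cannot form ", k, " classes from ", n_distinct,
         " distinct values; use fewer classes", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("class_", seq_len(k))
  if (length(labels) != k) stop("`labels` must have length k", call. = FALSE)

  x <- sort(unname(values))
  n <- length(x)
  # prefix sums for O(1) within-class SSD of x[(a+1)..b]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  ssd_seg <- function(a, b) {           # a, b are 1-based, a <= b
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    s2 - s^2 / (b - a + 1)
  }

  # D[i, j]: minimal SSD of x[1..i] in j classes; B[i, j]: end of class j-1
  D <- matrix(Inf, n, k)
  B <- matrix(0L, n, k)
  for (i in seq_len(n)) D[i, 1L] <- ssd_seg(1L, i)
  if (k > 1) {
    for (j in 2:k) {
      for (i in j:n) {
        best <- Inf; arg <- 0L
        for (b in (j - 1L):(i - 1L)) {
          cost <- D[b, j - 1L] + ssd_seg(b + 1L, i)
          if (cost < best - 1e-12) {    # strict improvement keeps lowest break
            best <- cost; arg <- b
          }
        }
        D[i, j] <- best
        B[i, j] <- arg
      }
    }
  }

  # backtrack class boundaries (indices of last member of each class)
  ends <- integer(k)
  ends[k] <- n
  if (k > 1) {
    for (j in k:2) ends[j - 1L] <- B[ends[j], j]
  }
  interior <- if (k > 1) x[ends[-k]] else numeric(0)

  total_ssd <- ssd_seg(1L, n)
  structure(
    list(k = k,
         breaks = interior,
         labels = labels,
         range = c(min = x[1L], max = x[n]),
         interval_convention = "left_open_right_closed",
         ssd = D[n, k],
         gvf = if (total_ssd > 0) 1 - D[n, k] / total_ssd else 1),
    class = "class_breaks")
}

#' @export
print.class_breaks <- function(x, ...) {
  cat("Natural-breaks classification:", x$k, "classes\n")
  bounds <- format(c(x$range[["min"]], x$breaks, x$range[["max"]]),
                   digits = 6, trim = TRUE)
  for (i in seq_len(x$k)) {
    open <- if (i == 1) "[" else "("
    cat(sprintf("  %-20s %s%s, %s]\n", x$labels[i], open,
                bounds[i], bounds[i + 1L]))
  }
  cat(sprintf("  goodness of variance fit: %.4f\n", x$gvf))
  invisible(x)
}

#' Classify values by fitted class breaks
#'
#' Assigns each value the label of the interval containing it.  Intervals
#' are left-open/right-closed, \code{(a, b]}, except the lowest interval
#' which is closed at the data minimum, so a value equal to an interior
#' break falls in the lower class.
#'
#' @param values numeric vector to classify.
#' @param breaks a \code{class_breaks} object from [jenks_breaks()].
#' @param clamp if \code{TRUE}, values outside the fitted range are assigned
#'   the extreme classes; if \code{FALSE} (default) they raise an error.
#' @return factor of class labels, ordered lowest to highest.
#' @export
classify_by_breaks <- function(values, breaks, clamp = FALSE) {
  stopifnot(inherits(breaks, "class_breaks"))
  lo <- breaks$range[["min"]]; hi <- breaks$range[["max"]]
  eps <- 1e-12
  if (!clamp && any(values < lo - eps | values > hi + eps)) {
    bad <- which(values < lo - eps | values > hi + eps)[1L]
    stop("value ", values[bad], " lies outside the fitted range [",
         lo, ", ", hi, "]; use clamp = TRUE to truncate", call. = FALSE)
  }
  v <- pmin(pmax(values, lo), hi)
  # (lo, b1], (b1, b2], ..., (b_{k-1}, hi]; lowest closed at lo
  idx <- rep.int(1L, length(v))
  for (b in breaks$breaks) idx <- idx + (v > b + eps)
  factor(breaks$labels[idx], levels = breaks$labels, ordered = TRUE)
}

#' Goodness of variance fit of a classification
#'
#' \code{1 - SSD_within / SSD_total}; 1 means each class is internally
#' homogeneous, 0 means classification explains no variance.
#'
#' @param values numeric vector.
#' @param breaks a \code{class_breaks} object covering the values.
#' @return scalar in \code{[0, 1]}.
#' @export
goodness_of_variance_fit <- function(values, breaks) {
  lab <- classify_by_breaks(values, breaks, clamp = TRUE)
  total <- sum((values - mean(values))^2)
  if (total == 0) return(1)
  within <- sum(vapply(split(values, lab), function(g) {
    if (length(g)) sum((g - mean(g))^2) else 0
  }, numeric(1)))
  1 - within / total
}
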