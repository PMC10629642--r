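MATCHING_CLASSES <- c("severe_mismatch", "general_mismatch",
                      "barely_matched", "intermediate_match", "high_match")

# coordination values are carried at 4 decimal places for reporting and
# classification; differences below that precision are treated as ties
.coord_digits <- 4

#' Coupling-coordination (spatial adaptation) value
#'
#' The two-system coupling degree between a normalized demand level x and
#' a normalized supply level y:
#' \deqn{C = \frac{2\sqrt{xy}}{x + y}}
#' C is symmetric, lies in \code{[0, 1]} (AM-GM), equals 1 exactly when
#' \code{x == y} (balanced supply and demand, including the degenerate
#' no-demand/no-supply pair 0, 0), and drops to 0 when exactly one side
#' vanishes.  For fixed x > 0 it increases strictly in y on \code{(0, x]}
#' and decreases strictly on \code{[x, Inf)}: mismatch in either direction
#' lowers C.
#'
#' @param x,y non-negative numeric vectors (normalized demand and supply).
#' @return coordination value(s) in \code{[0, 1]}.
#' @export
coupling_coordination <- function(x, y) {
  if (any(x < 0) || any(y < 0)) {
    stop("demand and supply levels must be non-negative", call. = FALSE)
  }
  s <- x + y
  out <- ifelse(s > 0, 2 * sqrt(x * y) / s, 1)
  # guard against floating overshoot when x == y
  pmin(out, 1)
}

#' Five-class matching labels for a coordination column
#'
#' Classifies per-city coordination values into severe_mismatch <
#' general_mismatch < barely_matched < intermediate_match < high_match by
#' exact natural breaks.  Values are first rounded to 4 decimals (the
#' reporting precision of coordination values), so sub-precision jitter
#' does not manufacture classes.  When fewer distinct values than classes
#' remain, the column is classified with that many natural-breaks classes
#' and each class is labelled by the position of its mean on the absolute
#' \code{[0, 1]} coordination scale (equal quintiles), with a warning --
#' a column of all-1 values is then uniformly high_match, a column of
#' near-zero values uniformly severe_mismatch.
#'
#' @param C_column numeric vector of coordination values in \code{[0, 1]}.
#' @param k target class count, default 5.
#' @return ordered factor with the five matching levels.
#' @export
classify_matching <- function(C_column, k = 5) {
  if (any(!is.finite(C_column) | C_column < 0 | C_column > 1)) {
    stop("coordination values must lie in [0, 1]", call. = FALSE)
  }
  v <- round(C_column, .coord_digits)
  d <- length(unique(v))
  if (d >= k) {
    br <- jenks_breaks(v, k = k, labels = MATCHING_CLASSES)
    return(classify_by_breaks(v, br))
  }
  warning("only ", d, " distinct coordination values; falling back to ",
          d, " class(es) anchored on the absolute [0, 1] scale",
          call. = FALSE)
  br <- jenks_breaks(v, k = d)
  grp <- classify_by_breaks(v, br)
  anchor <- vapply(split(v, grp), mean, numeric(1))
  lab_idx <- pmin(length(MATCHING_CLASSES),
                  floor(anchor * length(MATCHING_CLASSES)) + 1L)
  factor(MATCHING_CLASSES[lab_idx[as.integer(grp)]],
         levels = MATCHING_CLASSES, ordered = TRUE)
}

#' Per-resource coupling-coordination matching
#'
#' Computes, for every city and each of the four resource classes, the
#' coupling-coordination value between the aging level (X1) and that
#' resource's per-older-adult supply level, then assigns five matching
#' classes per resource column by natural breaks.  Demand and supply are
#' range-normalized across cities first (raw scales differ by orders of
#' magnitude, which would pin C near 0 regardless of matching); disable
#' with \code{normalize = FALSE} only for pre-normalized input.
#'
#' @param indicators an \code{indicator_table} (columns X1, Y1-Y4, id).
#' @param normalize range-normalize columns across cities first (default
#'   \code{TRUE}).
#' @return object of class \code{matching_result}: list with
#'   \code{C_matrix} (k cities x 4 resources), \code{match_class} (same
#'   shape, ordered factors in a data frame), and \code{breaks} (per
#'   resource, the fitted \code{class_breaks} or NULL on fallback).
#' @export
match_resources <- function(indicators, normalize = TRUE) {
  need <- c("X1", SUPPLY_COLUMNS)
  if (!all(need %in% names(indicators))) {
    stop("indicator table must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ids <- if ("id" %in% names(indicators)) indicators$id
         else as.character(seq_len(nrow(indicators)))
  x <- indicators$X1
  Y <- as.matrix(indicators[SUPPLY_COLUMNS])
  if (normalize) {
    x <- minmax_normalize(x)
    Y <- minmax_normalize(Y)
  }
  if (any(x < 0 | x > 1) || any(Y < 0 | Y > 1)) {
    stop("with normalize = FALSE the inputs must already lie in [0, 1]",
         call. = FALSE)
  }
  k <- length(x)
  C_matrix <- matrix(NA_real_, k, length(SUPPLY_COLUMNS),
                     dimnames = list(ids, SUPPLY_COLUMNS))
  match_class <- vector("list", length(SUPPLY_COLUMNS))
  names(match_class) <- SUPPLY_COLUMNS
  breaks <- match_class
  for (j in SUPPLY_COLUMNS) {
    C_matrix[, j] <- coupling_coordination(x, Y[, j])
    match_class[[j]] <- classify_matching(C_matrix[, j])
    vj <- round(C_matrix[, j], .coord_digits)
    breaks[[j]] <- if (length(unique(vj)) >= 5) {
      jenks_breaks(vj, k = 5, labels = MATCHING_CLASSES)
    } else NULL
  }
  structure(
    list(C_matrix = C_matrix,
         match_class = as.data.frame(match_class, row.names = ids),
         breaks = breaks),
    class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat("Coupling-coordination matching:", nrow(x$C_matrix), "cities x",
      ncol(x$C_matrix), "resources\n")
  for (j in colnames(x$C_matrix)) {
    tab <- table(x$match_class[[j]])
    cat(sprintf("  %s: mean C = %.4f | %s\n", j, mean(x$C_matrix[, j]),
                paste(names(tab), tab, sep = "=", collapse = " ")))
  }
  invisible(x)
}
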