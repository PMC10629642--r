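CORRELATION_CLASSES <- c("low", "moderate", "relatively_high", "high")

#' Grey relation coefficients between demand and supply indicators
#'
#' For each demand indicator i, supply indicator j and city c, the grey
#' relation coefficient compresses the absolute difference of the
#' normalized values through the distinguishing rate rho:
#' \deqn{R_{ijc} = \frac{\Delta_{min} + \rho \Delta_{max}}
#'                      {\Delta_{ijc} + \rho \Delta_{max}}}
#' with \eqn{\Delta_{ijc} = |Xn_{ci} - Yn_{cj}|} and the min/max taken
#' globally over all i, j, c.  When the two systems are identical
#' everywhere (\eqn{\Delta_{max} = 0}) every coefficient is 1 (logged as a
#' message, not an error).
#'
#' @param Xn k x l matrix of normalized demand indicators in \code{[0, 1]}.
#' @param Yn k x m matrix of normalized supply indicators in \code{[0, 1]}.
#' @param rho distinguishing rate in \code{(0, 1]}; conventionally 0.5.
#'   Larger rho compresses differences less sharply.
#' @return l x m x k array of relation coefficients, each in \code{(0, 1]}.
#'   When \eqn{\Delta_{min} = 0}, every coefficient is bounded below by
#'   \eqn{\rho / (1 + \rho)} (1/3 at rho = 0.5).
#' @export
relation_coefficients <- function(Xn, Yn, rho = 0.5) {
  Xn <- as.matrix(Xn); Yn <- as.matrix(Yn)
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]", call. = FALSE)
  if (nrow(Xn) != nrow(Yn)) {
    stop("demand and supply must cover the same cities", call. = FALSE)
  }
  if (any(Xn < -1e-9 | Xn > 1 + 1e-9) || any(Yn < -1e-9 | Yn > 1 + 1e-9)) {
    stop("indicators must be range-normalized to [0, 1] first",
         call. = FALSE)
  }
  k <- nrow(Xn); l <- ncol(Xn); m <- ncol(Yn)
  delta <- array(0, dim = c(l, m, k))
  for (i in seq_len(l)) {
    for (j in seq_len(m)) {
      delta[i, j, ] <- abs(Xn[, i] - Yn[, j])
    }
  }
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    message("demand and supply systems are identical after normalization; ",
            "all relation coefficients are 1")
    R <- array(1, dim = c(l, m, k))
  } else {
    R <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  dimnames(R) <- list(colnames(Xn), colnames(Yn), rownames(Xn))
  R
}

#' Relation grades: city-averaged relation coefficients
#'
#' \eqn{\gamma_{ij} = \frac{1}{k} \sum_c R_{ijc}} where k is the sample
#' size (number of cities).
#'
#' @param R l x m x k relation-coefficient array from
#'   [relation_coefficients()].
#' @return l x m matrix of relation grades, each in \code{(0, 1]}.
#' @export
relation_grades <- function(R) {
  stopifnot(is.array(R), length(dim(R)) == 3)
  apply(R, c(1, 2), mean)
}

#' Indicator-mean relation grades
#'
#' Averages the relation-grade matrix along each axis: \code{d_demand[i]}
#' is the mean grade between demand indicator i and the whole supply
#' system; \code{d_supply[j]} the mean grade between supply indicator j
#' and the whole demand system.
#'
#' @param gamma l x m relation-grade matrix.
#' @return list with numeric vectors \code{d_demand} (length l) and
#'   \code{d_supply} (length m).
#' @export
indicator_mean_grades <- function(gamma) {
  gamma <- as.matrix(gamma)
  list(d_demand = rowMeans(gamma), d_supply = colMeans(gamma))
}

#' System coupling degree
#'
#' Grand mean of the relation grades over all demand x supply indicator
#' pairs; equals the mean of \code{d_demand} and of \code{d_supply}.
#'
#' @param gamma l x m relation-grade matrix.
#' @return scalar coupling degree in \code{(0, 1]}.
#' @export
system_coupling_degree <- function(gamma) {
  mean(as.matrix(gamma))
}

#' Classify a coupling/correlation value
#'
#' Four categories on left-open/right-closed intervals: low
#' \code{(0, 0.35]}, moderate \code{(0.35, 0.65]}, relatively_high
#' \code{(0.65, 0.85]}, high \code{(0.85, 1]}.
#'
#' @param value coupling degree(s) or relation grade(s) in \code{(0, 1]}.
#' @return ordered factor low < moderate < relatively_high < high.
#' @export
classify_correlation <- function(value) {
  if (any(!is.finite(value) | value <= 0 | value > 1 + 1e-12)) {
    stop("correlation value must lie in (0, 1]", call. = FALSE)
  }
  v <- value
  for (t in c(0.35, 0.65, 0.85)) v <- ifelse(abs(v - t) < 1e-12, t, v)
  cl <- ifelse(v <= 0.35, "low",
        ifelse(v <= 0.65, "moderate",
        ifelse(v <= 0.85, "relatively_high", "high")))
  factor(cl, levels = CORRELATION_CLASSES, ordered = TRUE)
}

#' Grey relational coupling of demand and supply systems
#'
#' Full grey-coupling analysis of an indicator table: range-normalizes the
#' demand (X1, X2) and supply (Y1-Y4) columns across cities, computes the
#' relation-coefficient tensor, the relation-grade matrix, the
#' indicator-mean grades, the scalar system coupling degree with its
#' correlation category, and a per-city coupling degree (mean relation
#' coefficient of that city over all indicator pairs) with per-city
#' categories.
#'
#' @param indicators an \code{indicator_table} from [build_indicators()]
#'   (or any data frame with columns X1, X2, Y1-Y4 and id).
#' @param rho distinguishing rate, default 0.5.
#' @return object of class \code{grey_coupling}: list with \code{R},
#'   \code{gamma}, \code{d_demand}, \code{d_supply}, \code{C},
#'   \code{category}, \code{gamma_category} (l x m), and \code{per_city}
#'   (data frame id, coupling, category).
#' @export
grey_coupling <- function(indicators, rho = 0.5) {
  need <- c(DEMAND_COLUMNS, SUPPLY_COLUMNS)
  if (!all(need %in% names(indicators))) {
    stop("indicator table must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  Xn <- minmax_normalize(as.matrix(indicators[DEMAND_COLUMNS]))
  Yn <- minmax_normalize(as.matrix(indicators[SUPPLY_COLUMNS]))
  rownames(Xn) <- rownames(Yn) <-
    if ("id" %in% names(indicators)) indicators$id else NULL

  R <- relation_coefficients(Xn, Yn, rho)
  gamma <- relation_grades(R)
  d <- indicator_mean_grades(gamma)
  C <- system_coupling_degree(gamma)
  per_city <- apply(R, 3, mean)

  structure(
    list(R = R, gamma = gamma,
         d_demand = d$d_demand, d_supply = d$d_supply,
         C = C, category = classify_correlation(C),
         gamma_category = matrix(classify_correlation(as.vector(gamma)),
                                 nrow(gamma), ncol(gamma),
                                 dimnames = dimnames(gamma)),
         per_city = data.frame(
           id = names(per_city) %||% seq_along(per_city),
           coupling = as.numeric(per_city),
           category = classify_correlation(as.numeric(per_city)),
           stringsAsFactors = FALSE),
         rho = rho),
    class = "grey_coupling")
}

#' @export
print.grey_coupling <- function(x, ...) {
  cat("Grey relational coupling (rho =", x$rho, ")\n")
  cat(sprintf("  system coupling degree C = %.4f (%s)\n",
              x$C, as.character(x$category)))
  cat("  relation grades gamma:\n")
  print(round(x$gamma, 4))
  cat("  supply-side mean grades d_j:",
      paste(sprintf("%.4f", x$d_supply), collapse = " "), "\n")
  invisible(x)
}
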