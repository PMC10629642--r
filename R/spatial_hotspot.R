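HOTSPOT_CLASSES <- c("cold", "sub_cold", "sub_hot", "hot")

#' Binary contiguity spatial weights
#'
#' Builds symmetric binary weights (w_ij = 1 for contiguous units, else 0)
#' from a region's adjacency list.  The self weight w_ii is governed by
#' \code{include_self}: the canonical Gi* statistic includes the unit
#' itself in its own neighbourhood.
#'
#' @param region a \code{region_dataset}, or a data frame of id pairs
#'   together with \code{ids} giving the full unit ordering.
#' @param include_self logical; treat each unit as its own neighbour
#'   (w_ii = 1).  Default \code{TRUE} (Gi* convention).
#' @param ids character vector of all unit ids in order; required when
#'   \code{region} is a bare edge list.
#' @return object of class \code{spatial_weights}: list with \code{n},
#'   \code{ids}, \code{neighbors} (list of 1-based neighbour index vectors,
#'   self excluded), \code{include_self}.  Isolated units are allowed and
#'   reported via a warning.
#' @export
contiguity_weights <- function(region, include_self = TRUE, ids = NULL) {
  if (inherits(region, "region_dataset")) {
    ids <- region$cities$id
    adj <- region$adjacency
  } else {
    if (is.null(ids)) stop("`ids` required with a bare edge list",
                           call. = FALSE)
    adj <- as.data.frame(region, stringsAsFactors = FALSE)
    if (nrow(adj)) {
      adj <- data.frame(from = as.character(adj[[1]]),
                        to = as.character(adj[[2]]),
                        stringsAsFactors = FALSE)
    } else {
      adj <- data.frame(from = character(0), to = character(0))
    }
  }
  n <- length(ids)
  if (n < 1) stop("no units", call. = FALSE)
  fi <- match(adj$from, ids)
  ti <- match(adj$to, ids)
  if (anyNA(fi) || anyNA(ti)) {
    bad <- c(adj$from[is.na(fi)], adj$to[is.na(ti)])[1L]
    stop("adjacency references unknown id: ", bad, call. = FALSE)
  }
  if (any(fi == ti)) stop("self-pairs are not allowed", call. = FALSE)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (r in seq_along(fi)) {
    nb[[fi[r]]] <- c(nb[[fi[r]]], ti[r])
    nb[[ti[r]]] <- c(nb[[ti[r]]], fi[r])
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  iso <- which(vapply(nb, length, integer(1)) == 0L)
  if (length(iso)) {
    warning("isolated unit(s) with no neighbours: ",
            paste(ids[iso], collapse = ", "), call. = FALSE)
  }
  structure(list(n = n, ids = as.character(ids), neighbors = nb,
                 include_self = isTRUE(include_self)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- vapply(x$neighbors, length, integer(1))
  cat("spatial_weights:", x$n, "units,", sum(k) / 2, "symmetric links",
      if (x$include_self) "(self-inclusive)" else "(self-exclusive)", "\n")
  cat("  neighbours per unit: min", min(k), "median", stats::median(k),
      "max", max(k), "\n")
  invisible(x)
}

check_values <- function(values, w) {
  if (!inherits(w, "spatial_weights")) {
    stop("`w` must be spatial_weights", call. = FALSE)
  }
  if (length(values) != w$n) {
    stop("length(values) must equal the number of units", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  invisible(values)
}

#' Raw Getis-Ord Gi* share statistic
#'
#' For each unit, the share of the total attribute mass held by the unit's
#' contiguity neighbourhood: \code{(sum_j w_ij x_j) / (sum_j x_j)}.  With
#' \code{include_self} weights (the Gi* convention) the unit's own value
#' enters both sums; the self-exclusive variant drops x_i from both the
#' numerator weights and the denominator (the Gi form).
#'
#' @param values per-unit attribute, finite, not all zero.
#' @param w \code{spatial_weights}.
#' @return numeric vector of neighbourhood shares.
#' @export
gi_star <- function(values, w) {
  check_values(values, w)
  total <- sum(values)
  out <- numeric(w$n)
  for (i in seq_len(w$n)) {
    num <- sum(values[w$neighbors[[i]]])
    if (w$include_self) {
      den <- total
      num <- num + values[i]
    } else {
      den <- total - values[i]
    }
    if (den == 0) {
      stop("denominator attribute sum is zero; Gi* undefined", call. = FALSE)
    }
    out[i] <- num / den
  }
  out
}

#' Standardized Gi* z-scores
#'
#' Standardizes the neighbourhood sum under the randomization null using
#' the Ord-Getis moments:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{x} W_i}
#'   {S \sqrt{[n S_{1i} - W_i^2] / (n - 1)}}}
#' with \eqn{W_i = \sum_j w_{ij}}, \eqn{S_{1i} = \sum_j w_{ij}^2}, and
#' \eqn{\bar{x}}, \eqn{S} the mean and (population) standard deviation over
#' all units.  Positive z signals clustering of high values around the unit
#' (hot spot), negative z clustering of low values (cold spot).
#'
#' A constant surface has no variance to standardize; by convention all z
#' are returned as 0 with a warning rather than an error, so pipelines on
#' degenerate inputs keep running.
#'
#' @param values per-unit attribute, finite.
#' @param w \code{spatial_weights}.
#' @return numeric vector of z-scores.
#' @export
gi_star_z <- function(values, w) {
  check_values(values, w)
  n <- w$n
  if (n < 2) stop("need at least two units", call. = FALSE)
  xbar <- mean(values)
  S <- sqrt(max(sum(values^2) / n - xbar^2, 0))
  # constant up to numerical precision: nothing to standardize
  if (S <= 1e-12 * max(abs(values), 1)) {
    warning("constant attribute surface: all Gi* z-scores set to 0",
            call. = FALSE)
    return(numeric(n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    Wi <- length(w$neighbors[[i]]) + w$include_self
    num <- sum(values[w$neighbors[[i]]]) +
      if (w$include_self) values[i] else 0
    S1 <- Wi                                # binary weights: w^2 = w
    denom <- S * sqrt((n * S1 - Wi^2) / (n - 1))
    out[i] <- if (denom == 0) 0 else (num - xbar * Wi) / denom
  }
  out
}

#' Conditional permutation test for Gi*
#'
#' Model-free inference for the local statistic: holding unit i's own value
#' fixed, the remaining values are randomly reassigned to the other units
#' \code{n_perm} times and the neighbourhood sum recomputed.  The pseudo
#' p-value is two-sided in the folded sense: the smaller tail rank of the
#' observed sum, \code{(min(n_ge, n_le) + 1) / (n_perm + 1)}, so a
#' constant surface yields p = 1 for every unit.
#'
#' @param values per-unit attribute.
#' @param w \code{spatial_weights}.
#' @param n_perm number of conditional permutations (>= 99).
#' @param seed integer RNG seed (mandatory; the draw is reproducible).
#' @return numeric vector of per-unit pseudo p-values.
#' @export
permutation_test <- function(values, w, n_perm = 999, seed) {
  check_values(values, w)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- w$n
  kmax <- max(vapply(w$neighbors, length, integer(1)))
  with_seed(seed, {
    # one (n_perm x kmax) index matrix into 1..(n-1), rows sampled without
    # replacement, shared across units (each unit reads its own k columns)
    idx <- matrix(0L, n_perm, max(kmax, 1L))
    for (r in seq_len(n_perm)) {
      idx[r, ] <- sample.int(n - 1L, max(kmax, 1L))
    }
    p <- numeric(n)
    for (i in seq_len(n)) {
      nbrs <- w$neighbors[[i]]
      k <- length(nbrs)
      self_term <- if (w$include_self) values[i] else 0
      obs <- sum(values[nbrs]) + self_term
      if (k == 0L) { p[i] <- 1; next }
      others <- values[-i]
      perm_mat <- matrix(others[idx[, seq_len(k), drop = FALSE]],
                         nrow = n_perm)
      sims <- rowSums(perm_mat) + self_term
      n_ge <- sum(sims >= obs - 1e-12)
      n_le <- sum(sims <= obs + 1e-12)
      p[i] <- (min(n_ge, n_le) + 1) / (n_perm + 1)
    }
    p
  })
}

#' Four-class hot/cold-spot pattern from z-scores
#'
#' Splits the Gi* z-scores into four ordered spatial-pattern classes by
#' exact natural breaks: cold < sub_cold < sub_hot < hot.  An alternative
#' fixed-cutoff mode classes by the usual normal quantiles (+-1.96, +-1.65
#' by default) instead of data-driven breaks.
#'
#' @param z per-unit z-scores; at least 4 distinct values in
#'   \code{"jenks"} mode.
#' @param method \code{"jenks"} (default) or \code{"cutoff"}.
#' @param cutoffs ascending length-3 numeric cutoffs for \code{"cutoff"}
#'   mode; default \code{c(-1.65, 0, 1.65)}.
#' @return ordered factor of pattern classes, one per unit.
#' @export
classify_hotspots <- function(z, method = c("jenks", "cutoff"),
                              cutoffs = c(-1.65, 0, 1.65)) {
  method <- match.arg(method)
  if (method == "jenks") {
    if (length(unique(z)) < 4) {
      stop("fewer than 4 distinct z values; use fewer classes or ",
           "method = \"cutoff\"", call. = FALSE)
    }
    br <- jenks_breaks(z, k = 4, labels = HOTSPOT_CLASSES)
    classify_by_breaks(z, br)
  } else {
    stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
    idx <- 1L + (z > cutoffs[1]) + (z > cutoffs[2]) + (z > cutoffs[3])
    factor(HOTSPOT_CLASSES[idx], levels = HOTSPOT_CLASSES, ordered = TRUE)
  }
}

#' Full hot-spot analysis of one attribute
#'
#' Convenience wrapper: raw Gi* shares, analytic z-scores, optional
#' conditional permutation p-values, and the four-class spatial pattern.
#'
#' @param values per-unit attribute.
#' @param w \code{spatial_weights}.
#' @param n_perm permutations for [permutation_test()]; 0 to skip.
#' @param seed RNG seed, required when \code{n_perm > 0}.
#' @return data frame with columns \code{gi_raw}, \code{z}, \code{p_perm}
#'   (NA when skipped) and \code{pattern_class}.
#' @export
hotspot_analysis <- function(values, w, n_perm = 0, seed = NULL) {
  gi <- gi_star(values, w)
  z <- gi_star_z(values, w)
  p <- if (n_perm > 0) permutation_test(values, w, n_perm, seed)
       else rep(NA_real_, w$n)
  cls <- if (length(unique(z)) >= 4) classify_hotspots(z)
         else factor(rep(if (mean(z) >= 0) "sub_hot" else "sub_cold", w$n),
                     levels = HOTSPOT_CLASSES, ordered = TRUE)
  data.frame(id = w$ids, gi_raw = gi, z = z, p_perm = p,
             pattern_class = cls, stringsAsFactors = FALSE)
}
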