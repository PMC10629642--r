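AGING_STAGES <- c("young", "adult", "primary", "moderate", "severe")
DENSITY_CLASSES <- c("sparse", "low", "medium", "high", "super_high")

# absolute snap tolerance applied before threshold comparison, so integer
# population ratios that land exactly on a class boundary are not pushed
# across it by floating error
.boundary_eps <- 1e-12

#' Aging coefficient
#'
#' Share of the population aged 65 and above in the total population, in
#' percent: \code{W = 100 * pop_65plus / pop_total}.
#'
#' @param pop_65plus older-adult population (65+), non-negative.
#' @param pop_total total population, positive.
#' @return W in percent, vectorized.
#' @export
aging_coefficient <- function(pop_65plus, pop_total) {
  if (any(pop_total <= 0)) {
    stop("pop_total must be positive: aging coefficient undefined",
         call. = FALSE)
  }
  if (any(pop_65plus < 0 | pop_65plus > pop_total)) {
    stop("pop_65plus must lie in [0, pop_total]", call. = FALSE)
  }
  100 * pop_65plus / pop_total
}

#' Classify the population-aging stage
#'
#' Stages a population by its aging coefficient \code{W} (percent):
#' young (\code{W <= 4}), adult (\code{4 < W < 7}), then the aging range
#' split into primary (\code{7 <= W < 14}), moderate (\code{14 <= W < 21})
#' and severe (\code{W >= 21}).  Boundary conventions: 4 is still young,
#' 7 and 14 open the next stage, 21 is already severe.
#'
#' @param W aging coefficient(s) in percent, in \code{[0, 100]}.
#' @return ordered factor with levels young < adult < primary < moderate <
#'   severe.
#' @export
classify_aging_stage <- function(W) {
  if (any(!is.finite(W) | W < 0 | W > 100)) {
    stop("aging coefficient must lie in [0, 100]", call. = FALSE)
  }
  snap <- function(v, t) ifelse(abs(v - t) < .boundary_eps, t, v)
  w <- W
  for (t in c(4, 7, 14, 21)) w <- snap(w, t)
  stage <- ifelse(w <= 4, "young",
           ifelse(w < 7, "adult",
           ifelse(w < 14, "primary",
           ifelse(w < 21, "moderate", "severe"))))
  factor(stage, levels = AGING_STAGES, ordered = TRUE)
}

#' Older-adult agglomeration degree
#'
#' Ratio of a region's older-adult density to the national older-adult
#' density: \code{JJD = (P_i / A_i) / (P_n / A_n)}.  A value above 1 means
#' the region concentrates older adults beyond the national average; it can
#' be read as the share of the national older-adult population held by a
#' region occupying 1\% of the national land.
#'
#' @param P_i regional older-adult population.
#' @param A_i regional land area (km^2), positive.
#' @param P_n national older-adult population, positive.
#' @param A_n national land area (km^2), positive.
#' @return dimensionless agglomeration degree(s).
#' @export
agglomeration_degree <- function(P_i, A_i, P_n, A_n) {
  if (any(A_i <= 0) || any(A_n <= 0)) {
    stop("land areas must be positive", call. = FALSE)
  }
  if (any(P_n <= 0)) {
    stop("national older-adult population must be positive", call. = FALSE)
  }
  (P_i / A_i) / (P_n / A_n)
}

#' Classify older-adult density
#'
#' Maps an agglomeration degree to one of five density classes using
#' left-open/right-closed intervals: sparse (\code{JJD <= 3}), low
#' (\code{3 < JJD <= 6}), medium (\code{6 < JJD <= 9}), high
#' (\code{9 < JJD <= 12}), super_high (\code{JJD > 12}).
#'
#' @param JJD agglomeration degree(s), non-negative.
#' @return ordered factor sparse < low < medium < high < super_high.
#' @export
classify_density <- function(JJD) {
  if (any(!is.finite(JJD) | JJD < 0)) {
    stop("agglomeration degree must be non-negative", call. = FALSE)
  }
  j <- JJD
  for (t in c(3, 6, 9, 12)) j <- ifelse(abs(j - t) < .boundary_eps, t, j)
  cl <- ifelse(j <= 3, "sparse",
        ifelse(j <= 6, "low",
        ifelse(j <= 9, "medium",
        ifelse(j <= 12, "high", "super_high"))))
  factor(cl, levels = DENSITY_CLASSES, ordered = TRUE)
}

#' Demand-side aging profile of a region
#'
#' Per-city aging coefficient with stage, old-age dependence rate, and
#' agglomeration degree with density class, relative to the region's
#' national denominators.
#'
#' @param region a \code{region_dataset}.
#' @return data frame with columns \code{id, W, stage, X2, JJD,
#'   density_class}, rows in city order.
#' @export
aging_profile <- function(region) {
  validate_region(region)
  ct <- region$cities
  if (any(ct$pop_15_64 <= 0)) {
    stop("zero working-age population for city ",
         ct$id[which(ct$pop_15_64 <= 0)[1L]], call. = FALSE)
  }
  W <- aging_coefficient(ct$pop_65plus, ct$pop_total)
  JJD <- agglomeration_degree(ct$pop_65plus, ct$land_area,
                              region$national_pop_65plus,
                              region$national_land_area)
  data.frame(
    id = ct$id,
    W = W,
    stage = classify_aging_stage(W),
    X2 = 100 * ct$pop_65plus / ct$pop_15_64,
    JJD = JJD,
    density_class = classify_density(JJD),
    stringsAsFactors = FALSE)
}
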