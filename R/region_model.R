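#' City table column names
#'
#' Fixed column layout of the per-city input table: identifier, name, land
#' area (km^2), total population, population aged 65+, working-age
#' population (15-64), and the four raw resource quantities (counts, except
#' green space in hectares).
#' @export
CITY_COLUMNS <- c("id", "name", "land_area", "pop_total", "pop_65plus",
                  "pop_15_64", "facilities", "green_space", "insured", "beds")

RESOURCE_COLUMNS <- c("facilities", "green_space", "insured", "beds")

#' Construct a region dataset
#'
#' Bundles the per-city table, the contiguity adjacency, the national
#' older-adult population and land area (denominators of the agglomeration
#' degree), and optional polygon geometry into a validated
#' \code{region_dataset}.
#'
#' @param cities data frame with the columns in [CITY_COLUMNS].
#' @param adjacency data frame or matrix with two columns of city ids, one
#'   row per unordered contiguity pair (no self-pairs).
#' @param national_pop_65plus national older-adult population; defaults to
#'   the sum over cities (i.e. the cities partition the nation).
#' @param national_land_area national land area in km^2; defaults to the
#'   sum over cities.
#' @param geometry optional list of GeoJSON feature objects (as parsed by
#'   jsonlite), one per city, carrying a property \code{id}.
#' @return object of class \code{region_dataset}.
#' @export
region_dataset <- function(cities, adjacency,
                           national_pop_65plus = NULL,
                           national_land_area = NULL,
                           geometry = NULL) {
  cities <- as.data.frame(cities, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CITY_COLUMNS, names(cities))
  if (length(missing_cols)) {
    stop("city table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cities <- cities[CITY_COLUMNS]
  cities$id <- as.character(cities$id)
  cities$name <- as.character(cities$name)
  rownames(cities) <- NULL

  adjacency <- as.data.frame(adjacency, stringsAsFactors = FALSE)
  if (ncol(adjacency) < 2 && nrow(adjacency) > 0) {
    stop("adjacency must have two id columns", call. = FALSE)
  }
  if (nrow(adjacency)) {
    adjacency <- data.frame(from = as.character(adjacency[[1]]),
                            to = as.character(adjacency[[2]]),
                            stringsAsFactors = FALSE)
  } else {
    adjacency <- data.frame(from = character(0), to = character(0))
  }
  rownames(adjacency) <- NULL

  region <- structure(
    list(cities = cities,
         adjacency = adjacency,
         national_pop_65plus =
           national_pop_65plus %||% sum(cities$pop_65plus),
         national_land_area =
           national_land_area %||% sum(cities$land_area),
         geometry = geometry),
    class = "region_dataset")
  validate_region(region)
  region
}

#' Validate a region dataset
#'
#' Checks all structural invariants: unique ids, positive areas, population
#' accounting (65+ and 15-64 components within the total), non-negative
#' resources, adjacency endpoints known and non-self, and national totals at
#' least the city sums.  Errors name the offending city.
#'
#' @param region a \code{region_dataset}.
#' @return the region, invisibly, if valid.
#' @export
validate_region <- function(region) {
  stopifnot(inherits(region, "region_dataset"))
  ct <- region$cities
  if (anyDuplicated(ct$id)) {
    stop("duplicate city id: ", ct$id[duplicated(ct$id)][1L], call. = FALSE)
  }
  num_cols <- setdiff(CITY_COLUMNS, c("id", "name"))
  for (cl in num_cols) {
    if (!is.numeric(ct[[cl]]) || anyNA(ct[[cl]])) {
      stop("column ", cl, " must be numeric and complete", call. = FALSE)
    }
  }
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(what, " for city ", ct$id[which(cond)[1L]], call. = FALSE)
    }
  }
  bad(ct$land_area <= 0, "non-positive land area")
  bad(ct$pop_total < 0, "negative total population")
  bad(ct$pop_65plus < 0 | ct$pop_65plus > ct$pop_total,
      "pop_65plus outside [0, pop_total]")
  bad(ct$pop_15_64 < 0 | ct$pop_15_64 > ct$pop_total,
      "pop_15_64 outside [0, pop_total]")
  bad(ct$pop_65plus + ct$pop_15_64 > ct$pop_total,
      "pop_65plus + pop_15_64 exceeds pop_total")
  for (rc in RESOURCE_COLUMNS) bad(ct[[rc]] < 0, paste("negative", rc))

  adj <- region$adjacency
  if (nrow(adj)) {
    unknown <- setdiff(c(adj$from, adj$to), ct$id)
    if (length(unknown)) {
      stop("adjacency references unknown city id: ", unknown[1L],
           call. = FALSE)
    }
    if (any(adj$from == adj$to)) {
      stop("adjacency contains a self-pair for city ",
           adj$from[adj$from == adj$to][1L], call. = FALSE)
    }
  }
  if (region$national_pop_65plus < sum(ct$pop_65plus) - 1e-9) {
    stop("national_pop_65plus smaller than the sum over cities",
         call. = FALSE)
  }
  if (region$national_land_area < sum(ct$land_area) - 1e-9) {
    stop("national_land_area smaller than the sum over cities",
         call. = FALSE)
  }
  invisible(region)
}

#' @export
print.region_dataset <- function(x, ...) {
  cat("region_dataset:", nrow(x$cities), "cities,",
      nrow(x$adjacency), "contiguity pairs\n")
  cat("  national 65+ population:",
      format(x$national_pop_65plus, big.mark = ","), "\n")
  cat("  national land area:",
      format(x$national_land_area, big.mark = ","), "km^2\n")
  if (!is.null(x$geometry)) cat("  polygon geometry attached\n")
  invisible(x)
}

#' Read a region dataset from delimited files
#'
#' Reads the per-city CSV table plus either an explicit two-column adjacency
#' edge list (CSV) or a GeoJSON FeatureCollection of city polygons, from
#' which queen contiguity is derived.
#'
#' @param table_path path to the city CSV (columns [CITY_COLUMNS], UTF-8,
#'   header row).
#' @param adjacency_path path to a two-column CSV of contiguity id pairs.
#' @param geojson_path path to a GeoJSON FeatureCollection whose features
#'   carry a property \code{id} matching the table; used to derive
#'   adjacency when \code{adjacency_path} is not given.
#' @param national_pop_65plus,national_land_area optional national
#'   denominators; default to city sums.
#' @param rule contiguity rule for geometry-derived adjacency.
#' @return a validated \code{region_dataset}.
#' @export
read_region <- function(table_path, adjacency_path = NULL,
                        geojson_path = NULL,
                        national_pop_65plus = NULL,
                        national_land_area = NULL,
                        rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  cities <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  geometry <- NULL
  if (!is.null(adjacency_path)) {
    adjacency <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8")
  } else if (!is.null(geojson_path)) {
    geometry <- read_geojson_features(geojson_path)
    adjacency <- geometry_adjacency(geometry, rule = rule)
  } else {
    stop("provide either adjacency_path or geojson_path", call. = FALSE)
  }
  region_dataset(cities, adjacency,
                 national_pop_65plus = national_pop_65plus,
                 national_land_area = national_land_area,
                 geometry = geometry)
}

#' Write a region dataset to delimited files
#'
#' Inverse of [read_region()]: writes the city table and adjacency edge
#' list as CSV (UTF-8), and optionally the polygon geometry as GeoJSON.
#'
#' @param region a \code{region_dataset}.
#' @param table_path,adjacency_path output CSV paths.
#' @param geojson_path optional GeoJSON output path (requires geometry).
#' @return paths written, invisibly.
#' @export
write_region <- function(region, table_path, adjacency_path,
                         geojson_path = NULL) {
  validate_region(region)
  utils::write.csv(region$cities, table_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(region$adjacency, adjacency_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  out <- c(table_path, adjacency_path)
  if (!is.null(geojson_path)) {
    if (is.null(region$geometry)) {
      stop("region carries no geometry to write", call. = FALSE)
    }
    write_geojson_features(region$geometry, geojson_path)
    out <- c(out, geojson_path)
  }
  invisible(out)
}

#' Build the demand/supply indicator table
#'
#' Converts raw city records into the six coupling-system indicators:
#' demand side \code{X1} (older-adult share of total population, percent)
#' and \code{X2} (older adults per 100 working-age persons, percent), and
#' supply side \code{Y1}-\code{Y4}, each resource expressed per 10,000
#' older adults (facility count, green-space hectares, insurance
#' participants, medical beds).
#'
#' @param region a \code{region_dataset}; every city must have positive
#'   older-adult and working-age populations.
#' @return data frame of class \code{indicator_table} with columns
#'   \code{id, X1, X2, Y1, Y2, Y3, Y4}, rows in city order.
#' @export
build_indicators <- function(region) {
  validate_region(region)
  ct <- region$cities
  degen <- ct$pop_65plus <= 0 | ct$pop_15_64 <= 0
  if (any(degen)) {
    stop("zero older-adult or working-age population for city ",
         ct$id[which(degen)[1L]],
         "; per-capita indicators are undefined", call. = FALSE)
  }
  out <- data.frame(
    id = ct$id,
    X1 = 100 * ct$pop_65plus / ct$pop_total,
    X2 = 100 * ct$pop_65plus / ct$pop_15_64,
    Y1 = 10000 * ct$facilities / ct$pop_65plus,
    Y2 = 10000 * ct$green_space / ct$pop_65plus,
    Y3 = 10000 * ct$insured / ct$pop_65plus,
    Y4 = 10000 * ct$beds / ct$pop_65plus,
    stringsAsFactors = FALSE)
  class(out) <- c("indicator_table", "data.frame")
  out
}

DEMAND_COLUMNS <- c("X1", "X2")
SUPPLY_COLUMNS <- c("Y1", "Y2", "Y3", "Y4")

# ---- GeoJSON helpers (plain FeatureCollection of polygons) ----------------

read_geojson_features <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    id <- f$properties$id
    if (is.null(id)) stop("GeoJSON feature lacks property \"id\"",
                          call. = FALSE)
    as.character(id)
  }, character(1))
  names(feats) <- ids
  feats
}

write_geojson_features <- function(features, path) {
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# All polygon vertices of one feature as "x|y" keys (coordinates rounded to
# 1e-8 so shared borders written/reread through text survive comparison).
feature_vertex_keys <- function(feature) {
  geom <- feature$geometry
  rings <- switch(geom$type,
    Polygon = geom$coordinates,
    MultiPolygon = do.call(c, geom$coordinates),
    stop("unsupported geometry type: ", geom$type, call. = FALSE))
  keys <- character(0)
  for (ring in rings) {
    for (pt in ring) {
      keys <- c(keys, paste(round(as.numeric(pt[[1]]), 8),
                            round(as.numeric(pt[[2]]), 8), sep = "|"))
    }
  }
  unique(keys)
}

#' Derive contiguity adjacency from polygon features
#'
#' Two cities are queen-contiguous when their polygons share at least one
#' boundary vertex, rook-contiguous when they share at least two (an edge).
#' Suitable for planar partitions whose shared borders repeat vertices
#' exactly, as written by [write_region()].
#'
#' @param features named list of GeoJSON features (names are city ids).
#' @param rule \code{"queen"} (default) or \code{"rook"}.
#' @return data frame with columns \code{from}, \code{to}.
#' @export
geometry_adjacency <- function(features, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  need <- if (rule == "queen") 1L else 2L
  keys <- lapply(features, feature_vertex_keys)
  ids <- names(features)
  n <- length(features)
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (length(intersect(keys[[i]], keys[[j]])) >= need) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}
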