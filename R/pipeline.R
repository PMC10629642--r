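#' Class shares of a classification
#'
#' Per-class city count and percentage of the total, with percentages
#' rounded half-up to two decimals (12 of 41 cities prints as 29.27).
#'
#' @param labels vector or factor of per-city class labels.
#' @return data frame with columns \code{class}, \code{count},
#'   \code{percent}; counts sum to the city total and percentages to
#'   100 within rounding.
#' @export
class_shares <- function(labels) {
  if (length(labels) == 0) stop("no labels supplied", call. = FALSE)
  f <- if (is.factor(labels)) labels else factor(labels)
  tab <- table(f)
  data.frame(class = names(tab),
             count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / length(f), 2),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()].  Input
#' is either synthetic-region settings (default) or paths to a city table
#' plus adjacency/GeoJSON.
#'
#' @param seed integer seed used for the synthetic region and any
#'   permutation inference.
#' @param table_path,adjacency_path,geojson_path input files; when
#'   \code{table_path} is NULL a default 41-city synthetic region is
#'   generated from \code{seed} (overridable via \code{synth}).
#' @param synth optional \code{synth_params} replacing the default
#'   generator settings (its own seed governs generation).
#' @param rho grey distinguishing rate.
#' @param include_self self-inclusive Gi* weights (default TRUE).
#' @param gi_variant \code{"canonical"} (self-inclusive Gi*) or
#'   \code{"literal"} (self-exclusive denominator).
#' @param n_perm conditional permutations for hotspot p-values (0 skips).
#' @param hotspot_classes,resource_classes,matching_classes class counts
#'   of the three classifications (4 / 5 / 5).
#' @param normalize_matching range-normalize before coordination matching.
#' @param out_dir optional output directory for [write_report()].
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            table_path = NULL, adjacency_path = NULL,
                            geojson_path = NULL, synth = NULL,
                            rho = 0.5, include_self = TRUE,
                            gi_variant = c("canonical", "literal"),
                            n_perm = 0L,
                            hotspot_classes = 4L, resource_classes = 5L,
                            matching_classes = 5L,
                            normalize_matching = TRUE, out_dir = NULL) {
  gi_variant <- match.arg(gi_variant)
  cfg <- list(seed = as.integer(seed), table_path = table_path,
              adjacency_path = adjacency_path, geojson_path = geojson_path,
              synth = synth, rho = rho,
              include_self = if (gi_variant == "literal") FALSE
                             else isTRUE(include_self),
              gi_variant = gi_variant, n_perm = as.integer(n_perm),
              hotspot_classes = as.integer(hotspot_classes),
              resource_classes = as.integer(resource_classes),
              matching_classes = as.integer(matching_classes),
              normalize_matching = isTRUE(normalize_matching),
              out_dir = out_dir)
  if (any(c(cfg$hotspot_classes, cfg$resource_classes,
            cfg$matching_classes) < 2)) {
    stop("class counts must be >= 2", call. = FALSE)
  }
  for (p in c(cfg$table_path, cfg$adjacency_path, cfg$geojson_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full supply-demand coupling pipeline
#'
#' Ingests or synthesizes a region, builds the indicator table, and runs
#' every stage: demand-side aging profile with stage/density shares,
#' Gi* hotspot analysis of the aging coefficient, natural-breaks
#' classification of each resource indicator, grey relational coupling of
#' the two systems, and per-resource coupling-coordination matching.
#' Deterministic given the configuration: the same config yields a
#' byte-identical JSON report.
#'
#' @param config a \code{pipeline_config}.
#' @return object of class \code{report_bundle}: list with \code{region},
#'   \code{indicators}, \code{aging} (profile + stage/density shares),
#'   \code{hotspot} (table + class shares), \code{resources} (per-resource
#'   class tables and shares), \code{coupling} (\code{grey_coupling}),
#'   \code{matching} (\code{matching_result} + per-resource shares), and
#'   \code{config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  region <- if (!is.null(config$table_path)) {
    read_region(config$table_path, config$adjacency_path,
                config$geojson_path)
  } else if (!is.null(config$synth)) {
    generate_region(config$synth)
  } else {
    default_yrd_like(config$seed)
  }

  indicators <- build_indicators(region)
  aging <- aging_profile(region)

  w <- contiguity_weights(region, include_self = config$include_self)
  hotspot <- hotspot_analysis(aging$W, w, n_perm = config$n_perm,
                              seed = config$seed)

  resources <- lapply(SUPPLY_COLUMNS, function(col) {
    v <- indicators[[col]]
    kk <- min(config$resource_classes, length(unique(v)))
    if (kk < config$resource_classes) {
      warning("resource ", col, ": only ", kk,
              " distinct values; using ", kk, " classes", call. = FALSE)
    }
    br <- jenks_breaks(v, k = kk)
    lab <- classify_by_breaks(v, br)
    list(breaks = br,
         table = data.frame(id = indicators$id, value = v, class = lab,
                            stringsAsFactors = FALSE),
         shares = class_shares(lab))
  })
  names(resources) <- SUPPLY_COLUMNS

  coupling <- grey_coupling(indicators, rho = config$rho)
  matching <- match_resources(indicators,
                              normalize = config$normalize_matching)

  bundle <- structure(
    list(region = region,
         indicators = indicators,
         aging = list(profile = aging,
                      stage_shares = class_shares(aging$stage),
                      density_shares = class_shares(aging$density_class)),
         hotspot = list(table = hotspot,
                        shares = class_shares(hotspot$pattern_class)),
         resources = resources,
         coupling = coupling,
         matching = list(result = matching,
                         shares = lapply(matching$match_class,
                                         class_shares)),
         config = config),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write the machine-readable report bundle
#'
#' Emits CSV tables (aging profile, hotspot table, per-resource classes,
#' per-city coupling, coordination matrix with classes) and a single JSON
#' summary (\code{report.json}) holding the grey-coupling results and all
#' class shares.  If the region carries geometry, a GeoJSON with appended
#' result attributes is written too.  Output is free of timestamps, so a
#' rerun of the same configuration reproduces the files byte for byte.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  w(bundle$aging$profile, "aging_profile.csv")
  w(bundle$hotspot$table, "hotspots.csv")
  for (col in names(bundle$resources)) {
    w(bundle$resources[[col]]$table, paste0("resource_", col, ".csv"))
  }
  w(bundle$coupling$per_city, "coupling_per_city.csv")
  m <- bundle$matching$result
  mt <- data.frame(id = rownames(m$C_matrix),
                   round(m$C_matrix, 4),
                   stats::setNames(m$match_class,
                                   paste0(names(m$match_class), "_class")),
                   stringsAsFactors = FALSE)
  w(mt, "matching.csv")

  report <- list(
    n_cities = nrow(bundle$region$cities),
    coupling = list(
      rho = bundle$coupling$rho,
      C = bundle$coupling$C,
      category = as.character(bundle$coupling$category),
      gamma = bundle$coupling$gamma,
      d_demand = bundle$coupling$d_demand,
      d_supply = bundle$coupling$d_supply),
    shares = list(
      aging_stage = bundle$aging$stage_shares,
      density_class = bundle$aging$density_shares,
      hotspot = bundle$hotspot$shares,
      resources = lapply(bundle$resources, `[[`, "shares"),
      matching = bundle$matching$shares))
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(report, pj, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(paths, pj)

  if (!is.null(bundle$region$geometry)) {
    feats <- bundle$region$geometry
    prof <- bundle$aging$profile
    hs <- bundle$hotspot$table
    for (i in seq_along(feats)) {
      id <- feats[[i]]$properties$id
      r <- match(id, prof$id)
      feats[[i]]$properties <- c(feats[[i]]$properties, list(
        W = prof$W[r], stage = as.character(prof$stage[r]),
        JJD = prof$JJD[r],
        density_class = as.character(prof$density_class[r]),
        gi_z = hs$z[r],
        pattern_class = as.character(hs$pattern_class[r]),
        coupling = bundle$coupling$per_city$coupling[r]))
    }
    pg <- file.path(dir, "region_results.geojson")
    write_geojson_features(feats, pg)
    paths <- c(paths, pg)
  }
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Supply-demand coupling report:", nrow(x$region$cities), "cities\n")
  cat("  aging stages: ",
      paste(x$aging$stage_shares$class, x$aging$stage_shares$percent,
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  system coupling degree C = %.4f (%s)\n",
              x$coupling$C, as.character(x$coupling$category)))
  invisible(x)
}
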