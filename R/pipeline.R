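#' Config-driven orchestration of the maturity-ogive analysis
#'
#' A pipeline run reads a fish table (one row per fish) and a relative
#' abundance table (area x season, e.g. CPUE-derived), derives seasons,
#' latitude bands and 5-cm length classes, compares the candidate model grid
#' by AICc, refits the discrete-latitude area model, computes abundance
#' weights from the sample's length composition and sex ratio, and writes the
#' weighted and unweighted seasonal ogives with an L50/L100 summary. All
#' randomness flows from the configured seed; outputs record the package
#' version, seed and a hash of the resolved configuration.
#'
#' @name pipeline_io
NULL

#' Pipeline configuration
#'
#' @param fish_table Path to the fish table (TSV/CSV). Required columns:
#'   `set_id`, `month`, `latitude_degS`, `fork_length_cm`, `sex`, and either
#'   `mature` (0/1) or `maturity` (mature/immature), or raw histology columns
#'   (see [classify_ovary_table()]) plus `fork_length_cm`.
#' @param abundance_table Path to the abundance table (`area`, `season`,
#'   `N`), or `NULL` for unweighted-only mode.
#' @param area_mapping Optional path to a table (`area_fine`, `area`)
#'   collapsing finer CPUE areas onto the three latitude bands.
#' @param output_dir Output directory (created if needed).
#' @param season_mode 2 or 4 season levels for the candidate grid.
#' @param band_edges_degS Interior latitude band edges (degrees south).
#' @param length_class_width_cm Length class width.
#' @param compare Run the candidate-grid AICc comparison stage.
#' @param candidate_axes List of axes passed to [candidate_grid()].
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fish_table, abundance_table = NULL,
                            area_mapping = NULL, output_dir = "ogive-out",
                            season_mode = 2, band_edges_degS = c(23, 29),
                            length_class_width_cm = 5, compare = TRUE,
                            candidate_axes = list(), seed = 1L) {
  if (is.unsorted(band_edges_degS, strictly = TRUE)) {
    stop("band edges must be strictly increasing", call. = FALSE)
  }
  if (length_class_width_cm <= 0) stop("length class width must be positive",
                                       call. = FALSE)
  cfg <- list(fish_table = fish_table, abundance_table = abundance_table,
              area_mapping = area_mapping, output_dir = output_dir,
              season_mode = season_mode, band_edges_degS = band_edges_degS,
              length_class_width_cm = length_class_width_cm,
              compare = compare, candidate_axes = candidate_axes,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(pipeline_config, raw)
}

#' Read and validate the pipeline inputs
#'
#' Row-level validation failures (month out of 1--12, non-positive length,
#' non-finite latitude) are collected and reported together with their line
#' numbers (header = line 1). If raw histology columns are present, fish are
#' first classified and the below-70 cm macroscopic-immature rule applied.
#'
#' @param config A [pipeline_config()].
#' @return List with `fish` (validated data.frame) and `abundance`
#'   (data.frame or `NULL`).
#' @export
read_inputs <- function(config) {
  fish <- read_delim_sniff(config$fish_table)
  if (!("mature" %in% names(fish) || "maturity" %in% names(fish))) {
    if ("mago" %in% names(fish)) {
      fish <- classify_ovary_table(config$fish_table)
      fish$maturity <- vapply(seq_len(nrow(fish)), function(i) {
        assign_maturity(fish$dev_class[i], fish$fork_length_cm[i])$status
      }, character(1))
    } else {
      stop("fish table needs 'mature'/'maturity' or histology columns",
           call. = FALSE)
    }
  }
  need <- c("set_id", "month", "latitude_degS", "fork_length_cm")
  miss <- setdiff(need, names(fish))
  if (length(miss)) stop("fish table is missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  problems <- character(0)
  line <- seq_len(nrow(fish)) + 1L
  bad <- which(is.na(fish$month) | fish$month < 1 | fish$month > 12 |
                 fish$month != round(fish$month))
  if (length(bad)) problems <- c(problems, paste0(
    "line ", bad + 1L, ": month out of range (", fish$month[bad], ")"))
  bad <- which(!is.finite(fish$fork_length_cm) | fish$fork_length_cm <= 0)
  if (length(bad)) problems <- c(problems, paste0(
    "line ", bad + 1L, ": non-positive fork length"))
  bad <- which(!is.finite(fish$latitude_degS))
  if (length(bad)) problems <- c(problems, paste0(
    "line ", bad + 1L, ": missing latitude"))
  if (length(problems)) {
    stop("fish table validation failed:\n  ",
         paste(utils::head(problems, 10), collapse = "\n  "), call. = FALSE)
  }

  abundance <- NULL
  if (!is.null(config$abundance_table)) {
    abundance <- read_delim_sniff(config$abundance_table)
    miss <- setdiff(c("area", "season", "N"), names(abundance))
    if (length(miss)) stop("abundance table is missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (!is.null(config$area_mapping)) {
      map <- read_delim_sniff(config$area_mapping)
      miss <- setdiff(c("area_fine", "area"), names(map))
      if (length(miss)) stop("area mapping is missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
      abundance$area <- map$area[match(abundance$area, map$area_fine)]
      if (any(is.na(abundance$area))) {
        stop("area mapping does not cover every CPUE area", call. = FALSE)
      }
      abundance <- stats::aggregate(N ~ area + season, abundance, sum)
    }
  }
  message(sprintf("read %d fish in %d sets; %s", nrow(fish),
                  length(unique(fish$set_id)),
                  if (is.null(abundance)) "no abundance table" else
                    sprintf("%d abundance cells", nrow(abundance))))
  list(fish = fish, abundance = abundance)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and validate inputs; derive covariates; compare the
#' candidate model grid by AICc (optional); fit the discrete-latitude area
#' model; compute abundance weights and the weighted seasonal ogives; fit the
#' unweighted seasonal ogives; summarise L50/L100. Without an abundance
#' table the run degrades to unweighted-only mode with a warning. Any stage
#' error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage outputs; files are written to
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("read_inputs", read_inputs(config))
  fish <- inputs$fish
  if (!"mature" %in% names(fish)) fish$mature <- fish$maturity == "mature"

  fish <- stage("derive_covariates", {
    fish$season <- season_of_month(fish$month, 2)
    fish$area <- latitude_band(fish$latitude_degS, config$band_edges_degS)
    lc <- length_class(fish$fork_length_cm, config$length_class_width_cm)
    fish$length_class <- lc$label
    fish$length_midpoint <- lc$midpoint
    fish
  })
  females <- fish[is.na(fish$sex) | fish$sex == "F", , drop = FALSE]

  comparison <- NULL
  if (isTRUE(config$compare)) {
    comparison <- stage("compare_models", {
      axes <- config$candidate_axes
      axes$predictor <- "length"
      grid <- do.call(candidate_grid, axes)
      compare_models(females, grid, keep_fits = FALSE)
    })
    write_delim_table(comparison$table,
                      file.path(config$output_dir, "model_comparison.tsv"))
  }

  weighted <- NULL
  comp <- stage("derive_abundance_inputs",
                derive_abundance_inputs(fish, config$band_edges_degS,
                                        config$length_class_width_cm))
  area_og <- stage("area_season_ogives",
                   area_season_ogives(females,
                                      midpoints =
                                        sort(unique(comp$composition$midpoint)),
                                      band_edges_degS = config$band_edges_degS))
  write_delim_table(area_og$predictions,
                    file.path(config$output_dir, "area_ogives.tsv"))

  if (!is.null(inputs$abundance)) {
    weighted <- stage("weighted_ogive", {
      weights <- compute_weights(inputs$abundance, comp$composition)
      combine_weighted(area_og$predictions, weights)
    })
    write_delim_table(as.data.frame(weighted),
                      file.path(config$output_dir, "weighted_ogive.tsv"))
  } else {
    warning("no abundance table: weighted ogive skipped ",
            "(unweighted-only mode)", call. = FALSE)
  }

  unweighted <- stage("fit_unweighted", {
    lapply(1:2, function(s) fit_unweighted(females, s))
  })

  summary_tab <- stage("l50_summary", {
    rows <- lapply(1:2, function(s) {
      data.frame(season = s,
                 l50_weighted = if (is.null(weighted)) NA_real_ else
                   length_at_quantile(weighted, 0.5, s),
                 l100_weighted = if (is.null(weighted)) NA_real_ else
                   length_at_quantile(weighted, 1, s),
                 l50_unweighted = unweighted[[s]]$l50)
    })
    do.call(rbind, rows)
  })
  write_delim_table(summary_tab, file.path(config$output_dir,
                                           "l50_summary.tsv"))

  meta <- list(package_version = as.character(utils::packageVersion("maturogive")),
               seed = config$seed,
               config_hash = config_hash(config),
               config = unclass(config))
  jsonlite::write_json(meta, file.path(config$output_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(fish = fish, comparison = comparison,
                 area_ogives = area_og, weighted = weighted,
                 unweighted = unweighted, summary = summary_tab))
}

# Polynomial rolling hash of the serialized config (hex string).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic scenario to disk
#'
#' Simulates a cluster-sampled population, tabulates relative abundance from
#' its attached census (standing in for the CPUE-derived abundance index),
#' and writes the fish table and the abundance table in the formats the
#' pipeline reads.
#'
#' @param dir Output directory.
#' @param params [population_params()] for the sample.
#' @return Invisibly, list of file paths.
#' @export
write_scenario <- function(dir, params = population_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_pop <- simulate_population(params)
  census <- attr(sample_pop, "population")
  ab <- derive_abundance_inputs(census)$abundance

  fish_path <- file.path(dir, "fish.tsv")
  ab_path <- file.path(dir, "abundance.tsv")
  write_delim_table(sample_pop, fish_path)
  write_delim_table(ab, ab_path)
  invisible(list(fish_table = fish_path, abundance_table = ab_path))
}
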