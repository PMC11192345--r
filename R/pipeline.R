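#' Build a pipeline run configuration
#'
#' Collects every input of an end-to-end valuation run: where areas come
#' from (a packaged area table, a CSV, or a synthetic landscape), the
#' coefficient sources, and the scalar economic parameters. Exactly one area
#' source is active; referenced files are checked up front so a bad path
#' fails before any computation.
#'
#' @param area_source `"esv"` or `"carbon"` for the packaged area tables,
#'   `"file"` for a CSV of your own, or `"raster"` to derive areas from a
#'   synthetic landscape.
#' @param area_file CSV path (columns `class`/`code`, `area_ha`) when
#'   `area_source = "file"`.
#' @param total_area_ha optional declared extent for `"file"` areas.
#' @param landscape a [landscape_spec()] when `area_source = "raster"`.
#' @param coefficients `NULL` for the packaged coefficient table, or a CSV
#'   path with columns `class`, `category`, `service`, `value_usd_ha_yr`.
#' @param scc social cost of carbon, USD per t CO2.
#' @param coffee list with `production_rate` (t ha-1 yr-1), `price_usd_t`,
#'   `cost_fraction`; used to recompute the coffee provisioning value.
#' @param delta sensitivity perturbation (default 0.5, i.e. +/-50%).
#' @param sensitivity_mode `"per_class"` or `"total"`.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing artifacts.
#' @param seed integer seed for the synthetic-landscape source.
#' @param quiet suppress progress logging (default `FALSE`).
#' @return a `run_config` list.
#' @export
run_config <- function(area_source = c("esv", "carbon", "file", "raster"),
                       area_file = NULL, total_area_ha = NULL,
                       landscape = NULL, coefficients = NULL,
                       scc = 1.47,
                       coffee = list(production_rate = 0.84,
                                     price_usd_t = 4685,
                                     cost_fraction = 0.13),
                       delta = 0.5,
                       sensitivity_mode = c("per_class", "total"),
                       out_dir = NULL, seed = 1L, quiet = FALSE) {
  area_source <- match.arg(area_source)
  sensitivity_mode <- match.arg(sensitivity_mode)
  if (area_source == "file") {
    if (is.null(area_file) || !file.exists(area_file)) {
      stop("`area_file` must point to an existing CSV", call. = FALSE)
    }
  }
  if (area_source == "raster" && !inherits(landscape, "landscape_spec")) {
    stop("`landscape` must be a landscape_spec when area_source = 'raster'",
         call. = FALSE)
  }
  if (!is.null(coefficients) && !file.exists(coefficients)) {
    stop("coefficient file not found: ", coefficients, call. = FALSE)
  }
  structure(
    list(area_source = area_source, area_file = area_file,
         total_area_ha = total_area_ha, landscape = landscape,
         coefficients = coefficients, scc = scc, coffee = coffee,
         delta = delta, sensitivity_mode = sensitivity_mode,
         out_dir = out_dir, seed = as.integer(seed), quiet = isTRUE(quiet)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map one-to-one onto [run_config()] arguments; a `landscape`
#' block (`n_rows`, `n_cols`, `pixel_size_m`, optional `seed`) builds a
#' default-composition [landscape_spec()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  landscape <- NULL
  if (!is.null(cfg$landscape)) {
    landscape <- landscape_spec(
      n_rows = cfg$landscape$n_rows, n_cols = cfg$landscape$n_cols,
      pixel_size_m = cfg$landscape$pixel_size_m %||% 10,
      seed = cfg$landscape$seed %||% (cfg$seed %||% 1L))
  }
  run_config(
    area_source = cfg$area_source %||% "esv",
    area_file = cfg$area_file, total_area_ha = cfg$total_area_ha,
    landscape = landscape, coefficients = cfg$coefficients,
    scc = cfg$scc %||% 1.47,
    coffee = utils::modifyList(list(production_rate = 0.84, price_usd_t = 4685,
                                    cost_fraction = 0.13),
                               cfg$coffee %||% list()),
    delta = cfg$delta %||% 0.5,
    sensitivity_mode = cfg$sensitivity_mode %||% "per_class",
    out_dir = cfg$out_dir, seed = cfg$seed %||% 1L,
    quiet = cfg$quiet %||% FALSE)
}

pipeline_log <- function(config, fmt, ...) {
  if (!config$quiet) message(sprintf(paste0("[esval] ", fmt), ...))
}

log_checksum <- function(config, path) {
  if (!config$quiet && file.exists(path)) {
    pipeline_log(config, "input %s (md5 %s)", basename(path),
                 unname(tools::md5sum(path)))
  }
}

#' Run the full valuation pipeline
#'
#' Resolves the configured area source, assembles the coefficient table
#' (recomputing the carbon chain at the configured social cost of carbon and
#' the coffee value at the configured production parameters), evaluates the
#' ESV report, the carbon valuation table, and the per-class sensitivity
#' coefficients, and — when `out_dir` is set — writes each artifact as CSV
#' plus a JSON summary. The same configuration and seed give byte-identical
#' outputs.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return list with `areas`, `coefficients`, `carbon`, `report`
#'   ([esv_total()] result), `sensitivity`, and `paths` (written files).
#' @examples
#' res <- run_pipeline(run_config("esv", quiet = TRUE))
#' res$report$total / 1e9  # billions of USD per year
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  # --- areas ---------------------------------------------------------------
  areas <- switch(config$area_source,
    esv = { log_checksum(config, esval_fixture("areas_esv.csv"))
            load_area_table("esv") },
    carbon = { log_checksum(config, esval_fixture("areas_carbon.csv"))
               load_area_table("carbon") },
    file = { log_checksum(config, config$area_file)
             read_area_table(config$area_file,
                             total_area_ha = config$total_area_ha) },
    raster = {
      spec <- config$landscape
      spec$seed <- config$seed
      pipeline_log(config, "generating %d x %d synthetic landscape (seed %d)",
                   spec$n_rows, spec$n_cols, config$seed)
      class_areas(generate_landcover(spec))
    })
  pipeline_log(config, "areas: %d classes, %.2f ha", nrow(areas),
               total_area(areas))

  # --- coefficients --------------------------------------------------------
  vc <- if (is.null(config$coefficients)) {
    log_checksum(config, esval_fixture("service_coefficients.csv"))
    load_coefficient_table()
  } else {
    log_checksum(config, config$coefficients)
    coefficient_table(utils::read.csv(config$coefficients,
                                      stringsAsFactors = FALSE))
  }

  # recompute the derived coefficients at the configured parameters
  carbon <- load_carbon_profiles(scc = config$scc)
  sel <- vc$service == "carbon_sequestration" &
    vc$class %in% carbon$class
  vc$value_usd_ha_yr[sel] <-
    carbon$value_usd_ha_yr[match(vc$class[sel], carbon$class)]
  coffee_value <- coffee_npv(config$coffee$production_rate,
                             config$coffee$price_usd_t,
                             config$coffee$cost_fraction)
  vc$value_usd_ha_yr[vc$service == "coffee_production"] <- coffee_value
  vc <- coefficient_table(vc)

  # --- class consistency ---------------------------------------------------
  area_key <- if ("name" %in% names(areas)) areas$name else as.character(areas$code)
  valued <- intersect(unique(vc$class), area_key)
  orphan <- setdiff(unique(vc$class), area_key)
  if (length(orphan) == length(unique(vc$class))) {
    stop("no coefficient class matches any area class; mismatched inputs: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (length(orphan) > 0L) {
    pipeline_log(config, "classes without areas dropped: %s",
                 paste(orphan, collapse = ", "))
    vc <- coefficient_table(vc[vc$class %in% valued, , drop = FALSE])
  }

  # --- valuation, carbon table, sensitivity --------------------------------
  report <- esv_total(areas, vc)
  pipeline_log(config, "total ESV %.3f billion USD / yr", report$total / 1e9)

  carbon_tab <- merge(
    data.frame(class = area_key, area_ha = areas$area_ha),
    as.data.frame(carbon), by = "class", sort = FALSE)
  carbon_tab$total_usd_yr <- carbon_tab$area_ha * carbon_tab$value_usd_ha_yr
  pipeline_log(config, "carbon sequestration %.2f million USD / yr",
               sum(carbon_tab$total_usd_yr) / 1e6)

  sens <- sensitivity_all_classes(areas, vc, delta = config$delta,
                                  mode = config$sensitivity_mode)

  # --- artifacts -----------------------------------------------------------
  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_area_table(areas, p("areas.csv"))
    utils::write.csv(as.data.frame(vc), p("coefficients.csv"), row.names = FALSE)
    utils::write.csv(carbon_tab, p("carbon_valuation.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(sens), p("sensitivity.csv"), row.names = FALSE)
    write_esv_report(report, csv_path = p("esv_by_class_category.csv"),
                     json_path = p("summary.json"))
    paths <- vapply(c("areas.csv", "coefficients.csv", "carbon_valuation.csv",
                      "sensitivity.csv", "esv_by_class_category.csv",
                      "summary.json"), p, character(1))
    pipeline_log(config, "wrote %d artifacts to %s", length(paths),
                 config$out_dir)
  }

  list(areas = areas, coefficients = vc, carbon = carbon_tab,
       report = report, sensitivity = sens, paths = paths)
}
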