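# Packaged Bench-Sheko input tables (plain CSV under inst/extdata).

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return absolute path (or a character vector of file names).
#' @export
esval_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "esval")))
  }
  path <- system.file("extdata", file, package = "esval")
  if (path == "") stop("no packaged file `", file, "`", call. = FALSE)
  path
}

#' Packaged per-class service coefficient table
#'
#' The adjusted per-hectare value coefficients (USD ha-1 yr-1) for the seven
#' valued Bench-Sheko classes, one row per (class, category, service) entry.
#' Blank entries of the published summary are absent, meaning the service is
#' not provided (coefficient 0).
#'
#' @return a [coefficient_table()].
#' @export
load_coefficient_table <- function() {
  coefficient_table(utils::read.csv(esval_fixture("service_coefficients.csv"),
                                    stringsAsFactors = FALSE))
}

#' Packaged per-class area tables
#'
#' Two published area sets exist for the same landscape and do not agree
#' (e.g. remnant forest 146,251.59 vs 146,929.5 ha); they are shipped as
#' separate fixtures and never reconciled. `"carbon"` is the area set printed
#' with the carbon-sequestration totals; `"esv"` the set printed with the
#' ecosystem-service totals.
#'
#' @param source `"esv"` (default) or `"carbon"`.
#' @return an [area_table()] whose declared total, for `"carbon"`, is the
#'   472,118-ha study area (the carbon table omits the built-up class).
#' @export
load_area_table <- function(source = c("esv", "carbon")) {
  source <- match.arg(source)
  if (source == "esv") {
    read_area_table(esval_fixture("areas_esv.csv"))
  } else {
    read_area_table(esval_fixture("areas_carbon.csv"), total_area_ha = 472118)
  }
}

#' Packaged carbon-stock profiles
#'
#' Per-class carbon stock (t C ha-1) with its CO2 equivalent, for the seven
#' vegetated classes.
#'
#' @param scc social cost of carbon in USD per t CO2 (default 1.47).
#' @return data frame from [carbon_profile()].
#' @export
load_carbon_profiles <- function(scc = 1.47) {
  df <- utils::read.csv(esval_fixture("carbon_stocks.csv"), stringsAsFactors = FALSE)
  carbon_profile(df$class, df$carbon_stock_t_ha, scc = scc)
}

#' Packaged value-transfer records
#'
#' The original and inflation-adjusted per-hectare values behind the
#' coefficient table: soil-erosion control (avoided-cost estimates), the
#' benefit-transfer service coefficients, and the provisioning values.
#'
#' @param which one of `"benefit_transfer"`, `"soil_erosion"`,
#'   `"provisioning"`.
#' @return data frame with columns including `class`, `service`,
#'   `original_value`, `adjusted_value`.
#' @export
load_value_transfer <- function(which = c("benefit_transfer", "soil_erosion",
                                          "provisioning")) {
  which <- match.arg(which)
  file <- switch(which,
                 benefit_transfer = "value_transfer.csv",
                 soil_erosion = "soil_erosion.csv",
                 provisioning = "provisioning_values.csv")
  utils::read.csv(esval_fixture(file), stringsAsFactors = FALSE)
}
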