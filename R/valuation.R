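#' Adjust a transferred unit value
#'
#' Benefit transfer carries a unit value estimated at a study site to the
#' policy site, multiplied by an explicit adjustment factor (inflation or
#' price-level correction). The factor is data, supplied per record: source
#' studies span different years and price indices, so no single index applies.
#'
#' @param original unit value in USD ha-1 yr-1, >= 0.
#' @param factor dimensionless multiplier, >= 0.
#' @return adjusted unit value (full precision; rounding happens only at
#'   serialization).
#' @examples
#' adjust_transferred_value(68.5, 84.31 / 68.5)  # 84.31
#' @export
adjust_transferred_value <- function(original, factor) {
  if (any(original < 0)) stop("`original` must be >= 0", call. = FALSE)
  if (any(factor < 0)) stop("`factor` must be >= 0", call. = FALSE)
  original * factor
}

#' Convert carbon stock to CO2 equivalent
#'
#' Multiplies tonnes of elemental carbon by the exact molar mass ratio
#' 44/12 (CO2 to C). The exact ratio, not the 3.67 shorthand, reproduces
#' published CO2 equivalents to 2 decimal places.
#'
#' @param stock carbon stock in t C ha-1, >= 0.
#' @return CO2 equivalent in t CO2 ha-1.
#' @examples
#' carbon_stock_to_co2(461)  # 1690.33
#' @export
carbon_stock_to_co2 <- function(stock) {
  if (any(stock < 0)) stop("carbon stock must be >= 0", call. = FALSE)
  stock * 44 / 12
}

#' Per-class carbon profile
#'
#' Builds the carbon valuation chain for each class: stock (t C ha-1) ->
#' CO2 equivalent (x 44/12) -> annual value (x social cost of carbon).
#'
#' @param class character vector of class names.
#' @param carbon_stock t C ha-1 per class, >= 0.
#' @param scc social cost of carbon, USD per t CO2 (default 1.47, an
#'   annualized estimate for 2021/22).
#' @return data frame of class `carbon_profile` with columns `class`,
#'   `carbon_stock_t_ha`, `co2_t_ha`, `scc`, `value_usd_ha_yr`.
#' @examples
#' carbon_profile("remnant_forest", 461)  # 2484.79 USD / ha / yr
#' @export
carbon_profile <- function(class, carbon_stock, scc = 1.47) {
  stop_if_not_scalar_number(scc, "scc", lower = 0)
  co2 <- carbon_stock_to_co2(carbon_stock)
  structure(
    data.frame(class = class, carbon_stock_t_ha = carbon_stock,
               co2_t_ha = co2, scc = scc, value_usd_ha_yr = co2 * scc),
    class = c("carbon_profile", "data.frame")
  )
}

#' Annual carbon-sequestration value per hectare
#'
#' @param profile a [carbon_profile()] row set.
#' @return named numeric vector, USD ha-1 yr-1 per class.
#' @export
carbon_sequestration_value <- function(profile) {
  stopifnot(inherits(profile, "carbon_profile"))
  stats::setNames(profile$value_usd_ha_yr, profile$class)
}

#' Coffee net present value per hectare
#'
#' Gross revenue is production rate times market price; the net value deducts
#' production cost as a fraction of gross revenue:
#' `NPV = rate x price x (1 - cost_fraction)`.
#'
#' @param production_rate t ha-1 yr-1, >= 0.
#' @param price USD per tonne, >= 0.
#' @param cost_fraction production cost as a fraction of gross revenue, in
#'   \[0, 1\] (default 0.13).
#' @return USD ha-1 yr-1.
#' @examples
#' coffee_npv(0.84, 4685)  # 3423.80
#' @export
coffee_npv <- function(production_rate, price, cost_fraction = 0.13) {
  stop_if_not_scalar_number(production_rate, "production_rate", lower = 0)
  stop_if_not_scalar_number(price, "price", lower = 0)
  stop_if_not_scalar_number(cost_fraction, "cost_fraction", lower = 0, upper = 1)
  production_rate * price * (1 - cost_fraction)
}

#' Construct / validate a service coefficient table
#'
#' Long-format table of per-hectare value coefficients: one row per
#' (class, category, service) with the annual unit value. Missing
#' (class, service) pairs mean the service is not provided (value 0).
#'
#' @param df data frame with columns `class`, `category` (one of
#'   `supporting`, `regulating`, `provisioning`, `cultural`), `service`,
#'   `value_usd_ha_yr` (>= 0).
#' @return the validated data frame with class `coefficient_table`.
#' @export
coefficient_table <- function(df) {
  need <- c("class", "category", "service", "value_usd_ha_yr")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  bad <- setdiff(unique(df$category), service_categories())
  if (length(bad) > 0L) {
    stop("unknown service categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$value_usd_ha_yr < 0)) stop("coefficients must be >= 0", call. = FALSE)
  key <- paste(df$class, df$service, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("class", "service")]
    stop("duplicate (class, service) entries: ",
         paste(paste(dup$class, dup$service, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("coefficient_table", "data.frame"))
}

#' The four Millennium Ecosystem Assessment service categories
#' @return character vector.
#' @export
service_categories <- function() {
  c("supporting", "regulating", "provisioning", "cultural")
}

#' Assemble a service coefficient table from its sources
#'
#' Unions three kinds of per-hectare unit values into one
#' [coefficient_table()]: inflation-adjusted transferred values, the carbon
#' valuation chain (entered under the regulating category as climate
#' regulation), and directly supplied values such as the coffee net present
#' value. Duplicate (class, service) pairs across sources are an error.
#'
#' @param transfers data frame with columns `class`, `category`, `service`,
#'   and either `adjusted_value` or both `original_value` and
#'   `adjustment_factor` (adjusted on the fly), or `NULL`.
#' @param carbon a [carbon_profile()] or `NULL`; valued as service
#'   `"carbon_sequestration"`, category `"regulating"`.
#' @param extra data frame with columns `class`, `category`, `service`,
#'   `value_usd_ha_yr`, or `NULL`.
#' @return a [coefficient_table()].
#' @export
assemble_coefficient_table <- function(transfers = NULL, carbon = NULL,
                                       extra = NULL) {
  parts <- list()
  if (!is.null(transfers)) {
    stopifnot(all(c("class", "category", "service") %in% names(transfers)))
    value <- if ("adjusted_value" %in% names(transfers)) {
      transfers$adjusted_value
    } else {
      adjust_transferred_value(transfers$original_value,
                               transfers$adjustment_factor)
    }
    parts$transfers <- data.frame(class = transfers$class,
                                  category = transfers$category,
                                  service = transfers$service,
                                  value_usd_ha_yr = value)
  }
  if (!is.null(carbon)) {
    stopifnot(inherits(carbon, "carbon_profile"))
    parts$carbon <- data.frame(class = carbon$class, category = "regulating",
                               service = "carbon_sequestration",
                               value_usd_ha_yr = carbon$value_usd_ha_yr)
  }
  if (!is.null(extra)) {
    stopifnot(all(c("class", "category", "service", "value_usd_ha_yr") %in%
                    names(extra)))
    parts$extra <- extra[, c("class", "category", "service", "value_usd_ha_yr")]
  }
  if (length(parts) == 0L) {
    return(coefficient_table(data.frame(class = character(), category = character(),
                                        service = character(),
                                        value_usd_ha_yr = numeric())))
  }
  coefficient_table(do.call(rbind, unname(parts)))
}

#' Per-class, per-category coefficient subtotals
#'
#' Sums the unit-value coefficients of each class within each service
#' category — the per-hectare subtotals of the published coefficient summary.
#'
#' @param vc a [coefficient_table()].
#' @return data frame with columns `class`, `category`, `value_usd_ha_yr`
#'   (absent categories are 0 rows).
#' @export
category_subtotals <- function(vc) {
  stopifnot(inherits(vc, "coefficient_table"))
  if (nrow(vc) == 0L) {
    return(data.frame(class = character(), category = character(),
                      value_usd_ha_yr = numeric()))
  }
  out <- stats::aggregate(value_usd_ha_yr ~ class + category, data = vc, FUN = sum)
  out[order(out$class, match(out$category, service_categories())), , drop = FALSE]
}

#' Per-class total coefficient
#'
#' @param vc a [coefficient_table()].
#' @return named numeric vector: total USD ha-1 yr-1 per class across all
#'   services.
#' @export
class_total_coefficients <- function(vc) {
  stopifnot(inherits(vc, "coefficient_table"))
  if (nrow(vc) == 0L) return(stats::setNames(numeric(), character()))
  agg <- stats::aggregate(value_usd_ha_yr ~ class, data = vc, FUN = sum)
  stats::setNames(agg$value_usd_ha_yr, agg$class)
}

# area lookup shared by the ESV aggregations; errors on classes the
# coefficient table has but the area table lacks
vc_area_lookup <- function(areas, vc) {
  stopifnot(inherits(areas, "area_table"), inherits(vc, "coefficient_table"))
  area_key <- if ("name" %in% names(areas)) areas$name else as.character(areas$code)
  missing <- setdiff(unique(vc$class), area_key)
  if (length(missing) > 0L) {
    stop("classes without an area entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(areas$area_ha, area_key)
}

#' Ecosystem service value by land-cover class
#'
#' `ESV_k = sum_f A_k VC_kf`: each class's area times the sum of its unit
#' coefficients.
#'
#' @param areas an [area_table()] whose `name` (or `code`) column matches the
#'   coefficient table's `class` column.
#' @param vc a [coefficient_table()].
#' @return named numeric vector, USD yr-1 per class.
#' @export
esv_by_class <- function(areas, vc) {
  a <- vc_area_lookup(areas, vc)
  if (nrow(vc) == 0L) return(stats::setNames(numeric(), character()))
  agg <- stats::aggregate(value_usd_ha_yr ~ class, data = vc, FUN = sum)
  stats::setNames(a[agg$class] * agg$value_usd_ha_yr, agg$class)
}

#' Ecosystem service value by service function
#'
#' `ESV_f = sum_k A_k VC_kf`: each service's value summed over classes.
#'
#' @inheritParams esv_by_class
#' @return named numeric vector, USD yr-1 per service function.
#' @export
esv_by_function <- function(areas, vc) {
  a <- vc_area_lookup(areas, vc)
  if (nrow(vc) == 0L) return(stats::setNames(numeric(), character()))
  contrib <- a[vc$class] * vc$value_usd_ha_yr
  agg <- stats::aggregate(contrib, by = list(service = vc$service), FUN = sum)
  stats::setNames(agg$x, agg$service)
}

#' Full ecosystem service valuation report
#'
#' Evaluates `ESV = sum_f sum_k A_k VC_kf` together with its class,
#' service-function, and class-by-category marginals. The total equals both
#' marginal sums by construction (bilinearity of the area-coefficient
#' product).
#'
#' @inheritParams esv_by_class
#' @return object of class `esv_report`: list with `by_class`, `by_function`
#'   (named vectors, USD yr-1), `by_class_category` (data frame with
#'   `class`, `category`, `value_usd_yr`), and `total` (USD yr-1).
#' @examples
#' rep <- esv_total(load_area_table("esv"), load_coefficient_table())
#' print(rep)
#' @export
esv_total <- function(areas, vc) {
  a <- vc_area_lookup(areas, vc)
  by_class <- esv_by_class(areas, vc)
  by_function <- esv_by_function(areas, vc)
  sub <- category_subtotals(vc)
  sub$value_usd_yr <- a[sub$class] * sub$value_usd_ha_yr
  structure(
    list(by_class = by_class, by_function = by_function,
         by_class_category = sub[, c("class", "category", "value_usd_yr")],
         total = sum(by_class)),
    class = "esv_report"
  )
}

#' @export
print.esv_report <- function(x, digits = 3, ...) {
  cat("Ecosystem service valuation\n")
  cat(sprintf("  total: %.*f billion USD / yr\n", digits, x$total / 1e9))
  cat("  by class (million USD / yr):\n")
  for (cl in names(x$by_class)) {
    cat(sprintf("    %-20s %10.*f\n", cl, digits, x$by_class[[cl]] / 1e6))
  }
  invisible(x)
}

#' Serialize an ESV report
#'
#' Writes the per-class/per-category table as CSV (values in millions of USD,
#' 3 decimal places) and the full report as JSON. Rounding happens only here;
#' all internal math is at full precision.
#'
#' @param report an [esv_report][esv_total].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_esv_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "esv_report"))
  if (!is.null(csv_path)) {
    tab <- report$by_class_category
    tab$value_million_usd <- round(tab$value_usd_yr / 1e6, 3)
    tab$value_usd_yr <- NULL
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(total_usd_yr = report$total,
           total_billion_usd = round(report$total / 1e9, 3),
           by_class_usd_yr = as.list(report$by_class),
           by_function_usd_yr = as.list(report$by_function)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
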