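#' Coefficient of sensitivity of the ecosystem service value
#'
#' Elasticity of ESV with respect to a uniform perturbation of one class's
#' value coefficients:
#' `CS = | ((ESV_j - ESV_i) / ESV_i) / ((VC_j - VC_i) / VC_i) |`,
#' where `i` is the initial and `j` the adjusted state and all of the target
#' class's service coefficients are scaled by `1 + delta` (the conventional
#' adjustment is +/-50%, `delta = +/-0.5`).
#'
#' Two readings of "ESV" are supported. In `per_class` mode (default) the
#' response variable is the target class's own ESV; because ESV is linear in
#' the coefficients, CS is then exactly 1 for every class and every delta —
#' complete elasticity. In `total` mode the response is the grand total, and
#' CS equals the class's share of total ESV (in \[0, 1\], summing to 1 over
#' classes), which ranks classes by how much the total depends on their
#' coefficients.
#'
#' @param areas an [area_table()].
#' @param vc a [coefficient_table()].
#' @param target_class class whose coefficients are perturbed; must have a
#'   nonzero ESV.
#' @param delta signed fractional perturbation, nonzero (default 0.5).
#' @param mode `"per_class"` (default) or `"total"`.
#' @return data frame of class `sensitivity_result` with columns `class`,
#'   `mode`, `delta`, `esv_initial`, `esv_adjusted`, `cs`.
#' @examples
#' areas <- load_area_table("esv")
#' vc <- load_coefficient_table()
#' sensitivity_coefficient(areas, vc, "wetland")$cs  # exactly 1
#' @export
sensitivity_coefficient <- function(areas, vc, target_class, delta = 0.5,
                                    mode = c("per_class", "total")) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(delta, "delta")
  if (delta == 0) stop("`delta` must be nonzero", call. = FALSE)
  stopifnot(inherits(vc, "coefficient_table"))
  if (!target_class %in% vc$class) {
    stop("`target_class` '", target_class, "' not in coefficient table",
         call. = FALSE)
  }
  esv_of <- function(table) {
    if (mode == "per_class") {
      esv_by_class(areas, table)[[as.character(target_class)]]
    } else {
      esv_total(areas, table)$total
    }
  }
  perturbed <- vc
  sel <- perturbed$class == target_class
  perturbed$value_usd_ha_yr[sel] <- perturbed$value_usd_ha_yr[sel] * (1 + delta)
  esv_i <- esv_of(vc)
  if (esv_i == 0) {
    stop("initial ESV for class '", target_class,
         "' is 0; sensitivity undefined", call. = FALSE)
  }
  esv_j <- esv_of(perturbed)
  # uniform scaling: the relative coefficient change is delta for every entry
  cs <- abs(((esv_j - esv_i) / esv_i) / delta)
  structure(
    data.frame(class = target_class, mode = mode, delta = delta,
               esv_initial = esv_i, esv_adjusted = esv_j, cs = cs),
    class = c("sensitivity_result", "data.frame")
  )
}

#' Sensitivity coefficients for every class
#'
#' Runs [sensitivity_coefficient()] over all classes of the coefficient
#' table.
#'
#' @inheritParams sensitivity_coefficient
#' @return data frame with one `sensitivity_result` row per class.
#' @export
sensitivity_all_classes <- function(areas, vc, delta = 0.5,
                                    mode = c("per_class", "total")) {
  mode <- match.arg(mode)
  classes <- unique(vc$class)
  do.call(rbind, lapply(classes, function(cl) {
    sensitivity_coefficient(areas, vc, cl, delta = delta, mode = mode)
  }))
}
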