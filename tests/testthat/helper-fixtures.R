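# shared in-code fixtures for the test suite

# single-class raster of the given size
uniform_raster <- function(n = 10, code = 1L, name = "forest", pixel = 10) {
  lc_raster(matrix(code, n, n), pixel_size_m = pixel,
            class_names = stats::setNames(name, code))
}

# two-class spec with equal proportions and no NDVI targets
two_class_spec <- function(n = 100, seed = 1L, props = c(0.5, 0.5)) {
  landscape_spec(n, n,
                 classes = data.frame(code = 1:2, name = c("a", "b"),
                                      proportion = props),
                 ndvi_targets = NULL, seed = seed)
}

# random confusion matrix with strictly positive total and p_e < 1
random_confusion_matrix <- function(k = 4) {
  m <- matrix(stats::rpois(k * k, lambda = 20) + (diag(k) > 0), k, k)
  confusion_matrix(m)
}

# random valuation instance: areas plus a sparse coefficient table
random_valuation_instance <- function(n_class = 5, n_service = 6) {
  classes <- paste0("class_", seq_len(n_class))
  services <- paste0("svc_", seq_len(n_service))
  cats <- sample(service_categories(), n_service, replace = TRUE)
  grid <- expand.grid(class = classes, service = services,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < 0.7
  keep[sample(nrow(grid), 1)] <- TRUE  # never fully empty
  grid <- grid[keep, , drop = FALSE]
  grid$category <- cats[match(grid$service, services)]
  grid$value_usd_ha_yr <- stats::runif(nrow(grid), 0, 3000)
  areas <- area_table(data.frame(code = seq_len(n_class), name = classes,
                                 area_ha = stats::runif(n_class, 100, 2e5)))
  list(areas = areas, vc = coefficient_table(grid))
}

# independent oracle: plain double loop over (class, service) pairs
brute_force_esv <- function(areas, vc) {
  key <- if ("name" %in% names(areas)) areas$name else as.character(areas$code)
  total <- 0
  for (i in seq_len(nrow(areas))) {
    for (j in seq_len(nrow(vc))) {
      if (vc$class[j] == key[i]) {
        total <- total + areas$area_ha[i] * vc$value_usd_ha_yr[j]
      }
    }
  }
  total
}
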