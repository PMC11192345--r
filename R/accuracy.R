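#' Build a confusion matrix from labelled reference points
#'
#' Tallies map label against reference label. Orientation follows the
#' remote-sensing convention: rows are the map labels (user's perspective),
#' columns the reference labels (producer's perspective).
#'
#' @param points data frame with columns `true_class` (reference) and
#'   `mapped_class` (map), e.g. from [generate_reference_points()].
#' @param class_order ordered class codes defining the matrix layout; every
#'   label in `points` must occur here.
#' @return square integer matrix of class `confusion_matrix`, dimnames
#'   `map` x `reference`.
#' @examples
#' pts <- data.frame(true_class = c(1, 1, 2), mapped_class = c(1, 2, 2))
#' build_confusion(pts, class_order = c(1, 2))
#' @export
build_confusion <- function(points, class_order) {
  stopifnot(all(c("true_class", "mapped_class") %in% names(points)))
  unknown <- setdiff(unique(c(points$true_class, points$mapped_class)), class_order)
  if (length(unknown) > 0L) {
    stop("class codes not in `class_order`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  f_map <- factor(points$mapped_class, levels = class_order)
  f_ref <- factor(points$true_class, levels = class_order)
  cm <- unclass(table(map = f_map, reference = f_ref))
  confusion_matrix(cm)
}

#' Construct / validate a confusion matrix
#'
#' @param counts square numeric matrix of nonnegative counts, rows = map
#'   labels, columns = reference labels. Dimnames, when absent, are taken
#'   from the row indices.
#' @return the matrix with class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square", call. = FALSE)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(map = seq_len(nrow(counts)),
                             reference = seq_len(ncol(counts)))
  }
  structure(counts, class = c("confusion_matrix", class(counts)))
}

cm_counts <- function(cm) {
  m <- unclass(cm)
  if (sum(m) <= 0) stop("confusion matrix is empty", call. = FALSE)
  m
}

#' Overall accuracy
#'
#' Fraction of points whose map label agrees with the reference label:
#' trace / total.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  m <- cm_counts(cm)
  sum(diag(m)) / sum(m)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum_i row_i col_i / total^2`. Equals 1 only for a perfect diagonal;
#' undefined (error) when `p_e = 1`, i.e. all counts in a single cell.
#'
#' @param cm a [confusion_matrix()].
#' @return the kappa coefficient (<= 1).
#' @export
kappa_coefficient <- function(cm) {
  m <- cm_counts(cm)
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    stop("kappa undefined: expected agreement is 1 (all counts in one cell)",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Producer's accuracy per class
#'
#' Fraction of reference points of each class that the map got right
#' (diagonal over column total); the complement of omission error. Classes
#' with no reference points are `NA`.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector, one entry per class.
#' @export
producers_accuracy <- function(cm) {
  m <- cm_counts(cm)
  ct <- colSums(m)
  out <- diag(m) / ct
  out[ct == 0] <- NA_real_
  stats::setNames(out, colnames(m))
}

#' User's accuracy per class
#'
#' Fraction of map points of each class that are correct (diagonal over row
#' total); the complement of commission error. Classes never mapped are `NA`.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector, one entry per class.
#' @export
users_accuracy <- function(cm) {
  m <- cm_counts(cm)
  rt <- rowSums(m)
  out <- diag(m) / rt
  out[rt == 0] <- NA_real_
  stats::setNames(out, rownames(m))
}

#' Full accuracy report
#'
#' Bundles overall accuracy, Cohen's kappa and the per-class producer's and
#' user's accuracies into one table-shaped summary.
#'
#' @param cm a [confusion_matrix()].
#' @return list with elements `overall_accuracy`, `kappa`, and `per_class`
#'   (data frame with columns `class`, `producers_accuracy`, `users_accuracy`).
#' @export
accuracy_report <- function(cm) {
  list(
    overall_accuracy = overall_accuracy(cm),
    kappa = kappa_coefficient(cm),
    per_class = data.frame(
      class = colnames(cm_counts(cm)),
      producers_accuracy = unname(producers_accuracy(cm)),
      users_accuracy = unname(users_accuracy(cm))
    )
  )
}
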