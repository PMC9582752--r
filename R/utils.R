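# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_gt <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "gtkit_error"), ...)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_gt(sprintf("`%s` must be a single finite number.", name), "gt_validation_error")
  }
  if (positive && x <= 0) {
    stop_gt(sprintf("`%s` must be > 0 (got %g).", name, x), "gt_validation_error")
  }
  if (nonneg && x < 0) {
    stop_gt(sprintf("`%s` must be >= 0 (got %g).", name, x), "gt_validation_error")
  }
  invisible(x)
}

# squared euclidean distance matrix between two n x 3 coordinate matrices
cross_dist <- function(a, b) {
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coord_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Restrict an atom table to heavy (non-hydrogen) atoms
#'
#' @param atoms Atom tibble with an `element` column.
#' @return The input rows whose element is not hydrogen, coordinates
#'   untouched.
#' @export
heavy_atoms <- function(atoms) {
  dplyr::filter(atoms, toupper(.data$element) != "H")
}

is_heavy <- function(element) toupper(element) != "H"
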