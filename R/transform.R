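#' Rigid-body transforms
#'
#' A `rigid_transform` is a proper rotation plus a translation, applied as
#' `x' = R x + t` (coordinates in Angstroms). These carry the maps produced
#' by [standard_orientation()] and [kabsch_superpose()].
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation vector (Angstroms).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    abort("rigid_transform requires finite rotation and translation entries.",
          class = "hingescan_error_transform")
  }
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1.",
          class = "hingescan_error_transform")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 numeric matrix, or a tibble with `x`, `y`, `z` columns
#'   (an atom table), in which case the same tibble is returned with the
#'   coordinates replaced.
#' @param transform a [rigid_transform()].
#' @return Object of the same shape as `xyz` with transformed coordinates.
#' @export
apply_transform <- function(xyz, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.data.frame(xyz)) {
    m <- as.matrix(xyz[, c("x", "y", "z")])
    m <- apply_transform(m, transform)
    xyz$x <- m[, 1]; xyz$y <- m[, 2]; xyz$z <- m[, 3]
    return(xyz)
  }
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}
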