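#' Fit angle-normalization constants
#'
#' Per-axis absolute maxima of a training set of wrist angles, used to
#' normalize each axis before forming the sum/difference coordinates.
#'
#' @param angles Time x 2 matrix of wrist angles in degrees (column 1:
#'   flexion-extension with extension positive; column 2: radial-ulnar with
#'   radial positive), or a list of such matrices.
#' @return Named numeric vector `c(max_x, max_y)`.
#' @export
fit_normalization <- function(angles) {
  if (is.list(angles) && !is.data.frame(angles)) {
    angles <- do.call(rbind, lapply(angles, as_matrix))
  }
  angles <- as_matrix(angles)
  if (ncol(angles) != 2L) stopf("angles must have two columns (x, y)")
  mx <- max(abs(angles[, 1L]))
  my <- max(abs(angles[, 2L]))
  if (mx == 0 || my == 0) {
    stopf("degenerate axis: zero absolute maximum on %s",
          paste(c("x", "y")[c(mx, my) == 0], collapse = " and "))
  }
  c(max_x = mx, max_y = my)
}

#' Normalized sum/difference transform of wrist angles
#'
#' Self-paced wrist movements drift diagonally; normalizing each axis by its
#' absolute maximum and taking the sum `u = x/max_x + y/max_y` and difference
#' `v = x/max_x - y/max_y` rotates the coordinate frame so the drifted
#' diagonals become the axes of the regression targets.
#'
#' @param angles Time x 2 angle matrix, degrees.
#' @param max_x,max_y Positive normalization constants, degrees (from
#'   [fit_normalization()]).
#' @return Time x 2 matrix with columns `u` (sum) and `v` (difference);
#'   normalization constants attached as attribute `norm`.
#' @export
to_sum_diff <- function(angles, max_x, max_y) {
  angles <- as_matrix(angles)
  if (ncol(angles) != 2L) stopf("angles must have two columns (x, y)")
  assert_scalar_pos(max_x, "max_x")
  assert_scalar_pos(max_y, "max_y")
  xn <- angles[, 1L] / max_x
  yn <- angles[, 2L] / max_y
  out <- cbind(u = xn + yn, v = xn - yn)
  attr(out, "norm") <- c(max_x = max_x, max_y = max_y)
  out
}

#' Invert the normalized sum/difference transform
#'
#' Exact algebraic inverse of [to_sum_diff()]:
#' `x = max_x (u + v) / 2`, `y = max_y (u - v) / 2`.
#'
#' @param sd Time x 2 matrix with columns u, v; if `max_x`/`max_y` are
#'   missing, they are taken from the matrix's `norm` attribute.
#' @param max_x,max_y Positive normalization constants, degrees.
#' @return Time x 2 angle matrix (columns x, y), degrees.
#' @export
from_sum_diff <- function(sd, max_x = NULL, max_y = NULL) {
  sd <- as_matrix(sd)
  if (ncol(sd) != 2L) stopf("sum/diff input must have two columns (u, v)")
  nrm <- attr(sd, "norm")
  if (is.null(max_x)) max_x <- nrm[["max_x"]]
  if (is.null(max_y)) max_y <- nrm[["max_y"]]
  assert_scalar_pos(max_x, "max_x")
  assert_scalar_pos(max_y, "max_y")
  cbind(x = max_x * (sd[, 1L] + sd[, 2L]) / 2,
        y = max_y * (sd[, 1L] - sd[, 2L]) / 2)
}
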