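#' Wrap positions into the periodic box
#'
#' Maps each coordinate into the half-open interval `[-L/2, L/2)` of its
#' axis; the result differs from the input by an integer multiple of the
#' box length per axis.
#'
#' @param x A 3-vector or n x 3 matrix of positions.
#' @param box A [domain_box()].
#' @return Wrapped positions with the same shape as `x`.
#' @examples
#' wrap_position(c(16, 0, 0), domain_box(30))  # -14 0 0
#' @export
wrap_position <- function(x, box) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != 3) stop("positions must have 3 columns")
  if (any(!is.finite(x))) stop("non-finite input coordinates")
  out <- wrap_position_cpp(x, box$lengths)
  if (vec) drop(out) else out
}

#' Minimum-image displacement between points
#'
#' Returns the shortest periodic displacement from `a` to `b`: each
#' component lies in `[-L/2, L/2)` and the norm equals the periodicised
#' Euclidean distance.
#'
#' @param a,b 3-vectors or n x 3 matrices of positions.
#' @inheritParams wrap_position
#' @return Displacement(s) with the same shape as the inputs.
#' @examples
#' periodic_displacement(c(14, 0, 0), c(-14, 0, 0), domain_box(30))  # 2 0 0
#' @export
periodic_displacement <- function(a, b, box) {
  vec <- is.null(dim(a)) && is.null(dim(b))
  a <- rbind(a); b <- rbind(b)
  if (ncol(a) != 3 || ncol(b) != 3 || nrow(a) != nrow(b))
    stop("a and b must be 3-vectors or matching n x 3 matrices")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite input coordinates")
  out <- periodic_displacement_cpp(a, b, box$lengths)
  if (vec) drop(out) else out
}

#' Closest points between two fibre axes
#'
#' Finds the mutually closest points of the two axis segments under the
#' minimum-image convention. Returns the abscissae `s1`, `s2` (in
#' `[-l_fib/2, l_fib/2]`, measured from each centre along each direction),
#' their distance, and the minimum-image vector `u` from the closest point
#' on fibre 1 to the closest point on fibre 2. For exactly parallel
#' segments the minimiser set is a continuum; the midpoint of the overlap
#' interval is returned as a deterministic tie-break.
#'
#' @param x1,omega1 Centre and unit direction of fibre 1.
#' @param x2,omega2 Centre and unit direction of fibre 2.
#' @param geometry A [fibre_geometry()].
#' @param box A [domain_box()].
#' @return `list(s1, s2, distance, u)`.
#' @export
segment_closest_points <- function(x1, omega1, x2, omega2, geometry, box) {
  for (v in list(x1, omega1, x2, omega2))
    if (length(v) != 3 || any(!is.finite(v))) stop("inputs must be finite 3-vectors")
  if (abs(sum(omega1^2) - 1) > 1e-9 || abs(sum(omega2^2) - 1) > 1e-9)
    stop("directions must be unit vectors")
  segment_closest_cpp(as.numeric(x1), as.numeric(omega1),
                      as.numeric(x2), as.numeric(omega2),
                      geometry$l_fib, box$lengths)
}
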