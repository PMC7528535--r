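#' B-spline basis with regulatory-informed knots
#'
#' Builds the quadratic B-spline basis used to model age-varying
#' exposure-response parameters.  The default knot recipe places knots at
#' each ICH E11 age-group boundary (0, 28/365, 2, 12, 18 years, excluding
#' pre-term newborns), `interior_per_group` equally spaced knots strictly
#' inside each group, and `external_each_side` external knots below 0 and
#' above 18 (spaced by extending the adjacent knot spacing).  With the
#' defaults this yields 29 knots and \eqn{J = 29 - d - 1 = 26} basis
#' functions of degree \eqn{d = 2}.  Knots are deliberately denser over the
#' youngest ages, where model parameters are expected to change fastest.
#'
#' @param boundaries Strictly increasing age-group boundaries spanning the
#'   age domain.
#' @param interior_per_group Number of equally spaced knots strictly inside
#'   each group.
#' @param external_each_side Number of external knots on each side.
#' @param degree Spline degree (default 2, i.e. quadratic).
#' @return An object of class `bspline_basis` with elements `knots`,
#'   `degree`, `J` and `boundaries`.
#' @examples
#' b <- build_knots()
#' b$J  # 26
#' @export
build_knots <- function(boundaries = c(0, 28 / 365, 2, 12, 18),
                        interior_per_group = 5,
                        external_each_side = 2,
                        degree = 2) {
  boundaries <- as.numeric(boundaries)
  if (any(diff(boundaries) <= 0))
    stop("group boundaries must be strictly increasing")
  interior <- unlist(lapply(seq_len(length(boundaries) - 1L), function(g) {
    lo <- boundaries[g]; hi <- boundaries[g + 1L]
    if (interior_per_group == 0L) return(numeric(0))
    seq(lo, hi, length.out = interior_per_group + 2L)[-c(1L, interior_per_group + 2L)]
  }))
  internal <- sort(c(boundaries, interior))
  if (anyDuplicated(internal))
    stop("degenerate groups produced duplicated knots")
  lo_step <- internal[2] - internal[1]
  hi_step <- internal[length(internal)] - internal[length(internal) - 1L]
  knots <- c(internal[1] - rev(seq_len(external_each_side)) * lo_step,
             internal,
             internal[length(internal)] + seq_len(external_each_side) * hi_step)
  J <- length(knots) - degree - 1L
  if (J < 1L) stop("too few knots for the requested degree")
  structure(list(knots = knots, degree = degree, J = J,
                 boundaries = boundaries),
            class = "bspline_basis")
}

#' Evaluate the B-spline basis at given ages
#'
#' Returns the n-by-J matrix with entry (i, j) equal to the j-th basis
#' function evaluated at the i-th age, computed with
#' [splines::splineDesign()].  Rows sum to one at every age in the domain
#' (partition of unity) and each column vanishes outside its local support.
#'
#' @param ages Numeric vector of ages in \[0, 18\].
#' @param basis A [build_knots()] object.
#' @return Numeric matrix of basis values.
#' @export
basis_matrix <- function(ages, basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  ages <- as.numeric(ages)
  lo <- basis$boundaries[1]; hi <- basis$boundaries[length(basis$boundaries)]
  if (any(ages < lo) || any(ages > hi))
    stop("ages outside the basis domain [", lo, ", ", hi, "]")
  splines::splineDesign(knots = basis$knots, x = ages,
                        ord = basis$degree + 1L, outer.ok = FALSE)
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("<bspline_basis: degree %d, %d knots, J = %d>\n",
              x$degree, length(x$knots), x$J))
  invisible(x)
}
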