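#' Age-varying parameter functions
#'
#' A `param_fn` represents one parameter of an exposure-response model as a
#' function of age on the closed interval \[0, 18\] years.  Three
#' representations are supported:
#' \describe{
#'   \item{step}{piecewise constant on age groups (left-open, right-closed
#'     intervals, with age 0 assigned to the first group) -- the natural
#'     output of a categorical fit or a partition tree;}
#'   \item{grid}{continuous, piecewise linear interpolation between values on
#'     an age grid -- the output of bootstrap aggregation;}
#'   \item{basis}{a basis expansion, i.e. a coefficient vector multiplied
#'     into a B-spline basis, optionally on a link scale -- the output of
#'     the Bayesian penalised B-spline fits.}
#' }
#' Evaluation outside \[0, 18\] is an error.
#'
#' @param boundaries Strictly increasing numeric vector of group boundaries
#'   spanning the age domain; length one more than `values`.
#' @param values Numeric vector of per-group (or per-grid-point) values.
#' @param ages Strictly increasing age grid covering \[0, 18\].
#' @param basis A [bspline_basis] object.
#' @param coef Coefficient vector of length `basis$J`.
#' @param link Either `"identity"` or `"log"`: with `"log"` the function
#'   evaluates to `exp(B(a) %*% coef)`, guaranteeing positivity.
#' @return An object of class `param_fn`.
#' @seealso [pf_eval()], [pf_constant()]
#' @examples
#' f <- pf_step(c(0, 2, 12, 18), c(1, 2, 3))
#' pf_eval(f, c(0, 1, 2, 5, 18))
#' @name param_fn
NULL

AGE_MIN <- 0
AGE_MAX <- 18

#' @rdname param_fn
#' @export
pf_step <- function(boundaries, values) {
  boundaries <- as.numeric(boundaries)
  values <- as.numeric(values)
  if (length(boundaries) != length(values) + 1L)
    stop("`boundaries` must have length(values) + 1 entries")
  if (any(diff(boundaries) <= 0))
    stop("`boundaries` must be strictly increasing")
  structure(list(kind = "step", boundaries = boundaries, values = values),
            class = "param_fn")
}

#' @rdname param_fn
#' @export
pf_grid <- function(ages, values) {
  ages <- as.numeric(ages)
  values <- as.numeric(values)
  if (length(ages) != length(values))
    stop("`ages` and `values` must have equal length")
  if (any(diff(ages) <= 0)) stop("grid ages must be strictly increasing")
  if (ages[1] > AGE_MIN || ages[length(ages)] < AGE_MAX)
    stop("grid must cover the full age domain [0, 18]")
  structure(list(kind = "grid", ages = ages, values = values),
            class = "param_fn")
}

#' @rdname param_fn
#' @export
pf_basis <- function(basis, coef, link = c("identity", "log")) {
  link <- match.arg(link)
  stopifnot(inherits(basis, "bspline_basis"))
  coef <- as.numeric(coef)
  if (length(coef) != basis$J)
    stop("`coef` must have length basis$J = ", basis$J)
  structure(list(kind = "basis", basis = basis, coef = coef, link = link),
            class = "param_fn")
}

#' Constant parameter function
#'
#' Convenience constructor for an age-invariant parameter.
#'
#' @param value The constant value.
#' @return A `param_fn` taking `value` at every age.
#' @export
pf_constant <- function(value) {
  pf_step(c(AGE_MIN, AGE_MAX), value)
}

#' Evaluate a parameter function at given ages
#'
#' @param fn A [param_fn] object (or a plain numeric scalar, treated as a
#'   constant).
#' @param age Numeric vector of ages in \[0, 18\].
#' @return Numeric vector of parameter values, one per age.
#' @export
pf_eval <- function(fn, age) {
  if (is.numeric(fn) && length(fn) == 1L) return(rep(fn, length(age)))
  stopifnot(inherits(fn, "param_fn"))
  age <- as.numeric(age)
  if (any(is.na(age)) || any(age < AGE_MIN) || any(age > AGE_MAX))
    stop("age outside the model domain [0, 18]")
  switch(fn$kind,
    step = {
      # (a_{h-1}, a_h] membership; age at the lower end goes to group 1
      idx <- findInterval(age, fn$boundaries, left.open = TRUE)
      idx[idx < 1L] <- 1L
      idx[idx > length(fn$values)] <- length(fn$values)
      fn$values[idx]
    },
    grid = stats::approx(fn$ages, fn$values, xout = age,
                         method = "linear", rule = 1)$y,
    basis = {
      eta <- drop(basis_matrix(age, fn$basis) %*% fn$coef)
      if (fn$link == "log") exp(eta) else eta
    },
    stop("unknown param_fn kind"))
}

#' @export
print.param_fn <- function(x, ...) {
  switch(x$kind,
    step = cat(sprintf(
      "<param_fn: step, %d groups on [%g, %g]>\n", length(x$values),
      x$boundaries[1], x$boundaries[length(x$boundaries)])),
    grid = cat(sprintf("<param_fn: interpolated grid, %d points>\n",
                       length(x$ages))),
    basis = cat(sprintf("<param_fn: basis expansion, J = %d, link = %s>\n",
                        x$basis$J, x$link)))
  invisible(x)
}
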