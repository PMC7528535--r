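# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Cox-de Boor recursion for a single B-spline basis function, coded from
# the textbook recurrence (independent of splines::splineDesign).
cox_de_boor <- function(x, j, d, knots) {
  if (d == 0) {
    return(as.numeric(knots[j] <= x & x < knots[j + 1]))
  }
  left <- 0
  if (knots[j + d] > knots[j]) {
    left <- (x - knots[j]) / (knots[j + d] - knots[j]) *
      cox_de_boor(x, j, d - 1, knots)
  }
  right <- 0
  if (knots[j + d + 1] > knots[j + 1]) {
    right <- (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) *
      cox_de_boor(x, j + 1, d - 1, knots)
  }
  left + right
}

# bisection on expected_response, used as the inversion oracle
bisect_exposure <- function(spec, age, target, lo = 0, hi = 1e6,
                            tol = 1e-10) {
  f <- function(cc) expected_response(spec, age, cc) - target
  stopifnot(f(lo) * f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# small helper: simulated dataset from an age-invariant linear truth
flat_linear_data <- function(n = 200, g0 = 4.7, gC = -0.05,
                             sigma2 = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- stats::runif(n, 0, 18)
  C <- stats::rlnorm(n, log(2.94), sqrt(0.921))
  y <- g0 + gC * C + stats::rnorm(n, 0, sqrt(sigma2))
  er_dataset(a, C, y)
}
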