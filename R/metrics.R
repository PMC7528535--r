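#' Composite Simpson quadrature on a uniform grid
#'
#' @param values Function values on a uniform grid with an odd number of
#'   points.
#' @param step Grid spacing.
#' @return The Simpson-rule integral.
#' @examples
#' x <- seq(0, 18, length.out = 2001)
#' simpson_integrate(x^2, x[2] - x[1])  # exactly 1944
#' @export
simpson_integrate <- function(values, step) {
  sum(simpson_weights(length(values)) * values) * step
}

simpson_weights <- function(n) {
  if (n < 3L || n %% 2L == 0L)
    stop("composite Simpson needs an odd number of points (>= 3), got ", n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w / 3
}

#' Metrics configuration for simulation studies
#'
#' Grid sizes for the Simpson-integrated metrics.  Defaults are
#' desk-scale (2001 points); larger grids (e.g. 40,001) can be configured
#' for high-resolution runs.  Even sizes are incremented to the next odd
#' number, with a notice, so composite Simpson applies.
#'
#' @param age_points Number of equally spaced ages on \[0, 18\].
#' @param exposure_points Number of equally spaced exposures.
#' @param exposure_range Exposure integration range (default \[0, 18\]).
#' @param replicates Default replicate count M for [run_study()].
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(age_points = 2001L, exposure_points = 2001L,
                           exposure_range = c(0, 18), replicates = 1000L) {
  fix_odd <- function(n, what) {
    n <- as.integer(n)
    if (n < 3L) stop(what, " grid needs at least 3 points")
    if (n %% 2L == 0L) {
      message(what, " grid size ", n, " incremented to ", n + 1L,
              " for Simpson quadrature")
      n <- n + 1L
    }
    n
  }
  structure(list(age_points = fix_odd(age_points, "age"),
                 exposure_points = fix_odd(exposure_points, "exposure"),
                 exposure_range = exposure_range,
                 replicates = as.integer(replicates)),
            class = "metrics_config")
}

age_grid_of <- function(config) {
  seq(AGE_MIN, AGE_MAX, length.out = config$age_points)
}

#' Accuracy and precision metrics for an estimated parameter curve
#'
#' Given M replicate estimates \eqn{\hat\gamma^{(m)}(A_q)} of a true
#' age-parameter curve \eqn{\gamma(A_q)} on an age grid, computes
#' pointwise
#' \deqn{AAB_q = \frac{1}{M}\sum_m |\hat\gamma^{(m)}(A_q) - \gamma(A_q)|}
#' \deqn{ESD_q = \sqrt{\frac{1}{M-1}\sum_m (\hat\gamma^{(m)}(A_q) -
#'   \bar{\hat\gamma}(A_q))^2}}
#' \deqn{EMSE_q = \frac{1}{M}\sum_m (\hat\gamma^{(m)}(A_q) -
#'   \gamma(A_q))^2}
#' and their Simpson integrals over age.
#'
#' @param estimates Either an M-row matrix of curve values on the age grid
#'   or a list of [param_fn]s (evaluated on the grid).
#' @param truth The true curve: a [param_fn] or a vector on the grid.
#' @param config A [metrics_config()].
#' @return List with `pointwise` (data frame over the grid) and
#'   `integrated` (named vector: aab, esd, emse).
#' @export
param_metrics <- function(estimates, truth, config = metrics_config()) {
  ages <- age_grid_of(config)
  est <- curves_on_grid(estimates, ages)
  M <- nrow(est)
  tr <- if (inherits(truth, "param_fn")) pf_eval(truth, ages) else
    rep_len(as.numeric(truth), length(ages))
  dev <- sweep(est, 2L, tr)
  aab <- colMeans(abs(dev))
  emse <- colMeans(dev^2)
  esd <- if (M >= 2L) apply(est, 2L, stats::sd) else rep(NA_real_, ncol(est))
  step <- ages[2] - ages[1]
  list(pointwise = data.frame(age = ages, aab = aab, esd = esd,
                              emse = emse),
       integrated = c(aab = simpson_integrate(aab, step),
                      esd = if (M >= 2L) simpson_integrate(esd, step)
                            else NA_real_,
                      emse = simpson_integrate(emse, step)))
}

curves_on_grid <- function(estimates, ages) {
  if (is.matrix(estimates)) {
    stopifnot(ncol(estimates) == length(ages))
    return(estimates)
  }
  if (is.list(estimates)) {
    return(t(vapply(estimates, pf_eval, numeric(length(ages)),
                    age = ages)))
  }
  stop("`estimates` must be a matrix or a list of param_fn objects")
}

#' Integrated metrics for the expected response surface
#'
#' Compares each replicate's fitted expected-response surface with the
#' truth over an age-by-exposure grid: pointwise AAB/ESD/EMSE are Simpson-
#' integrated over age for each exposure, then Simpson-integrated over
#' exposure.  Computation streams one exposure column at a time, so the
#' full Q-by-J-by-M array is never materialised.
#'
#' @param fits List of M fitted [er_spec]s (linear or Emax).
#' @param truth The true [er_spec].
#' @param config A [metrics_config()].
#' @return Named vector: integrated `aab`, `esd`, `emse`.
#' @export
response_metrics <- function(fits, truth, config = metrics_config()) {
  ages <- age_grid_of(config)
  expo <- seq(config$exposure_range[1], config$exposure_range[2],
              length.out = config$exposure_points)
  M <- length(fits)
  fit_curves <- lapply(fits, spec_curves, ages = ages)
  truth_curves <- spec_curves(truth, ages)
  astep <- ages[2] - ages[1]
  estep <- expo[2] - expo[1]
  aab_j <- esd_j <- emse_j <- numeric(length(expo))
  for (j in seq_along(expo)) {
    tr <- curves_response(truth_curves, expo[j])
    est <- vapply(fit_curves, curves_response, numeric(length(ages)),
                  exposure = expo[j])  # Q x M
    dev <- est - tr
    aab_q <- rowMeans(abs(dev))
    emse_q <- rowMeans(dev^2)
    aab_j[j] <- simpson_integrate(aab_q, astep)
    emse_j[j] <- simpson_integrate(emse_q, astep)
    if (M >= 2L) {
      esd_q <- sqrt(pmax(0, (emse_q - (rowMeans(dev))^2) * M / (M - 1)))
      esd_j[j] <- simpson_integrate(esd_q, astep)
    } else esd_j[j] <- NA_real_
  }
  c(aab = simpson_integrate(aab_j, estep),
    esd = if (M >= 2L) simpson_integrate(esd_j, estep) else NA_real_,
    emse = simpson_integrate(emse_j, estep))
}

# pre-evaluated parameter curves of a spec on the age grid
spec_curves <- function(spec, ages) {
  if (inherits(spec, "linear_er_spec")) {
    list(kind = "linear", g0 = pf_eval(spec$intercept, ages),
         gC = pf_eval(spec$slope, ages))
  } else {
    list(kind = "emax", g0 = pf_eval(spec$intercept, ages),
         emax = pf_eval(spec$emax, ages), ec50 = pf_eval(spec$ec50, ages),
         hill = pf_eval(spec$hill, ages))
  }
}

curves_response <- function(cv, exposure) {
  if (cv$kind == "linear") {
    cv$g0 + cv$gC * exposure
  } else if (exposure == 0) {
    cv$g0
  } else {
    cd <- exposure^cv$hill
    cv$g0 + cv$emax * cd / (cv$ec50^cv$hill + cd)
  }
}

#' Integrated accuracy of estimated K-group dosing rules
#'
#' For each replicate's estimated rule (boundaries plus target
#' exposures), evaluates the TRUE expected response at the rule's
#' exposure for every grid age, and averages the absolute difference from
#' the target response over replicates:
#' \deqn{Y_{q,diff} = \frac{1}{M} \sum_m |E[Y_{q}^{(m)}] - Y^*|,}
#' then Simpson-integrates over age.  Zero means children of every age
#' would, in truth, hit the target response exactly under the estimated
#' rules.
#'
#' @param rules List of M rules; each a `dosing_rule` or a list with
#'   `boundaries` and `exposures`.
#' @param truth The true [er_spec].
#' @param y_star Target response.
#' @param config A [metrics_config()].
#' @return List with `pointwise` (Yq_diff on the age grid) and
#'   `integrated` (scalar).
#' @export
rule_accuracy <- function(rules, truth, y_star = log(60),
                          config = metrics_config()) {
  ages <- age_grid_of(config)
  if (length(rules) == 0L) stop("no rules supplied")
  tc <- spec_curves(truth, ages)
  acc <- numeric(length(ages))
  for (r in rules) {
    if (is.null(r$boundaries) || is.null(r$exposures))
      stop("each rule needs boundaries and exposures")
    gi <- findInterval(ages, r$boundaries, left.open = TRUE)
    gi[gi < 1L] <- 1L
    gi[gi > length(r$exposures)] <- length(r$exposures)
    cc <- r$exposures[gi]
    ey <- if (tc$kind == "linear") tc$g0 + tc$gC * cc else {
      cd <- cc^tc$hill
      ifelse(cc == 0, tc$g0, tc$g0 + tc$emax * cd / (tc$ec50^tc$hill + cd))
    }
    acc <- acc + abs(ey - y_star)
  }
  yq <- acc / length(rules)
  list(pointwise = data.frame(age = ages, yq_diff = yq),
       integrated = simpson_integrate(yq, ages[2] - ages[1]))
}
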