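#' Exposure-response model specifications
#'
#' A model specification couples age-varying parameter functions with global
#' (age-invariant) covariate effects and a residual variance.  Two families
#' are supported.  The linear model is
#' \deqn{Y = \gamma_0(A) + \sum_p \gamma_p x_p + \gamma_C(A) C + \epsilon}
#' and the sigmoid Emax model is
#' \deqn{Y = \gamma_0(A) + \sum_p \gamma_p x_p +
#'   \frac{E_{max}(A) C^{\delta(A)}}{EC_{50}(A)^{\delta(A)} + C^{\delta(A)}}
#'   + \epsilon}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}.  Each age-varying parameter is a
#' [param_fn] (plain scalars are promoted to constants).
#'
#' @param intercept Intercept \eqn{\gamma_0(A)}: a [param_fn] or scalar.
#' @param slope Exposure slope \eqn{\gamma_C(A)} (linear model only).
#' @param emax,ec50,hill Maximum drug effect \eqn{E_{max}(A)}, half-maximal
#'   concentration \eqn{EC_{50}(A)} (must be positive) and Hill coefficient
#'   \eqn{\delta(A)} (must be positive).
#' @param global_effects Numeric vector \eqn{\gamma_1, ..., \gamma_P} of
#'   age-invariant covariate effects (possibly empty).
#' @param noise_variance Residual variance \eqn{\sigma^2 \ge 0}.
#' @return An object of class `linear_er_spec` or `emax_er_spec` (both also
#'   inherit from `er_spec`).
#' @examples
#' spec <- linear_er_spec(intercept = 4.7, slope = -0.05,
#'                        noise_variance = 0.02)
#' expected_response(spec, age = 9, exposure = 10)
#' @name er_spec
NULL

as_param_fn <- function(x, what) {
  if (inherits(x, "param_fn")) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(pf_constant(x))
  stop("`", what, "` must be a param_fn or a finite scalar")
}

#' @rdname er_spec
#' @export
linear_er_spec <- function(intercept, slope, global_effects = numeric(0),
                           noise_variance = 0) {
  stopifnot(is.numeric(noise_variance), noise_variance >= 0)
  structure(list(intercept = as_param_fn(intercept, "intercept"),
                 slope = as_param_fn(slope, "slope"),
                 global_effects = as.numeric(global_effects),
                 noise_variance = noise_variance),
            class = c("linear_er_spec", "er_spec"))
}

#' @rdname er_spec
#' @export
emax_er_spec <- function(intercept, emax, ec50, hill = 1,
                         global_effects = numeric(0), noise_variance = 0) {
  stopifnot(is.numeric(noise_variance), noise_variance >= 0)
  spec <- structure(list(intercept = as_param_fn(intercept, "intercept"),
                         emax = as_param_fn(emax, "emax"),
                         ec50 = as_param_fn(ec50, "ec50"),
                         hill = as_param_fn(hill, "hill"),
                         global_effects = as.numeric(global_effects),
                         noise_variance = noise_variance),
                    class = c("emax_er_spec", "er_spec"))
  probe <- seq(AGE_MIN, AGE_MAX, length.out = 181)
  if (any(pf_eval(spec$ec50, probe) <= 0))
    stop("ec50(a) must be positive over the age domain")
  if (any(pf_eval(spec$hill, probe) <= 0))
    stop("hill(a) must be positive over the age domain")
  spec
}

check_covariates <- function(spec, covariates) {
  p <- length(spec$global_effects)
  if (is.null(covariates)) covariates <- numeric(0)
  if (is.matrix(covariates)) {
    if (ncol(covariates) != p)
      stop("covariate matrix must have ", p, " columns")
    return(covariates)
  }
  covariates <- as.numeric(covariates)
  if (length(covariates) != p)
    stop("covariate vector length ", length(covariates),
         " does not match the ", p, " global effects")
  covariates
}

cov_term <- function(spec, covariates, n) {
  p <- length(spec$global_effects)
  if (p == 0L) return(rep(0, n))
  if (is.matrix(covariates)) drop(covariates %*% spec$global_effects)
  else rep(sum(covariates * spec$global_effects), n)
}

#' Expected (noiseless) response under a model specification
#'
#' Evaluates the mean response of a linear or Emax exposure-response model
#' at given ages and exposures.  Vectorised over `age` and `exposure`
#' (recycled to a common length).
#'
#' @param spec An [er_spec].
#' @param age Ages in years, within \[0, 18\].
#' @param exposure Non-negative exposures (e.g. steady-state trough
#'   concentration).
#' @param covariates Either a length-P vector applied to all subjects or an
#'   n-by-P matrix; may be omitted when the spec has no global effects.
#' @return Numeric vector of expected responses.
#' @export
expected_response <- function(spec, age, exposure, covariates = NULL) {
  UseMethod("expected_response")
}

#' @export
expected_response.linear_er_spec <- function(spec, age, exposure,
                                             covariates = NULL) {
  n <- max(length(age), length(exposure))
  age <- rep_len(age, n); exposure <- rep_len(exposure, n)
  if (any(exposure < 0)) stop("exposure must be non-negative")
  covariates <- check_covariates(spec, covariates)
  pf_eval(spec$intercept, age) + cov_term(spec, covariates, n) +
    pf_eval(spec$slope, age) * exposure
}

#' @export
expected_response.emax_er_spec <- function(spec, age, exposure,
                                           covariates = NULL) {
  n <- max(length(age), length(exposure))
  age <- rep_len(age, n); exposure <- rep_len(exposure, n)
  if (any(exposure < 0)) stop("exposure must be non-negative")
  covariates <- check_covariates(spec, covariates)
  emx <- pf_eval(spec$emax, age)
  ec <- pf_eval(spec$ec50, age)
  dl <- pf_eval(spec$hill, age)
  cd <- exposure^dl
  drug <- ifelse(exposure == 0, 0, emx * cd / (ec^dl + cd))
  pf_eval(spec$intercept, age) + cov_term(spec, covariates, n) + drug
}

#' Invert the expected response for a target value
#'
#' Finds the exposure `C` such that `expected_response(spec, age, C,
#' covariate_profile)` equals `target`.  The linear model is inverted in
#' closed form, \eqn{C = (Y^* - \gamma_0(a) - \sum_p \gamma_p \bar x_p) /
#' \gamma_C(a)}.  The sigmoid Emax model also admits a closed form: with
#' \eqn{r = (Y^* - b)/E_{max}(a)} and \eqn{b} the non-drug part,
#' \eqn{C = EC_{50}(a) (r/(1-r))^{1/\delta(a)}}; the target must lie
#' strictly between the baseline and the asymptote \eqn{b + E_{max}(a)}.
#'
#' @param spec An [er_spec].
#' @param age A single age in \[0, 18\].
#' @param target The target response \eqn{Y^*}.
#' @param covariate_profile Covariate values at which to condition (length-P
#'   vector); defaults to none.
#' @return The non-negative exposure achieving the target.
#' @export
invert_for_exposure <- function(spec, age, target, covariate_profile = NULL) {
  UseMethod("invert_for_exposure")
}

#' @export
invert_for_exposure.linear_er_spec <- function(spec, age, target,
                                               covariate_profile = NULL) {
  stopifnot(length(age) == 1L, length(target) == 1L)
  covariate_profile <- check_covariates(spec, covariate_profile)
  g0 <- pf_eval(spec$intercept, age) + cov_term(spec, covariate_profile, 1L)
  gC <- pf_eval(spec$slope, age)
  if (abs(gC) < 1e-14)
    stop("slope is zero at age ", age, "; target exposure undefined")
  cc <- (target - g0) / gC
  if (cc < 0)
    stop("target response implies a negative exposure at age ", age)
  cc
}

#' @export
invert_for_exposure.emax_er_spec <- function(spec, age, target,
                                             covariate_profile = NULL) {
  stopifnot(length(age) == 1L, length(target) == 1L)
  covariate_profile <- check_covariates(spec, covariate_profile)
  b <- pf_eval(spec$intercept, age) + cov_term(spec, covariate_profile, 1L)
  emx <- pf_eval(spec$emax, age)
  ec <- pf_eval(spec$ec50, age)
  dl <- pf_eval(spec$hill, age)
  r <- (target - b) / emx
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("target outside the attainable response range at age ", age,
         " (baseline ", signif(b, 6), ", asymptote ", signif(b + emx, 6), ")")
  ec * (r / (1 - r))^(1 / dl)
}

#' @export
print.er_spec <- function(x, ...) {
  fam <- if (inherits(x, "linear_er_spec")) "linear" else "sigmoid Emax"
  cat(sprintf("<%s exposure-response spec, P = %d global effects, sigma^2 = %g>\n",
              fam, length(x$global_effects), x$noise_variance))
  invisible(x)
}

#' Read or write an exposure-response dataset
#'
#' Datasets are plain data frames with columns `age`, `exposure`,
#' `x1`..`xP` (optional baseline covariates) and `response`, serialised as
#' CSV with a header.
#'
#' @param age,exposure,response Numeric vectors of equal length.
#' @param covariates Optional numeric matrix (n by P) of baseline
#'   covariates.
#' @return `er_dataset()` returns a validated data frame; `read_er_dataset()`
#'   reads one from CSV; `write_er_dataset()` writes and invisibly returns
#'   the file path.
#' @export
er_dataset <- function(age, exposure, response, covariates = NULL) {
  n <- length(age)
  stopifnot(length(exposure) == n, length(response) == n)
  d <- data.frame(age = as.numeric(age), exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    d <- cbind(d, as.data.frame(covariates))
  }
  d$response <- as.numeric(response)
  validate_er_dataset(d)
}

validate_er_dataset <- function(d) {
  need <- c("age", "exposure", "response")
  if (!all(need %in% names(d)))
    stop("dataset must contain columns age, exposure, response")
  if (anyNA(d[need])) stop("dataset contains missing values")
  if (any(d$age < AGE_MIN | d$age > AGE_MAX))
    stop("all ages must lie in [0, 18]")
  if (any(d$exposure < 0)) stop("exposures must be non-negative")
  d
}

covariate_matrix <- function(d) {
  xc <- grep("^x[0-9]+$", names(d), value = TRUE)
  if (length(xc) == 0L) return(NULL)
  as.matrix(d[xc[order(as.integer(sub("^x", "", xc)))]])
}

#' @rdname er_dataset
#' @param path File path of the CSV.
#' @export
read_er_dataset <- function(path) {
  validate_er_dataset(utils::read.csv(path))
}

#' @rdname er_dataset
#' @param data A dataset as returned by [er_dataset()].
#' @export
write_er_dataset <- function(data, path) {
  utils::write.csv(validate_er_dataset(data), path, row.names = FALSE)
  invisible(path)
}
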