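#' Study designs for simulated exposure-response data
#'
#' A scenario couples a generative truth (an [er_spec]) with a recruitment
#' design and an exposure law.  The default design enrols 25 subjects into
#' each of the four ICH E11 age groups (0, 28/365\], (28/365, 2\], (2, 12\]
#' and (12, 18\] years (pre-term newborns excluded), samples ages uniformly
#' within each group, and samples log trough concentrations from
#' N(log(2.94), 0.921) truncated above at log(17.27) -- parameters
#' anchored to adjunctive-therapy epilepsy trials.  Gaussian residual noise
#' has variance 0.02 by default.  The 0.921 and 0.02 are variances; both
#' are explicit arguments so either reading of the dispersion can be
#' configured.
#'
#' @param truth An [er_spec] giving the generative model (its
#'   `noise_variance` is used for the residuals).
#' @param group_boundaries Strictly increasing recruitment-group boundaries
#'   within \[0, 18\].
#' @param n_per_group Per-group sample sizes (recycled across groups).
#' @param exposure An [exposure_law()].
#' @param covariate_sampler Optional `function(n, ages)` returning an
#'   n-by-P matrix of baseline covariates matching the truth's
#'   `global_effects`.
#' @param seed Default seed used by [generate_dataset()].
#' @return An object of class `er_scenario`.
#' @export
scenario <- function(truth,
                     group_boundaries = c(0, 28 / 365, 2, 12, 18),
                     n_per_group = 25,
                     exposure = exposure_law(),
                     covariate_sampler = NULL,
                     seed = NULL) {
  stopifnot(inherits(truth, "er_spec"))
  group_boundaries <- as.numeric(group_boundaries)
  if (any(diff(group_boundaries) <= 0))
    stop("group boundaries must be strictly increasing")
  if (group_boundaries[1] < AGE_MIN ||
      group_boundaries[length(group_boundaries)] > AGE_MAX)
    stop("group boundaries must lie within [0, 18]")
  sizes <- rep_len(as.integer(n_per_group), length(group_boundaries) - 1L)
  if (any(sizes < 1L)) stop("each group needs at least one subject")
  structure(list(truth = truth, group_boundaries = group_boundaries,
                 n_per_group = sizes, exposure = exposure,
                 covariate_sampler = covariate_sampler, seed = seed),
            class = "er_scenario")
}

#' @rdname scenario
#' @param log_mean,log_variance Mean and variance of log exposure.
#' @param upper Upper truncation bound on the exposure scale (`Inf` to
#'   disable); truncation is by rejection, so no atom forms at the bound.
#' @export
exposure_law <- function(log_mean = log(2.94), log_variance = 0.921,
                         upper = 17.27) {
  stopifnot(log_variance > 0, upper > 0)
  list(log_mean = log_mean, log_variance = log_variance, upper = upper)
}

#' Sample subject ages uniformly within recruitment groups
#'
#' @param group_boundaries Strictly increasing group boundaries.
#' @param sizes Integer vector of per-group sample sizes.
#' @return Numeric vector of ages (grouped in boundary order).
#' @export
sample_ages <- function(group_boundaries, sizes) {
  stopifnot(length(sizes) == length(group_boundaries) - 1L)
  unlist(lapply(seq_along(sizes), function(g) {
    stats::runif(sizes[g], group_boundaries[g], group_boundaries[g + 1L])
  }))
}

#' Sample exposures from a truncated log-normal law
#'
#' Log exposures are normal with the law's mean and variance; draws above
#' the truncation bound are rejected and redrawn.
#'
#' @param n Number of exposures.
#' @param law An [exposure_law()].
#' @return Numeric vector of exposures in (0, upper\].
#' @export
sample_exposures <- function(n, law = exposure_law()) {
  sd <- sqrt(law$log_variance)
  out <- stats::rlnorm(n, law$log_mean, sd)
  while (any(bad <- out > law$upper)) {
    out[bad] <- stats::rlnorm(sum(bad), law$log_mean, sd)
  }
  out
}

#' Generate a simulated exposure-response dataset
#'
#' Draws ages, exposures and (optionally) covariates per the scenario's
#' design, then responses as the truth's expected response plus Gaussian
#' noise with the truth's `noise_variance`.
#'
#' @param scn An [scenario()].
#' @param seed Integer seed; identical seeds give identical datasets.
#'   Defaults to the scenario's own seed (or leaves the RNG state alone if
#'   neither is set).
#' @return An [er_dataset()] data frame.
#' @export
generate_dataset <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "er_scenario"))
  if (!is.null(seed)) set.seed(seed)
  ages <- sample_ages(scn$group_boundaries, scn$n_per_group)
  n <- length(ages)
  expo <- sample_exposures(n, scn$exposure)
  covs <- if (!is.null(scn$covariate_sampler)) {
    as.matrix(scn$covariate_sampler(n, ages))
  } else NULL
  mu <- expected_response(scn$truth, ages, expo, covariates = covs)
  y <- mu + stats::rnorm(n, 0, sqrt(scn$truth$noise_variance))
  er_dataset(ages, expo, y, covariates = covs)
}

#' Fixed-panel Emax study design
#'
#' A small in-vitro-style concentration-response design: 41 subjects in
#' four age groups (10 infants 0-1 y; 12 children 1-4 y; 9 pre-adolescents
#' 4-12 y; 10 adults 12-18 y), each group receiving every member of a fixed
#' 9-concentration panel once, with the surplus subjects (1 infant, 3
#' children, 1 adult) assigned a uniformly random panel member.  Responses
#' follow a hyperbolic Emax truth (zero intercept, Hill coefficient 1) with
#' group-specific Emax and EC50 and Gaussian noise of variance 15.  The
#' default Emax/EC50 values are synthetic stand-ins chosen so that infants
#' differ markedly from the three older groups.
#'
#' @param group_boundaries Age-group boundaries.
#' @param group_sizes Subjects per group.
#' @param panel Concentration panel (ng/mL).
#' @param emax,ec50 Per-group true parameter values.
#' @param noise_variance Residual variance.
#' @param seed Default seed for [generate_emax_example()].
#' @return An object of class `emax_example_design`.
#' @export
emax_example_design <- function(group_boundaries = c(0, 1, 4, 12, 18),
                                group_sizes = c(10, 12, 9, 10),
                                panel = c(6.25, 12.5, 25, 50, 100, 250,
                                          500, 1000, 5000),
                                emax = c(80, 64, 62.7, 61),
                                ec50 = c(25, 58, 55, 52),
                                noise_variance = 15,
                                seed = NULL) {
  ng <- length(group_boundaries) - 1L
  stopifnot(length(group_sizes) == ng, length(emax) == ng,
            length(ec50) == ng, all(group_sizes >= length(panel)))
  structure(list(group_boundaries = group_boundaries,
                 group_sizes = as.integer(group_sizes), panel = panel,
                 emax = emax, ec50 = ec50,
                 noise_variance = noise_variance, seed = seed),
            class = "emax_example_design")
}

#' @rdname emax_example_design
#' @param design An [emax_example_design()].
#' @export
emax_example_truth <- function(design) {
  emax_er_spec(intercept = 0,
               emax = pf_step(design$group_boundaries, design$emax),
               ec50 = pf_step(design$group_boundaries, design$ec50),
               hill = 1,
               noise_variance = design$noise_variance)
}

#' Generate data from the fixed-panel Emax design
#'
#' @inheritParams emax_example_design
#' @param design An [emax_example_design()].
#' @param seed Integer seed (defaults to the design's seed).
#' @return An [er_dataset()] with one row per subject.
#' @export
generate_emax_example <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "emax_example_design"))
  if (!is.null(seed)) set.seed(seed)
  truth <- emax_example_truth(design)
  rows <- lapply(seq_along(design$group_sizes), function(g) {
    n <- design$group_sizes[g]
    extra <- n - length(design$panel)
    conc <- c(design$panel,
              if (extra > 0) sample(design$panel, extra, replace = TRUE))
    ages <- stats::runif(n, design$group_boundaries[g],
                         design$group_boundaries[g + 1L])
    data.frame(age = ages, exposure = conc)
  })
  d <- do.call(rbind, rows)
  mu <- expected_response(truth, d$age, d$exposure)
  y <- mu + stats::rnorm(nrow(d), 0, sqrt(design$noise_variance))
  er_dataset(d$age, d$exposure, y)
}
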