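#' Random-walk prior for penalised B-spline coefficients
#'
#' First-order random-walk prior on adjacent basis coefficients:
#' \eqn{\beta_1 \sim N(0, 100)} and \eqn{\beta_j | \beta_{j-1} \sim
#' N(\beta_{j-1}, \tau^2)}, which shrinks the fitted curve towards a
#' common constant.  The hyperprior on the random-walk scale is either an
#' Inverse-Gamma on the variance \eqn{\tau^2} (default IG(1, 0.005); the
#' conjugate choice for the linear model) or a Gamma on the standard
#' deviation \eqn{\tau} (default Gamma(2, 0.1); a boundary-avoiding choice
#' used for the Emax model).  The random-walk scales are not weighted by
#' the distance between successive knots, since knots are deliberately
#' denser where rapid change is expected.
#'
#' @param hyper `"inv_gamma"` or `"gamma"`.
#' @param a,b Shape and rate of the hyperprior.
#' @param on Whether the hyperprior applies to the `"variance"` or the
#'   `"sd"` of the random walk.
#' @param init_variance Variance of the first coefficient's prior.
#' @return An object of class `rw_prior`.
#' @export
rw_prior <- function(hyper = c("inv_gamma", "gamma"), a = 1, b = 0.005,
                     on = c("variance", "sd"), init_variance = 100) {
  hyper <- match.arg(hyper)
  on <- match.arg(on)
  stopifnot(a > 0, b > 0, init_variance > 0)
  if (hyper == "gamma" && on == "variance")
    stop("Gamma hyperprior is supported on the sd scale only")
  structure(list(hyper = hyper, a = a, b = b, on = on,
                 init_variance = init_variance),
            class = "rw_prior")
}

# log hyperprior density of tau (the SD), up to a constant
rw_prior_logd_tau <- function(prior, tau) {
  if (prior$hyper == "gamma") {
    stats::dgamma(tau, prior$a, rate = prior$b, log = TRUE)
  } else if (prior$on == "sd") {
    # IG(a, b) on tau itself
    -(prior$a + 1) * log(tau) - prior$b / tau
  } else {
    # IG(a, b) on tau^2, transformed to tau: jacobian 2*tau
    -(2 * prior$a + 1) * log(tau) - prior$b / tau^2
  }
}

# Univariate slice sampler (stepping-out; Neal 2003) on an unbounded scale.
slice_sample1 <- function(lp, x0, w = 1, max_steps = 50L) {
  y <- lp(x0) - stats::rexp(1)
  u <- stats::runif(1)
  lo <- x0 - w * u
  hi <- lo + w
  k <- max_steps
  while (k > 0L && lp(lo) > y) { lo <- lo - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && lp(hi) > y) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (lp(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# draw tau^2 given the RW increment sum of squares (m increments)
draw_tau2 <- function(prior, ssq, m, tau2_cur) {
  if (prior$hyper == "inv_gamma" && prior$on == "variance") {
    return(1 / stats::rgamma(1, prior$a + m / 2, rate = prior$b + ssq / 2))
  }
  lp <- function(ltau) {
    tau <- exp(ltau)
    rw_prior_logd_tau(prior, tau) + ltau - m * ltau - ssq / (2 * tau^2)
  }
  exp(2 * slice_sample1(lp, 0.5 * log(tau2_cur)))
}

#' Fit the Bayesian penalised B-spline linear model
#'
#' Linear exposure-response model whose intercept and slope are quadratic
#' B-splines of age,
#' \deqn{Y_i = \sum_j \beta_{0j} B_j(A_i) + C_i \sum_j \beta_{Cj} B_j(A_i)
#'   + \sum_p \gamma_p x_{pi} + \epsilon_i,}
#' with first-order random-walk priors on both coefficient vectors.  The
#' model is linear-Gaussian given the variance parameters, so it is fitted
#' by a blocked Gibbs sampler: all regression coefficients are drawn
#' jointly from their multivariate-normal full conditional; the random-walk
#' variances from their (conjugate) full conditionals; the residual
#' variance from an Inverse-Gamma(0.01, 0.01) conjugate update.  Global
#' covariate effects get independent N(0, 100) priors.
#'
#' @param data An [er_dataset()].
#' @param basis A [build_knots()] basis (default recipe, J = 26).
#' @param prior An [rw_prior()] applied to both coefficient vectors.
#' @param chains,iterations,burn_in,thin MCMC settings; `iterations` is the
#'   total per chain, of which the first `burn_in` are discarded.
#' @param seed Integer seed (chain c uses `seed + c`).
#' @param tau_fixed Optional length-2 vector fixing the two random-walk
#'   variances (intercept, slope) instead of sampling them; useful for
#'   studying the shrinkage limit (small tau flattens the curves towards
#'   constants).
#' @param likelihood Set `FALSE` to sample from the prior only
#'   (prior-predictive checks).
#' @return A `posterior_draws` object; see [posterior_param_function()]
#'   and [rhat()].
#' @examples
#' \donttest{
#' scn <- linear_scenario(5, seed = 4)
#' fit <- fit_bspline_linear(generate_dataset(scn), iterations = 500,
#'                           burn_in = 250, seed = 1)
#' max(rhat(fit))
#' }
#' @export
fit_bspline_linear <- function(data, basis = build_knots(),
                               prior = rw_prior(), chains = 3L,
                               iterations = 3000L, burn_in = 1500L,
                               thin = 1L, seed = 1L, tau_fixed = NULL,
                               likelihood = TRUE) {
  data <- validate_er_dataset(data)
  stopifnot(iterations > burn_in, chains >= 1L, thin >= 1L)
  y <- data$response
  n <- length(y)
  B <- basis_matrix(data$age, basis)
  J <- basis$J
  X <- covariate_matrix(data)
  P <- if (is.null(X)) 0L else ncol(X)
  if (stats::var(data$exposure) < 1e-12)
    warning("exposure has no variation: the slope curve is prior-driven")
  D <- cbind(B, B * data$exposure, X)
  q <- ncol(D)
  DtD <- crossprod(D)
  Dty <- crossprod(D, y)
  # structure matrices of the two RW1 priors
  Dif <- diff(diag(J))
  K <- crossprod(Dif)
  E1 <- matrix(0, J, J); E1[1, 1] <- 1
  a_s <- 0.01; b_s <- 0.01  # residual variance IG prior
  keep <- seq(burn_in + 1L, iterations, by = thin)
  par_names <- c(paste0("b0[", 1:J, "]"), paste0("bC[", 1:J, "]"),
                 if (P > 0L) paste0("g[", 1:P, "]"),
                 "tau0_sq", "tauC_sq", "sigma")
  chains_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    theta <- drop(solve(DtD + diag(1e-3, q), Dty))
    if (is.null(tau_fixed)) {
      tau0 <- tauC <- 0.01
    } else {
      tau0 <- tau_fixed[1]; tauC <- tau_fixed[length(tau_fixed)]
    }
    s2 <- max(stats::var(y), 1e-4)
    out <- matrix(NA_real_, length(keep), length(par_names),
                  dimnames = list(NULL, par_names))
    row <- 0L
    for (it in seq_len(iterations)) {
      Pr <- matrix(0, q, q)
      Pr[1:J, 1:J] <- K / tau0 + E1 / prior$init_variance
      Pr[J + 1:J, J + 1:J] <- K / tauC + E1 / prior$init_variance
      if (P > 0L) {
        ix <- 2L * J + 1:P
        Pr[cbind(ix, ix)] <- 1 / 100
      }
      Q <- if (likelihood) DtD / s2 + Pr else Pr
      R <- chol(Q)
      mu <- if (likelihood) backsolve(R, forwardsolve(t(R), Dty / s2))
            else numeric(q)
      theta <- drop(mu + backsolve(R, stats::rnorm(q)))
      b0 <- theta[1:J]; bC <- theta[J + 1:J]
      if (is.null(tau_fixed)) {
        tau0 <- draw_tau2(prior, sum(diff(b0)^2), J - 1L, tau0)
        tauC <- draw_tau2(prior, sum(diff(bC)^2), J - 1L, tauC)
      }
      if (likelihood) {
        r <- y - drop(D %*% theta)
        s2 <- 1 / stats::rgamma(1, a_s + n / 2, rate = b_s + sum(r^2) / 2)
      }
      if (it %in% keep) {
        row <- row + 1L
        out[row, ] <- c(theta, tau0, tauC, sqrt(s2))
      }
    }
    chains_out[[ch]] <- out
  }
  new_posterior_draws(
    chains = chains_out, model = "linear", basis = basis,
    blocks = list(intercept = list(prefix = "b0", link = "identity"),
                  slope = list(prefix = "bC", link = "identity")),
    settings = list(chains = chains, iterations = iterations,
                    burn_in = burn_in, thin = thin, seed = seed))
}

#' Fit the Bayesian penalised B-spline Emax model
#'
#' Sigmoid Emax exposure-response model whose age-varying parameters are
#' quadratic B-splines.  Emax(A) and EC50(A) (and the Hill coefficient,
#' when estimated) are modelled on the log scale, so the fitted curves are
#' positive by construction.  By default the intercept is fixed at zero
#' and the Hill coefficient at one (hyperbolic Emax).  Sampling is by
#' MCMC via JAGS (rjags), with Gamma(2, 0.1) boundary-avoiding priors on
#' the random-walk standard deviations and a half-normal(0, 5) prior on
#' the residual standard deviation.  Convergence should be checked with
#' [rhat()].
#'
#' @inheritParams fit_bspline_linear
#' @param zero_intercept Fix \eqn{\gamma_0(A) \equiv 0}.
#' @param fix_hill_to_1 Fix \eqn{\delta(A) \equiv 1}.
#' @param adapt JAGS adaptation iterations.
#' @return A `posterior_draws` object.
#' @export
fit_bspline_emax <- function(data, basis = build_knots(),
                             prior = rw_prior("gamma", a = 2, b = 0.1,
                                              on = "sd"),
                             zero_intercept = TRUE, fix_hill_to_1 = TRUE,
                             chains = 3L, iterations = 9000L,
                             burn_in = 4500L, thin = 3L, seed = 1L,
                             adapt = 500L) {
  data <- validate_er_dataset(data)
  stopifnot(iterations > burn_in, chains >= 1L)
  if (all(data$exposure <= 0)) stop("Emax model needs positive exposures")
  y <- data$response
  B <- basis_matrix(data$age, basis)
  J <- basis$J
  rw_block <- function(nm) {
    hp <- if (prior$hyper == "gamma" && prior$on == "sd") {
      sprintf("sd%s ~ dgamma(%g, %g)\n  prec%s <- pow(sd%s, -2)",
              nm, prior$a, prior$b, nm, nm)
    } else {
      sprintf("prec%s ~ dgamma(%g, %g)\n  sd%s <- pow(prec%s, -0.5)",
              nm, prior$a, prior$b, nm, nm)
    }
    sprintf(paste0(
      "b%s[1] ~ dnorm(0, %g)\n",
      "  for (j in 2:J) { b%s[j] ~ dnorm(b%s[j-1], prec%s) }\n  %s"),
      nm, 1 / prior$init_variance, nm, nm, nm, hp)
  }
  g0_term <- if (zero_intercept) "0" else "inprod(B[i,], bI)"
  hill_term <- if (fix_hill_to_1) NULL else "exp(inprod(B[i,], bH))"
  mu_line <- if (fix_hill_to_1) {
    "mu[i] <- %s + exp(inprod(B[i,], bE)) * C[i] / (exp(inprod(B[i,], bC50)) + C[i])"
  } else {
    "mu[i] <- %s + exp(inprod(B[i,], bE)) * pow(C[i], d[i]) / (pow(exp(inprod(B[i,], bC50)), d[i]) + pow(C[i], d[i]))"
  }
  model_string <- paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    if (!fix_hill_to_1) sprintf("    d[i] <- %s\n", hill_term) else "",
    "    ", sprintf(mu_line, g0_term), "\n",
    "    y[i] ~ dnorm(mu[i], prec_y)\n",
    "  }\n",
    "  ", rw_block("E"), "\n",
    "  ", rw_block("C50"), "\n",
    if (!zero_intercept) paste0("  ", rw_block("I"), "\n") else "",
    if (!fix_hill_to_1) paste0("  ", rw_block("H"), "\n") else "",
    "  sigma_y ~ dnorm(0, 0.04) T(0,)\n",
    "  prec_y <- pow(sigma_y, -2)\n",
    "}\n")
  monitors <- c("bE", "bC50", if (!zero_intercept) "bI",
                if (!fix_hill_to_1) "bH", "sdE", "sdC50",
                if (!zero_intercept) "sdI", if (!fix_hill_to_1) "sdH",
                "sigma_y")
  pos <- data$exposure[data$exposure > 0]
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(bE = rep(log(max(abs(y)) + 1), J),
                bC50 = rep(log(stats::median(pos)), J),
                sigma_y = max(stats::sd(y) / 2, 0.1),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = seed + ch)
    if (!zero_intercept) ini$bI <- rep(0, J)
    if (!fix_hill_to_1) ini$bH <- rep(0, J)
    if (prior$hyper == "gamma" && prior$on == "sd") {
      ini$sdE <- 1; ini$sdC50 <- 1
      if (!zero_intercept) ini$sdI <- 1
      if (!fix_hill_to_1) ini$sdH <- 1
    }
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string),
                          data = list(n = nrow(data), J = J, B = B,
                                      C = data$exposure, y = y),
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  stats::update(jm, burn_in, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = iterations - burn_in,
                            thin = thin, progress.bar = "none")
  chains_out <- lapply(sm, function(m) {
    m <- as.matrix(m)
    m
  })
  blocks <- list(emax = list(prefix = "bE", link = "log"),
                 ec50 = list(prefix = "bC50", link = "log"))
  if (!zero_intercept)
    blocks$intercept <- list(prefix = "bI", link = "identity")
  if (!fix_hill_to_1) blocks$hill <- list(prefix = "bH", link = "log")
  new_posterior_draws(
    chains = chains_out, model = "emax", basis = basis, blocks = blocks,
    settings = list(chains = chains, iterations = iterations,
                    burn_in = burn_in, thin = thin, seed = seed))
}

new_posterior_draws <- function(chains, model, basis, blocks, settings) {
  structure(list(chains = chains, model = model, basis = basis,
                 blocks = blocks, settings = settings,
                 par_names = colnames(chains[[1]])),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws: %s B-spline model, %d chain(s) x %d kept draws, %d parameters>\n",
    x$model, length(x$chains), nrow(x$chains[[1]]), ncol(x$chains[[1]])))
  invisible(x)
}

# all post-burn-in draws pooled across chains
pool_draws <- function(draws) do.call(rbind, draws$chains)

block_cols <- function(draws, which) {
  blk <- draws$blocks[[which]]
  if (is.null(blk))
    stop("no '", which, "' parameter in this model; available: ",
         paste(names(draws$blocks), collapse = ", "))
  cols <- paste0(blk$prefix, "[", seq_len(draws$basis$J), "]")
  miss <- setdiff(cols, draws$par_names)
  if (length(miss)) stop("draw matrix lacks columns: ", miss[1], ", ...")
  list(cols = cols, link = blk$link)
}

#' Posterior parameter curve from B-spline draws
#'
#' Summarises the posterior coefficient vectors of one age-varying
#' parameter and returns the corresponding basis-expansion [param_fn]:
#' the coefficient summary (posterior mean by default) multiplied into the
#' B-spline basis, mapped through the block's link (`exp` for the
#' positivity-constrained Emax-model parameters).
#'
#' @param draws A `posterior_draws` object.
#' @param which Parameter name: `"intercept"`, `"slope"`, `"emax"`,
#'   `"ec50"` or `"hill"`.
#' @param summary Summary statistic applied to each coefficient
#'   (`"mean"` or `"median"`).
#' @return A [param_fn] (basis representation).
#' @export
posterior_param_function <- function(draws, which,
                                     summary = c("mean", "median")) {
  stopifnot(inherits(draws, "posterior_draws"))
  summary <- match.arg(summary)
  bc <- block_cols(draws, which)
  m <- pool_draws(draws)[, bc$cols, drop = FALSE]
  coef <- if (summary == "mean") colMeans(m) else
    apply(m, 2L, stats::median)
  pf_basis(draws$basis, coef, link = bc$link)
}

#' Pointwise posterior quantiles of a parameter curve
#'
#' Evaluates every posterior draw's curve on an age grid and returns
#' pointwise quantiles (2.5th/50th/97.5th by default), giving credible
#' bands for the age-parameter relationship.
#'
#' @inheritParams posterior_param_function
#' @param ages Age grid.
#' @param probs Quantile probabilities.
#' @return A data frame with `age` and one column per quantile.
#' @export
posterior_curve_quantiles <- function(draws, which,
                                      ages = seq(AGE_MIN, AGE_MAX,
                                                 length.out = 181),
                                      probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(draws, "posterior_draws"))
  bc <- block_cols(draws, which)
  m <- pool_draws(draws)[, bc$cols, drop = FALSE]
  Bg <- basis_matrix(ages, draws$basis)
  curves <- m %*% t(Bg)
  if (bc$link == "log") curves <- exp(curves)
  qs <- matrix(apply(curves, 2L, stats::quantile, probs = probs),
               nrow = length(probs))
  out <- data.frame(age = ages)
  for (i in seq_along(probs))
    out[[sprintf("q%g", 100 * probs[i])]] <- qs[i, ]
  out
}

#' Export posterior draws as CSV
#'
#' Long format: chain, iteration, parameter, value.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output file path.
#' @export
write_posterior_draws <- function(draws, path) {
  rows <- lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Split-chain Gelman-Rubin statistics
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, for every scalar parameter.  Values near 1 indicate convergence;
#' values above about 1.01-1.1 indicate the chains have not mixed.
#'
#' @param draws A `posterior_draws` object (at least 2 chains, or 1 chain
#'   which is then split).
#' @return Named vector of split-chain PSRF values.
#' @export
rhat <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  half <- function(m) {
    n2 <- floor(nrow(m) / 2)
    list(m[seq_len(n2), , drop = FALSE],
         m[(nrow(m) - n2 + 1L):nrow(m), , drop = FALSE])
  }
  halves <- do.call(c, lapply(draws$chains, half))
  n <- nrow(halves[[1]])
  if (n < 2L) stop("too few post-burn-in draws for rhat")
  out <- vapply(seq_len(ncol(halves[[1]])), function(j) {
    x <- vapply(halves, function(m) m[, j], numeric(n))
    mns <- colMeans(x)
    vrs <- apply(x, 2L, stats::var)
    W <- mean(vrs)
    Bv <- n * stats::var(mns)
    if (W < 1e-300) return(if (Bv < 1e-300) 1 else Inf)
    sqrt(((n - 1) / n * W + Bv / n) / W)
  }, 0)
  stats::setNames(out, colnames(halves[[1]]))
}

#' Linear or Emax spec from posterior draws
#'
#' @param draws A `posterior_draws` object.
#' @param summary Posterior summary for the coefficient vectors.
#' @return An [er_spec] built from the posterior parameter curves.
#' @export
as_posterior_spec <- function(draws, summary = "mean") {
  if (draws$model == "linear") {
    linear_er_spec(posterior_param_function(draws, "intercept", summary),
                   posterior_param_function(draws, "slope", summary))
  } else {
    g0 <- if (!is.null(draws$blocks$intercept))
      posterior_param_function(draws, "intercept", summary) else 0
    dl <- if (!is.null(draws$blocks$hill))
      posterior_param_function(draws, "hill", summary) else 1
    emax_er_spec(g0, posterior_param_function(draws, "emax", summary),
                 posterior_param_function(draws, "ec50", summary), dl)
  }
}
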