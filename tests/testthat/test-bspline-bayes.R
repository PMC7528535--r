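test_that("linear P-spline recovers a constant truth within 3 posterior SDs", {
  set.seed(20)
  n <- 400
  a <- runif(n, 0, 18)
  C <- rlnorm(n, log(2.94), sqrt(0.921))
  y <- 4 - 0.05 * C + rnorm(n, 0, sqrt(0.02))
  fit <- fit_bspline_linear(er_dataset(a, C, y), seed = 21)
  expect_lt(max(rhat(fit)), 1.05)
  grid <- seq(0, 18, length.out = 100)
  for (par in c("intercept", "slope")) {
    truth <- if (par == "intercept") 4 else -0.05
    qb <- posterior_curve_quantiles(fit, par, ages = grid,
                                    probs = c(0.5))
    pm <- pf_eval(posterior_param_function(fit, par), grid)
    # pointwise posterior SD from the draws
    draws <- do.call(rbind, fit$chains)
    cols <- grep(if (par == "intercept") "^b0\\[" else "^bC\\[",
                 colnames(draws))
    curves <- draws[, cols] %*% t(basis_matrix(grid, fit$basis))
    psd <- apply(curves, 2, sd)
    z <- abs(pm - truth) / psd
    expect_gte(mean(z < 3), 0.95)
    expect_lt(max(z), 5)
  }
})

test_that("posterior parameter curves are the coefficient-summary expansion", {
  set.seed(22)
  d <- flat_linear_data(80)
  fit <- fit_bspline_linear(d, iterations = 220, burn_in = 120, seed = 23)
  draws <- do.call(rbind, fit$chains)
  cols <- grep("^b0\\[", colnames(draws))
  grid <- seq(0, 18, length.out = 40)
  Bg <- basis_matrix(grid, fit$basis)
  # linearity: mean of per-draw curves equals the mean-coefficient curve
  pm_fun <- pf_eval(posterior_param_function(fit, "intercept"), grid)
  pm_pointwise <- colMeans(draws[, cols] %*% t(Bg))
  expect_equal(pm_fun, pm_pointwise, tolerance = 1e-12)
  # a single draw reproduces that draw's basis expansion exactly
  one <- fit$chains[[1]][7, cols]
  expect_equal(drop(Bg %*% one),
               pf_eval(pf_basis(fit$basis, one), grid))
  # quantile bands bracket the median curve
  qb <- posterior_curve_quantiles(fit, "slope", ages = grid)
  expect_true(all(qb$q2.5 <= qb$q50 & qb$q50 <= qb$q97.5))
})

test_that("tiny fixed random-walk variance shrinks curves to constants", {
  set.seed(24)
  scn <- linear_scenario(1)
  d <- generate_dataset(scn, seed = 25)
  fit <- fit_bspline_linear(d, iterations = 600, burn_in = 300,
                            seed = 26, tau_fixed = c(1e-6, 1e-6))
  grid <- seq(0, 18, length.out = 200)
  g0 <- pf_eval(posterior_param_function(fit, "intercept"), grid)
  # the truth spans ~1.8 response units; the shrunk fit must be nearly flat
  expect_lt(diff(range(g0)), 0.1)
})

test_that("prior-only sampling reproduces the random-walk prior structure", {
  set.seed(27)
  d <- flat_linear_data(50)
  fit <- fit_bspline_linear(d, iterations = 3000, burn_in = 500,
                            seed = 28, tau_fixed = c(1, 1),
                            likelihood = FALSE)
  draws <- do.call(rbind, fit$chains)
  cols <- grep("^b0\\[", colnames(draws))
  sds <- apply(draws[, cols], 2, sd)
  # under the prior, sd(beta_j) = sqrt(100 + (j - 1) tau^2)
  expected <- sqrt(100 + (seq_along(cols) - 1) * 1)
  expect_lt(max(abs(sds / expected - 1)), 0.15)
})

test_that("absence of exposure variation is flagged", {
  set.seed(29)
  a <- runif(60, 0, 18)
  d <- er_dataset(a, rep(2, 60), 4 - 0.1 * 2 + rnorm(60, 0, 0.1))
  expect_warning(fit_bspline_linear(d, iterations = 120, burn_in = 60,
                                    seed = 30),
                 "no variation")
})

test_that("rhat separates mixed from unmixed chains", {
  mk <- function(chains) {
    agedose:::new_posterior_draws(
      chains = chains, model = "linear", basis = build_knots(),
      blocks = list(intercept = list(prefix = "b0", link = "identity")),
      settings = list())
  }
  set.seed(31)
  m1 <- matrix(rnorm(2000), ncol = 2,
               dimnames = list(NULL, c("p1", "p2")))
  # copied chains: statistic essentially 1
  r_same <- rhat(mk(list(m1, m1)))
  expect_lt(max(abs(r_same - 1)), 0.05)
  # long iid chains from the same distribution
  m2 <- matrix(rnorm(2000), ncol = 2,
               dimnames = list(NULL, c("p1", "p2")))
  expect_lt(max(rhat(mk(list(m1, m2)))), 1.01)
  # disjoint chains centred at different constants
  m3 <- m2 + 50
  expect_gt(min(rhat(mk(list(m1, m3)))), 3)
  # agreement with the coda implementation on the pooled chains
  cd <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(m1), coda::mcmc(m2)),
                          autoburnin = FALSE, multivariate = FALSE)
  expect_equal(unname(rhat(mk(list(m1, m2)))),
               unname(cd$psrf[, 1]), tolerance = 0.01)
})

test_that("Emax P-spline fit recovers group truths on panel data", {
  des <- emax_example_design()
  d <- generate_emax_example(des, seed = 32)
  fit <- fit_bspline_emax(d, iterations = 3000, burn_in = 1500,
                          thin = 3, seed = 33)
  # constraint accounting: no intercept or hill blocks by default
  expect_false(any(grepl("^bI\\[|^bH\\[", fit$par_names)))
  expect_named(fit$blocks, c("emax", "ec50"))
  mids <- c(0.5, 2.5, 8, 15)
  draws <- do.call(rbind, fit$chains)
  Bg <- basis_matrix(mids, fit$basis)
  for (par in c("emax", "ec50")) {
    truth <- if (par == "emax") des$emax else des$ec50
    cols <- grep(if (par == "emax") "^bE\\[" else "^bC50\\[",
                 colnames(draws))
    curves <- exp(draws[, cols] %*% t(Bg))
    pm <- colMeans(curves)
    psd <- apply(curves, 2, sd)
    expect_true(all(abs(pm - truth) < 3 * psd),
                info = paste("parameter", par))
  }
  # positivity by construction
  grid <- seq(0, 18, length.out = 100)
  expect_true(all(pf_eval(posterior_param_function(fit, "ec50"),
                          grid) > 0))
})

test_that("seeded MCMC is reproducible", {
  d <- flat_linear_data(60, seed = 34)
  f1 <- fit_bspline_linear(d, iterations = 150, burn_in = 80, seed = 35)
  f2 <- fit_bspline_linear(d, iterations = 150, burn_in = 80, seed = 35)
  expect_identical(f1$chains, f2$chains)
  des <- emax_example_design()
  de <- generate_emax_example(des, seed = 36)
  g1 <- fit_bspline_emax(de, iterations = 400, burn_in = 200, thin = 1,
                         chains = 2, seed = 37, adapt = 100)
  g2 <- fit_bspline_emax(de, iterations = 400, burn_in = 200, thin = 1,
                         chains = 2, seed = 37, adapt = 100)
  expect_identical(g1$chains, g2$chains)
})
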