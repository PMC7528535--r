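test_that("Simpson quadrature is exact for polynomials and accurate for sin", {
  x <- seq(0, 18, length.out = 2001)
  h <- x[2] - x[1]
  expect_equal(simpson_integrate(x^2, h), 1944)
  expect_equal(simpson_integrate(rep(1, 2001), h), 18)
  expect_equal(simpson_integrate(x^3, h), 18^4 / 4)  # exact for cubics
  expect_equal(simpson_integrate(sin(x), h), 1 - cos(18),
               tolerance = 1e-9)
  expect_error(simpson_integrate(1:10, 0.1), "odd")
  expect_message(metrics_config(age_points = 100), "incremented")
})

test_that("parameter metrics implement the three estimators", {
  cfg <- metrics_config(age_points = 201, exposure_points = 201)
  ages <- seq(0, 18, length.out = 201)
  truth <- pf_constant(2)
  # single replicate: AAB = |dev|, EMSE = AAB^2, ESD undefined
  est <- matrix(3, 1, 201)
  pm <- param_metrics(est, truth, cfg)
  expect_equal(pm$pointwise$aab, rep(1, 201))
  expect_equal(pm$pointwise$emse, rep(1, 201))
  expect_equal(pm$integrated[["aab"]], 18)
  expect_true(is.na(pm$integrated[["esd"]]))
  # identical replicates: zero spread
  pm2 <- param_metrics(matrix(5, 20, 201), truth, cfg)
  expect_equal(pm2$integrated[["esd"]], 0)
  # known-noise oracle: iid N(0, sigma^2) curves, integrated ESD ~ 18 sigma
  set.seed(50)
  M <- 400; sigma <- 0.7
  est3 <- matrix(2 + rnorm(M * 201, 0, sigma), M, 201)
  pm3 <- param_metrics(est3, truth, cfg)
  expect_lt(abs(pm3$integrated[["esd"]] - 18 * sigma), 0.05 * 18 * sigma)
  # pointwise identity EMSE = ESD^2 (M-1)/M + squared mean bias
  est4 <- matrix(rnorm(50 * 201, 1, 0.3), 50, 201)
  pm4 <- param_metrics(est4, truth, cfg)$pointwise
  bias2 <- (colMeans(est4) - 2)^2
  expect_equal(pm4$emse, pm4$esd^2 * 49 / 50 + bias2, tolerance = 1e-10)
})

test_that("response metrics match a naive recomputation", {
  cfg <- metrics_config(age_points = 41, exposure_points = 41)
  truth <- linear_er_spec(pf_grid(c(0, 18), c(5, 6)),
                          pf_grid(c(0, 18), c(-0.2, -0.3)))
  set.seed(51)
  fits <- lapply(1:5, function(m) {
    linear_er_spec(pf_grid(c(0, 18), c(5, 6) + rnorm(2, 0, 0.1)),
                   pf_grid(c(0, 18), c(-0.2, -0.3) + rnorm(2, 0, 0.02)))
  })
  got <- response_metrics(fits, truth, cfg)
  # naive: materialise the full Q x J x M deviation array
  ages <- seq(0, 18, length.out = 41)
  expo <- seq(0, 18, length.out = 41)
  dev <- array(0, c(41, 41, 5))
  for (m in 1:5) for (j in 1:41) {
    dev[, j, m] <- expected_response(fits[[m]], ages, rep(expo[j], 41)) -
      expected_response(truth, ages, rep(expo[j], 41))
  }
  h <- ages[2] - ages[1]
  int2 <- function(mat) {
    byj <- apply(mat, 2, simpson_integrate, step = h)
    simpson_integrate(byj, h)
  }
  expect_equal(got[["aab"]], int2(apply(abs(dev), 1:2, mean)),
               tolerance = 1e-10)
  expect_equal(got[["emse"]], int2(apply(dev^2, 1:2, mean)),
               tolerance = 1e-10)
  expect_equal(got[["esd"]], int2(apply(dev, 1:2, sd)), tolerance = 1e-10)
  # perfect fits give all-zero metrics
  perfect <- response_metrics(list(truth, truth), truth, cfg)
  expect_equal(unname(perfect), c(0, 0, 0))
  # pointwise linear-spec oracle at random grid nodes
  g0_1 <- pf_eval(fits[[1]]$intercept, ages)
  gC_1 <- pf_eval(fits[[1]]$slope, ages)
  for (probe in sample(41, 5)) {
    expect_equal(dev[probe, 3, 1],
                 (g0_1[probe] - pf_eval(truth$intercept, ages[probe])) +
                   expo[3] * (gC_1[probe] -
                                pf_eval(truth$slope, ages[probe])),
                 tolerance = 1e-10)
  }
})

test_that("grid refinement changes smooth-response metrics by < 0.1%", {
  truth <- linear_er_spec(pf_grid(c(0, 18), c(5, 6)), pf_constant(-0.2))
  set.seed(52)
  fits <- lapply(1:3, function(m)
    linear_er_spec(pf_grid(c(0, 18), c(5.05, 6.02)), pf_constant(-0.21)))
  m1 <- response_metrics(fits, truth,
                         metrics_config(age_points = 101,
                                        exposure_points = 101))
  m2 <- response_metrics(fits, truth,
                         metrics_config(age_points = 201,
                                        exposure_points = 201))
  expect_lt(abs(m1[["aab"]] - m2[["aab"]]) / m2[["aab"]], 0.001)
})

test_that("dosing-rule accuracy integrates the true response error", {
  cfg <- metrics_config(age_points = 201, exposure_points = 201)
  truth <- linear_er_spec(5.6, -0.25)
  y_star <- log(60)
  c_star <- (y_star - 5.6) / -0.25
  perfect <- list(list(boundaries = c(0, 18), exposures = c_star))
  expect_equal(rule_accuracy(perfect, truth, y_star, cfg)$integrated, 0)
  # single replicate, exposure off by eps under slope b: 18 |b eps|
  eps <- 0.3
  off <- list(list(boundaries = c(0, 18), exposures = c_star + eps))
  expect_equal(rule_accuracy(off, truth, y_star, cfg)$integrated,
               18 * abs(-0.25 * eps), tolerance = 1e-9)
  # naive recomputation oracle on 5 heterogeneous rules
  set.seed(53)
  truth2 <- linear_er_spec(pf_grid(c(0, 18), c(5, 6.2)), -0.25)
  rules <- lapply(1:5, function(m) {
    b <- sort(runif(2, 1, 17))
    list(boundaries = c(0, b, 18), exposures = runif(3, 1, 8))
  })
  got <- rule_accuracy(rules, truth2, y_star, cfg)$integrated
  ages <- seq(0, 18, length.out = 201)
  acc <- sapply(rules, function(r) {
    gi <- findInterval(ages, r$boundaries, left.open = TRUE)
    gi[gi < 1] <- 1; gi[gi > 3] <- 3
    abs(expected_response(truth2, ages, r$exposures[gi]) - y_star)
  })
  expect_equal(got, simpson_integrate(rowMeans(acc), ages[2] - ages[1]),
               tolerance = 1e-10)
})

test_that("run_study completes a smoke sweep and tallies K*", {
  suppressMessages(suppressWarnings(
    tab <- run_study(scenario_library()["scenario5"], "categorical",
                     M = 2, seed = 60,
                     config = metrics_config(101, 101),
                     rule_config = rule_search_config(boundary_step = 2,
                                                      k_max = 2))))
  expect_s3_class(tab, "metrics_table")
  expect_equal(nrow(tab$parameters), 2)  # intercept and slope rows
  expect_true(all(c("aab", "esd", "emse") %in% names(tab$parameters)))
  expect_equal(nrow(tab$response), 1)
  expect_equal(sum(tab$k_star$percent), 100)
  expect_equal(nrow(tab$rule_accuracy), 2)
  # age-invariant truth + categorical fit: slope bias shrinks with M
  stem <- tempfile()
  write_metrics_table(tab, stem)
  expect_true(file.exists(paste0(stem, "_parameters.csv")))
})
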