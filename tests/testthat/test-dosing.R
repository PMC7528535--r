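test_that("target exposures invert the model at group midpoints", {
  spec <- linear_er_spec(5.6, -0.25)
  tgt <- dosing_target(log(60))
  # age-invariant truth: every group gets the same closed-form exposure
  cc <- target_exposures(spec, c(0, 2, 12, 18), tgt)
  expect_equal(cc, rep((log(60) - 5.6) / -0.25, 3))
  # K = 1 uses the age-9 midpoint
  spec2 <- linear_er_spec(pf_grid(c(0, 18), c(5, 6)), -0.25)
  c1 <- target_exposures(spec2, c(0, 18), tgt)
  expect_equal(c1, (log(60) - pf_eval(spec2$intercept, 9)) / -0.25)
  # Emax spec midpoint inversion agrees with a bisection oracle
  des <- emax_example_design()
  emx <- emax_example_truth(des)
  ce <- target_exposures(emx, c(0, 1, 18), dosing_target(40))
  expect_equal(ce[1], bisect_exposure(emx, 0.5, 40), tolerance = 1e-6)
  expect_equal(ce[2], bisect_exposure(emx, 9.5, 40), tolerance = 1e-6)
})

test_that("objective G averages the dosing error over reference intervals", {
  cfg <- rule_search_config()
  # constant absolute error delta gives G = 6 * delta with the default
  # NICHD reference boundaries
  spec <- linear_er_spec(5.6, -0.25)
  tgt <- dosing_target(log(60))
  c_star <- (log(60) - 5.6) / -0.25
  delta <- 0.37
  off <- objective_G(spec, c(0, 18), tgt, cfg,
                     exposures = c_star + delta / 0.25)
  expect_equal(off$G, 6 * delta, tolerance = 1e-9)
  # exact targeting gives G = 0
  expect_equal(objective_G(spec, c(0, 18), tgt, cfg)$G, 0)
  # arbitrary rule on a piecewise-linear truth matches a 10x finer
  # quadrature to 1e-4 relative
  spec2 <- linear_er_spec(pf_grid(c(0, 3, 9, 18), c(5, 5.4, 5.9, 6.2)),
                          pf_grid(c(0, 18), c(-0.2, -0.3)))
  bnd <- c(0, 4.3, 11.1, 18)
  g_coarse <- objective_G(spec2, bnd, tgt,
                          rule_search_config(integration_points = 401))$G
  g_fine <- objective_G(spec2, bnd, tgt,
                        rule_search_config(integration_points = 4001))$G
  expect_equal(g_coarse, g_fine, tolerance = 1e-4)
})

test_that("boundary search finds jumps and is nested in K", {
  tgt <- dosing_target(log(60))
  cfg <- rule_search_config(boundary_step = 0.25)
  spec <- linear_er_spec(pf_step(c(0, 2, 18), c(5.0, 5.8)),
                         pf_constant(-0.25))
  r1 <- optimise_boundaries(spec, 1, tgt, cfg)
  expect_equal(r1$boundaries, c(0, 18))
  r2 <- optimise_boundaries(spec, 2, tgt, cfg)
  expect_lt(abs(r2$boundaries[2] - 2), 0.25 + 1e-9)
  expect_lt(r2$G, 1e-10)
  # G* never increases with K
  drs <- derive_dosing_rule(linear_scenario(1)$truth, tgt,
                            rule_search_config(boundary_step = 0.5))
  expect_true(all(diff(drs$G_star) <= 1e-12))
})

test_that("select_K implements the 25% improvement rule", {
  expect_equal(select_K(c(10, 4, 3.5, 3.4, 3.4, 3.4)), 2)
  expect_equal(select_K(rep(5, 6)), 1)
  expect_warning(ks <- select_K(c(32, 16, 8, 4, 2, 1)), "k_max")
  expect_equal(ks, 6)
  # scale invariance
  g <- c(12, 7, 5.2, 5.1, 5.05, 5.05)
  expect_equal(select_K(g), select_K(1000 * g))
  expect_equal(select_K(g), select_K(g / 1000))
  # a perfect fit at K selects K immediately
  expect_equal(select_K(c(3, 0, 0, 0)), 2)
})

test_that("refined target exposure dominates the midpoint rule", {
  tgt <- dosing_target(log(60))
  cfg <- rule_search_config(integration_points = 201)
  # age-invariant truth: refined equals midpoint exactly
  spec <- linear_er_spec(5.6, -0.25)
  expect_equal(refined_target_exposure(spec, c(2, 12), tgt, cfg),
               (log(60) - 5.6) / -0.25, tolerance = 1e-6)
  # linear intercept drift, constant slope: matches a dense grid search
  spec2 <- linear_er_spec(pf_grid(c(0, 18), c(5, 6.2)), -0.25)
  ref <- refined_target_exposure(spec2, c(2, 12), tgt, cfg)
  grid_cc <- seq(0.1, 12, length.out = 12000)
  ages <- seq(2, 12, length.out = 201)
  crit <- vapply(grid_cc, function(cc) {
    mean(abs(pf_eval(spec2$intercept, ages) - 0.25 * cc - log(60)))
  }, 0)
  expect_lt(abs(ref - grid_cc[which.min(crit)]), 1e-2)
  # and the refined exposure never does worse within the group
  int_da <- function(cc) {
    mean(abs(expected_response(spec2, ages, rep(cc, length(ages))) -
               log(60)))
  }
  mid <- target_exposures(spec2, c(2, 12), tgt)
  expect_lte(int_da(ref), int_da(mid) + 1e-10)
})

test_that("full pipeline on an age-invariant truth returns the closed form", {
  spec <- linear_er_spec(5.6, -0.25)
  tgt <- dosing_target(log(60))
  drs <- derive_dosing_rule(spec, tgt,
                            rule_search_config(boundary_step = 1))
  expect_equal(drs$K_star, 1)
  expect_equal(drs$rule$exposures, (log(60) - 5.6) / -0.25)
  expect_lt(drs$rule$G, 1e-12)
})

test_that("rules export and errors are informative", {
  spec <- linear_er_spec(5.6, -0.25)
  r <- optimise_boundaries(spec, 2, dosing_target(log(60)),
                           rule_search_config(boundary_step = 2))
  path <- tempfile(fileext = ".csv")
  write_dosing_rule(r, path)
  d <- read.csv(path)
  expect_equal(d$target_exposure, r$exposures)
  expect_error(target_exposures(linear_er_spec(5.6, 0), c(0, 18),
                                dosing_target(log(60))),
               "group 1")
})
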