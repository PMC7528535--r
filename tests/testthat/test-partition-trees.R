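# two-regime data with a clean break, optionally noiseless
break_data <- function(n = 200, break_age = 6, jump = 1, noise = 0,
                       seed = 1) {
  set.seed(seed)
  a <- sort(runif(n, 0, 18))
  C <- rlnorm(n, log(2.94), sqrt(0.921))
  y <- 5 + 0.2 * C + jump * (a > break_age) +
    rnorm(n, 0, sqrt(noise))
  er_dataset(a, C, y)
}

test_that("instability test handles degenerate and strong-signal cases", {
  # constant response: finite statistic, no rejection
  d <- er_dataset(seq(0.1, 17.9, length.out = 50),
                  rlnorm(50, 1, 0.5), rep(2, 50))
  ts <- instability_test(d)
  expect_true(is.finite(ts$statistic))
  expect_gte(ts$p_value, 0.99)
  # a strong break is detected decisively
  ts2 <- instability_test(break_data(noise = 0.01))
  expect_lt(ts2$p_value, 0.001)
})

test_that("supLM statistic is invariant to affine response rescaling", {
  d <- break_data(noise = 0.05, seed = 2)
  s1 <- instability_test(d)$statistic
  d2 <- d
  d2$response <- 3 + 10 * d$response
  s2 <- instability_test(d2)$statistic
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("find_split locates breaks and matches an exhaustive oracle", {
  d <- break_data(noise = 0)
  sp <- find_split(d)
  a <- sort(d$age)
  gap <- max(diff(a[abs(a - 6) < 2]))
  expect_lt(abs(sp$split_age - 6), gap + 1e-9)
  # exhaustive oracle: every admissible split, OLS on both sides
  d3 <- break_data(n = 60, noise = 0.1, seed = 3)
  d3 <- d3[order(d3$age), ]
  objs <- rep(NA_real_, 59)
  for (i in 10:50) {
    if (d3$age[i] == d3$age[i + 1]) next
    rl <- sum(resid(lm(response ~ exposure, d3[1:i, ]))^2)
    rr <- sum(resid(lm(response ~ exposure, d3[(i + 1):60, ]))^2)
    objs[i] <- rl + rr
  }
  best <- which.min(objs)
  expect_equal(find_split(d3)$split_age,
               (d3$age[best] + d3$age[best + 1]) / 2)
  # children objectives never exceed the parent's
  fam <- mob_family("linear")
  parent <- fam$fit(d3$response, d3$exposure)
  expect_lte(find_split(d3)$objective, parent$rss + 1e-10)
})

test_that("ties in the split objective break toward the youngest age", {
  # constant response: every split has zero objective
  d <- er_dataset(seq(1, 10, length.out = 10), 1:10, rep(0, 10))
  sp <- find_split(d, min_node_size = 2L)
  a <- sort(d$age)
  expect_equal(sp$split_age, (a[2] + a[3]) / 2)
})

test_that("grow_mob recovers regimes and honours its controls", {
  # noiseless break at 6: two leaves, split within one observation gap
  tree <- grow_mob(break_data(noise = 1e-8))
  lv <- mob_leaves(tree)
  expect_equal(nrow(lv), 2)
  expect_lt(abs(mob_splits(tree) - 6), 0.6)
  # depth cap 0 gives the root-only global fit
  d <- break_data(noise = 0.05, seed = 4)
  t0 <- grow_mob(d, max_depth = 0)
  expect_equal(nrow(mob_leaves(t0)), 1)
  gl <- mob_family("linear")$fit(d$response, d$exposure)
  expect_equal(t0$root$coef, gl$coef)
  # leaves partition the data and refits reproduce stored parameters
  scn <- linear_scenario(1)
  d1 <- generate_dataset(scn, seed = 11)
  tr <- grow_mob(d1)
  lv1 <- mob_leaves(tr)
  expect_equal(sum(lv1$n), nrow(d1))
  for (i in seq_len(nrow(lv1))) {
    inside <- d1$age > lv1$lower[i] & d1$age <= lv1$upper[i] |
      (lv1$lower[i] == 0 & d1$age == 0)
    expect_equal(sum(inside), lv1$n[i])
    refit <- mob_family("linear")$fit(d1$response[inside],
                                      d1$exposure[inside])
    expect_equal(unname(refit$coef),
                 unname(c(lv1$intercept[i], lv1$slope[i])),
                 tolerance = 1e-10)
  }
})

test_that("age-invariant truth mostly yields a single leaf", {
  scn <- linear_scenario(5)
  nl <- vapply(1:100, function(m) {
    nrow(mob_leaves(grow_mob(generate_dataset(scn, seed = 400 + m))))
  }, 0)
  # expected single-leaf rate about 1 - alpha = 0.95
  expect_gte(mean(nl == 1), 0.85)
})

test_that("PALM reduces to MOB without covariates and recovers global effects", {
  d <- break_data(noise = 0.05, seed = 5)
  pt <- fit_palm(d)
  expect_identical(pt$global_effects, numeric(0))
  expect_equal(mob_splits(pt$tree), mob_splits(grow_mob(d)))
  # known global effect 2.0 with an age-varying intercept
  set.seed(6)
  ests <- vapply(1:20, function(m) {
    set.seed(600 + m)
    n <- 200
    a <- runif(n, 0, 18)
    C <- rlnorm(n, log(2.94), sqrt(0.921))
    x <- rnorm(n)
    y <- 5 + (a > 6) + 0.2 * C + 2 * x + rnorm(n, 0, 0.2)
    fit_palm(er_dataset(a, C, y, covariates = cbind(x)))$global_effects
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 2), 3 * max(se, 0.01))
  # on a cleanly partitioned dataset the joint estimate matches OLS with
  # oracle group dummies
  set.seed(7)
  n <- 300
  a <- runif(n, 0, 18)
  C <- rlnorm(n, log(2.94), sqrt(0.921))
  x <- rnorm(n)
  grp <- a > 6
  y <- 5 + 2 * grp + (0.2 + 0.3 * grp) * C + 1.5 * x +
    rnorm(n, 0, 0.05)
  pf <- fit_palm(er_dataset(a, C, y, covariates = cbind(x)))
  oracle <- lm(y ~ 0 + factor(grp) + factor(grp):C + x)
  expect_equal(pf$global_effects, unname(coef(oracle)["x"]),
               tolerance = 1e-2)
  expect_true(pf$converged)
})

test_that("bootstrap aggregation averages tree step functions", {
  d <- break_data(noise = 0.05, seed = 8)
  # degenerate bootstrap: equals the single tree sampled on the grid
  agg1 <- bootstrap_aggregate(d, B = 1, resample = FALSE)
  tr <- grow_mob(d)
  pf <- mob_param_functions(tr)
  expect_equal(agg1$params[, 1], pf_eval(pf$intercept, agg1$age_grid))
  expect_equal(agg1$params[, 2], pf_eval(pf$slope, agg1$age_grid))
  # aggregated curves from several resamples are valid param functions
  agg <- bootstrap_aggregate(d, B = 10, seed = 9)
  fns <- aggregated_param_functions(agg)
  ages <- seq(0, 18, length.out = 500)
  expect_true(all(is.finite(pf_eval(fns$intercept, ages))))
  # age-invariant truth: aggregated slope flat within MC error
  scn <- linear_scenario(5)
  d5 <- generate_dataset(scn, seed = 10)
  agg5 <- bootstrap_aggregate(d5, B = 30, seed = 11)
  expect_lt(diff(range(agg5$params[, "slope"])), 0.05)
})
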