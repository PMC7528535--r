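#' Dosing target and search configuration
#'
#' `dosing_target()` holds the target response \eqn{Y^*} (default
#' `log(60)`, i.e. a 50\% reduction in seizure frequency on the
#' log(percent change + 110) scale of the epilepsy application) and an
#' optional age-to-mean-covariate profile used when the model adjusts for
#' baseline covariates.
#'
#' `rule_search_config()` controls the optimal-boundary search: the fixed
#' reference boundaries weighting the objective G (default NICHD-style
#' 0, 28/365, 1, 2, 6, 12, 18 years), the largest number of dose groups
#' `k_max`, the K-selection threshold `c`, the candidate-boundary grid
#' resolution, and the per-reference-interval Simpson integration grid
#' size (forced odd).
#'
#' @param y_star Target response.
#' @param covariate_profile `NULL`, a fixed length-P vector, or a
#'   `function(age)` returning the mean covariate vector at that age.
#' @return `dosing_target()` returns a `dosing_target` object.
#' @export
dosing_target <- function(y_star = log(60), covariate_profile = NULL) {
  stopifnot(is.finite(y_star))
  structure(list(y_star = y_star, covariate_profile = covariate_profile),
            class = "dosing_target")
}

#' @rdname dosing_target
#' @param reference_boundaries Strictly increasing fixed boundaries
#'   spanning \[0, 18\] defining the P intervals whose interval-averaged
#'   dosing error is summed in G.
#' @param k_max Maximum number of dose groups considered.
#' @param c_threshold Relative-improvement threshold for selecting K*.
#' @param boundary_step Candidate-boundary grid step in years (28/365 is
#'   always included as a candidate).
#' @param integration_points Simpson points per reference interval.
#' @export
rule_search_config <- function(reference_boundaries = c(0, 28 / 365, 1, 2,
                                                        6, 12, 18),
                               k_max = 6L, c_threshold = 0.25,
                               boundary_step = 0.1,
                               integration_points = 101L) {
  reference_boundaries <- as.numeric(reference_boundaries)
  stopifnot(all(diff(reference_boundaries) > 0),
            reference_boundaries[1] == AGE_MIN,
            reference_boundaries[length(reference_boundaries)] == AGE_MAX,
            k_max >= 1L, c_threshold > 0, c_threshold < 1,
            boundary_step > 0, integration_points >= 3L)
  if (integration_points %% 2L == 0L)
    integration_points <- integration_points + 1L
  structure(list(reference_boundaries = reference_boundaries,
                 k_max = as.integer(k_max), c_threshold = c_threshold,
                 boundary_step = boundary_step,
                 integration_points = as.integer(integration_points)),
            class = "rule_search_config")
}

profile_at <- function(target, age) {
  cp <- target$covariate_profile
  if (is.null(cp)) return(NULL)
  if (is.function(cp)) cp(age) else cp
}

#' Target exposures for given age groups
#'
#' For each group \eqn{(a_{k-1}, a_k]}, the target exposure \eqn{C_k} is
#' the exposure at which a patient aged at the group midpoint
#' \eqn{(a_{k-1}+a_k)/2}, with age-appropriate mean covariates, has
#' expected response equal to \eqn{Y^*} (via [invert_for_exposure()]).
#'
#' @param spec A fitted or true [er_spec].
#' @param boundaries Age boundaries \eqn{a_0 < ... < a_K} spanning
#'   \[0, 18\].
#' @param target A [dosing_target()].
#' @return Numeric vector of K target exposures.
#' @export
target_exposures <- function(spec, boundaries, target = dosing_target()) {
  boundaries <- as.numeric(boundaries)
  stopifnot(all(diff(boundaries) > 0))
  K <- length(boundaries) - 1L
  vapply(seq_len(K), function(k) {
    mid <- (boundaries[k] + boundaries[k + 1L]) / 2
    tryCatch(
      invert_for_exposure(spec, mid, target$y_star,
                          covariate_profile = profile_at(target, mid)),
      error = function(e)
        stop("target exposure undefined for group ", k, " (",
             signif(boundaries[k], 4), ", ", signif(boundaries[k + 1L], 4),
             "]: ", conditionMessage(e)))
  }, 0)
}

# Pre-computed integration scaffolding shared by all G evaluations: per
# reference interval, a Simpson grid with weights scaled so that the
# weighted sum of Da values IS the interval average, plus the expected
# response pieces evaluated once per grid age.
dosing_grid <- function(spec, target, config) {
  rb <- config$reference_boundaries
  np <- config$integration_points
  ages <- c(); wts <- c()
  for (p in seq_len(length(rb) - 1L)) {
    a <- seq(rb[p], rb[p + 1L], length.out = np)
    h <- a[2] - a[1]
    w <- simpson_weights(np) * h / (rb[p + 1L] - rb[p])
    ages <- c(ages, a); wts <- c(wts, w)
  }
  base <- pf_eval(spec$intercept, ages)
  if (length(spec$global_effects)) {
    cp <- lapply(ages, function(a) profile_at(target, a))
    if (any(vapply(cp, is.null, TRUE)))
      stop("spec has global effects: dosing_target needs a covariate profile")
    base <- base + vapply(cp, function(x) sum(x * spec$global_effects), 0)
  }
  g <- list(ages = ages, weights = wts, base = base)
  if (inherits(spec, "linear_er_spec")) {
    g$slope <- pf_eval(spec$slope, ages)
  } else {
    g$emax <- pf_eval(spec$emax, ages)
    g$ec50 <- pf_eval(spec$ec50, ages)
    g$hill <- pf_eval(spec$hill, ages)
  }
  g
}

# G for a rule given the scaffolding; exposures indexed by the group
# containing each grid age (left-open/right-closed).
grid_objective <- function(grid, boundaries, exposures, y_star) {
  gi <- findInterval(grid$ages, boundaries, left.open = TRUE)
  gi[gi < 1L] <- 1L
  gi[gi > length(exposures)] <- length(exposures)
  cc <- exposures[gi]
  ey <- if (!is.null(grid$slope)) {
    grid$base + grid$slope * cc
  } else {
    cd <- cc^grid$hill
    grid$base + grid$emax * cd / (grid$ec50^grid$hill + cd)
  }
  sum(grid$weights * abs(ey - y_star))
}

#' Dosing objective G for a given rule
#'
#' Evaluates \eqn{G = \sum_p \frac{1}{a^*_p - a^*_{p-1}}
#' \int_{a^*_{p-1}}^{a^*_p} D_a \, da} where \eqn{D_a = |E[Y | A = a,
#' C = C_k] - Y^*|} and \eqn{C_k} is the rule's target exposure for the
#' group containing age a.  Integrals use composite Simpson quadrature on
#' the configured per-interval grids.
#'
#' @inheritParams target_exposures
#' @param config A [rule_search_config()].
#' @param exposures Optional per-group exposures; by default the
#'   midpoint-inversion [target_exposures()] are used.
#' @return A list with `G`, the `exposures` used, and the `boundaries`.
#' @export
objective_G <- function(spec, boundaries, target = dosing_target(),
                        config = rule_search_config(), exposures = NULL) {
  if (is.null(exposures))
    exposures <- target_exposures(spec, boundaries, target)
  stopifnot(length(exposures) == length(boundaries) - 1L)
  grid <- dosing_grid(spec, target, config)
  list(G = grid_objective(grid, boundaries, exposures, target$y_star),
       exposures = exposures, boundaries = boundaries)
}

candidate_boundaries <- function(config) {
  cand <- seq(config$boundary_step, AGE_MAX - config$boundary_step,
              by = config$boundary_step)
  sort(unique(c(cand, 28 / 365)))
}

#' Optimal age boundaries for a K-group dosing rule
#'
#' Finds the K-group rule minimising G.  For K up to 3 the search is
#' exhaustive over all configurations of interior boundaries on the
#' candidate grid (0.1-year steps plus 28/365 by default); for larger K
#' it starts from the optimal (K-1)-group rule, adds the best extra
#' boundary, and refines by coordinate descent until stable.  The search
#' is deterministic; ties favour the lexicographically smallest boundary
#' vector.
#'
#' @inheritParams objective_G
#' @param K Number of dose groups.
#' @return An object of class `dosing_rule`: `K`, `boundaries`,
#'   `exposures`, `G`.
#' @export
optimise_boundaries <- function(spec, K, target = dosing_target(),
                                config = rule_search_config()) {
  stopifnot(K >= 1L, K <= config$k_max)
  optimise_chain(spec, K, target, config)[[K]]
}

# Optimal rules for K = 1..k_upto, computed incrementally so the
# coordinate-descent stages reuse the previous K's solution and all stages
# share one integration scaffold.
optimise_chain <- function(spec, k_upto, target, config) {
  grid <- dosing_grid(spec, target, config)
  cand <- candidate_boundaries(config)
  midpoints <- function(bnd) (bnd[-length(bnd)] + bnd[-1]) / 2
  exposures_for <- function(bnd) {
    vapply(midpoints(bnd), function(mid) {
      tryCatch(invert_for_exposure(spec, mid, target$y_star,
                                   profile_at(target, mid)),
               error = function(e) NA_real_)
    }, 0)
  }
  eval_rule <- function(interior) {
    bnd <- c(AGE_MIN, interior, AGE_MAX)
    ex <- exposures_for(bnd)
    if (anyNA(ex)) return(Inf)
    grid_objective(grid, bnd, ex, target$y_star)
  }
  rules <- vector("list", k_upto)
  interior <- numeric(0)
  for (K in seq_len(k_upto)) {
    if (K == 1L) {
      interior <- numeric(0)
    } else if (K <= 3L) {
      combs <- utils::combn(cand, K - 1L)
      vals <- apply(combs, 2L, eval_rule)
      interior <- combs[, which.min(vals)]
    } else {
      add <- setdiff(cand, interior)
      vals <- vapply(add, function(a) eval_rule(sort(c(interior, a))), 0)
      interior <- sort(c(interior, add[which.min(vals)]))
      repeat {
        changed <- FALSE
        cur_val <- eval_rule(interior)
        for (j in seq_along(interior)) {
          lo <- if (j == 1L) AGE_MIN else interior[j - 1L]
          hi <- if (j == length(interior)) AGE_MAX else interior[j + 1L]
          opts <- cand[cand > lo & cand < hi & !(cand %in% interior[-j])]
          if (length(opts) == 0L) next
          vals <- vapply(opts, function(a) {
            eval_rule(sort(replace(interior, j, a)))
          }, 0)
          if (min(vals) < cur_val - 1e-12) {
            interior[j] <- opts[which.min(vals)]
            interior <- sort(interior)
            cur_val <- min(vals)
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
    bnd <- c(AGE_MIN, interior, AGE_MAX)
    ex <- target_exposures(spec, bnd, target)
    rules[[K]] <- structure(
      list(K = K, boundaries = bnd, exposures = ex,
           G = grid_objective(grid, bnd, ex, target$y_star)),
      class = "dosing_rule")
  }
  rules
}

#' Select the optimal number of dose groups K*
#'
#' Given the minimised objective values \eqn{G^*_1, ..., G^*_{K_{max}}},
#' K* is the smallest K whose relative improvement
#' \eqn{(G^*_K - G^*_{K+1})/G^*_K} falls below the threshold `c` (default
#' 25\%).  A zero objective selects that K immediately; if every step
#' improves by more than `c`, K* is `k_max` (with a warning).
#'
#' @param G_star Numeric vector of minimised objective values for
#'   K = 1, ..., Kmax.
#' @param c_threshold Relative-improvement threshold.
#' @return Integer K*.
#' @export
select_K <- function(G_star, c_threshold = 0.25) {
  stopifnot(length(G_star) >= 1L)
  if (any(G_star < 0)) stop("objective values must be non-negative")
  for (K in seq_len(length(G_star) - 1L)) {
    if (G_star[K] <= 1e-12) return(K)
    if ((G_star[K] - G_star[K + 1L]) / G_star[K] < c_threshold) return(K)
  }
  K <- length(G_star)
  if (K > 1L && G_star[K] > 1e-12)
    warning("every refinement improved G by more than the threshold; ",
            "K* set to k_max = ", K)
  K
}

#' Derive the optimal dosing rule across K = 1..Kmax
#'
#' Convenience wrapper: optimises the boundaries for every K, selects K*,
#' and returns the selected rule together with the full G profile.
#'
#' @inheritParams objective_G
#' @return An object of class `dosing_rule_set` with `rules` (list of
#'   [optimise_boundaries()] results), `G_star`, `K_star` and the selected
#'   `rule`.
#' @examples
#' spec <- linear_er_spec(4.7, -0.05)
#' drs <- derive_dosing_rule(spec,
#'   config = rule_search_config(boundary_step = 1, k_max = 3))
#' drs$K_star  # 1: the truth is age-invariant
#' @export
derive_dosing_rule <- function(spec, target = dosing_target(),
                               config = rule_search_config()) {
  rules <- optimise_chain(spec, config$k_max, target, config)
  G_star <- vapply(rules, function(r) r$G, 0)
  K_star <- select_K(G_star, config$c_threshold)
  structure(list(rules = rules, G_star = G_star, K_star = K_star,
                 rule = rules[[K_star]], target = target, config = config),
            class = "dosing_rule_set")
}

#' Refined target exposure for one age group
#'
#' Rather than inverting the model at the group midpoint, finds the single
#' exposure minimising the integrated absolute difference between the
#' expected response and the target over the whole group,
#' \eqn{\arg\min_C \int_{a_{k-1}}^{a_k} |E[Y | a, C] - Y^*| \, da},
#' by one-dimensional numerical minimisation on a Simpson grid.
#'
#' @inheritParams objective_G
#' @param interval Length-2 numeric: the group's age interval.
#' @return The refined exposure (scalar).
#' @export
refined_target_exposure <- function(spec, interval,
                                    target = dosing_target(),
                                    config = rule_search_config()) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  np <- config$integration_points
  ages <- seq(interval[1], interval[2], length.out = np)
  w <- simpson_weights(np) * (ages[2] - ages[1])
  cps <- if (length(spec$global_effects)) {
    t(vapply(ages, function(a) profile_at(target, a),
             numeric(length(spec$global_effects))))
  } else NULL
  crit <- function(cc) {
    ey <- expected_response(spec, ages, rep(cc, np), covariates = cps)
    sum(w * abs(ey - target$y_star))
  }
  anchor <- target_exposures(spec, interval, target)
  hi <- max(anchor * 4, 1)
  if (crit(0) == crit(hi) && crit(0) == crit(anchor))
    stop("flat dosing objective over the group: exposure has no effect")
  stats::optimize(crit, c(0, hi), tol = 1e-8)$minimum
}

#' @export
print.dosing_rule <- function(x, ...) {
  cat(sprintf("Dosing rule with K = %d age group(s), G = %.6g\n", x$K, x$G))
  for (k in seq_len(x$K)) {
    cat(sprintf("  (%.4g, %.4g] years: target exposure %.6g\n",
                x$boundaries[k], x$boundaries[k + 1L], x$exposures[k]))
  }
  invisible(x)
}

#' @export
print.dosing_rule_set <- function(x, ...) {
  cat("Optimal dosing rules, K = 1..", length(x$G_star), "\n", sep = "")
  cat("  G*:", paste(signif(x$G_star, 5), collapse = ", "), "\n")
  cat("  selected K* =", x$K_star, "\n\n")
  print(x$rule)
  invisible(x)
}

#' Export a dosing rule as CSV
#'
#' One row per age group: lower bound, upper bound, target exposure.
#'
#' @param rule A `dosing_rule`.
#' @param path Output file path.
#' @export
write_dosing_rule <- function(rule, path) {
  d <- data.frame(lower = rule$boundaries[-length(rule$boundaries)],
                  upper = rule$boundaries[-1],
                  target_exposure = rule$exposures)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
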