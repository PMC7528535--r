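#' Bootstrap-aggregated partition trees
#'
#' Draws `B` bootstrap resamples of the exposure-response data, fits a
#' partition tree to each (a PALM fit when the data carry baseline
#' covariates and the node model is linear, a plain MOB tree otherwise),
#' evaluates each tree's step parameter functions on an age grid, and
#' averages per grid point.  Linear interpolation of the averaged values
#' gives smooth age-parameter curves: no parametric form is assumed for
#' the relationship between a model parameter and age.
#'
#' Resamples whose tree fit fails are counted and excluded from the
#' average.
#'
#' @inheritParams grow_mob
#' @param B Number of bootstrap replicates.
#' @param age_grid Evaluation grid over \[0, 18\] (default 0.05-year
#'   steps, 361 points).
#' @param resample Set to `FALSE` to refit on the original data each
#'   replicate (degenerate bootstrap, used for checks).
#' @param seed Optional integer seed.
#' @return An object of class `aggregated_fit` with the grid, the averaged
#'   per-parameter values, averaged global effects (PALM case), `B`, the
#'   number of failed replicates, and the node-model family.
#' @examples
#' scn <- linear_scenario(5, seed = 2)
#' agg <- bootstrap_aggregate(generate_dataset(scn), B = 5, seed = 3)
#' @export
bootstrap_aggregate <- function(data, family = "linear", B = 1000L,
                                age_grid = seq(AGE_MIN, AGE_MAX, by = 0.05),
                                alpha = 0.05, min_node_size = 10L,
                                max_depth = Inf, trim = 0.1,
                                resample = TRUE, seed = NULL) {
  stopifnot(B >= 1L)
  data <- validate_er_dataset(data)
  if (!is.null(seed)) set.seed(seed)
  fam_name <- if (is.character(family)) family else family$name
  use_palm <- fam_name == "linear" && !is.null(covariate_matrix(data))
  n <- nrow(data)
  acc <- NULL
  par_names <- NULL
  gacc <- NULL
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    db <- data[idx, , drop = FALSE]
    vals <- tryCatch({
      if (use_palm) {
        fit <- fit_palm(db, alpha = alpha, min_node_size = min_node_size,
                        max_depth = max_depth, trim = trim)
        pf <- mob_param_functions(fit$tree)
        list(pars = pf, gamma = fit$global_effects)
      } else {
        tree <- grow_mob(db, family, alpha = alpha,
                         min_node_size = min_node_size,
                         max_depth = max_depth, trim = trim)
        list(pars = mob_param_functions(tree), gamma = numeric(0))
      }
    }, error = function(e) NULL)
    if (is.null(vals)) {
      n_failed <- n_failed + 1L
      next
    }
    m <- vapply(vals$pars, pf_eval, numeric(length(age_grid)), age = age_grid)
    if (is.null(acc)) {
      acc <- m
      par_names <- names(vals$pars)
      gacc <- vals$gamma
    } else {
      acc <- acc + m
      gacc <- gacc + vals$gamma
    }
  }
  B_used <- B - n_failed
  if (B_used == 0L) stop("all ", B, " bootstrap tree fits failed")
  if (n_failed > 0L)
    message(n_failed, " of ", B, " bootstrap fits failed and were excluded")
  structure(list(age_grid = age_grid,
                 params = acc / B_used,
                 par_names = par_names,
                 global_effects = gacc / B_used,
                 family = fam_name,
                 B = B, n_failed = n_failed),
            class = "aggregated_fit")
}

#' Interpolated parameter functions from an aggregated fit
#'
#' @param agg An [bootstrap_aggregate()] result.
#' @return Named list of interpolated-grid [param_fn]s.
#' @export
aggregated_param_functions <- function(agg) {
  stopifnot(inherits(agg, "aggregated_fit"))
  out <- lapply(seq_along(agg$par_names), function(j) {
    pf_grid(agg$age_grid, agg$params[, j])
  })
  names(out) <- agg$par_names
  out
}

#' Model spec implied by an aggregated fit
#'
#' @param agg An [bootstrap_aggregate()] result.
#' @return An [er_spec] with interpolated-grid parameter functions.
#' @export
as_aggregated_spec <- function(agg) {
  pf <- aggregated_param_functions(agg)
  if (agg$family == "linear") {
    linear_er_spec(pf$intercept, pf$slope,
                   global_effects = agg$global_effects)
  } else {
    emax_er_spec(0, pf$emax, pf$ec50, hill = 1)
  }
}

#' Export an aggregated fit as CSV
#'
#' Writes one row per grid age with a column per parameter.
#'
#' @param agg An [bootstrap_aggregate()] result.
#' @param path Output file path.
#' @export
write_aggregated_fit <- function(agg, path) {
  d <- data.frame(age = agg$age_grid)
  for (j in seq_along(agg$par_names)) d[[agg$par_names[j]]] <- agg$params[, j]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.aggregated_fit <- function(x, ...) {
  cat(sprintf(
    "Bootstrap-aggregated %s fit: B = %d (%d failed), %d-point age grid\n",
    x$family, x$B, x$n_failed, length(x$age_grid)))
  invisible(x)
}
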