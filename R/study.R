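#' Fit one modelling method to a dataset
#'
#' Dispatch for the simulation driver and the command-line interface.
#' Methods:
#' \describe{
#'   \item{categorical}{OLS with pre-specified ICH E11 age groups
#'     ([fit_categorical()]);}
#'   \item{mob / palm}{a single partition tree ([grow_mob()] /
#'     [fit_palm()]);}
#'   \item{mob_boot / palm_boot}{bootstrap-aggregated trees
#'     ([bootstrap_aggregate()]);}
#'   \item{bspline_linear / bspline_emax}{Bayesian penalised B-splines
#'     ([fit_bspline_linear()] / [fit_bspline_emax()]).}
#' }
#'
#' @param data An [er_dataset()].
#' @param method Method name (see above).
#' @param options Named list of extra arguments passed to the underlying
#'   fitter (e.g. `B`, `iterations`, `alpha`).
#' @return A list with `spec` (an [er_spec] exposing the fitted parameter
#'   functions) and `fit` (the method's native fit object).
#' @export
fit_method <- function(data, method = c("categorical", "mob", "palm",
                                        "mob_boot", "palm_boot",
                                        "bspline_linear", "bspline_emax"),
                       options = list()) {
  method <- match.arg(method)
  call_with <- function(f, data, ...) {
    args <- utils::modifyList(list(...), options)
    do.call(f, c(list(data), args))
  }
  fit <- switch(method,
    categorical = call_with(fit_categorical, data),
    mob = call_with(grow_mob, data),
    palm = call_with(fit_palm, data),
    mob_boot = call_with(bootstrap_aggregate, data, family = "emax2"),
    palm_boot = call_with(bootstrap_aggregate, data, family = "linear"),
    bspline_linear = call_with(fit_bspline_linear, data),
    bspline_emax = call_with(fit_bspline_emax, data))
  spec <- switch(method,
    categorical = as_linear_spec(fit),
    mob = as_tree_spec(fit),
    palm = as_tree_spec(fit),
    mob_boot = as_aggregated_spec(fit),
    palm_boot = as_aggregated_spec(fit),
    bspline_linear = as_posterior_spec(fit),
    bspline_emax = as_posterior_spec(fit))
  list(spec = spec, fit = fit, method = method)
}

#' Run a scenario-by-method simulation study
#'
#' The full evaluation loop: for every scenario and method, generate M
#' seeded datasets, fit the method, accumulate parameter and
#' expected-response metrics against the generative truth, derive optimal
#' dosing rules for K = 1..Kmax, tally the selected K*, and compute the
#' integrated dosing-rule accuracy per K.  Per-replicate seeds are
#' derived from the master seed by a counter scheme
#' (`seed * 1000 + replicate`), so any single replicate can be re-run in
#' isolation.  Replicates whose fit fails are logged, counted and
#' skipped.
#'
#' @param scenarios Named list of [scenario()]s.
#' @param methods Character vector of method names ([fit_method()]).
#' @param M Replicates per scenario-method cell.
#' @param seed Master seed.
#' @param config A [metrics_config()].
#' @param target A [dosing_target()].
#' @param rule_config A [rule_search_config()]; set `NULL` to skip the
#'   dosing-rule stage.
#' @param method_options Named list (per method) of option lists for
#'   [fit_method()].
#' @param verbose Log per-replicate progress to stderr.
#' @return A `metrics_table`: data frames `parameters` (integrated
#'   AAB/ESD/EMSE per scenario, method and parameter), `response` (same
#'   for expected response), `rule_accuracy` (per K), and `k_star`
#'   (frequency distribution of K*).
#' @examples
#' \donttest{
#' tab <- run_study(scenario_library()["scenario5"], "categorical", M = 2,
#'                  seed = 1, config = metrics_config(101, 101),
#'                  rule_config = rule_search_config(boundary_step = 1,
#'                                                   k_max = 2))
#' tab$parameters
#' }
#' @export
run_study <- function(scenarios, methods, M = 10L, seed = 1L,
                      config = metrics_config(),
                      target = dosing_target(),
                      rule_config = rule_search_config(),
                      method_options = list(), verbose = FALSE) {
  if (inherits(scenarios, "er_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  par_rows <- resp_rows <- acc_rows <- k_rows <- list()
  for (sc_name in names(scenarios)) {
    scn <- scenarios[[sc_name]]
    truth <- scn$truth
    for (method in methods) {
      opts <- method_options[[method]] %||% list()
      fits <- list()
      rule_sets <- list()
      n_failed <- 0L
      for (m in seq_len(M)) {
        rep_seed <- seed * 1000L + m
        dat <- generate_dataset(scn, seed = rep_seed)
        res <- tryCatch(fit_method(dat, method, opts),
                        error = function(e) {
                          if (verbose)
                            message("  replicate ", m, " failed: ",
                                    conditionMessage(e))
                          NULL
                        })
        if (is.null(res)) {
          n_failed <- n_failed + 1L
          next
        }
        fits[[length(fits) + 1L]] <- res$spec
        if (!is.null(rule_config)) {
          rs <- tryCatch(
            derive_dosing_rule(res$spec, target, rule_config),
            error = function(e) NULL)
          if (!is.null(rs)) rule_sets[[length(rule_sets) + 1L]] <- rs
        }
        if (verbose)
          message(sprintf("[%s/%s] replicate %d/%d done", sc_name, method,
                          m, M))
      }
      if (length(fits) == 0L) {
        warning("all replicates failed for ", sc_name, "/", method)
        next
      }
      # parameter metrics (linear family only has intercept/slope; Emax
      # methods expose emax/ec50)
      par_names <- if (inherits(truth, "linear_er_spec"))
        c("intercept", "slope") else c("emax", "ec50")
      for (p in par_names) {
        pm <- param_metrics(lapply(fits, `[[`, p), truth[[p]], config)
        par_rows[[length(par_rows) + 1L]] <- data.frame(
          scenario = sc_name, method = method, parameter = p,
          M = length(fits), n_failed = n_failed,
          aab = pm$integrated[["aab"]], esd = pm$integrated[["esd"]],
          emse = pm$integrated[["emse"]])
      }
      rm_ <- response_metrics(fits, truth, config)
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        scenario = sc_name, method = method, M = length(fits),
        aab = rm_[["aab"]], esd = rm_[["esd"]], emse = rm_[["emse"]])
      if (length(rule_sets)) {
        k_max <- rule_config$k_max
        for (K in seq_len(k_max)) {
          rules_k <- lapply(rule_sets, function(rs) rs$rules[[K]])
          ra <- rule_accuracy(rules_k, truth, target$y_star, config)
          acc_rows[[length(acc_rows) + 1L]] <- data.frame(
            scenario = sc_name, method = method, K = K,
            integrated_accuracy = ra$integrated)
        }
        ks <- vapply(rule_sets, function(rs) rs$K_star, 0L)
        tab <- tabulate(ks, nbins = k_max)
        k_rows[[length(k_rows) + 1L]] <- data.frame(
          scenario = sc_name, method = method, K_star = seq_len(k_max),
          count = tab, percent = 100 * tab / length(ks))
      }
    }
  }
  structure(list(parameters = do.call(rbind, par_rows),
                 response = do.call(rbind, resp_rows),
                 rule_accuracy = if (length(acc_rows))
                   do.call(rbind, acc_rows) else NULL,
                 k_star = if (length(k_rows)) do.call(rbind, k_rows)
                   else NULL,
                 M = M, seed = seed),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("Simulation study metrics (M =", x$M, ", master seed", x$seed, ")\n")
  cat("\nIntegrated parameter metrics:\n")
  print(x$parameters, row.names = FALSE)
  cat("\nIntegrated expected-response metrics:\n")
  print(x$response, row.names = FALSE)
  if (!is.null(x$rule_accuracy)) {
    cat("\nIntegrated dosing-rule accuracy by K:\n")
    print(x$rule_accuracy, row.names = FALSE)
  }
  if (!is.null(x$k_star)) {
    cat("\nSelected K* distribution (%):\n")
    print(x$k_star, row.names = FALSE)
  }
  invisible(x)
}

#' Write a metrics table to CSV files
#'
#' Writes `<stem>_parameters.csv`, `<stem>_response.csv` and, when
#' present, `<stem>_rule_accuracy.csv` and `<stem>_k_star.csv`.
#'
#' @param tab A [run_study()] result.
#' @param stem Output path stem.
#' @export
write_metrics_table <- function(tab, stem) {
  utils::write.csv(tab$parameters, paste0(stem, "_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(tab$response, paste0(stem, "_response.csv"),
                   row.names = FALSE)
  if (!is.null(tab$rule_accuracy))
    utils::write.csv(tab$rule_accuracy,
                     paste0(stem, "_rule_accuracy.csv"), row.names = FALSE)
  if (!is.null(tab$k_star))
    utils::write.csv(tab$k_star, paste0(stem, "_k_star.csv"),
                     row.names = FALSE)
  invisible(stem)
}
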