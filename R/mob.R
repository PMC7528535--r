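#' @title Model-based recursive partitioning over age
#' @description Internal machinery: node-model families, the supLM
#'   parameter-instability test, split search, tree growth, and PALM-style
#'   estimation of global covariate effects.
#' @name mob
NULL

# --- node-model families -----------------------------------------------------

#' Node-model family for partition trees
#'
#' Two parametric node models are available: `"linear"` (intercept and
#' exposure slope, ordinary least squares) and `"emax2"` (two-parameter
#' hyperbolic Emax, fitted by profiled least squares: for fixed EC50 the
#' Emax coefficient is linear, so the profile residual sum of squares is
#' minimised over log EC50 by a deterministic grid search refined with
#' golden-section optimisation).
#'
#' @param family `"linear"` or `"emax2"`.
#' @return A list with elements `name`, `npar`, `par_names`, `fit(y, C)`
#'   and `scores(y, C, coef)` used by the tree-growing functions.
#' @export
mob_family <- function(family = c("linear", "emax2")) {
  family <- match.arg(family)
  if (family == "linear") {
    list(
      name = "linear", npar = 2L, par_names = c("intercept", "slope"),
      fit = function(y, C) {
        X <- cbind(1, C)
        f <- stats::lm.fit(X, y)
        if (any(is.na(f$coefficients)))
          stop("singular node fit: no exposure variation in node")
        r <- y - X %*% f$coefficients
        list(coef = c(intercept = unname(f$coefficients[1]),
                      slope = unname(f$coefficients[2])),
             rss = sum(r^2), residuals = drop(r))
      },
      scores = function(y, C, coef) {
        r <- y - coef[1] - coef[2] * C
        cbind(r, r * C)
      })
  } else {
    list(
      name = "emax2", npar = 2L, par_names = c("emax", "ec50"),
      fit = function(y, C) {
        if (all(C <= 0)) stop("emax2 node needs positive exposures")
        pos <- C[C > 0]
        lo <- log(min(pos)) - log(10); hi <- log(max(pos)) + log(10)
        prof <- function(lec) {
          g <- C / (exp(lec) + C)
          sg2 <- sum(g^2)
          if (sg2 < 1e-12) return(sum(y^2))
          sum(y^2) - sum(g * y)^2 / sg2
        }
        grid <- seq(lo, hi, length.out = 60)
        rssg <- vapply(grid, prof, 0)
        i <- which.min(rssg)
        br <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
        opt <- stats::optimize(prof, br, tol = 1e-9)
        ec50 <- exp(opt$minimum)
        g <- C / (ec50 + C)
        emax <- sum(g * y) / sum(g^2)
        r <- y - emax * g
        list(coef = c(emax = emax, ec50 = ec50), rss = sum(r^2),
             residuals = r)
      },
      scores = function(y, C, coef) {
        g <- C / (coef[2] + C)
        r <- y - coef[1] * g
        cbind(r * g, -r * coef[1] * C / (coef[2] + C)^2)
      })
  }
}

# --- supLM asymptotic null distribution (simulated, cached) ------------------

.agedose_cache <- new.env(parent = emptyenv())

# Simulated asymptotic null of sup_{t in [trim, 1-trim]} ||BB_k(t)||^2/(t(1-t)),
# with BB_k a k-dimensional Brownian bridge.  Computed once per (k, trim) on a
# fixed internal RNG stream (user RNG state untouched) and cached.
suplm_null <- function(k, trim = 0.1, nsim = 20000L, ngrid = 1000L) {
  key <- sprintf("suplm_k%d_t%0.3f", k, trim)
  if (!is.null(.agedose_cache[[key]])) return(.agedose_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(83100000L + 1000L * k + round(trim * 100))
  tt <- seq_len(ngrid - 1L) / ngrid
  keep <- tt >= trim & tt <= 1 - trim
  denom <- (tt * (1 - tt))[keep]
  out <- numeric(nsim)
  block <- 250L
  done <- 0L
  while (done < nsim) {
    b <- min(block, nsim - done)
    ss <- matrix(0, sum(keep), b)
    for (j in seq_len(k)) {
      z <- matrix(stats::rnorm(ngrid * b), ngrid, b)
      w <- apply(z, 2L, cumsum) / sqrt(ngrid)
      bb <- w[seq_len(ngrid - 1L), , drop = FALSE] -
        outer(tt, w[ngrid, ])
      ss <- ss + bb[keep, , drop = FALSE]^2
    }
    out[done + seq_len(b)] <- apply(ss / denom, 2L, max)
    done <- done + b
  }
  .agedose_cache[[key]] <- sort(out)
  .agedose_cache[[key]]
}

# --- instability test --------------------------------------------------------

#' Test for parameter instability over age (supLM)
#'
#' Orders the node's observations by age, accumulates the standardised
#' model scores, and computes the supremum-LM statistic over candidate
#' split fractions in a trimmed range.  The p-value is taken from the
#' asymptotic null distribution (a simulated, cached reference
#' distribution of the supremum of a squared standardised Brownian
#' bridge).
#'
#' @param data An [er_dataset()].
#' @param family A [mob_family()] or its name.
#' @param trim Trimming fraction for the candidate split range (default
#'   0.1, i.e. split fractions in \[0.1, 0.9\]).
#' @param fit Optional pre-computed node fit (list with `coef`).
#' @return A list with `statistic` and `p_value`.
#' @export
instability_test <- function(data, family = "linear", trim = 0.1, fit = NULL) {
  if (is.character(family)) family <- mob_family(family)
  data <- data[order(data$age), , drop = FALSE]
  y <- data$response; C <- data$exposure
  n <- length(y)
  if (is.null(fit)) fit <- family$fit(y, C)
  S <- family$scores(y, C, fit$coef)
  if (max(abs(S)) < 1e-10)
    return(list(statistic = 0, p_value = 1))
  J <- crossprod(S) / n
  R <- tryCatch(chol(J), error = function(e)
    stop("singular information matrix at node"))
  # pre-whiten the scores so the cumulative process is standard under H0
  Sw <- S %*% backsolve(R, diag(ncol(S)))
  W <- apply(Sw, 2L, cumsum) / sqrt(n)
  tt <- seq_len(n - 1L) / n
  keep <- which(tt >= trim & tt <= 1 - trim)
  if (length(keep) == 0L) return(list(statistic = 0, p_value = 1))
  lm_t <- rowSums(W[keep, , drop = FALSE]^2) / (tt[keep] * (1 - tt[keep]))
  stat <- max(lm_t)
  null <- suplm_null(family$npar, trim)
  p <- (sum(null >= stat) + 1) / (length(null) + 1)
  list(statistic = stat, p_value = p)
}

# --- split search ------------------------------------------------------------

#' Find the best age split for a node
#'
#' Scans candidate split ages (midpoints between consecutive distinct
#' observed ages, with at least `min_node_size` subjects on each side) and
#' returns the one minimising the sum of the two children's residual sums
#' of squares.  Ties are broken toward the youngest admissible split age.
#'
#' @inheritParams instability_test
#' @param min_node_size Minimum subjects per child.
#' @return A list with `split_age`, `objective` and the children's fits, or
#'   `NULL` when no admissible split exists.
#' @export
find_split <- function(data, family = "linear", min_node_size = 10L) {
  if (is.character(family)) family <- mob_family(family)
  data <- data[order(data$age), , drop = FALSE]
  y <- data$response; C <- data$exposure; a <- data$age
  n <- length(y)
  cand <- which(seq_len(n - 1L) >= min_node_size &
                  (n - seq_len(n - 1L)) >= min_node_size &
                  diff(a) > 0)
  if (length(cand) == 0L) return(NULL)
  best <- NULL
  for (i in cand) {
    obj <- tryCatch({
      fl <- family$fit(y[1:i], C[1:i])
      fr <- family$fit(y[(i + 1L):n], C[(i + 1L):n])
      fl$rss + fr$rss
    }, error = function(e) NA_real_)
    if (is.na(obj)) next
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(split_age = (a[i] + a[i + 1L]) / 2, objective = obj,
                   index = i)
    }
  }
  best
}

# --- tree growth -------------------------------------------------------------

#' Grow a model-based partition tree over age
#'
#' Recursively fits the node model, tests for parameter instability over
#' age, and splits at the objective-minimising age until no test rejects
#' at level `alpha` (or node-size / depth limits bind).  Leaves partition
#' \[0, 18\] into left-open/right-closed age intervals.
#'
#' @inheritParams find_split
#' @param alpha Significance level of the instability test (default 0.05).
#' @param max_depth Maximum number of splits along any path (`Inf` for no
#'   cap; 0 returns the root-only tree, i.e. a single global fit).
#' @param trim Trimming fraction passed to [instability_test()].
#' @return An object of class `mob_tree`.
#' @examples
#' scn <- linear_scenario(1, seed = 7)
#' tree <- grow_mob(generate_dataset(scn))
#' print(tree)
#' @export
grow_mob <- function(data, family = "linear", alpha = 0.05,
                     min_node_size = 10L, max_depth = Inf, trim = 0.1) {
  if (is.character(family)) family <- mob_family(family)
  data <- validate_er_dataset(data)
  data <- data[order(data$age), , drop = FALSE]
  node <- grow_node(data, family, alpha, min_node_size, max_depth, trim,
                    interval = c(AGE_MIN, AGE_MAX), depth = 0L)
  structure(list(family = family$name, alpha = alpha,
                 min_node_size = min_node_size, root = node),
            class = "mob_tree")
}

grow_node <- function(data, family, alpha, min_node_size, max_depth, trim,
                      interval, depth) {
  y <- data$response; C <- data$exposure
  fit <- family$fit(y, C)
  node <- list(interval = interval, n = nrow(data), coef = fit$coef,
               rss = fit$rss, p_value = NA_real_, statistic = NA_real_,
               split = NULL)
  can_split <- nrow(data) >= 2L * min_node_size && depth < max_depth
  if (can_split) {
    ts <- tryCatch(instability_test(data, family, trim, fit = fit),
                   error = function(e) NULL)
    if (!is.null(ts)) {
      node$p_value <- ts$p_value
      node$statistic <- ts$statistic
      if (ts$p_value <= alpha) {
        sp <- find_split(data, family, min_node_size)
        if (!is.null(sp)) {
          node$split <- sp$split_age
          left <- data[data$age <= sp$split_age, , drop = FALSE]
          right <- data[data$age > sp$split_age, , drop = FALSE]
          node$left <- grow_node(left, family, alpha, min_node_size,
                                 max_depth, trim,
                                 c(interval[1], sp$split_age), depth + 1L)
          node$right <- grow_node(right, family, alpha, min_node_size,
                                  max_depth, trim,
                                  c(sp$split_age, interval[2]), depth + 1L)
        }
      }
    }
  }
  node
}

tree_leaves <- function(node) {
  if (is.null(node$split)) return(list(node))
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Leaves and split ages of a partition tree
#'
#' @param tree A [grow_mob()] tree.
#' @return `mob_leaves()` returns a data frame with one row per leaf
#'   (interval bounds, size and fitted parameters); `mob_splits()` the
#'   sorted split ages.
#' @export
mob_leaves <- function(tree) {
  lv <- tree_leaves(tree$root)
  cf <- do.call(rbind, lapply(lv, function(l) l$coef))
  d <- data.frame(lower = vapply(lv, function(l) l$interval[1], 0),
                  upper = vapply(lv, function(l) l$interval[2], 0),
                  n = vapply(lv, function(l) l$n, 0L))
  cbind(d, as.data.frame(cf))[order(vapply(lv, function(l) l$interval[1], 0)), ]
}

#' @rdname mob_leaves
#' @export
mob_splits <- function(tree) {
  collect <- function(node) {
    if (is.null(node$split)) return(numeric(0))
    c(node$split, collect(node$left), collect(node$right))
  }
  sort(collect(tree$root))
}

#' Step parameter functions from a partition tree
#'
#' @param tree A [grow_mob()] tree.
#' @return Named list of piecewise-constant [param_fn]s, one per node-model
#'   parameter, over the tree's leaf intervals.
#' @export
mob_param_functions <- function(tree) {
  lv <- mob_leaves(tree)
  bnd <- c(lv$lower, AGE_MAX)
  pars <- setdiff(names(lv), c("lower", "upper", "n"))
  out <- lapply(pars, function(p) pf_step(bnd, lv[[p]]))
  names(out) <- pars
  out
}

#' Linear or Emax spec implied by a partition tree
#'
#' @param tree A [grow_mob()] tree (or PALM fit).
#' @return An [er_spec] whose age-varying parameters are the tree's step
#'   functions.
#' @export
as_tree_spec <- function(tree) {
  if (inherits(tree, "palm_fit")) {
    pf <- mob_param_functions(tree$tree)
    return(linear_er_spec(pf$intercept, pf$slope,
                          global_effects = tree$global_effects))
  }
  pf <- mob_param_functions(tree)
  if (tree$family == "linear") {
    linear_er_spec(pf$intercept, pf$slope)
  } else {
    emax_er_spec(0, pf$emax, pf$ec50, hill = 1)
  }
}

#' @export
print.mob_tree <- function(x, ...) {
  cat(sprintf("Model-based partition tree (%s node model)\n", x$family))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split)) {
      cat(sprintf("%s* leaf (%.4g, %.4g], n = %d: %s\n", pad,
                  node$interval[1], node$interval[2], node$n,
                  paste(names(node$coef), signif(node$coef, 4),
                        sep = " = ", collapse = ", ")))
    } else {
      cat(sprintf("%s+ split at age %.4g (supLM p = %.3g)\n", pad,
                  node$split, node$p_value))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  invisible(x)
}

# --- PALM: global effects held constant across subgroups ---------------------

#' Partition tree with global covariate effects (PALM)
#'
#' Fits a linear-model partition tree in which the baseline-covariate
#' effects are constant across age subgroups, by EM-type alternation:
#' (i) given current global-effect estimates, grow a tree on the
#' covariate-adjusted responses; (ii) given the tree's leaf structure,
#' re-estimate the global effects jointly with the leaf-specific
#' intercepts and slopes by OLS.  Iterate until the global-effect
#' estimates stabilise.
#'
#' @inheritParams grow_mob
#' @param tol Convergence tolerance on successive global-effect estimates.
#' @param max_iter Maximum EM iterations; non-convergence is reported via
#'   a warning and the last iterate returned.
#' @return An object of class `palm_fit` with elements `tree`,
#'   `global_effects`, `iterations` and `converged`.
#' @export
fit_palm <- function(data, alpha = 0.05, min_node_size = 10L,
                     max_depth = Inf, trim = 0.1, tol = 1e-6,
                     max_iter = 50L) {
  data <- validate_er_dataset(data)
  X <- covariate_matrix(data)
  if (is.null(X)) {
    tree <- grow_mob(data, "linear", alpha, min_node_size, max_depth, trim)
    return(structure(list(tree = tree, global_effects = numeric(0),
                          iterations = 0L, converged = TRUE),
                     class = "palm_fit"))
  }
  gamma <- stats::lm.fit(cbind(1, data$exposure, X), data$response)$coefficients[-(1:2)]
  adj <- data
  tree <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    adj$response <- data$response - drop(X %*% gamma)
    adj_no_x <- adj[c("age", "exposure", "response")]
    tree <- grow_mob(adj_no_x, "linear", alpha, min_node_size, max_depth, trim)
    gamma_new <- palm_global_ols(data, X, tree)
    if (max(abs(gamma_new - gamma)) < tol) {
      gamma <- gamma_new
      converged <- TRUE
      break
    }
    gamma <- gamma_new
  }
  if (!converged)
    warning("PALM EM did not converge in ", max_iter, " iterations")
  # refit leaf models on adjusted responses for the final gamma
  adj$response <- data$response - drop(X %*% gamma)
  tree <- grow_mob(adj[c("age", "exposure", "response")], "linear",
                   alpha, min_node_size, max_depth, trim)
  structure(list(tree = tree, global_effects = unname(gamma),
                 iterations = it, converged = converged),
            class = "palm_fit")
}

# joint OLS of leaf-wise intercept/slope dummies plus global covariates
palm_global_ols <- function(data, X, tree) {
  lv <- mob_leaves(tree)
  bnd <- c(lv$lower, AGE_MAX)
  g <- findInterval(data$age, bnd, left.open = TRUE)
  g[g < 1L] <- 1L
  G <- stats::model.matrix(~ 0 + factor(g, levels = seq_len(nrow(lv))))
  D <- cbind(G, G * data$exposure, X)
  cf <- stats::lm.fit(D, data$response)$coefficients
  unname(cf[(2L * nrow(lv) + 1L):length(cf)])
}

#' @export
print.palm_fit <- function(x, ...) {
  cat("PALM fit: global effects",
      if (length(x$global_effects)) paste(signif(x$global_effects, 4),
                                          collapse = ", ") else "(none)",
      sprintf("[%d EM iteration(s)]\n", x$iterations))
  print(x$tree)
  invisible(x)
}
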