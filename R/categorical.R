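#' Linear exposure-response model with categorical age groups
#'
#' The benchmark model: a single ordinary least-squares fit with a main
#' effect and an exposure interaction for each pre-specified age group,
#' \deqn{Y_i = \gamma_0 + \sum_p \gamma_p x_{pi} + \gamma_C C_i +
#'   \sum_{h=2}^{H} I_{A_h}(A_i)\{\gamma_{A,h} + \gamma_{I,h} C_i\} +
#'   \epsilon_i}
#' so each group h has implied intercept \eqn{\gamma_0 + \gamma_{A,h}} and
#' slope \eqn{\gamma_C + \gamma_{I,h}} (reference group h = 1).  Group
#' membership uses left-open/right-closed intervals \eqn{(a_{h-1}, a_h]},
#' with age 0 assigned to the first group.
#'
#' @param data An [er_dataset()].
#' @param boundaries Strictly increasing age boundaries spanning the data;
#'   the default follows the ICH E11 groups (excluding pre-term newborns).
#' @return An object of class `categorical_fit` with per-group intercepts
#'   and slopes, global covariate effects, and the residual variance
#'   estimate.
#' @examples
#' scn <- linear_scenario(1, seed = 1)
#' fit <- fit_categorical(generate_dataset(scn))
#' fit$group_intercepts
#' @export
fit_categorical <- function(data, boundaries = c(0, 28 / 365, 2, 12, 18)) {
  data <- validate_er_dataset(data)
  boundaries <- as.numeric(boundaries)
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  h <- findInterval(data$age, boundaries, left.open = TRUE)
  h[h < 1L] <- 1L
  H <- length(boundaries) - 1L
  if (any(h > H)) stop("ages fall outside the stated groups")
  counts <- tabulate(h, nbins = H)
  if (any(counts == 0L))
    stop("empty age group(s): ", paste(which(counts == 0L), collapse = ", "))
  if (any(counts < 2L))
    stop("each group needs at least 2 subjects to identify its parameters")
  xmat <- covariate_matrix(data)
  grp <- factor(h, levels = seq_len(H))
  df <- data.frame(y = data$response, C = data$exposure, grp = grp)
  if (!is.null(xmat)) df <- cbind(df, as.data.frame(xmat))
  fml <- if (H > 1L) {
    stats::as.formula(paste(c("y ~ C + grp + grp:C",
                              colnames(xmat)), collapse = " + "))
  } else {
    stats::as.formula(paste(c("y ~ C", colnames(xmat)), collapse = " + "))
  }
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  core <- setdiff(names(cf), colnames(xmat))
  if (anyNA(cf[core]))
    stop("rank-deficient design: a group lacks exposure variation")
  if (anyNA(cf)) {
    # degenerate covariate column(s), e.g. identically zero: no effect
    warning("covariate(s) ", paste(names(cf)[is.na(cf)], collapse = ", "),
            " are not identifiable; effect set to 0")
    cf[is.na(cf)] <- 0
  }
  g0 <- cf[["(Intercept)"]]
  gC <- cf[["C"]]
  gA <- if (H > 1L) cf[paste0("grp", 2:H)] else numeric(0)
  gI <- if (H > 1L) cf[paste0("C:grp", 2:H)] else numeric(0)
  gX <- if (!is.null(xmat)) cf[colnames(xmat)] else numeric(0)
  structure(list(
    boundaries = boundaries,
    reference_intercept = g0,
    reference_slope = gC,
    group_main_effects = unname(gA),
    group_interactions = unname(gI),
    group_intercepts = unname(c(g0, g0 + gA)),
    group_slopes = unname(c(gC, gC + gI)),
    global_effects = unname(gX),
    sigma2 = sum(stats::residuals(fit)^2) / stats::df.residual(fit),
    lm = fit),
    class = "categorical_fit")
}

#' Step parameter functions implied by a categorical fit
#'
#' @param fit A [fit_categorical()] object.
#' @return A list with `intercept` and `slope`, each a piecewise-constant
#'   [param_fn] over the fit's groups.
#' @export
categorical_param_functions <- function(fit) {
  stopifnot(inherits(fit, "categorical_fit"))
  list(intercept = pf_step(fit$boundaries, fit$group_intercepts),
       slope = pf_step(fit$boundaries, fit$group_slopes))
}

#' Linear spec built from a categorical fit
#'
#' @param fit A [fit_categorical()] object.
#' @return A [linear_er_spec()] whose parameter functions are the fit's
#'   step functions.
#' @export
as_linear_spec <- function(fit) {
  pf <- categorical_param_functions(fit)
  linear_er_spec(pf$intercept, pf$slope,
                 global_effects = fit$global_effects,
                 noise_variance = fit$sigma2)
}

#' @export
print.categorical_fit <- function(x, ...) {
  H <- length(x$group_intercepts)
  cat(sprintf("Categorical-age linear E-R fit (%d groups)\n", H))
  for (g in seq_len(H)) {
    cat(sprintf("  (%.4g, %.4g]: intercept %.4g, slope %.4g\n",
                x$boundaries[g], x$boundaries[g + 1L],
                x$group_intercepts[g], x$group_slopes[g]))
  }
  if (length(x$global_effects))
    cat("  global effects:", paste(signif(x$global_effects, 4),
                                   collapse = ", "), "\n")
  cat(sprintf("  residual variance %.4g\n", x$sigma2))
  invisible(x)
}
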