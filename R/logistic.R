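#' Univariate logistic screen
#'
#' Fits one single-covariate logistic regression per candidate variable
#' (outcome: positive class = first factor level) by maximum likelihood and
#' advances the variables whose Wald p-value falls below `alpha`. Fits
#' showing signs of complete or quasi-complete separation are flagged as
#' non-converged and excluded from advancement with a warning.
#'
#' @param table cohort data.frame with a two-level factor `outcome` column.
#' @param variables candidate covariate names; default all non-outcome
#'   columns.
#' @param outcome outcome column name.
#' @param alpha advancement threshold on the Wald p-value (default 0.05).
#' @return list of class `univariate_screen`: `fits` (data.frame with
#'   `variable`, `estimate`, `ci_lo`, `ci_hi`, `p_value`, `converged`) and
#'   `advancing` (character vector).
#' @export
univariate_screen <- function(table, variables = NULL, outcome = "outcome",
                              alpha = 0.05) {
  grp <- check_outcome(table, outcome)
  y <- as.integer(grp == levels(grp)[1])
  if (is.null(variables)) variables <- setdiff(names(table), outcome)
  rows <- lapply(variables, function(v) {
    fit <- fit_logistic(y, table[v])
    data.frame(variable = v, estimate = fit$estimate[1],
               ci_lo = fit$ci_lo[1], ci_hi = fit$ci_hi[1],
               p_value = fit$p_value[1], converged = fit$converged)
  })
  fits <- do.call(rbind, rows)
  bad <- !fits$converged
  if (any(bad))
    warning("excluded from advancement (separation/non-convergence): ",
            paste(fits$variable[bad], collapse = ", "))
  advancing <- fits$variable[fits$converged & !is.na(fits$p_value) &
                               fits$p_value < alpha]
  structure(list(fits = fits, advancing = advancing, alpha = alpha),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat("Univariate logistic screen (alpha =", x$alpha, ")\n")
  print(x$fits, row.names = FALSE)
  cat("advancing:", if (length(x$advancing)) paste(x$advancing, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# shared logistic fitting with Wald CIs and separation detection;
# covariates arrive as a data.frame (factors allowed, dummy-coded)
fit_logistic <- function(y, covars) {
  df <- as.data.frame(lapply(covars, function(x)
    if (is.factor(x) || is.character(x)) as.factor(x) else x))
  names(df) <- names(covars)
  df$.y <- y
  fit <- suppressWarnings(stats::glm(
    .y ~ ., family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  keep <- rownames(co) != "(Intercept)"
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  p <- co[keep, "Pr(>|z|)"]
  # separation heuristics: fitted probabilities at the boundary together
  # with exploding coefficients or standard errors
  probs <- stats::fitted(fit)
  sep <- any(probs > 1 - 1e-8) && any(probs < 1e-8) ||
    any(abs(est) > 1e3) || any(se > 1e3)
  z <- stats::qnorm(0.975)
  list(estimate = unname(est), se = unname(se),
       ci_lo = unname(est - z * se), ci_hi = unname(est + z * se),
       p_value = unname(p), converged = fit$converged && !sep,
       term = rownames(co)[keep], fit = fit)
}

#' Variance-inflation-factor collinearity filter
#'
#' Computes the VIF of each candidate variable -- `1 / (1 - R^2)` from an
#' ordinary least-squares regression of that variable on all the others --
#' and iteratively removes the variable with the highest VIF until all
#' remaining VIFs are `<= limit`. An exact linear dependence yields an
#' infinite VIF and is removed first. Factors are dummy-coded before
#' regression.
#'
#' @param table cohort data.frame.
#' @param variables variable names to screen (`>= 1`; with a single variable
#'   no collinearity is possible and it is retained with VIF 1).
#' @param limit VIF removal threshold (default 10).
#' @return list with `retained`, `removed` (in removal order) and `vif`
#'   (named vector for the retained set).
#' @export
vif_filter <- function(table, variables, limit = 10) {
  stopifnot(length(variables) >= 1L, all(variables %in% names(table)))
  X <- covariate_matrix(table, variables)
  active <- variables
  removed <- character(0)
  repeat {
    if (length(active) < 2L) break
    vifs <- vapply(active, function(v) vif_one(X, v, active), numeric(1))
    if (all(vifs <= limit)) break
    worst <- active[which.max(vifs)]
    removed <- c(removed, worst)
    active <- setdiff(active, worst)
  }
  vif <- if (length(active) >= 2L)
    vapply(active, function(v) vif_one(X, v, active), numeric(1))
  else stats::setNames(rep(1, length(active)), active)
  list(retained = active, removed = removed, vif = vif)
}

# numeric design columns for a set of variables (factors -> 0/1 dummies)
covariate_matrix <- function(table, variables) {
  cols <- lapply(variables, function(v) {
    x <- table[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- as.factor(x)
      as.numeric(x == levels(x)[nlevels(x)])
    } else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- variables
  X
}

vif_one <- function(X, v, active) {
  yv <- X[, v]
  others <- X[, setdiff(active, v), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, others), yv)
  res <- fit$residuals
  tss <- sum((yv - mean(yv))^2)
  if (tss == 0) return(Inf)
  r2 <- 1 - sum(res^2) / tss
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Multivariate logistic model
#'
#' Joint maximum-likelihood logistic fit of the outcome on the given
#' variables, with Wald 95% confidence intervals and p-values, plus the VIF
#' of each covariate within the model. Non-convergence or separation is
#' reported in the `converged` flag, never silently.
#'
#' @inheritParams univariate_screen
#' @param variables covariate names (normally the screened, VIF-filtered set).
#' @return list of class `logistic_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `ci_lo`, `ci_hi`, `p_value`, `vif`), `converged`,
#'   and the underlying `glm` object.
#' @export
multivariate_logistic <- function(table, variables, outcome = "outcome") {
  grp <- check_outcome(table, outcome)
  stopifnot(length(variables) >= 1L, all(variables %in% names(table)))
  y <- as.integer(grp == levels(grp)[1])
  fit <- fit_logistic(y, table[variables])
  vifs <- vif_filter(table, variables, limit = Inf)$vif
  # map dummy-coded terms back to source variables for the VIF column
  vif_col <- vapply(fit$term, function(tm) {
    hit <- variables[vapply(variables, function(v) startsWith(tm, v),
                            logical(1))]
    if (length(hit)) unname(vifs[hit[which.max(nchar(hit))]]) else NA_real_
  }, numeric(1))
  structure(list(
    coefficients = data.frame(term = fit$term, estimate = fit$estimate,
                              ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
                              p_value = fit$p_value, vif = vif_col),
    converged = fit$converged, glm = fit$fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Multivariate logistic fit",
      if (!x$converged) "(NOT CONVERGED)", "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
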