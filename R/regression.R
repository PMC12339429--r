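#' Logistic regression of a report-level binary event on covariates
#'
#' Fits a binomial GLM by iteratively reweighted least squares and reports
#' one row per coefficient level as odds ratio, Wald 95% confidence
#' interval (`exp(coef +/- 1.96 SE)`) and two-sided Wald p-value.  Factor
#' reference levels are included with OR 1 by convention.  Rows with a
#' missing covariate or response, or a factor level named `"unknown"`, are
#' excluded listwise.  Coefficients diverging beyond 15 on the log-odds
#' scale are flagged as (quasi-)separated and reported with infinite
#' interval markers rather than crashing.
#'
#' @param formula Model formula, e.g. `event ~ age_band + sex`.
#' @param data Data frame of report-level covariates and outcome.
#' @param model Label stored on the result rows (`"univariable"` or
#'   `"multivariable"`).
#' @return A data frame of class `logistic_or` with columns `term`,
#'   `level`, `reference`, `or`, `ci_low`, `ci_high`, `p`, `model`,
#'   `separated`.
#' @export
fit_logistic <- function(formula, data, model = "multivariable") {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2)
    stop_stage("fit_logistic", "response has fewer than 2 distinct values")
  # treat 'unknown' factor levels as missing (listwise deletion)
  vars <- attr(stats::terms(mf), "term.labels")
  dat <- as.data.frame(mf)
  for (v in vars) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]]) && "unknown" %in% levels(dat[[v]])) {
      dat[[v]][dat[[v]] == "unknown"] <- NA
      dat[[v]] <- droplevels(dat[[v]])
    }
  }
  dat <- stats::na.omit(dat)
  for (v in vars)
    if (is.factor(dat[[v]]) && nlevels(dat[[v]]) < 2)
      stop_stage("fit_logistic",
                 sprintf("covariate '%s' has no variation after filtering", v))

  fit <- suppressWarnings(
    stats::glm(formula, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  if (!fit$converged)
    stop_stage("fit_logistic", "IRLS did not converge within 50 iterations")
  sm <- summary(fit)$coefficients

  rows <- list()
  for (v in vars) {
    if (is.factor(dat[[v]])) {
      ref <- levels(dat[[v]])[1]
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = ref, reference = TRUE, or = 1, ci_low = NA_real_,
        ci_high = NA_real_, p = NA_real_, model = model, separated = FALSE,
        stringsAsFactors = FALSE)
      for (lev in levels(dat[[v]])[-1]) {
        cn <- paste0(v, lev)
        est <- sm[cn, "Estimate"]; se <- sm[cn, "Std. Error"]
        sep <- abs(est) > 15
        rows[[length(rows) + 1L]] <- data.frame(
          term = v, level = lev, reference = FALSE,
          or = if (sep) ifelse(est > 0, Inf, 0) else exp(est),
          ci_low = if (sep) NA_real_ else exp(est - Z95 * se),
          ci_high = if (sep) NA_real_ else exp(est + Z95 * se),
          p = if (sep) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
          model = model, separated = sep, stringsAsFactors = FALSE)
      }
    } else {
      est <- sm[v, "Estimate"]; se <- sm[v, "Std. Error"]
      sep <- abs(est) > 15
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = "", reference = FALSE,
        or = if (sep) ifelse(est > 0, Inf, 0) else exp(est),
        ci_low = if (sep) NA_real_ else exp(est - Z95 * se),
        ci_high = if (sep) NA_real_ else exp(est + Z95 * se),
        p = if (sep) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
        model = model, separated = sep, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_used") <- nrow(dat)
  class(out) <- c("logistic_or", class(out))
  out
}

#' @export
print.logistic_or <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$or <- round(df$or, digits)
  df$ci <- ifelse(df$reference, "-",
                  sprintf("%.2f-%.2f", df$ci_low, df$ci_high))
  df$p <- ifelse(is.na(df$p), "-", formatC(df$p, format = "g", digits = 3))
  print(df[, c("term", "level", "or", "ci", "p", "model")], row.names = FALSE)
  invisible(x)
}

#' Univariable screen of report-level covariates
#'
#' Fits each covariate alone against the outcome and flags for
#' multivariable carry-forward any covariate with a non-reference level
#' significant at `alpha` (two-sided Wald test), mirroring the common
#' screen-then-adjust modelling flow for spontaneous-report risk factors.
#'
#' @param outcome Name of the binary outcome column in `data`.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param data Data frame.
#' @param alpha Screening significance level.
#' @return A list: `results` (stacked `logistic_or` rows, one fit per
#'   covariate) and `carried_forward` (character vector of covariate names
#'   passing the screen).
#' @export
univariable_screen <- function(outcome, covariates, data, alpha = 0.05) {
  if (!length(covariates))
    return(list(results = NULL, carried_forward = character(0)))
  res <- list(); carried <- character(0)
  for (v in covariates) {
    f <- stats::as.formula(paste(outcome, "~", v))
    r <- fit_logistic(f, data, model = "univariable")
    res[[v]] <- r
    p <- r$p[!r$reference & !r$separated]
    if (any(p < alpha, na.rm = TRUE)) carried <- c(carried, v)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("logistic_or", "data.frame")
  list(results = out, carried_forward = carried)
}

#' Univariable screen plus multivariable model, side by side
#'
#' Runs [univariable_screen()] and, if any covariate passes, fits the
#' multivariable model on the carried-forward covariates, returning one
#' stacked results table in the familiar OR / 95% CI / P layout.
#'
#' @inheritParams univariable_screen
#' @return A list: `univariable` (`logistic_or`), `multivariable`
#'   (`logistic_or` or `NULL`), `carried_forward`.
#' @export
logistic_table <- function(outcome, covariates, data, alpha = 0.05) {
  scr <- univariable_screen(outcome, covariates, data, alpha = alpha)
  multi <- NULL
  if (length(scr$carried_forward)) {
    f <- stats::as.formula(paste(outcome, "~",
                                 paste(scr$carried_forward, collapse = " + ")))
    multi <- fit_logistic(f, data, model = "multivariable")
  }
  list(univariable = scr$results, multivariable = multi,
       carried_forward = scr$carried_forward)
}
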