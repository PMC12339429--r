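ratio_estimates <- function(h) h$beta_out / h$beta_exp
ratio_se_first_order <- function(h) h$se_out / abs(h$beta_exp)

new_mr_estimate <- function(method, beta, se, p, k, extras = list()) {
  ci <- beta_to_or(beta, se)
  structure(list(method = method, beta = beta, se = se, p = p,
                 or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 k_snps = k, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (k = %d): beta %.4f (SE %.4f), OR %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$method, x$k_snps, x$beta, x$se, x$or, x$ci_low, x$ci_high,
              x$p))
  if (!is.null(x$extras$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n", x$extras$intercept,
                x$extras$intercept_se, x$extras$intercept_p))
  invisible(x)
}

#' Convert a log-odds effect to an odds ratio with 95% interval
#'
#' @param beta Log-odds-scale estimate.
#' @param se Its standard error (`> 0`).
#' @return A list: `or = exp(beta)`, `ci_low = exp(beta - 1.96 se)`,
#'   `ci_high = exp(beta + 1.96 se)`.
#' @export
beta_to_or <- function(beta, se) {
  stopifnot(all(se > 0))
  list(or = exp(beta), ci_low = exp(beta - Z95 * se),
       ci_high = exp(beta + Z95 * se))
}

#' Inverse-variance weighted estimator
#'
#' The primary two-sample MR estimator: a weighted regression of outcome on
#' exposure effects through the origin with first-order weights
#' `1/se_out^2`, equivalent to the inverse-variance meta-analysis of
#' per-SNP Wald ratios.  By default the standard error uses a
#' multiplicative random-effects model, inflating the fixed-effect SE by
#' `max(1, sqrt(Q / (k - 1)))` so heterogeneity can widen but never narrow
#' the interval.  p-values are two-sided normal.
#'
#' @param h An `mr_harmonized` set with `k >= 2` SNPs (`k = 1` permitted
#'   only with `allow_single = TRUE`, giving the single Wald ratio).
#' @param random_effects Use the multiplicative random-effects SE.
#' @param allow_single Permit the degenerate single-SNP Wald ratio.
#' @return An `mr_estimate` (`extras$Q` carries Cochran's Q).
#' @export
mr_ivw <- function(h, random_effects = TRUE, allow_single = FALSE) {
  stopifnot(inherits(h, "mr_harmonized"))
  k <- nrow(h)
  if (k < 2 && !allow_single)
    stop_stage("mr_ivw", "needs at least 2 instruments")
  w <- 1 / h$se_out^2
  beta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exp^2))
  Q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
  infl <- if (random_effects && k >= 2) max(1, sqrt(Q / (k - 1))) else 1
  se <- se_fixed * infl
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("Inverse variance weighted", beta, se, p, k,
                  extras = list(Q = Q, se_fixed = se_fixed,
                                random_effects = random_effects))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights `1/se_out^2`).  The slope estimates the causal
#' effect under the InSIDE assumption; a nonzero intercept indicates
#' directional horizontal pleiotropy.  Standard errors are inflated by
#' `max(1, sqrt(Q_egger / (k - 2)))` and inference uses the t reference
#' with `k - 2` degrees of freedom.
#'
#' @param h An `mr_harmonized` set with `k >= 3` SNPs and variation in the
#'   exposure effects.
#' @return An `mr_estimate`; `extras` holds `intercept`, `intercept_se`,
#'   `intercept_p` and `Q`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "mr_harmonized"))
  k <- nrow(h)
  if (k < 3) stop_stage("mr_egger", "needs at least 3 instruments")
  w <- 1 / h$se_out^2
  # orient every instrument to its exposure-increasing allele: the slope is
  # invariant, but the intercept is only interpretable as directional
  # pleiotropy under a common orientation
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- s * h$beta_exp; y <- s * h$beta_out
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx < 1e-12 * sw * max(mean(abs(x)), 1)^2)
    stop_stage("mr_egger",
               "exposure effects are (numerically) constant; slope not identifiable")
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  Q <- sum(w * (y - intercept - slope * x)^2)
  sigma2 <- Q / (k - 2)
  # causal slope: multiplicative random-effects inflation, truncated below
  # at 1 so heterogeneity can only widen the interval
  se_slope <- sqrt(max(1, sigma2) / sxx)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  # pleiotropy test: exact weighted-least-squares t-test on the intercept
  # (untruncated residual variance), so the test holds its nominal size
  se_int <- sqrt(sigma2 * (1 / sw + mx^2 / sxx))
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = k - 2)
  new_mr_estimate("MR Egger", slope, se_slope, p_slope, k,
                  extras = list(intercept = intercept, intercept_se = se_int,
                                intercept_p = p_int, Q = Q))
}

weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(b[1])
  below <- max(which(cw < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

boot_resample <- function(h, n_boot, seed, stat_fun) {
  with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      stat_fun(by / bx, by, bx)
    }, numeric(1))
  })
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and interpolates the weighted empirical
#' distribution (weights `se_ratio^{-2}`, first order) at cumulative
#' weight one half; consistent when at least half the weight comes from
#' valid instruments.  The standard error is a seeded parametric bootstrap
#' resampling each SNP's effects from their normal sampling distributions.
#'
#' @param h An `mr_harmonized` set with `k >= 3`.
#' @param n_boot Number of bootstrap draws (`>= 100`).
#' @param seed Seed for the bootstrap, or `NULL`.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(h, "mr_harmonized"), n_boot >= 100)
  k <- nrow(h)
  if (k < 3) stop_stage("mr_weighted_median", "needs at least 3 instruments")
  r <- ratio_estimates(h)
  w <- ratio_se_first_order(h)^-2
  beta <- weighted_median_point(r, w)
  boots <- boot_resample(h, n_boot, seed, function(rat, by, bx) {
    weighted_median_point(rat, (abs(bx) / h$se_out)^2)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("Weighted median", beta, se, p, k)
}

mode_point <- function(r, w, bandwidth_factor) {
  # modified Silverman rule; the MAD guards against outliers but collapses
  # to zero under majority ties, where the SD takes over
  scale_ <- min(stats::sd(r), if (stats::mad(r) > 0) stats::mad(r) else Inf)
  s <- 0.9 * scale_ * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(stats::median(r))
  bw <- bandwidth_factor * s
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g - r, sd = bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator (simple or weighted)
#'
#' Estimates the causal effect as the argmax of a normal-kernel-smoothed
#' density of the per-SNP Wald ratios, evaluated on a 512-point grid
#' spanning the ratios plus/minus three bandwidths.  The bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 min(sd, mad) k^{-1/5}` on the ratios.  The weighted variant
#' weights each ratio by `se_ratio^{-2}`; the simple variant weights
#' equally.  Consistent when the largest group of instruments sharing a
#' causal estimate is valid (plurality validity).  SE by seeded parametric
#' bootstrap.
#'
#' @param h An `mr_harmonized` set with `k >= 3`.
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth.
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the bootstrap, or `NULL`.
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(h, variant = c("simple", "weighted"),
                    bandwidth_factor = 1, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(h, "mr_harmonized"))
  variant <- match.arg(variant)
  k <- nrow(h)
  if (k < 3) stop_stage("mr_mode", "needs at least 3 instruments")
  r <- ratio_estimates(h)
  w <- if (variant == "weighted") ratio_se_first_order(h)^-2 else
    rep(1 / k, k)
  w <- w / sum(w)
  beta <- mode_point(r, w, bandwidth_factor)
  boots <- boot_resample(h, n_boot, seed, function(rat, by, bx) {
    wb <- if (variant == "weighted") (abs(bx) / h$se_out)^2 else rep(1, k)
    mode_point(rat, wb / sum(wb), bandwidth_factor)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (variant == "simple") "Simple mode" else "Weighted mode",
                  beta, se, p, k)
}

#' Fit the full two-sample MR estimator suite
#'
#' Runs the inverse-variance weighted estimator plus the four secondary
#' estimators (MR-Egger, weighted median, simple and weighted mode) on a
#' harmonized instrument set, each reported as log-odds effect, odds ratio
#' with 95% interval and p-value.  Estimators whose instrument-count
#' precondition fails are skipped with a recorded reason.
#'
#' @param h An `mr_harmonized` set.
#' @param n_boot Bootstrap draws for median/mode standard errors.
#' @param seed Single seed driving every stochastic component.
#' @param random_effects Multiplicative random-effects IVW standard error.
#' @param bandwidth_factor Mode-estimator bandwidth multiplier.
#' @return An object of class `mr_fit`: list with `estimates` (data
#'   frame), `fits` (the `mr_estimate` objects), `skipped` (named reasons),
#'   and the harmonized `data`.
#' @examples
#' sim <- simulate_gwas_pair(gwas_sim_config(seed = 11))
#' h <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, n_boot = 200, seed = 1)
#' print(fit)
#' @export
mr_fit <- function(h, n_boot = 1000, seed = NULL, random_effects = TRUE,
                   bandwidth_factor = 1) {
  stopifnot(inherits(h, "mr_harmonized"))
  specs <- list(
    ivw = function() mr_ivw(h, random_effects = random_effects),
    egger = function() mr_egger(h),
    weighted_median = function() mr_weighted_median(h, n_boot, seed),
    simple_mode = function() mr_mode(h, "simple", bandwidth_factor, n_boot,
                                     if (is.null(seed)) NULL else seed + 1L),
    weighted_mode = function() mr_mode(h, "weighted", bandwidth_factor,
                                       n_boot,
                                       if (is.null(seed)) NULL else seed + 2L)
  )
  fits <- list(); skipped <- character(0)
  for (nm in names(specs)) {
    res <- tryCatch(specs[[nm]](), error = function(e) conditionMessage(e))
    if (inherits(res, "mr_estimate")) fits[[nm]] <- res
    else skipped[nm] <- res
  }
  est <- do.call(rbind, lapply(fits, function(f)
    data.frame(method = f$method, k_snps = f$k_snps, beta = f$beta,
               se = f$se, or = f$or, ci_low = f$ci_low, ci_high = f$ci_high,
               p = f$p, stringsAsFactors = FALSE)))
  rownames(est) <- NULL
  structure(list(estimates = est, fits = fits, skipped = skipped, data = h),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample Mendelian randomization\n")
  df <- x$estimates
  df$`OR (95% CI)` <- sprintf("%.3f (%.3f, %.3f)", df$or, df$ci_low,
                              df$ci_high)
  df$p <- signif(df$p, 3)
  print(df[, c("method", "k_snps", "OR (95% CI)", "p")], row.names = FALSE)
  if (length(x$skipped))
    for (nm in names(x$skipped))
      cat(sprintf("  [skipped %s: %s]\n", nm, x$skipped[nm]))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, names(object$fits))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(names(object$fits),
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  h <- object$data
  het <- list(ivw = tryCatch(cochran_q(h, "ivw"), error = function(e) NULL),
              egger = tryCatch(cochran_q(h, "egger"), error = function(e) NULL))
  structure(list(fit = object, heterogeneity = het,
                 pleiotropy = object$fits$egger$extras),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nHeterogeneity:\n")
  for (m in names(x$heterogeneity)) {
    q <- x$heterogeneity[[m]]
    if (!is.null(q))
      cat(sprintf("  %s: Q = %.3f, df = %d, p = %.3f\n", m, q$Q, q$df, q$p))
  }
  if (!is.null(x$pleiotropy$intercept))
    cat(sprintf("Egger intercept: %.4f (SE %.4f), p = %.3f\n",
                x$pleiotropy$intercept, x$pleiotropy$intercept_se,
                x$pleiotropy$intercept_p))
  invisible(x)
}

#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  graphics::plot(h$beta_exp, h$beta_out,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(h$beta_exp, h$beta_out - Z95 * h$se_out,
                     h$beta_exp, h$beta_out + Z95 * h$se_out, col = "grey60")
  graphics::segments(h$beta_exp - Z95 * h$se_exp, h$beta_out,
                     h$beta_exp + Z95 * h$se_exp, h$beta_out, col = "grey60")
  cols <- seq_along(x$fits) + 1
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    intercept <- f$extras$intercept %||% 0
    graphics::abline(intercept, f$beta, col = cols[i], lwd = 1.5)
  }
  graphics::legend("topleft",
                   legend = vapply(x$fits, `[[`, character(1), "method"),
                   col = cols, lwd = 1.5, bty = "n", cex = 0.8)
  invisible(x)
}
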