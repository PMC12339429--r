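#' Cochran's Q heterogeneity test
#'
#' Weighted residual sum of squares
#' `Q = sum(se_out^{-2} (beta_out - fitted)^2)` around the fixed-effect IVW
#' slope (`df = k - 1`) or the Egger regression line (`df = k - 2`), with
#' the upper-tail chi-square p-value.  Under instrument homogeneity Q is
#' approximately chi-square distributed on its degrees of freedom.
#'
#' @param h An `mr_harmonized` set (`k >= 2` for IVW, `k >= 3` for Egger).
#' @param model `"ivw"` or `"egger"`.
#' @return An object of class `mr_heterogeneity`: `model`, `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  stopifnot(inherits(h, "mr_harmonized"))
  model <- match.arg(model)
  k <- nrow(h)
  w <- 1 / h$se_out^2
  if (model == "ivw") {
    if (k < 2) stop_stage("cochran_q", "ivw Q needs at least 2 instruments")
    fit <- mr_ivw(h, random_effects = FALSE)
    resid <- h$beta_out - fit$beta * h$beta_exp
    df <- k - 1L
  } else {
    if (k < 3) stop_stage("cochran_q", "egger Q needs at least 3 instruments")
    fit <- mr_egger(h)
    resid <- h$beta_out - fit$extras$intercept - fit$beta * h$beta_exp
    df <- k - 2L
  }
  Q <- sum(w * resid^2)
  structure(list(model = model, Q = Q, df = df, p = chisq_upper_p(Q, df)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %.3f, df = %d, p = %.3f\n",
              x$model, x$Q, x$df, x$p))
  invisible(x)
}

#' MR-PRESSO global and outlier tests
#'
#' Simulation-based residual test for pleiotropic outlier instruments.
#' The observed statistic is the weighted residual sum of squares where
#' each SNP's residual is taken against the IVW estimate fitted with that
#' SNP left out.  `n_sim` seeded parametric datasets are simulated under
#' the fitted no-outlier model (per-SNP effects redrawn from their normal
#' sampling distributions around leave-one-out fitted values); the global
#' p-value is the rank-based tail probability of the observed RSS, and
#' each SNP's outlier p-value is the tail probability of its own weighted
#' squared residual, Bonferroni-adjusted by the number of instruments.
#'
#' @param h An `mr_harmonized` set with `k >= 4`.
#' @param n_sim Number of simulated datasets (`>= 1000`).
#' @param seed Seed, or `NULL`.
#' @param alpha Flagging level for adjusted outlier p-values.
#' @return An object of class `mr_presso`: `global_rss`, `global_p`,
#'   `outliers` (data frame `snp_id`, `p`, `p_adj`, `flag`), `n_sim`,
#'   `alpha`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(h, "mr_harmonized"), n_sim >= 1000)
  k <- nrow(h)
  if (k < 4) stop_stage("mr_presso", "needs at least 4 instruments")
  w <- 1 / h$se_out^2
  bx <- h$beta_exp; by <- h$beta_out

  loo_beta <- function(BX, BY) {
    # leave-one-out IVW slope for each column j, vectorized over rows
    S1 <- as.vector((BX * BY) %*% w)
    S2 <- as.vector((BX * BX) %*% w)
    (S1 - sweep(BX * BY, 2, w, `*`)) / (S2 - sweep(BX * BX, 2, w, `*`))
  }

  BX0 <- matrix(bx, 1); BY0 <- matrix(by, 1)
  b_loo <- as.vector(loo_beta(BX0, BY0))
  obs_res2 <- w * (by - b_loo * bx)^2
  rss_obs <- sum(obs_res2)

  sims <- with_seed(seed, {
    BXs <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                               sd = rep(h$se_exp, each = n_sim)), n_sim, k)
    BYs <- matrix(stats::rnorm(n_sim * k,
                               mean = rep(b_loo * bx, each = n_sim),
                               sd = rep(h$se_out, each = n_sim)), n_sim, k)
    B_loo_s <- loo_beta(BXs, BYs)
    res2 <- sweep((BYs - B_loo_s * BXs)^2, 2, w, `*`)
    list(rss = rowSums(res2), res2 = res2)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_snp <- vapply(seq_len(k), function(j)
    (1 + sum(sims$res2[, j] >= obs_res2[j])) / (n_sim + 1), numeric(1))
  p_adj <- pmin(1, p_snp * k)
  outliers <- data.frame(snp_id = h$snp_id, p = p_snp, p_adj = p_adj,
                         flag = p_adj < alpha, stringsAsFactors = FALSE)
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outliers = outliers, n_sim = n_sim, alpha = alpha),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4f (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  flagged <- x$outliers[x$outliers$flag, , drop = FALSE]
  if (nrow(flagged)) {
    cat("Outlier instruments (Bonferroni-adjusted p <", x$alpha, "):\n")
    print(flagged, row.names = FALSE)
  } else cat("No outlier instruments at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator `k` times, each time excluding one instrument,
#' alongside the all-SNP reference estimate, to reveal single-SNP
#' influence.  A row whose estimate leaves the full-set 95% interval
#' raises the `influential` attribute.
#'
#' @param h An `mr_harmonized` set with `k >= 3`.
#' @param random_effects Passed to [mr_ivw()].
#' @return A data frame of class `mr_loo`: `excluded`, `k_snps`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`; the first row (`excluded =
#'   "(none)"`) is the full-set estimate.  `attr(, "influential")` is TRUE
#'   if any leave-one-out estimate falls outside the full-set CI.
#' @export
mr_leave_one_out <- function(h, random_effects = TRUE) {
  stopifnot(inherits(h, "mr_harmonized"))
  k <- nrow(h)
  if (k < 3) stop_stage("mr_leave_one_out", "needs at least 3 instruments")
  row_of <- function(label, fit)
    data.frame(excluded = label, k_snps = fit$k_snps, beta = fit$beta,
               se = fit$se, or = fit$or, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p = fit$p, stringsAsFactors = FALSE)
  full <- mr_ivw(h, random_effects = random_effects)
  rows <- list(row_of("(none)", full))
  for (j in seq_len(k)) {
    hj <- h[-j, , drop = FALSE]
    class(hj) <- c("mr_harmonized", "data.frame")
    rows[[j + 1L]] <- row_of(h$snp_id[j],
                             mr_ivw(hj, random_effects = random_effects))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  loo_beta <- out$beta[-1]
  attr(out, "influential") <- any(loo_beta < full$beta - Z95 * full$se |
                                  loo_beta > full$beta + Z95 * full$se)
  class(out) <- c("mr_loo", "data.frame")
  out
}
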