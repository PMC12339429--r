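`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so seeded routines (bootstraps,
#' simulations) do not perturb the global random stream.  A `NULL` seed leaves
#' the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Upper-tail chi-square probability
#'
#' Convenience wrapper used for Cochran's Q heterogeneity tests and the PRR
#' chi-square criterion: the probability that a chi-square variate with `df`
#' degrees of freedom exceeds `q`.
#'
#' @param q Observed statistic (nonnegative).
#' @param df Degrees of freedom (positive).
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' chisq_upper_p(11.95, 8)
#' @export
chisq_upper_p <- function(q, df) {
  stopifnot(all(q >= 0), all(df > 0))
  stats::pchisq(q, df = df, lower.tail = FALSE)
}

# z quantile used for all 95% intervals; the conventional 1.96 rather than
# qnorm(0.975) so printed intervals match the field's reporting habits.
Z95 <- 1.96

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

trimws_squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))
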