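#' Construct a 2x2 drug-event contingency table
#'
#' Counts reports in the four cells of the classical disproportionality
#' table: `a` = reports listing both the target drug and the target PT,
#' `b` = drug without the PT, `c` = PT without the drug, `d` = neither.
#' A report contributes to exactly one cell regardless of how many other
#' drugs or PTs it lists (set semantics).
#'
#' @param rs A deduplicated [report_set].
#' @param drug Target drug name (normalized internally).
#' @param pt Target PT code (integer) or PT name (string).
#' @return An object of class `contab`.
#' @export
contingency_table <- function(rs, drug, pt) {
  stopifnot(inherits(rs, "report_set"))
  n <- nrow(rs$reports)
  if (n == 0L) stop_stage("contingency_table", "empty report set")
  di <- drug_report_indices(rs, drug)
  pi <- pt_report_indices(rs, pt)
  a <- length(intersect(di, pi))
  b <- length(di) - a
  c_ <- length(pi) - a
  d <- n - a - b - c_
  contab(a, b, c_, d, drug = drug, pt = pt)
}

#' Build a `contab` from raw cell counts
#' @param a,b,c,d Nonnegative integer cell counts (`a` = drug & event).
#' @param drug,pt Optional labels.
#' @return An object of class `contab` with elements `a`, `b`, `c`, `d`.
#' @export
contab <- function(a, b, c, d, drug = NA_character_, pt = NA_character_) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop_stage("contab", "empty table (N = 0)")
  structure(list(a = a, b = b, c = c, d = d, drug = drug, pt = as.character(pt)),
            class = "contab")
}

#' @export
print.contab <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

new_signal_stat <- function(method, point, ci_low = NA_real_,
                            ci_high = NA_real_, chi2 = NA_real_, flag,
                            corrected = FALSE) {
  structure(list(method = method, point = point, ci_low = ci_low,
                 ci_high = ci_high, chi2 = chi2, flag = flag,
                 corrected = corrected),
            class = "signal_stat")
}

#' @export
print.signal_stat <- function(x, ...) {
  cat(sprintf("%s = %.3f", x$method, x$point))
  if (!is.na(x$ci_low) && !is.na(x$ci_high))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high))
  else if (!is.na(x$ci_low))
    cat(sprintf(" (lower bound %.3f)", x$ci_low))
  if (!is.na(x$chi2)) cat(sprintf(", chi2 = %.2f", x$chi2))
  cat(sprintf(", signal: %s%s\n", x$flag,
              if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Reporting odds ratio
#'
#' Point estimate `ad/bc` with a log-normal 95% interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero the Haldane-Anscombe correction (0.5 added to all four cells) keeps
#' the estimate finite; the result is marked `corrected`.  The signal
#' criterion is `a >= 3` (on the uncorrected count) and lower CI limit > 1.
#'
#' @param t A [contab].
#' @return A `signal_stat` with `method = "ROR"`.
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contab"))
  corrected <- any(c(t$a, t$b, t$c, t$d) == 0)
  k <- if (corrected) 0.5 else 0
  a <- t$a + k; b <- t$b + k; c_ <- t$c + k; d <- t$d + k
  point <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  lo <- exp(log(point) - Z95 * se)
  hi <- exp(log(point) + Z95 * se)
  new_signal_stat("ROR", point, lo, hi,
                  flag = (t$a >= 3) && (lo > 1), corrected = corrected)
}

pearson_chi2 <- function(t, yates = FALSE) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) return(NA_real_)
  num <- abs(a * d - b * c_) - if (yates) n / 2 else 0
  num <- max(num, 0)
  n * num^2 / prod(margins)
}

#' Proportional reporting ratio
#'
#' Point estimate `[a/(a+b)] / [c/(c+d)]` with the Pearson chi-square of the
#' 2x2 table (Yates continuity correction optional, off by default).  Zero
#' drug or comparator margins are a domain error; a zero cell elsewhere
#' triggers the Haldane-Anscombe correction for the point estimate (the
#' chi-square is computed on the uncorrected counts).  The signal criterion
#' is `a >= 3`, `PRR >= 2` and `chi2 >= 4`.
#'
#' @param t A [contab].
#' @param yates Apply the Yates continuity correction to the chi-square.
#' @return A `signal_stat` with `method = "PRR"`.
#' @export
prr <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "contab"))
  if ((t$a + t$b) == 0 || (t$c + t$d) == 0)
    stop_stage("prr", "zero drug or comparator margin")
  corrected <- any(c(t$a, t$b, t$c, t$d) == 0)
  k <- if (corrected) 0.5 else 0
  a <- t$a + k; b <- t$b + k; c_ <- t$c + k; d <- t$d + k
  point <- (a / (a + b)) / (c_ / (c_ + d))
  chi2 <- pearson_chi2(t, yates = yates)
  new_signal_stat("PRR", point, chi2 = chi2,
                  flag = (t$a >= 3) && (point >= 2) && !is.na(chi2) && (chi2 >= 4),
                  corrected = corrected)
}

#' Information component
#'
#' Shrinkage observed-to-expected information component:
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N`, and the
#' standard approximate lower credibility bound
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`.  The shrinkage
#' makes all cells safe; the signal criterion is `IC025 > 0`.
#'
#' @param t A [contab].
#' @return A `signal_stat` with `method = "IC"`; `ci_low` holds IC025 and
#'   `ci_high` is unused.
#' @export
ic <- function(t) {
  stopifnot(inherits(t, "contab"))
  n <- t$a + t$b + t$c + t$d
  expected <- (t$a + t$b) * (t$a + t$c) / n
  point <- log2((t$a + 0.5) / (expected + 0.5))
  ic025 <- point - 3.3 * (t$a + 0.5)^(-0.5) - 2 * (t$a + 0.5)^(-1.5)
  new_signal_stat("IC", point, ci_low = ic025, flag = ic025 > 0)
}

#' Combine method-level flags into a signal verdict
#'
#' An adverse event is declared a positive signal for the drug when at
#' least two of the three disproportionality criteria (ROR, PRR, IC) flag
#' it on the same contingency table.
#'
#' @param drug,pt Labels.
#' @param stats List of the three `signal_stat`s (ROR, PRR, IC).
#' @param table Optionally, the shared [contab].
#' @return An object of class `signal_result`.
#' @export
classify_signal <- function(drug, pt, stats, table = NULL) {
  stopifnot(is.list(stats),
            all(vapply(stats, inherits, logical(1), "signal_stat")))
  flags <- vapply(stats, `[[`, logical(1), "flag")
  n_pos <- sum(flags)
  structure(list(drug = drug, pt = as.character(pt), table = table,
                 stats = stats, n_positive_methods = n_pos,
                 is_signal = n_pos >= 2L),
            class = "signal_result")
}

#' Disproportionality analysis of one drug-event pair
#'
#' Convenience fit: builds the 2x2 table from a deduplicated report set and
#' evaluates all three disproportionality statistics plus the >= 2-of-3
#' signal verdict.
#'
#' @param rs A deduplicated [report_set].
#' @param drug Target drug name.
#' @param pt Target PT code or name.
#' @param yates Yates continuity correction for the PRR chi-square.
#' @return A `signal_result`.
#' @examples
#' rs <- simulate_srs(srs_config(n_reports = 5000, seed = 7))
#' disprop(rs, "somatropin", 10061019)
#' @export
disprop <- function(rs, drug, pt, yates = FALSE) {
  t <- contingency_table(rs, drug, pt)
  classify_signal(drug, pt, list(ror(t), prr(t, yates = yates), ic(t)),
                  table = t)
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Disproportionality signal: %s x %s\n", x$drug, x$pt))
  if (!is.null(x$table))
    cat(sprintf("  cases a = %d (N = %d)\n", x$table$a,
                x$table$a + x$table$b + x$table$c + x$table$d))
  for (s in x$stats) { cat("  "); print(s) }
  cat(sprintf("  positive methods: %d of %d -> %s\n", x$n_positive_methods,
              length(x$stats),
              if (x$is_signal) "SIGNAL" else "no signal"))
  invisible(x)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact two-sided p-value by enumeration of the conditional hypergeometric
#' distribution: the sum of probabilities of all tables (with the observed
#' margins) no more likely than the observed one, using the customary
#' `(1 + 1e-7)` likelihood tolerance for ties.
#'
#' @param a,b,c,d Cell counts as in [contab()].
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # drug reports
  n2 <- c + d         # non-drug reports
  k <- a + c          # event reports
  support <- max(0L, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  d_obs <- dens[support == a]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Volcano-plot statistics for all events of a drug
#'
#' For every PT co-reported with the target drug, computes the 2x2 table,
#' the (Haldane-corrected where needed) log10 reporting odds ratio, the
#' two-sided Fisher exact p, and its Bonferroni adjustment over the `m`
#' distinct PTs tested for this drug, with `-log10` of the adjusted p for
#' plotting.
#'
#' @param rs A deduplicated [report_set].
#' @param drug Target drug name.
#' @return A data frame with one row per PT: `pt_code`, `pt_name`, `n`
#'   (= cell `a`), `log_ror` (log10), `p_fisher`, `p_bonferroni`,
#'   `neg_log10_p`.
#' @export
volcano_stats <- function(rs, drug) {
  stopifnot(inherits(rs, "report_set"))
  n <- nrow(rs$reports)
  if (n == 0L) stop_stage("volcano_stats", "empty report set")
  di <- drug_report_indices(rs, drug)
  n_drug <- length(di)
  in_drug <- rs$pts$report %in% di
  # cell a per PT among the drug's reports; a + c per PT overall
  a_tab <- table(rs$pts$pt_code[in_drug])
  if (!length(a_tab))
    return(data.frame(pt_code = integer(0), pt_name = character(0),
                      n = integer(0), log_ror = numeric(0),
                      p_fisher = numeric(0), p_bonferroni = numeric(0),
                      neg_log10_p = numeric(0)))
  codes <- as.integer(names(a_tab))
  ac_tab <- table(rs$pts$pt_code)
  ac <- as.integer(ac_tab[as.character(codes)])
  a <- as.integer(a_tab)
  b <- n_drug - a
  c_ <- ac - a
  d <- n - n_drug - c_
  m <- length(codes)
  name_of <- rs$pts$pt_name[match(codes, rs$pts$pt_code)]
  lr <- pf <- numeric(m)
  for (i in seq_len(m)) {
    k <- if (any(c(a[i], b[i], c_[i], d[i]) == 0)) 0.5 else 0
    lr[i] <- log10(((a[i] + k) * (d[i] + k)) / ((b[i] + k) * (c_[i] + k)))
    pf[i] <- fisher_exact_p(a[i], b[i], c_[i], d[i])
  }
  pb <- pmin(1, pf * m)
  out <- data.frame(pt_code = codes, pt_name = name_of, n = a, log_ror = lr,
                    p_fisher = pf, p_bonferroni = pb,
                    neg_log10_p = -log10(pb), stringsAsFactors = FALSE)
  out[order(out$p_bonferroni, -out$n), ]
}
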