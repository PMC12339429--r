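#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics table into the
#' canonical layout used by the MR suite: `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.  A
#' `col_map` (named list or vector, canonical name -> source column name)
#' renames nonstandard headers.  A missing `p` column is filled from the
#' two-sided normal tail of `beta/se`.
#'
#' @param x File path or data frame.
#' @param col_map Optional named mapping, e.g.
#'   `c(snp_id = "SNPs", beta = "B")`.
#' @return A data frame of class `gwas_sumstats`.
#' @export
read_gwas <- function(x, col_map = NULL) {
  if (is.character(x))
    x <- utils::read.table(x, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop_stage("read_gwas", sprintf("mapped column '%s' not found", src))
      names(df)[names(df) == src] <- canon
    }
  as_gwas_sumstats(df)
}

#' Validate and class a summary-statistics data frame
#' @param df Data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`.
#' @return The validated data frame, classed `gwas_sumstats`.
#' @export
as_gwas_sumstats <- function(df) {
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_stage("gwas_sumstats",
               "missing required column(s): ", paste(missing, collapse = ", "))
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  if (any(df$se <= 0)) stop_stage("gwas_sumstats", "non-positive SE")
  if (any(df$effect_allele == df$other_allele))
    stop_stage("gwas_sumstats", "effect and other allele identical")
  for (opt in c("chrom", "pos", "eaf", "p", "n"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  df$chrom <- as.character(df$chrom)
  if (all(is.na(df$p))) df$p <- 2 * stats::pnorm(-abs(df$beta / df$se))
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  df <- df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
  class(df) <- unique(c("gwas_sumstats", class(df)))
  df
}

#' Write GWAS summary statistics as TSV
#' @param df A `gwas_sumstats` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-form LD table
#' @param x Path to a 3-column TSV (`snp_i`, `snp_j`, `r2`) or a data frame.
#' @return A data frame with those columns.
#' @export
read_ld <- function(x) {
  if (is.character(x))
    x <- utils::read.table(x, header = TRUE, stringsAsFactors = FALSE)
  df <- as.data.frame(x)
  stopifnot(all(c("snp_i", "snp_j", "r2") %in% names(df)))
  df
}

ld_lookup <- function(ld) {
  # symmetric pair -> r2 environment; absent pairs read as 0 (unlinked)
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(ld)))
  if (!is.null(ld) && nrow(ld))
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$snp_i[i], ld$snp_j[i], sep = "\r"), ld$r2[i], envir = env)
      assign(paste(ld$snp_j[i], ld$snp_i[i], sep = "\r"), ld$r2[i], envir = env)
    }
  function(s1, s2) {
    v <- mget(paste(s1, s2, sep = "\r"), envir = env,
              ifnotfound = list(0))[[1]]
    as.numeric(v)
  }
}

#' Instrument strength F-statistic
#'
#' The per-SNP instrument-strength statistic `(beta / se)^2` for the
#' SNP-exposure association; F > 10 is the conventional weak-instrument
#' bar.
#'
#' @param beta,se Numeric vectors (`se > 0`).
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Select genetic instruments by p-value, LD clumping and strength
#'
#' Screens exposure SNPs at `p < p_thresh`, then greedily clumps: repeatedly
#' retain the smallest-p remaining SNP and discard all same-chromosome SNPs
#' within `window_kb` whose pairwise r-squared with it exceeds `r2_max`
#' (absent LD entries are treated as unlinked).  Finally drops retained
#' SNPs with F-statistic `<= f_min`.  Every exclusion is logged with its
#' reason in `attr(, "exclusions")`.
#'
#' @param exposure A `gwas_sumstats` data frame for the exposure.
#' @param p_thresh Significance threshold for candidacy.
#' @param ld Long-form LD table (see [read_ld()]) or `NULL`.
#' @param r2_max Clumping r-squared ceiling.
#' @param window_kb Clumping window in kilobases.
#' @param f_min Minimum F-statistic (exclusive).
#' @return The surviving rows (class `gwas_sumstats`) with an added
#'   `f_stat` column; `attr(, "exclusions")` is a data frame
#'   (`snp_id`, `reason`).
#' @export
select_instruments <- function(exposure, p_thresh = 5e-6, ld = NULL,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  exposure <- as_gwas_sumstats(exposure)
  excl <- list()
  note <- function(ids, reason)
    if (length(ids)) excl[[length(excl) + 1L]] <<- data.frame(
      snp_id = ids, reason = reason, stringsAsFactors = FALSE)

  cand <- exposure[!is.na(exposure$p) & exposure$p < p_thresh, , drop = FALSE]
  note(setdiff(exposure$snp_id, cand$snp_id), "p_above_threshold")

  if (nrow(cand)) {
    lookup <- ld_lookup(if (is.null(ld)) NULL else read_ld(ld))
    cand <- cand[order(cand$p), , drop = FALSE]
    kept <- logical(nrow(cand)); dropped <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (dropped[i]) next
      kept[i] <- TRUE
      if (i == nrow(cand)) break
      js <- which(!kept & !dropped & seq_len(nrow(cand)) > i)
      for (j in js) {
        same_chr <- !is.na(cand$chrom[i]) && !is.na(cand$chrom[j]) &&
          cand$chrom[i] == cand$chrom[j]
        if (!same_chr) next
        close <- !is.na(cand$pos[i]) && !is.na(cand$pos[j]) &&
          abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
        if (close && lookup(cand$snp_id[i], cand$snp_id[j]) > r2_max) {
          dropped[j] <- TRUE
          note(cand$snp_id[j],
               sprintf("clumped_with:%s", cand$snp_id[i]))
        }
      }
    }
    cand <- cand[kept, , drop = FALSE]
  }

  if (nrow(cand)) {
    cand$f_stat <- f_statistic(cand$beta, cand$se)
    weak <- cand$f_stat <= f_min
    note(cand$snp_id[weak], "weak_instrument")
    cand <- cand[!weak, , drop = FALSE]
  }
  if (!nrow(cand))
    stop_stage("select_instruments", "no instruments survive selection")
  rownames(cand) <- NULL
  attr(cand, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(snp_id = character(0), reason = character(0))
  cand
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  !is.na(COMPLEMENT[ea]) & COMPLEMENT[ea] == oa
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two panels on `snp_id` and aligns the outcome association
#' to the exposure's effect allele: when the outcome's effect allele equals
#' the exposure's other allele (directly or after strand complement) the
#' outcome beta sign is flipped and its allele frequency complemented.
#' SNPs whose allele pairs cannot be reconciled are dropped, as are
#' strand-ambiguous palindromic (A/T, C/G) SNPs with exposure allele
#' frequency inside `palindromic_window`.  Every exclusion is logged.
#'
#' @param exposure,outcome `gwas_sumstats` data frames keyed by `snp_id`.
#' @param palindromic_window EAF interval inside which palindromic SNPs are
#'   considered unresolvable.
#' @return An object of class `mr_harmonized`: a data frame with columns
#'   `snp_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`; `attr(, "exclusions")` logs dropped SNPs and actions.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  exposure <- as_gwas_sumstats(exposure)
  outcome <- as_gwas_sumstats(outcome)
  common <- intersect(exposure$snp_id, outcome$snp_id)
  excl <- list()
  note <- function(ids, reason)
    if (length(ids)) excl[[length(excl) + 1L]] <<- data.frame(
      snp_id = ids, reason = reason, stringsAsFactors = FALSE)
  note(setdiff(exposure$snp_id, common), "absent_from_outcome")
  if (!length(common))
    stop_stage("harmonize", "no overlapping instruments")

  ex <- exposure[match(common, exposure$snp_id), ]
  ou <- outcome[match(common, outcome$snp_id), ]
  keep <- logical(length(common))
  beta_out <- ou$beta; eaf_out <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- pal & !is.na(ex$eaf) &
    ex$eaf >= palindromic_window[1] & ex$eaf <= palindromic_window[2]

  for (i in seq_along(common)) {
    if (ambiguous[i]) { note(common[i], "palindromic_ambiguous"); next }
    ea_e <- ex$effect_allele[i]; oa_e <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]
    ea_oc <- unname(COMPLEMENT[ea_o]); oa_oc <- unname(COMPLEMENT[oa_o])
    if ((ea_o == ea_e && oa_o == oa_e) ||
        (!is.na(ea_oc) && !pal[i] && ea_oc == ea_e && oa_oc == oa_e)) {
      keep[i] <- TRUE
    } else if ((ea_o == oa_e && oa_o == ea_e) ||
               (!is.na(ea_oc) && !pal[i] && ea_oc == oa_e && oa_oc == ea_e)) {
      keep[i] <- TRUE
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      note(common[i], "flipped_outcome_beta")
    } else {
      note(common[i], "allele_mismatch")
    }
  }

  h <- data.frame(snp_id = common[keep],
                  beta_exp = ex$beta[keep], se_exp = ex$se[keep],
                  beta_out = beta_out[keep], se_out = ou$se[keep],
                  eaf_exp = ex$eaf[keep], eaf_out = eaf_out[keep],
                  stringsAsFactors = FALSE)
  if (!nrow(h)) stop_stage("harmonize", "no overlapping instruments")
  rownames(h) <- NULL
  attr(h, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(snp_id = character(0), reason = character(0))
  class(h) <- c("mr_harmonized", "data.frame")
  h
}

#' Assemble a harmonized set directly from aligned effect estimates
#'
#' Bypasses allele bookkeeping when per-SNP exposure and outcome effects
#' are already on the same effect allele (e.g. simulator output or worked
#' examples).
#'
#' @param beta_exp,se_exp,beta_out,se_out Aligned numeric vectors.
#' @param snp_id Optional SNP labels.
#' @return An `mr_harmonized` data frame.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = NULL) {
  k <- length(beta_exp)
  stopifnot(k >= 1, length(se_exp) == k, length(beta_out) == k,
            length(se_out) == k, all(se_exp > 0), all(se_out > 0))
  h <- data.frame(snp_id = snp_id %||% paste0("snp", seq_len(k)),
                  beta_exp = beta_exp, se_exp = se_exp,
                  beta_out = beta_out, se_out = se_out,
                  eaf_exp = NA_real_, eaf_out = NA_real_,
                  stringsAsFactors = FALSE)
  attr(h, "exclusions") <- data.frame(snp_id = character(0),
                                      reason = character(0))
  class(h) <- c("mr_harmonized", "data.frame")
  h
}
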