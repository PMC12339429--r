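read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

pipeline_log <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

config_fingerprint <- function(config, dir) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  # fingerprint the analysis-relevant config: file-system locations do not
  # change results, so they stay out of the hash
  stable <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(stable, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the pharmacovigilance arm end to end
#'
#' Parses (or simulates) a spontaneous-report extract, deduplicates it,
#' evaluates the three disproportionality statistics and the signal
#' verdict for the target drug-event pair, computes the clinical-priority
#' score, the per-PT volcano statistics for the drug, and the
#' age-band/sex logistic regression among the drug's reports.  All
#' outputs are written as TSV/JSON into the configured output directory
#' together with a deterministic run log (version, config fingerprint,
#' thresholds, exclusion counts).
#'
#' Config fields: `reports` (path) or `simulate` (list of [srs_config()]
#' arguments); optional `schema` (path to a YAML [report_schema()] or a
#' list); `drug`; `pt` (code or name); `clinical_relevance`
#' (`"DME"`/`"IME"`/`"none"`, default `"none"`); `yates` (default FALSE);
#' `priority_gate` (`"any"` = score when at least one method flags, the
#' default, or `"majority"`); `regression` (default TRUE); `output_dir`;
#' `seed`.
#'
#' @param config A list or a path to a YAML file.
#' @return Invisibly, a list with the fitted objects (`signal`,
#'   `priority`, `volcano`, `regression`, `report_set`).
#' @export
run_pv <- function(config) {
  config <- read_pipeline_config(config)
  out_dir <- config$output_dir %||% stop_stage("run_pv", "output_dir not set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  drug <- config$drug %||% stop_stage("run_pv", "drug not set")
  pt <- config$pt %||% stop_stage("run_pv", "pt not set")
  log <- c(sprintf("pvmr %s | arm: pharmacovigilance",
                   as.character(utils::packageVersion("pvmr"))),
           sprintf("config md5: %s", config_fingerprint(config, out_dir)))

  rs <- if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed) && is.null(sim_args$seed))
      sim_args$seed <- config$seed
    simulate_srs(do.call(srs_config, sim_args))
  } else if (!is.null(config$reports)) {
    schema <- if (is.null(config$schema)) report_schema()
      else if (is.character(config$schema)) read_report_schema(config$schema)
      else do.call(report_schema, config$schema)
    parse_reports(config$reports, schema)
  } else stop_stage("run_pv", "neither 'reports' nor 'simulate' configured")
  if (nrow(rs$reports) == 0L)
    stop_stage("run_pv", "no parseable reports in input")
  log <- c(log, sprintf("reports parsed: %d (provenance %s)",
                        nrow(rs$reports), rs$provenance))

  rs <- deduplicate(rs)
  log <- c(log, sprintf("deduplication: %d removed, %d survive",
                        rs$counts$dedup_removed, nrow(rs$reports)))

  yates <- isTRUE(config$yates)
  signal <- disprop(rs, drug, pt, yates = yates)
  t <- signal$table
  stats_row <- data.frame(
    drug = drug, pt = as.character(pt), a = t$a, b = t$b, c = t$c, d = t$d,
    ror = signal$stats[[1]]$point, ror_ci_low = signal$stats[[1]]$ci_low,
    ror_ci_high = signal$stats[[1]]$ci_high,
    prr = signal$stats[[2]]$point, chi2 = signal$stats[[2]]$chi2,
    ic = signal$stats[[3]]$point, ic025 = signal$stats[[3]]$ci_low,
    flag_ror = signal$stats[[1]]$flag, flag_prr = signal$stats[[2]]$flag,
    flag_ic = signal$stats[[3]]$flag,
    n_positive = signal$n_positive_methods, is_signal = signal$is_signal,
    stringsAsFactors = FALSE)
  write_tsv(stats_row, file.path(out_dir, "signals.tsv"))
  log <- c(log,
           sprintf("thresholds: ror a>=3 & ci_low>1; prr a>=3 & prr>=2 & chi2>=4 (yates=%s); ic025>0; signal >=2 of 3",
                   yates),
           sprintf("signal verdict: %d of 3 methods positive -> %s",
                   signal$n_positive_methods, signal$is_signal))

  gate <- config$priority_gate %||% "any"
  gate_n <- if (identical(gate, "majority")) 2L else 1L
  priority <- NULL
  if (signal$n_positive_methods >= gate_n) {
    di <- drug_report_indices(rs, drug)
    ei <- intersect(di, pt_report_indices(rs, pt))
    reporting_rate <- length(ei) / length(di)
    deaths <- sum(grepl("death", rs$reports$outcomes[ei], fixed = TRUE))
    fatality_rate <- if (length(ei)) deaths / length(ei) else 0
    priority <- score_priority(config$clinical_relevance %||% "none",
                               reporting_rate, fatality_rate,
                               signal$n_positive_methods)
    jsonlite::write_json(
      list(drug = drug, pt = as.character(pt),
           clinical_relevance = config$clinical_relevance %||% "none",
           reporting_rate = reporting_rate, fatality_rate = fatality_rate,
           stability = signal$n_positive_methods,
           component_points = as.list(priority$component_points),
           total = priority$total, category = priority$category),
      file.path(out_dir, "priority.json"), auto_unbox = TRUE, digits = NA)
    log <- c(log, sprintf("priority: total %d (%s)", priority$total,
                          priority$category))
  } else log <- c(log, "priority: not scored (gate not met)")

  volcano <- volcano_stats(rs, drug)
  write_tsv(volcano, file.path(out_dir, "volcano.tsv"))
  log <- c(log, sprintf("volcano: %d PTs tested", nrow(volcano)))

  regression <- NULL
  if (!identical(config$regression, FALSE)) {
    di <- drug_report_indices(rs, drug)
    ei <- pt_report_indices(rs, pt)
    dat <- data.frame(
      event = as.integer(di %in% ei),
      age_band = factor(assign_age_band(rs$reports$age_years[di],
                                        "regression"),
                        levels = c(AGE_SCHEMES$regression$labels, "unknown")),
      sex = factor(rs$reports$sex[di],
                   levels = c("female", "male", "unknown")),
      stringsAsFactors = FALSE)
    regression <- tryCatch(
      logistic_table("event", c("age_band", "sex"), dat,
                     alpha = config$alpha %||% 0.05),
      error = function(e) conditionMessage(e))
    if (is.character(regression)) {
      log <- c(log, sprintf("regression: skipped (%s)", regression))
      regression <- NULL
    } else {
      write_tsv(rbind(as.data.frame(regression$univariable),
                      if (!is.null(regression$multivariable))
                        as.data.frame(regression$multivariable)),
                file.path(out_dir, "regression.tsv"))
      log <- c(log, sprintf("regression: carried forward: %s",
                            paste(regression$carried_forward,
                                  collapse = ", ") %||% ""))
    }
  }

  pipeline_log(log, file.path(out_dir, "run_log.txt"))
  invisible(list(report_set = rs, signal = signal, priority = priority,
                 volcano = volcano, regression = regression))
}

#' Run the Mendelian-randomization arm end to end
#'
#' Reads (or simulates) exposure and outcome GWAS summary panels, selects
#' instruments (p-value screen, LD clumping, F-statistic filter),
#' harmonizes alleles, fits the five-estimator suite, and computes the
#' diagnostic bundle (Cochran's Q under IVW and Egger, Egger intercept,
#' MR-PRESSO, leave-one-out).  A positive-control outcome panel, when
#' configured, is run through the identical flow and labelled `control`.
#' Outputs (per outcome label: estimates TSV, diagnostics JSON,
#' leave-one-out TSV; shared instrument-exclusion TSV and run log) are
#' written to the output directory; estimators whose preconditions fail
#' are recorded with reasons rather than aborting the run.
#'
#' Config fields: `exposure` (path) or `simulate` (list of
#' [gwas_sim_config()] arguments); `outcome` (path; ignored when
#' simulating); optional `outcome_control` path; optional `exposure_cols`
#' / `outcome_cols` column maps; optional `ld` path; thresholds
#' `p_thresh`, `r2_max`, `window_kb`, `f_min`; `n_boot`, `n_sim`;
#' `output_dir`; `seed`.
#'
#' @param config A list or a path to a YAML file.
#' @return Invisibly, a list of per-label bundles (`fit`, `heterogeneity`,
#'   `presso`, `loo`) plus `instruments`.
#' @export
run_mr <- function(config) {
  config <- read_pipeline_config(config)
  out_dir <- config$output_dir %||% stop_stage("run_mr", "output_dir not set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  log <- c(sprintf("pvmr %s | arm: mendelian_randomization",
                   as.character(utils::packageVersion("pvmr"))),
           sprintf("config md5: %s", config_fingerprint(config, out_dir)))

  outcomes <- list()
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- simulate_gwas_pair(do.call(gwas_sim_config, sim_args))
    exposure <- sim$exposure
    outcomes$primary <- sim$outcome
  } else {
    exposure <- read_gwas(config$exposure %||%
                            stop_stage("run_mr", "exposure not set"),
                          config$exposure_cols)
    outcomes$primary <- read_gwas(config$outcome %||%
                                    stop_stage("run_mr", "outcome not set"),
                                  config$outcome_cols)
    if (!is.null(config$outcome_control))
      outcomes$control <- read_gwas(config$outcome_control,
                                    config$outcome_cols)
  }

  p_thresh <- config$p_thresh %||% 5e-6
  instruments <- select_instruments(
    exposure, p_thresh = p_thresh,
    ld = if (!is.null(config$ld)) read_ld(config$ld) else NULL,
    r2_max = config$r2_max %||% 0.001,
    window_kb = config$window_kb %||% 10000,
    f_min = config$f_min %||% 10)
  excl <- attr(instruments, "exclusions")
  write_tsv(excl, file.path(out_dir, "instrument_exclusions.tsv"))
  log <- c(log,
           sprintf("instrument selection: p<%g, r2<=%g in %g kb, F>%g -> %d retained, %d excluded",
                   p_thresh, config$r2_max %||% 0.001,
                   config$window_kb %||% 10000, config$f_min %||% 10,
                   nrow(instruments), nrow(excl)))

  n_boot <- config$n_boot %||% 1000
  n_sim <- config$n_sim %||% 1000
  bundles <- list()
  for (label in names(outcomes)) {
    h <- harmonize(instruments, outcomes[[label]])
    hx <- attr(h, "exclusions")
    for (i in seq_len(nrow(hx)))
      log <- c(log, sprintf("[%s] harmonize %s: %s", label, hx$snp_id[i],
                            hx$reason[i]))
    log <- c(log, sprintf("[%s] harmonized instruments: k = %d", label,
                          nrow(h)))

    fit <- mr_fit(h, n_boot = n_boot, seed = seed)
    write_tsv(fit$estimates, file.path(out_dir,
                                       sprintf("estimates_%s.tsv", label)))
    for (nm in names(fit$skipped))
      log <- c(log, sprintf("[%s] estimator %s skipped: %s", label, nm,
                            fit$skipped[nm]))

    het <- lapply(c(ivw = "ivw", egger = "egger"), function(m)
      tryCatch(cochran_q(h, m), error = function(e) conditionMessage(e)))
    presso <- tryCatch(mr_presso(h, n_sim = n_sim, seed = seed + 7L),
                       error = function(e) conditionMessage(e))
    loo <- tryCatch(mr_leave_one_out(h),
                    error = function(e) conditionMessage(e))

    diag <- list(
      heterogeneity = lapply(het, function(q)
        if (inherits(q, "mr_heterogeneity"))
          list(Q = q$Q, df = q$df, p = q$p) else list(skipped = q)),
      egger_intercept = if (!is.null(fit$fits$egger))
        fit$fits$egger$extras[c("intercept", "intercept_se", "intercept_p")]
      else list(skipped = unname(fit$skipped["egger"])),
      mr_presso = if (inherits(presso, "mr_presso"))
        list(global_rss = presso$global_rss, global_p = presso$global_p,
             n_outliers = sum(presso$outliers$flag),
             outliers = presso$outliers)
      else list(skipped = presso))
    jsonlite::write_json(diag,
                         file.path(out_dir,
                                   sprintf("diagnostics_%s.json", label)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (inherits(loo, "mr_loo"))
      write_tsv(as.data.frame(loo),
                file.path(out_dir, sprintf("leave_one_out_%s.tsv", label)))
    else log <- c(log, sprintf("[%s] leave-one-out skipped: %s", label, loo))

    bundles[[label]] <- list(fit = fit, heterogeneity = het,
                             presso = presso, loo = loo)
  }

  pipeline_log(log, file.path(out_dir, "run_log.txt"))
  invisible(c(bundles, list(instruments = instruments)))
}
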