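#' Configuration for the spontaneous-report simulator
#'
#' Describes a seeded synthetic spontaneous reporting system with one
#' target drug, one target adverse event (PT) with a planted relative
#' risk, a panel of unassociated decoy PTs, and FAERS-like report
#' demographics.  The defaults emulate the rare-event regime of large SRS
#' extracts: a drug listed on 0.5% of reports, a background event rate of
#' 3 per 10,000 reports, and a planted relative risk of 12, with
#' demographic category frequencies mirroring published brain-neoplasm
#' report characteristics (45% unknown age, near-even sex split, ~17%
#' hospitalization outcome).
#'
#' @param n_reports Number of reports.
#' @param p_drug Marginal probability a report lists the target drug.
#' @param p_event_background Baseline probability a report lists the
#'   target PT.
#' @param rr Planted relative risk of the PT given the drug
#'   (`p_event_background * rr <= 1`).
#' @param n_decoy_pts Number of unassociated decoy PTs.
#' @param decoy_rate Per-report probability of each decoy PT.
#' @param target_drug,target_pt_code,target_pt_name Target labels.
#' @param demographics List with `age_band_probs` (named, descriptive
#'   bands plus `"unknown"`), `sex_probs`, `outcome_probs`,
#'   `country_probs`.
#' @param age_effect Optional named log-OR vector on the event, keyed by
#'   regression age band (applied on the logit scale).
#' @param dup_rate Fraction of reports re-injected as exact duplicates (to
#'   exercise deduplication).
#' @param seed Integer seed.
#' @return A list of class `srs_config`.
#' @export
srs_config <- function(n_reports = 200000, p_drug = 0.005,
                       p_event_background = 3e-4, rr = 12,
                       n_decoy_pts = 20, decoy_rate = 0.002,
                       target_drug = "somatropin",
                       target_pt_code = 10061019L,
                       target_pt_name = "brain neoplasm",
                       demographics = NULL, age_effect = NULL,
                       dup_rate = 0, seed = 1) {
  demographics <- demographics %||% list(
    age_band_probs = c("0-11" = 0.099, "12-17" = 0.131, "18-34" = 0.057,
                       "35-64" = 0.223, "65-79" = 0.033, ">=80" = 0.007,
                       unknown = 0.450),
    sex_probs = c(female = 0.482, male = 0.468, unknown = 0.050),
    outcome_probs = c(death = 0.021, disability = 0.007,
                      hospitalization = 0.170, life_threatening = 0.021,
                      unknown = 0.053, other = 0.728),
    country_probs = c(US = 0.255, GB = 0.252, CA = 0.149, CO = 0.046,
                      TR = 0.039, other = 0.259)
  )
  if (!is.null(age_effect)) age_effect <- unlist(age_effect)
  cfg <- list(n_reports = as.integer(n_reports), p_drug = p_drug,
              p_event_background = p_event_background, rr = rr,
              n_decoy_pts = as.integer(n_decoy_pts),
              decoy_rate = decoy_rate, target_drug = target_drug,
              target_pt_code = as.integer(target_pt_code),
              target_pt_name = target_pt_name, demographics = demographics,
              age_effect = age_effect, dup_rate = dup_rate,
              seed = as.integer(seed))
  validate_srs_config(cfg)
  structure(cfg, class = "srs_config")
}

validate_srs_config <- function(cfg) {
  probs <- c(cfg$p_drug, cfg$p_event_background, cfg$decoy_rate, cfg$dup_rate)
  if (any(probs < 0 | probs > 1))
    stop_stage("srs_config", "probabilities must lie in [0, 1]")
  if (cfg$rr <= 0) stop_stage("srs_config", "rr must be positive")
  if (cfg$p_event_background * cfg$rr > 1)
    stop_stage("srs_config", "p_event_background * rr exceeds 1")
  if (cfg$n_reports < 1) stop_stage("srs_config", "n_reports must be >= 1")
  for (nm in c("age_band_probs", "sex_probs", "outcome_probs",
               "country_probs")) {
    p <- cfg$demographics[[nm]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop_stage("srs_config", nm, " must be nonnegative and sum to 1")
  }
  invisible(cfg)
}

#' Read an `srs_config` from YAML
#' @param path Path to a YAML file whose keys match [srs_config()]
#'   arguments.
#' @return An `srs_config`.
#' @export
read_srs_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("demographics"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- lapply(cfg[[nm]], unlist)
  if (!is.null(cfg$age_effect)) cfg$age_effect <- unlist(cfg$age_effect)
  do.call(srs_config, cfg)
}

AGE_BAND_RANGES <- list("0-11" = c(0, 11), "12-17" = c(12, 17),
                        "18-34" = c(18, 34), "35-64" = c(35, 64),
                        "65-79" = c(65, 79), ">=80" = c(80, 100))

BACKGROUND_DRUGS <- c("ibuprofen", "metformin", "amoxicillin",
                      "lisinopril", "atorvastatin")

#' Simulate a spontaneous reporting system extract
#'
#' Generates `n_reports` independent reports under the planted-signal
#' model: the target drug is Bernoulli(`p_drug`); the target PT occurs
#' with probability `p_event_background * rr` on drug reports and
#' `p_event_background` otherwise (optionally shifted on the logit scale
#' by a per-age-band effect); decoy PTs are independent Bernoullis;
#' demographics are sampled from the configured category frequencies.
#' Reports without any sampled PT receive one decoy PT so every record is
#' codable.  With `dup_rate > 0`, a fraction of reports is appended again
#' as exact duplicates.  Fully reproducible for a given seed.
#'
#' @param cfg An [srs_config()].
#' @return A [report_set] with provenance `"synthetic-srs"`.
#' @export
simulate_srs <- function(cfg) {
  stopifnot(inherits(cfg, "srs_config"))
  validate_srs_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_reports
    dem <- cfg$demographics

    band <- sample(names(dem$age_band_probs), n, replace = TRUE,
                   prob = dem$age_band_probs)
    age <- rep(NA_real_, n)
    for (b in names(AGE_BAND_RANGES)) {
      idx <- which(band == b)
      if (length(idx)) {
        rg <- AGE_BAND_RANGES[[b]]
        age[idx] <- floor(stats::runif(length(idx), rg[1], rg[2] + 1))
      }
    }
    sex <- sample(names(dem$sex_probs), n, replace = TRUE,
                  prob = dem$sex_probs)
    outcome <- sample(names(dem$outcome_probs), n, replace = TRUE,
                      prob = dem$outcome_probs)
    country <- sample(names(dem$country_probs), n, replace = TRUE,
                      prob = dem$country_probs)

    has_drug <- stats::runif(n) < cfg$p_drug
    p_event <- ifelse(has_drug, cfg$p_event_background * cfg$rr,
                      cfg$p_event_background)
    if (!is.null(cfg$age_effect)) {
      reg_band <- assign_age_band(age, "regression")
      shift <- cfg$age_effect[reg_band]
      shift[is.na(shift)] <- 0
      p_event <- stats::plogis(stats::qlogis(p_event) + shift)
    }
    has_event <- stats::runif(n) < p_event

    # decoy PT incidence matrix in sparse triplet form
    n_decoy <- cfg$n_decoy_pts
    decoy_codes <- 10000000L + seq_len(n_decoy)
    decoy_names <- paste0("decoy event ", seq_len(n_decoy))
    hits <- which(matrix(stats::runif(n * n_decoy) < cfg$decoy_rate,
                         n, n_decoy), arr.ind = TRUE)
    pt_report <- c(which(has_event), hits[, 1])
    pt_code <- c(rep(cfg$target_pt_code, sum(has_event)),
                 decoy_codes[hits[, 2]])
    pt_name <- c(rep(cfg$target_pt_name, sum(has_event)),
                 decoy_names[hits[, 2]])
    # guarantee every report carries at least one PT
    bare <- setdiff(seq_len(n), unique(pt_report))
    if (length(bare)) {
      j <- sample.int(n_decoy, length(bare), replace = TRUE)
      pt_report <- c(pt_report, bare)
      pt_code <- c(pt_code, decoy_codes[j])
      pt_name <- c(pt_name, decoy_names[j])
    }
    ord <- order(pt_report, pt_code)
    pts <- data.frame(report = pt_report[ord], pt_code = pt_code[ord],
                      pt_name = pt_name[ord], stringsAsFactors = FALSE)

    drug_name <- ifelse(has_drug, cfg$target_drug,
                        BACKGROUND_DRUGS[sample.int(length(BACKGROUND_DRUGS),
                                                    n, replace = TRUE)])
    drugs <- data.frame(report = seq_len(n), drug = drug_name,
                        stringsAsFactors = FALSE)

    reports <- data.frame(
      report_id = sprintf("R%07d", seq_len(n)), case_version = 0L,
      age_years = age, sex = sex,
      country = ifelse(country == "other", NA_character_, country),
      receipt_date = as.Date(NA), outcomes = outcome,
      stringsAsFactors = FALSE)

    rs <- new_report_set(reports, drugs, pts, provenance = "synthetic-srs",
                         counts = list(n_simulated = n))
    if (cfg$dup_rate > 0) {
      n_dup <- floor(cfg$dup_rate * n)
      if (n_dup > 0) {
        pick <- sort(sample.int(n, n_dup))
        m <- nrow(rs$reports)
        dup_rep <- rs$reports[pick, , drop = FALSE]
        rs$reports <- rbind(rs$reports, dup_rep)
        rownames(rs$reports) <- NULL
        remap <- stats::setNames(m + seq_along(pick), pick)
        dd <- rs$drugs[rs$drugs$report %in% pick, , drop = FALSE]
        dd$report <- unname(remap[as.character(dd$report)])
        dp <- rs$pts[rs$pts$report %in% pick, , drop = FALSE]
        dp$report <- unname(remap[as.character(dp$report)])
        rs$drugs <- rbind(rs$drugs, dd); rownames(rs$drugs) <- NULL
        rs$pts <- rbind(rs$pts, dp); rownames(rs$pts) <- NULL
        rs$counts$duplicates_injected <- n_dup
      }
    }
    rs
  })
}
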