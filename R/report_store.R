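#' @title Spontaneous-report store
#' @description
#' A `report_set` holds deduplicable spontaneous adverse-event reports in a
#' normalized long layout: one row per report in `$reports`, one row per
#' (report, drug) in `$drugs` and one row per (report, preferred term) in
#' `$pts`.  The layout mirrors the extracts distributed by spontaneous
#' reporting systems (FAERS, JADER, CVARD) after MedDRA PT-level coding.
#' @name report_set
NULL

OUTCOME_LEVELS <- c("death", "disability", "hospitalization",
                    "life_threatening", "other", "unknown")

# lax aliases seen in SRS extracts -> canonical outcome tokens
OUTCOME_ALIASES <- c(
  de = "death", death = "death", died = "death",
  ds = "disability", disability = "disability",
  ho = "hospitalization", hospitalization = "hospitalization",
  "hospitalization-initial or prolonged" = "hospitalization",
  lt = "life_threatening", "life-threatening" = "life_threatening",
  life_threatening = "life_threatening",
  ot = "other", other = "other", "other outcome" = "other",
  unknown = "unknown", unk = "unknown"
)

new_report_set <- function(reports, drugs, pts, provenance = "unknown",
                           counts = list()) {
  stopifnot(is.data.frame(reports), is.data.frame(drugs), is.data.frame(pts))
  structure(list(reports = reports, drugs = drugs, pts = pts,
                 provenance = provenance, counts = counts),
            class = "report_set")
}

#' Number of reports in a report set
#' @param rs A `report_set`.
#' @return Integer count of reports.
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$reports)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports (%s), %d drug mentions, %d PT mentions\n",
              nrow(x$reports), x$provenance, nrow(x$drugs), nrow(x$pts)))
  if (length(x$counts))
    cat("  ingest counts:",
        paste(names(x$counts), unlist(x$counts), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Column-mapping schema for report ingest
#'
#' Describes how a delimited extract maps onto the canonical report fields.
#' `report_id`, `drug`, `pt_code` and `sex` are required; the rest are
#' optional.  `drug`, `pt_code`, `pt_name` and `outcome` cells may be
#' multi-valued with separator `multi_sep`.  `synonyms` is a named character
#' vector mapping raw (lower-cased) drug names to their standardized generic
#' names, applied after case/whitespace normalization.
#'
#' @param report_id,drug,pt_code,pt_name,sex,case_version,age,country,outcome,receipt_date,record
#'   Source column names (`NULL` for absent optional columns).
#' @param multi_sep Separator for multi-valued cells.
#' @param sep Field separator of the file (`"\t"` or `","`); `NULL` infers
#'   from the file extension.
#' @param synonyms Named character vector of drug-name synonyms, or `NULL`.
#' @param provenance Source label, e.g. `"faers-like"`.
#' @return A list of class `report_schema`.
#' @export
report_schema <- function(report_id = "report_id", drug = "drugs",
                          pt_code = "pt_code", pt_name = "pt_name",
                          sex = "sex", case_version = "case_version",
                          age = "age_years", country = "country",
                          outcome = "outcome", receipt_date = "receipt_date",
                          record = "record", multi_sep = ";", sep = NULL,
                          synonyms = NULL, provenance = "unknown") {
  structure(list(report_id = report_id, drug = drug, pt_code = pt_code,
                 pt_name = pt_name, sex = sex, case_version = case_version,
                 age = age, country = country, outcome = outcome,
                 receipt_date = receipt_date, record = record,
                 multi_sep = multi_sep, sep = sep, synonyms = synonyms,
                 provenance = provenance),
            class = "report_schema")
}

#' Read a report schema from a YAML file
#' @param path Path to a YAML file whose keys match [report_schema()]
#'   arguments.
#' @return A `report_schema`.
#' @export
read_report_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synonyms)) cfg$synonyms <- unlist(cfg$synonyms)
  do.call(report_schema, cfg)
}

normalize_drug <- function(x, synonyms = NULL) {
  x <- tolower(trimws_squish(x))
  if (!is.null(synonyms)) {
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female", "2")] <- "female"
  out[x %in% c("m", "male", "1")] <- "male"
  out
}

normalize_outcomes <- function(cells, multi_sep) {
  vapply(cells, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return("unknown")
    toks <- tolower(trimws(strsplit(cell, multi_sep, fixed = TRUE)[[1]]))
    toks <- toks[nzchar(toks)]
    mapped <- OUTCOME_ALIASES[toks]
    mapped[is.na(mapped)] <- ifelse(toks[is.na(mapped)] %in% OUTCOME_LEVELS,
                                    toks[is.na(mapped)], "other")
    paste(sort(unique(unname(mapped))), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Parse spontaneous adverse-event reports from a delimited table
#'
#' Ingests a CSV/TSV extract (or an in-memory data frame) into a
#' [report_set], applying the field normalizations expected downstream:
#' drug names are lower-cased, whitespace-collapsed and mapped through the
#' schema's synonym table; sex is coded female/male/unknown; outcomes are
#' mapped to a fixed token set; unparseable or out-of-range ages become
#' missing (the row is retained).  Rows lacking a report id or any valid PT
#' code are skipped and counted.  If the schema names a `record` column the
#' file is treated as the canonical long form (one row per report-PT pair)
#' and rows are grouped by record number; otherwise each row is one report
#' with possibly multi-valued drug/PT cells.
#'
#' @param x Path to a delimited file, or a data frame.
#' @param schema A [report_schema()].
#' @return A `report_set`.
#' @export
parse_reports <- function(x, schema = report_schema()) {
  stopifnot(inherits(schema, "report_schema"))
  if (is.character(x)) {
    sep <- schema$sep %||% if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- utils::read.delim(x, sep = sep, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  }
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (req in c("report_id", "drug", "pt_code", "sex")) {
    colname <- schema[[req]]
    if (is.null(colname) || !colname %in% names(df))
      stop_stage("parse_reports",
                 sprintf("required column '%s' (%s) missing from input",
                         colname %||% "<unset>", req))
  }
  getcol <- function(field) {
    colname <- schema[[field]]
    if (!is.null(colname) && colname %in% names(df)) as.character(df[[colname]]) else NULL
  }

  id_raw <- trimws(as.character(df[[schema$report_id]]))
  # record grouping: canonical long form groups rows into records
  rec_col <- getcol("record")
  grp <- if (!is.null(rec_col)) {
    match(rec_col, unique(rec_col))
  } else seq_len(nrow(df))

  skipped_no_id <- 0L
  skipped_no_pt <- 0L
  bad_age <- 0L

  ver_col <- getcol("case_version")
  age_col <- getcol("age")
  ctry_col <- getcol("country")
  out_col <- getcol("outcome")
  date_col <- getcol("receipt_date")
  name_col <- getcol("pt_name")
  sex_col <- as.character(df[[schema$sex]])
  drug_col <- as.character(df[[schema$drug]])
  pt_col <- as.character(df[[schema$pt_code]])

  rep_rows <- list(); drug_rows <- list(); pt_rows <- list()
  rec_i <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    rid <- id_raw[idx[1]]
    if (is.na(rid) || !nzchar(rid)) { skipped_no_id <- skipped_no_id + 1L; next }

    codes <- integer(0); names_ <- character(0)
    for (i in idx) {
      raw_codes <- trimws(strsplit(pt_col[i] %||% "", schema$multi_sep,
                                   fixed = TRUE)[[1]])
      raw_names <- if (!is.null(name_col))
        trimws(strsplit(name_col[i], schema$multi_sep, fixed = TRUE)[[1]])
      else character(0)
      ci <- suppressWarnings(as.integer(raw_codes))
      keep <- !is.na(ci)
      ni <- if (length(raw_names) == length(raw_codes)) raw_names[keep]
            else rep(NA_character_, sum(keep))
      codes <- c(codes, ci[keep]); names_ <- c(names_, ni)
    }
    if (!length(codes)) { skipped_no_pt <- skipped_no_pt + 1L; next }
    ord <- order(codes)
    codes <- codes[ord]; names_ <- names_[ord]
    dup <- duplicated(codes)
    codes <- codes[!dup]; names_ <- names_[!dup]
    names_[is.na(names_)] <- paste0("PT", codes[is.na(names_)])

    drugs <- unlist(lapply(idx, function(i)
      strsplit(drug_col[i] %||% "", schema$multi_sep, fixed = TRUE)[[1]]))
    drugs <- normalize_drug(drugs, schema$synonyms)
    drugs <- sort(unique(drugs[nzchar(drugs)]))

    age <- NA_real_
    if (!is.null(age_col)) {
      age <- suppressWarnings(as.numeric(age_col[idx[1]]))
      if (!is.na(age) && (age < 0 || age > 130)) { age <- NA_real_; bad_age <- bad_age + 1L }
      if (is.na(age) && nzchar(trimws(age_col[idx[1]] %||% "")) &&
          is.na(suppressWarnings(as.numeric(age_col[idx[1]]))))
        bad_age <- bad_age + 0L  # unparseable: field left missing, row kept
    }
    ver <- if (!is.null(ver_col))
      suppressWarnings(as.integer(ver_col[idx[1]])) else NA_integer_
    if (is.na(ver)) ver <- 0L
    date <- if (!is.null(date_col))
      suppressWarnings(as.Date(date_col[idx[1]])) else as.Date(NA)

    rec_i <- rec_i + 1L
    rep_rows[[rec_i]] <- data.frame(
      report_id = rid, case_version = ver, age_years = age,
      sex = normalize_sex(sex_col[idx[1]]),
      country = if (!is.null(ctry_col) && nzchar(trimws(ctry_col[idx[1]] %||% "")))
        trimws(ctry_col[idx[1]]) else NA_character_,
      receipt_date = date,
      outcomes = normalize_outcomes(if (!is.null(out_col)) out_col[idx[1]] else NA,
                                    schema$multi_sep),
      stringsAsFactors = FALSE)
    if (length(drugs))
      drug_rows[[rec_i]] <- data.frame(report = rec_i, drug = drugs,
                                       stringsAsFactors = FALSE)
    pt_rows[[rec_i]] <- data.frame(report = rec_i, pt_code = codes,
                                   pt_name = names_, stringsAsFactors = FALSE)
  }

  reports <- if (rec_i) do.call(rbind, rep_rows) else
    data.frame(report_id = character(0), case_version = integer(0),
               age_years = numeric(0), sex = character(0),
               country = character(0), receipt_date = as.Date(character(0)),
               outcomes = character(0), stringsAsFactors = FALSE)
  rownames(reports) <- NULL
  drugs_df <- if (length(drug_rows)) do.call(rbind, Filter(Negate(is.null), drug_rows)) else
    data.frame(report = integer(0), drug = character(0))
  pts_df <- if (length(pt_rows)) do.call(rbind, pt_rows) else
    data.frame(report = integer(0), pt_code = integer(0), pt_name = character(0))
  rownames(drugs_df) <- NULL; rownames(pts_df) <- NULL
  new_report_set(reports, drugs_df, pts_df, provenance = schema$provenance,
                 counts = list(parsed = rec_i, skipped_no_report_id = skipped_no_id,
                               skipped_no_pt = skipped_no_pt))
}

#' Write a report set in the canonical long form
#'
#' Serializes one row per (report, PT) pair to a TSV, with a `record` column
#' preserving record identity, plus a JSON sidecar (`<path>.json`) carrying
#' provenance and ingest counts.  [parse_reports()] with the default schema
#' round-trips the output.
#'
#' @param rs A `report_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(rs, path) {
  stopifnot(inherits(rs, "report_set"))
  drugs_by <- split(rs$drugs$drug, rs$drugs$report)
  drug_str <- vapply(seq_len(nrow(rs$reports)), function(i) {
    d <- drugs_by[[as.character(i)]]
    if (is.null(d)) "" else paste(d, collapse = "; ")
  }, character(1))
  out <- data.frame(
    record = rs$pts$report,
    report_id = rs$reports$report_id[rs$pts$report],
    case_version = rs$reports$case_version[rs$pts$report],
    drugs = drug_str[rs$pts$report],
    pt_code = rs$pts$pt_code,
    pt_name = rs$pts$pt_name,
    age_years = rs$reports$age_years[rs$pts$report],
    sex = rs$reports$sex[rs$pts$report],
    country = rs$reports$country[rs$pts$report],
    outcome = rs$reports$outcomes[rs$pts$report],
    receipt_date = as.character(rs$reports$receipt_date[rs$pts$report]),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  jsonlite::write_json(list(provenance = rs$provenance, counts = rs$counts),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Deduplicate a report set
#'
#' Spontaneous reporting systems accumulate duplicate and versioned
#' submissions.  Among records sharing the composite key
#' (report id, sex, country) exactly one survives: the highest case version,
#' ties broken by latest receipt date, then by last position in file order.
#' Idempotent.
#'
#' @param rs A `report_set`.
#' @return A deduplicated `report_set`; `$counts$dedup_removed` records the
#'   number of dropped records.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  r <- rs$reports
  if (!nrow(r)) return(rs)
  key <- paste(r$report_id, r$sex, ifelse(is.na(r$country), "", r$country),
               sep = "\r")
  date_num <- as.numeric(r$receipt_date)
  date_num[is.na(date_num)] <- -Inf
  ord <- order(key, r$case_version, date_num, seq_len(nrow(r)))
  keep_sorted <- !duplicated(key[ord], fromLast = TRUE)  # last = best in sort order
  keep <- sort(ord[keep_sorted])
  removed <- nrow(r) - length(keep)

  new_idx <- integer(nrow(r)); new_idx[keep] <- seq_along(keep)
  drugs <- rs$drugs[rs$drugs$report %in% keep, , drop = FALSE]
  drugs$report <- new_idx[drugs$report]
  pts <- rs$pts[rs$pts$report %in% keep, , drop = FALSE]
  pts$report <- new_idx[pts$report]
  rownames(drugs) <- NULL; rownames(pts) <- NULL
  out <- new_report_set(r[keep, , drop = FALSE], drugs, pts,
                        provenance = rs$provenance, counts = rs$counts)
  rownames(out$reports) <- NULL
  out$counts$dedup_removed <- removed
  out$counts$dedup_survivors <- length(keep)
  out
}

#' Filter a report set to records mentioning a PT
#' @param rs A `report_set`.
#' @param pt A PT code (integer) or PT name (string, case-insensitive).
#' @return A `report_set` restricted to matching records.
#' @export
filter_by_pt <- function(rs, pt) {
  stopifnot(inherits(rs, "report_set"))
  hit <- pt_report_indices(rs, pt)
  keep <- sort(hit)
  new_idx <- integer(nrow(rs$reports)); new_idx[keep] <- seq_along(keep)
  drugs <- rs$drugs[rs$drugs$report %in% keep, , drop = FALSE]
  drugs$report <- new_idx[drugs$report]
  pts <- rs$pts[rs$pts$report %in% keep, , drop = FALSE]
  pts$report <- new_idx[pts$report]
  rownames(drugs) <- NULL; rownames(pts) <- NULL
  out <- new_report_set(rs$reports[keep, , drop = FALSE], drugs, pts,
                        rs$provenance, rs$counts)
  rownames(out$reports) <- NULL
  out
}

pt_report_indices <- function(rs, pt) {
  if (is.numeric(pt)) unique(rs$pts$report[rs$pts$pt_code == as.integer(pt)])
  else unique(rs$pts$report[tolower(rs$pts$pt_name) == tolower(pt)])
}

drug_report_indices <- function(rs, drug) {
  unique(rs$drugs$report[rs$drugs$drug == tolower(trimws_squish(drug))])
}

# Age-band schemes.  The regression scheme uses half-open bands
# [0,18), [18,45), [45,66), [66,Inf) so that every age maps to exactly one
# band; the descriptive scheme mirrors the demographic-table convention
# 0-11 / 12-17 / 18-34 / 35-64 / 65-79 / >=80.
AGE_SCHEMES <- list(
  regression  = list(breaks = c(0, 18, 45, 66, Inf),
                     labels = c("<18", "18-44", "45-65", ">65")),
  descriptive = list(breaks = c(0, 12, 18, 35, 65, 80, Inf),
                     labels = c("0-11", "12-17", "18-34", "35-64", "65-79",
                                ">=80"))
)

#' Assign ages to analysis bands
#'
#' Maps ages in years onto one of two band schemes: `"regression"` (the
#' four WHO-style bands used as logistic-regression covariates) or
#' `"descriptive"` (the six bands used in demographic summary tables).
#' Missing ages map to `"unknown"`; bands partition `[0, 130]`.
#'
#' @param age_years Numeric vector of ages (NA allowed).
#' @param scheme `"regression"` or `"descriptive"`.
#' @param labels Optional replacement labels (same length as the scheme's
#'   default), e.g. to render the regression bands as "18-45"/"46-65".
#' @return Character vector of band labels.
#' @examples
#' assign_age_band(c(17.9, 33, 65, NA), "regression")
#' @export
assign_age_band <- function(age_years, scheme = c("regression", "descriptive"),
                            labels = NULL) {
  scheme <- match.arg(scheme)
  sc <- AGE_SCHEMES[[scheme]]
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(sc$labels))
    sc$labels <- labels
  }
  age_years <- as.numeric(age_years)
  if (any(age_years < 0, na.rm = TRUE))
    stop_stage("assign_age_band", "negative age")
  band <- as.character(cut(age_years, breaks = sc$breaks, labels = sc$labels,
                           right = FALSE, include.lowest = TRUE))
  band[is.na(band)] <- "unknown"
  band
}
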