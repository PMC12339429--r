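# In-memory report rows in the wide (one row per report) ingest layout.
toy_report_rows <- function() {
  data.frame(
    report_id = c("A1", "A2", "A3"),
    drugs = c("Somatropin;  Ibuprofen", "metformin", "somatropin"),
    pt_code = c("10061019", "10019211", "10061019;10019211"),
    pt_name = c("brain neoplasm", "headache", "brain neoplasm;headache"),
    sex = c("F", "male", "x"),
    age_years = c("33", "thirty", "7"),
    country = c("US", "JP", ""),
    outcome = c("HO", "death;other", ""),
    stringsAsFactors = FALSE)
}

# Build a report_set directly from vectors of per-report drug and PT lists.
make_report_set <- function(report_id, drugs, pts, sex = NULL,
                            country = NULL, case_version = NULL,
                            receipt_date = NULL, age = NULL,
                            outcome = NULL) {
  n <- length(report_id)
  df <- data.frame(
    report_id = report_id,
    case_version = if (is.null(case_version)) 0L else case_version,
    drugs = vapply(drugs, paste, character(1), collapse = ";"),
    pt_code = vapply(pts, function(p) paste(p, collapse = ";"), character(1)),
    sex = if (is.null(sex)) rep("unknown", n) else sex,
    age_years = if (is.null(age)) rep(NA, n) else age,
    country = if (is.null(country)) rep("", n) else country,
    outcome = if (is.null(outcome)) rep("", n) else outcome,
    receipt_date = if (is.null(receipt_date)) rep("", n) else receipt_date,
    stringsAsFactors = FALSE)
  parse_reports(df, report_schema(provenance = "test"))
}

# Independent brute-force 2x2 recount: loop over reports.
brute_force_table <- function(rs, drug, pt) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(rs$reports))) {
    has_d <- drug %in% rs$drugs$drug[rs$drugs$report == i]
    has_e <- pt %in% rs$pts$pt_code[rs$pts$report == i]
    if (has_d && has_e) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_e) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# Exhaustive greedy-clumping oracle that re-checks every retained pair.
clump_oracle <- function(snps, ld, r2_max, window_kb) {
  r2_of <- function(s1, s2) {
    hit <- (ld$snp_i == s1 & ld$snp_j == s2) |
      (ld$snp_i == s2 & ld$snp_j == s1)
    if (any(hit)) ld$r2[which(hit)[1]] else 0
  }
  snps <- snps[order(snps$p), ]
  kept <- character(0)
  for (i in seq_len(nrow(snps))) {
    ok <- TRUE
    for (k in kept) {
      ki <- snps[snps$snp_id == k, ]
      if (identical(ki$chrom, snps$chrom[i]) &&
          abs(ki$pos - snps$pos[i]) <= window_kb * 1000 &&
          r2_of(k, snps$snp_id[i]) > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, snps$snp_id[i])
  }
  sort(kept)
}

random_contab <- function() {
  contab(sample(0:30, 1), sample(0:50, 1), sample(0:50, 1),
         sample(1:2000, 1))
}
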