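#' Semiquantitative clinical-priority score for a detected signal
#'
#' Grades a disproportionality signal on four criteria, each worth 0-2
#' points:
#' \itemize{
#'   \item clinical relevance: DME-listed event 2, IME-listed 1, neither 0;
#'   \item reporting rate (target-event reports / all reports for the drug):
#'     >= 10\% scores 2, 1\%-10\% scores 1, below 1\% scores 0;
#'   \item case fatality rate (death-outcome reports / target-event reports):
#'     > 50\% scores 2, 25\%-50\% scores 1, below 25\% scores 0;
#'   \item signal stability (disproportionality methods positive): 3 of 3
#'     scores 2, 2 of 3 scores 1, otherwise 0.
#' }
#' The total (0-8) maps to a priority category: 0-2 low, 3-5 moderate,
#' 6-8 high.
#'
#' @param clinical_relevance `"DME"`, `"IME"` or `"none"`.
#' @param reporting_rate Fraction in `[0, 1]`.
#' @param fatality_rate Fraction in `[0, 1]`.
#' @param stability Number of positive disproportionality methods (0-3).
#' @return An object of class `priority_score`: `component_points`
#'   (named integer vector), `total` and `category`.
#' @examples
#' score_priority("IME", 0.002, 0.021, 3)  # total 3, moderate
#' @export
score_priority <- function(clinical_relevance = c("none", "IME", "DME"),
                           reporting_rate, fatality_rate, stability) {
  clinical_relevance <- match.arg(clinical_relevance)
  if (!is_scalar_number(reporting_rate) || reporting_rate < 0 || reporting_rate > 1)
    stop_stage("score_priority", "reporting_rate outside [0, 1]")
  if (!is_scalar_number(fatality_rate) || fatality_rate < 0 || fatality_rate > 1)
    stop_stage("score_priority", "fatality_rate outside [0, 1]")
  stopifnot(is_scalar_number(stability), stability %in% 0:3)

  pts <- c(
    clinical_relevance = switch(clinical_relevance, DME = 2L, IME = 1L, none = 0L),
    reporting_rate = if (reporting_rate >= 0.10) 2L
                     else if (reporting_rate >= 0.01) 1L else 0L,
    fatality_rate = if (fatality_rate > 0.50) 2L
                    else if (fatality_rate >= 0.25) 1L else 0L,
    stability = if (stability == 3) 2L else if (stability == 2) 1L else 0L
  )
  total <- sum(pts)
  category <- if (total >= 6) "high" else if (total >= 3) "moderate" else "low"
  structure(list(component_points = pts, total = total, category = category),
            class = "priority_score")
}

#' @export
print.priority_score <- function(x, ...) {
  cat("Clinical priority score\n")
  for (nm in names(x$component_points))
    cat(sprintf("  %-18s %d\n", nm, x$component_points[[nm]]))
  cat(sprintf("  total %d -> %s priority\n", x$total, x$category))
  invisible(x)
}
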