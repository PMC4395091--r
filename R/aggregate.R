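#' Aggregate response records into a condition table
#'
#' Collapses response records onto the social-information conditions
#' `(n_A, n_B)`: for each condition, `R` is the number of answers observed
#' under it and `N_A` the number of those that chose A, so `N_A / R` is the
#' empirical probability of a correct answer under that condition — the
#' quantity the choice models are fitted to.
#'
#' @param records Response records as produced by [run_experiment()] or
#'   [read_responses()].
#' @param scope `"pooled"` (one table), `"per_question"` (adds a
#'   `question_id` column), or `"per_r"` (adds an `r_condition` column).
#' @param include_r0 Keep the private-answer records (`r = 0`, condition
#'   `(0, 0)`)? They carry the information about the prior odds `p`; default
#'   `TRUE`.
#' @param include_sentinel Keep records from the all-predecessors round
#'   (`r = Inf`), entered under their literal observed counts? Default
#'   `TRUE`.
#' @param min_R Drop conditions observed fewer than `min_R` times
#'   (default 1, i.e. no filtering).
#' @return A data.frame with columns `n_A`, `n_B`, `R`, `N_A`, `fraction`
#'   (plus the scope column), ordered by condition.
#' @examples
#' sim <- run_experiment(protocol_config("D1", n_questions = 5), seed = 1)
#' head(aggregate_conditions(sim$records))
#' @export
aggregate_conditions <- function(records,
                                 scope = c("pooled", "per_question", "per_r"),
                                 include_r0 = TRUE, include_sentinel = TRUE,
                                 min_R = 1L) {
  scope <- match.arg(scope)
  check_records(records)
  if (!include_r0) records <- records[records$r_condition != 0, , drop = FALSE]
  if (!include_sentinel) {
    records <- records[is.finite(records$r_condition), , drop = FALSE]
  }
  if (nrow(records) == 0) {
    out <- data.frame(n_A = integer(0), n_B = integer(0), R = integer(0),
                      N_A = integer(0), fraction = numeric(0))
    return(out)
  }
  key_cols <- switch(scope,
    pooled = list(n_A = records$n_A_observed, n_B = records$n_B_observed),
    per_question = list(question_id = records$question_id,
                        n_A = records$n_A_observed, n_B = records$n_B_observed),
    per_r = list(r_condition = records$r_condition,
                 n_A = records$n_A_observed, n_B = records$n_B_observed)
  )
  tab <- stats::aggregate(
    cbind(R = rep(1L, nrow(records)), N_A = as.integer(records$answer == "A")),
    by = key_cols, FUN = sum
  )
  tab$fraction <- tab$N_A / tab$R
  tab <- tab[tab$R >= min_R, , drop = FALSE]
  ord <- switch(scope,
    pooled = order(tab$n_A + tab$n_B, tab$n_A),
    per_question = order(tab$question_id, tab$n_A + tab$n_B, tab$n_A),
    per_r = order(tab$r_condition, tab$n_A)
  )
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Tabulate correct-answer fractions against the fraction of A answers
#'
#' Builds the table used to test Weber's law: records are grouped by finite
#' information condition `r >= 1`, and within each group by the exact
#' fraction `x = n_A / (n_A + n_B)` of correct answers among those observed.
#' If choice probabilities depended on `x` only (Weber's law), the per-`r`
#' curves would coincide.
#'
#' @inheritParams aggregate_conditions
#' @param include_sentinel Include the all-predecessors round? Default
#'   `FALSE` because its effective `r` varies with the subject's label.
#' @return A data.frame with columns `r`, `x`, `R`, `N_A`, `fraction`.
#' @export
weber_table <- function(records, include_sentinel = FALSE) {
  check_records(records)
  keep <- records$r_condition >= 1 &
    (include_sentinel | is.finite(records$r_condition))
  records <- records[keep, , drop = FALSE]
  # x is undefined when non-response left a subject with nothing to observe
  tot <- records$n_A_observed + records$n_B_observed
  records <- records[tot > 0, , drop = FALSE]
  if (nrow(records) == 0) {
    return(data.frame(r = numeric(0), x = numeric(0), R = integer(0),
                      N_A = integer(0), fraction = numeric(0)))
  }
  x <- records$n_A_observed / (records$n_A_observed + records$n_B_observed)
  tab <- stats::aggregate(
    cbind(R = rep(1L, nrow(records)), N_A = as.integer(records$answer == "A")),
    by = list(r = records$r_condition, x = x), FUN = sum
  )
  tab$fraction <- tab$N_A / tab$R
  tab <- tab[order(tab$r, tab$x), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

record_columns <- c("dataset_id", "question_id", "round_index", "r_condition",
                    "subject_label", "n_A_observed", "n_B_observed", "answer")

check_records <- function(records) {
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    stop("response records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}
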