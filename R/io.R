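#' Read and write response-record CSV files
#'
#' Response records are exchanged as plain UTF-8 CSV with header
#' `dataset_id,question_id,round_index,r_condition,subject_label,
#' n_A_observed,n_B_observed,answer`; the all-predecessors round is written
#' as the literal `r_condition` value `"inf"` and read back as `Inf`.
#' Ground truths use header `question_id,p_q,s_q`.
#'
#' @param records Response records data.frame.
#' @param path File path.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   the records data.frame. Malformed files raise errors naming the missing
#'   column or offending line.
#' @export
write_responses <- function(records, path) {
  check_records(records)
  out <- records[record_columns]
  out$r_condition <- ifelse(is.infinite(out$r_condition), "inf",
                            format(out$r_condition, trim = TRUE,
                                   scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(record_columns, names(df))
  if (length(missing)) {
    stop("response CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no data: response CSV has no rows", call. = FALSE)
  df$r_condition[df$r_condition == "inf"] <- "Inf"
  for (col in c("round_index", "r_condition", "subject_label",
                "n_A_observed", "n_B_observed")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      # +1 for the header line
      stop(sprintf("malformed value in column %s at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- !df$answer %in% c("A", "B")
  if (any(bad)) {
    stop(sprintf("malformed answer at line %d of %s (must be A or B)",
                 which(bad)[1] + 1L, path), call. = FALSE)
  }
  int_cols <- c("round_index", "subject_label", "n_A_observed", "n_B_observed")
  df[int_cols] <- lapply(df[int_cols], as.integer)
  df
}

#' @rdname write_responses
#' @param truths Ground-truth data.frame (`question_id`, `p_q`, `s_q`).
#' @export
write_truths <- function(truths, path) {
  utils::write.csv(truths[c("question_id", "p_q", "s_q")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_truths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("question_id", "p_q", "s_q"), names(df))
  if (length(missing)) {
    stop("truth CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname write_responses
#' @param table Condition table or Weber table.
#' @export
write_condition_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_condition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_condition_table(df)
  df
}
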