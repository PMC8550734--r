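# Dataset readers and writers. The CSV dialect matches the deposited
# benchmark files (3ps.csv family): comma-separated UTF-8 with header
# columns id, sequence, task, response_type, choices, response, condition.
# Loading such external files is optional; all tests run on generated data.

.DATASET_COLS <- c("id", "sequence", "task", "response_type", "choices",
                   "response", "condition")

#' Read a benchmark dataset CSV
#'
#' Validates every row: the task string must parse, `response_type` must be
#' `verify` or `single-choice`, and a non-empty response must match the
#' response type (True/False for verification, one of the offered choices
#' otherwise). Errors name the offending row and column.
#'
#' @param path CSV file path.
#' @return A dataset data frame (character columns except `sequence`).
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(.DATASET_COLS, names(raw))
  if (length(missing) > 0L)
    stop("dataset ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty dataset: ", path, call. = FALSE)
    out <- data.frame(matrix(character(0L), ncol = length(.DATASET_COLS)),
                      stringsAsFactors = FALSE)
    names(out) <- .DATASET_COLS
    out$sequence <- integer(0L)
    return(out)
  }
  raw <- raw[, .DATASET_COLS]
  raw$sequence <- as.integer(raw$sequence)
  validate_dataset(raw)
  raw
}

validate_dataset <- function(df) {
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$response_type %in% c("verify", "single-choice"))
      stop("row ", i, ", column response_type: unknown value '",
           row$response_type, "'", call. = FALSE)
    p <- tryCatch(row_problem(row), error = function(e)
      stop("row ", i, ", column task: ", conditionMessage(e), call. = FALSE))
    if (nzchar(row$response)) {
      ok <- if (row$response_type == "verify")
        row$response %in% c("True", "False")
      else row$response %in% vapply(p$choices, format_premise, character(1L))
      if (!ok)
        stop("row ", i, ", column response: '", row$response,
             "' does not match response_type '", row$response_type, "'",
             call. = FALSE)
    }
  }
  seqs <- split(df$sequence, df$id)
  bad <- names(seqs)[!vapply(seqs, function(s) all(diff(s) > 0L), logical(1L))]
  if (length(bad) > 0L)
    stop("non-increasing sequence numbers for participant(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' @rdname read_dataset
#' @param dataset A dataset data frame.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset[, .DATASET_COLS], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
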