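# Reference models bracketing cognitive-model performance: Random (lower
# bound), MFA (aggregate ceiling for participant-independent models),
# TransitiveClosure (pure logic), BestModel (per-participant model selection)
# and Optimal (per-trial union of a model pool).

response_options <- function(problem) {
  if (problem$task_type == "verification") c("True", "False")
  else vapply(problem$choices, format_premise, character(1L))
}

#' Random baseline
#'
#' Draws uniformly among the possible responses (True/False for verification,
#' the offered choices otherwise) from the current RNG stream, so runs are
#' reproducible under a seed.
#'
#' @return A `spatial_model`.
#' @export
random_model <- function() {
  structure(list(name = "random"), class = c("random_model", "spatial_model"))
}

#' @export
predict.random_model <- function(object, problem, ...) {
  opts <- response_options(problem)
  opts[sample.int(length(opts), 1L)]
}

#' Transitive-closure baseline
#'
#' A purely logical model driven by the oracle: a verification item is
#' accepted iff the conclusion (or arrangement) is jointly consistent with
#' the premises; on single-choice items one of the logically possible choices
#' is selected uniformly at random (so on fully indeterminate problems it
#' guesses among all options).
#'
#' @return A `spatial_model`.
#' @export
closure_model <- function() {
  structure(list(name = "closure"),
            class = c("closure_model", "spatial_model"))
}

#' @export
predict.closure_model <- function(object, problem, ...) {
  if (problem$task_type == "verification") {
    ok <- premises_consistent(c(problem$premises, problem$conclusion))
    if (ok) "True" else "False"
  } else {
    ok <- vapply(problem$choices, function(ch)
      premises_consistent(c(problem$premises, list(ch))), logical(1L))
    idx <- which(ok)
    if (length(idx) == 0L) idx <- seq_along(problem$choices)
    pick <- idx[sample.int(length(idx), 1L)]
    format_premise(problem$choices[[pick]])
  }
}

#' Most-frequent-answer baseline
#'
#' Counts, in the pre-training data, how often each response was given to
#' each problem (problem identity includes premise presentation order) and
#' predicts the most frequent one; ties go to the lexicographically smaller
#' encoded response, unseen problems fall back to a random draw among the
#' options.
#'
#' @return A `spatial_model`.
#' @export
mfa_model <- function() {
  structure(list(name = "mfa", table = list()),
            class = c("mfa_model", "spatial_model"))
}

mfa_key <- function(row) paste(row$task, row$response_type, row$choices,
                               sep = "||")

#' @export
pre_train.mfa_model <- function(model, dataset) {
  tab <- model$table
  for (i in seq_len(nrow(dataset))) {
    k <- mfa_key(dataset[i, ])
    r <- dataset$response[i]
    if (is.null(tab[[k]])) tab[[k]] <- integer(0L)
    tab[[k]][r] <- if (is.na(tab[[k]][r])) 1L else tab[[k]][r] + 1L
  }
  model$table <- tab
  model
}

#' @export
predict.mfa_model <- function(object, problem, ...) {
  k <- paste(format_task(problem),
             if (problem$task_type == "verification") "verify"
             else "single-choice",
             format_choices(problem), sep = "||")
  counts <- object$table[[k]]
  if (is.null(counts) || length(counts) == 0L) {
    opts <- response_options(problem)
    return(opts[sample.int(length(opts), 1L)])
  }
  top <- names(counts)[counts == max(counts)]
  sort(top)[1L]
}

#' BestModel baseline
#'
#' Selects, for each participant, the pool model with the highest accuracy on
#' that participant's own trials (the coverage data; ties resolved by pool
#' order) and answers with the selected model.
#'
#' @param pool List of `spatial_model`s (or registry names).
#' @return A `spatial_model`.
#' @export
best_model <- function(pool) {
  pool <- resolve_pool(pool)
  structure(list(name = "best", pool = pool, selected = NULL),
            class = c("best_model", "spatial_model")
  )
}

resolve_pool <- function(pool) {
  stopifnot(length(pool) >= 1L)
  lapply(pool, function(m) if (is.character(m)) make_model(m) else m)
}

#' @export
pre_train.best_model <- function(model, dataset) {
  model$pool <- lapply(model$pool, pre_train, dataset = dataset)
  model
}

#' @export
fit_person.best_model <- function(model, trials) {
  model$pool <- lapply(model$pool, fit_person, trials = trials)
  accs <- vapply(model$pool, model_accuracy, numeric(1L), trials = trials)
  model$selected <- model$pool[[which.max(accs)]]  # tie -> pool order
  model
}

#' @export
predict.best_model <- function(object, problem, ...) {
  sel <- if (is.null(object$selected)) object$pool[[1L]] else object$selected
  model_predict(sel, problem)
}

#' @export
model_name.best_model <- function(model) "best"

#' Optimal baseline
#'
#' The per-trial union of a model pool: its prediction counts as correct iff
#' at least one pool model predicts the recorded response. As a standalone
#' model its prediction for a problem is the first pool model's; inside
#' [coverage()] its correctness is computed from the pool's predictions.
#'
#' @param pool List of `spatial_model`s (or registry names).
#' @return A `spatial_model`.
#' @export
optimal_model <- function(pool) {
  pool <- resolve_pool(pool)
  structure(list(name = "optimal", pool = pool),
            class = c("optimal_model", "spatial_model"))
}

#' @export
pre_train.optimal_model <- function(model, dataset) {
  model$pool <- lapply(model$pool, pre_train, dataset = dataset)
  model
}

#' @export
fit_person.optimal_model <- function(model, trials) {
  model$pool <- lapply(model$pool, fit_person, trials = trials)
  model
}

#' @export
predict.optimal_model <- function(object, problem, ...) {
  model_predict(object$pool[[1L]], problem)
}

#' Score a trial against a model pool
#'
#' @param pool List of fitted `spatial_model`s.
#' @param trial A single dataset row with a recorded response.
#' @return `"correct"` iff at least one pool model predicts the response,
#'   else `"incorrect"`.
#' @export
optimal_score <- function(pool, trial) {
  stopifnot(nrow(trial) == 1L, nzchar(trial$response))
  p <- row_problem(trial)
  hit <- any(vapply(pool, function(m)
    identical(model_predict(m, p), trial$response), logical(1L)))
  if (hit) "correct" else "incorrect"
}
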