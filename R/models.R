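# Common surface for all cognitive models and baselines. Every model is an S3
# object inheriting from "spatial_model" and implements predict(); optional
# methods pre_train() (fit on other participants' data) and fit_person()
# (fit on the target participant's own trials) default to no-ops, matching
# the coverage protocol's two fitting phases.

#' Model fitting phases
#'
#' `pre_train()` offers a model the trials of all *other* participants;
#' `fit_person()` offers it the target participant's own trial-response pairs
#' (the coverage setting). Both return a (possibly updated) model; models
#' without free parameters return themselves unchanged.
#'
#' @param model A `spatial_model`.
#' @param dataset,trials Data frames in the dataset dialect (see
#'   [read_dataset()]).
#' @return The updated model.
#' @export
pre_train <- function(model, dataset) UseMethod("pre_train")

#' @rdname pre_train
#' @export
pre_train.spatial_model <- function(model, dataset) model

#' @rdname pre_train
#' @export
fit_person <- function(model, trials) UseMethod("fit_person")

#' @rdname pre_train
#' @export
fit_person.spatial_model <- function(model, trials) model

#' @export
print.spatial_model <- function(x, ...) {
  cat("<spatial_model: ", model_name(x), ">\n", sep = "")
  invisible(x)
}

#' Name of a model as used in registries and result tables
#'
#' @param model A `spatial_model`.
#' @return A short name such as `"prism"` or `"sr-credulous"`.
#' @export
model_name <- function(model) UseMethod("model_name")

#' @export
model_name.spatial_model <- function(model) model$name

# Cache key for deterministic per-problem predictions, or NULL if the model's
# prediction for this problem may be stochastic or training-dependent.
predict_cache_key <- function(model, problem) UseMethod("predict_cache_key")

#' @export
predict_cache_key.default <- function(model, problem) NULL

# Central prediction entry point with memoisation of deterministic models.
model_predict <- function(model, problem) {
  key <- predict_cache_key(model, problem)
  if (is.null(key)) return(predict(model, problem))
  cached(paste("pred", key, problem_key(problem), sep = "|"),
         predict(model, problem))
}

# Parse a dataset row's problem, memoised by its textual identity.
row_problem <- function(row) {
  key <- paste("prob", row$response_type, row$task, row$choices, sep = "|")
  cached(key, parse_task(row$task, row$response_type, row$choices))
}

# Accuracy of a model on a set of trials (data-frame rows with responses).
model_accuracy <- function(model, trials) {
  if (nrow(trials) == 0L) return(NA_real_)
  ok <- vapply(seq_len(nrow(trials)), function(i) {
    identical(model_predict(model, row_problem(trials[i, ])),
              trials$response[i])
  }, logical(1L))
  mean(ok)
}

#' Construct a model by registry name
#'
#' Known names: `random`, `mfa`, `closure`, `best`, `optimal`, `prism`,
#' `verbal`, `sr-skeptical`, `sr-credulous`, `sr-initial`, `sr-adapted`.
#'
#' @param name Registry name.
#' @param ... Passed to the model constructor.
#' @return A `spatial_model`.
#' @export
#' @examples
#' make_model("prism", strategy = "ff", variation_depth = 0)
make_model <- function(name, ...) {
  ctor <- switch(name,
    "random"        = random_model,
    "mfa"           = mfa_model,
    "closure"       = closure_model,
    "best"          = best_model,
    "optimal"       = optimal_model,
    "prism"         = prism_model,
    "verbal"        = verbal_model,
    "sr-skeptical"  = function(...) spatial_reasoner("skeptical", ...),
    "sr-credulous"  = function(...) spatial_reasoner("credulous", ...),
    "sr-initial"    = function(...) spatial_reasoner("initial", ...),
    "sr-adapted"    = function(...) spatial_reasoner("adapted", ...),
    stop("unknown model name: '", name, "'. Registered models: ",
         paste(registered_models(), collapse = ", "), call. = FALSE)
  )
  ctor(...)
}

#' @rdname make_model
#' @export
registered_models <- function() {
  c("random", "mfa", "closure", "best", "optimal", "prism", "verbal",
    "sr-skeptical", "sr-credulous", "sr-initial", "sr-adapted")
}
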