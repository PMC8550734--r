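# Coverage-style individual-level evaluation: for every participant, models
# are pre-trained on all other participants' data, then fitted on the target
# participant's own trial-response pairs, and finally asked to predict those
# very trials in presentation order. Only the two pre-training phases are
# used; the trial-by-trial adaption hook exists in the interface but no model
# in this package uses it.

#' Run a coverage evaluation
#'
#' @param dataset A dataset data frame (see [read_dataset()] or
#'   [generate_dataset()]) in which every trial has a response.
#' @param models Character vector of registry names and/or a list of
#'   `spatial_model` objects. `"best"` and `"optimal"` may be requested by
#'   name; their pool defaults to the cognitive models of the run (PRISM,
#'   verbal, SpatialReasoner variants) and can be overridden via `pool`.
#' @param seed Run seed; every stochastic model draws from a stream derived
#'   from the seed, the model and the participant id, so participant order
#'   does not affect results.
#' @param pool Optional pool (names or models) for BestModel/Optimal.
#' @return An object of class `coverage_result` with elements `predictions`
#'   (long data frame: model, id, sequence, condition, prediction, truth,
#'   correct), `accuracy` (per model x participant), `summary` (per-model
#'   median and MAD of participant accuracies, percent scale), and
#'   `co_optimality` (square matrix, see [co_optimality()]).
#' @export
#' @examples
#' d <- generate_dataset("figural", 3, closure_model(), 0, seed = 2)
#' r <- coverage(d, c("closure", "mfa"), seed = 2)
#' summary(r)
coverage <- function(dataset, models, seed = 1L, pool = NULL) {
  stopifnot(nrow(dataset) > 0L)
  validate_dataset(dataset)
  if (any(!nzchar(dataset$response)))
    stop("coverage requires a response for every trial", call. = FALSE)

  specs <- list()
  for (m in models) {
    if (is.character(m)) {
      if (m %in% c("best", "optimal")) {
        specs[[m]] <- m  # resolved below, needs the pool
      } else specs[[m]] <- make_model(m)
    } else specs[[model_name(m)]] <- m
  }
  cognitive <- c("prism", "verbal", "sr-skeptical", "sr-credulous",
                 "sr-initial", "sr-adapted")
  if (is.null(pool)) pool <- intersect(names(specs), cognitive)
  pool_names <- vapply(pool, function(m)
    if (is.character(m)) m else model_name(m), character(1L))
  if (any(c("best", "optimal") %in% names(specs)) && length(pool) == 0L)
    stop("best/optimal requested but the pool is empty", call. = FALSE)

  participants <- unique(dataset$id)
  rows <- list()
  for (mname in names(specs)) {
    if (mname %in% c("best", "optimal")) next
    proto <- specs[[mname]]
    for (p in participants) {
      person <- dataset[dataset$id == p, , drop = FALSE]
      person <- person[order(person$sequence), , drop = FALSE]
      if (nrow(person) == 0L) {
        warning("participant ", p, " has no trials; skipped", call. = FALSE)
        next
      }
      set.seed(block_seed(seed, mname, p))
      m <- pre_train(proto, dataset[dataset$id != p, , drop = FALSE])
      m <- fit_person(m, person)
      preds <- vapply(seq_len(nrow(person)), function(i)
        model_predict(m, row_problem(person[i, ])), character(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mname, id = p, sequence = person$sequence,
        task = person$task, condition = person$condition,
        prediction = preds, truth = person$response,
        correct = preds == person$response, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)

  # BestModel: per participant, adopt the pool model with the best accuracy
  if ("best" %in% names(specs)) {
    best_rows <- lapply(participants, function(p) {
      sub <- long[long$id == p & long$model %in% pool_names, , drop = FALSE]
      accs <- vapply(pool_names, function(mn)
        mean(sub$correct[sub$model == mn]), numeric(1L))
      chosen <- pool_names[which.max(accs)]
      out <- sub[sub$model == chosen, , drop = FALSE]
      out$model <- "best"
      attr(out, "chosen") <- chosen
      out
    })
    chosen_by <- vapply(best_rows, attr, character(1L), which = "chosen")
    names(chosen_by) <- participants
    long <- rbind(long, do.call(rbind, best_rows))
  } else chosen_by <- NULL

  # Optimal: correct on a trial iff any pool model is correct there
  if ("optimal" %in% names(specs)) {
    opt_rows <- lapply(participants, function(p) {
      sub <- long[long$id == p & long$model %in% pool_names, , drop = FALSE]
      base <- sub[sub$model == pool_names[1L], , drop = FALSE]
      key <- base$sequence
      ok <- vapply(key, function(s) any(sub$correct[sub$sequence == s]),
                   logical(1L))
      hitm <- vapply(key, function(s) {
        hits <- sub$model[sub$sequence == s & sub$correct]
        if (length(hits) > 0L) hits[1L] else pool_names[1L]
      }, character(1L))
      pred <- vapply(seq_along(key), function(i)
        sub$prediction[sub$sequence == key[i] & sub$model == hitm[i]][1L],
        character(1L))
      base$model <- "optimal"; base$prediction <- pred; base$correct <- ok
      base
    })
    long <- rbind(long, do.call(rbind, opt_rows))
  }
  rownames(long) <- NULL

  acc <- stats::aggregate(correct ~ model + id, data = long, FUN = mean)
  names(acc)[names(acc) == "correct"] <- "accuracy"
  res <- structure(
    list(predictions = long, accuracy = acc,
         summary = coverage_summary_table(long, acc),
         co_optimality = co_optimality_matrix_from(long),
         pool = pool_names, chosen_by = chosen_by, seed = seed),
    class = "coverage_result")
  res
}

coverage_summary_table <- function(long, acc) {
  per_model <- do.call(rbind, lapply(split(acc, acc$model), function(g) {
    med <- stats::median(g$accuracy)
    data.frame(model = g$model[1L],
               median_pct = 100 * med,
               mad_pct = 100 * stats::median(abs(g$accuracy - med)),
               n_participants = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per_model) <- NULL
  per_cond <- NULL
  if (!is.null(long$condition) && any(nzchar(long$condition))) {
    long$cond_base <- sub("[-:].*$", "", long$condition)
    agg <- stats::aggregate(correct ~ model + cond_base, data = long,
                            FUN = mean)
    names(agg) <- c("model", "condition", "mean_accuracy")
    per_cond <- agg
  }
  list(per_model = per_model, per_condition = per_cond)
}

co_optimality_matrix_from <- function(long) {
  models <- unique(long$model)
  wide <- lapply(models, function(mn) {
    sub <- long[long$model == mn, , drop = FALSE]
    sub$correct[order(sub$id, sub$sequence)]
  })
  names(wide) <- models
  n <- length(models)
  m <- matrix(NA_real_, n, n, dimnames = list(models, models))
  for (i in models) for (j in models) {
    ci <- wide[[i]]; cj <- wide[[j]]
    if (any(ci)) m[i, j] <- mean(cj[ci])
  }
  m
}

#' Co-optimality between two evaluated models
#'
#' Among the trials on which `model_i` predicted the participant's response
#' correctly, the fraction on which `model_j` did too. Not symmetric; `NA`
#' when `model_i` was never correct; 1 on the diagonal whenever the model has
#' at least one correct prediction.
#'
#' @param result A `coverage_result`.
#' @param model_i,model_j Model names present in the result.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
co_optimality <- function(result, model_i, model_j) {
  m <- result$co_optimality
  if (!model_i %in% rownames(m) || !model_j %in% rownames(m))
    stop("model not present in the result", call. = FALSE)
  m[model_i, model_j]
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result> ", length(unique(x$predictions$id)),
      " participants, ", length(unique(x$predictions$model)),
      " models, seed ", x$seed, "\n", sep = "")
  print(x$summary$per_model, row.names = FALSE)
  invisible(x)
}

#' @export
summary.coverage_result <- function(object, ...) {
  object$summary
}

#' @export
plot.coverage_result <- function(x, type = c("accuracy", "co_optimality"),
                                 ...) {
  type <- match.arg(type)
  if (type == "accuracy") {
    acc <- x$accuracy
    graphics::boxplot(accuracy ~ model, data = acc, las = 2,
                      ylab = "predictive accuracy", xlab = "", ...)
  } else {
    m <- x$co_optimality
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                    t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1), ...)
    graphics::axis(1L, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
    graphics::axis(2L, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 1)
  }
  invisible(x)
}
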