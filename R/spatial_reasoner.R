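# Coordinate-based mental-model reasoner: incremental first-free construction
# of an initial model, classification of a putative premise into four validity
# outcomes, and four prediction policies (skeptical, credulous, initial,
# adapted).

# Place a term by scanning from a reference cell in a unit direction until the
# first free cell. `occ` is a named character vector keyed "x,y".
scan_free <- function(occ, from, dir) {
  cell <- from + dir
  while (!is.null(occ[[paste(cell, collapse = ",")]])) cell <- cell + dir
  cell
}

#' Build the initial coordinate model of a premise set
#'
#' The first term of the first premise is placed at the origin; every further
#' term is placed at the first free lattice cell scanning outward from its
#' reference term in the premise direction. Premises sharing no term with the
#' model so far are buffered and integrated once linkable. The z coordinate is
#' carried along but always 0 for the 1D/2D tasks handled here.
#'
#' @param premises List of [premise()] triples.
#' @return A list with `coords` (integer matrix, rownames = terms, columns
#'   x/y/z), `order` (insertion order of terms) and `consistent` (FALSE when a
#'   premise with both terms already placed contradicts the premises so far
#'   and no alternative model exists).
#' @export
#' @examples
#' sr_build_model(list(premise("left", "A", "B"), premise("right", "C", "B")))$coords
sr_build_model <- function(premises) {
  key <- paste("srbuild", premises_key(premises), sep = "|")
  cached(key, {
    pos <- list()            # term -> c(x, y)
    occ <- list()            # "x,y" -> term
    ord <- character(0L)
    consistent <- TRUE
    place <- function(term, cell) {
      pos[[term]] <<- cell
      occ[[paste(cell, collapse = ",")]] <<- term
      ord <<- c(ord, term)
    }
    integrate_one <- function(p) {
      v <- encode_relation(p$rel)$vec
      s_in <- !is.null(pos[[p$s]]); o_in <- !is.null(pos[[p$o]])
      if (!s_in && !o_in) {
        start <- c(0L, 0L)
        if (!is.null(occ[["0,0"]])) start <- scan_free(occ, start, c(1L, 0L))
        place(p$s, start)
        place(p$o, scan_free(occ, pos[[p$s]], -v))
      } else if (o_in && !s_in) {
        place(p$s, scan_free(occ, pos[[p$o]], v))
      } else if (s_in && !o_in) {
        place(p$o, scan_free(occ, pos[[p$s]], -v))
      } else {
        d <- pos[[p$s]] - pos[[p$o]]
        if (!all(sign(d) == v)) {
          # direct contradiction with the current model; acceptable only if
          # some alternative model of all premises seen so far exists
          seen <- premises[seq_len(which_premise)]
          if (!premises_consistent(seen)) consistent <<- FALSE
        }
      }
    }
    buffer <- list()
    which_premise <- 0L
    for (p in premises) {
      which_premise <- which_premise + 1L
      if (length(pos) > 0L && is.null(pos[[p$s]]) && is.null(pos[[p$o]])) {
        buffer[[length(buffer) + 1L]] <- p
      } else {
        integrate_one(p)
      }
      repeat {
        linkable <- vapply(buffer, function(b)
          !is.null(pos[[b$s]]) || !is.null(pos[[b$o]]), logical(1L))
        if (!any(linkable)) break
        i <- which(linkable)[1L]
        integrate_one(buffer[[i]])
        buffer[[i]] <- NULL
      }
    }
    for (b in buffer) integrate_one(b)  # fully disconnected leftovers
    coords <- do.call(rbind, pos[ord])
    coords <- cbind(coords, 0L)
    dimnames(coords) <- list(ord, c("x", "y", "z"))
    list(coords = coords, order = ord, consistent = consistent)
  })
}

#' Classify a putative premise against premises integrated so far
#'
#' The four outcomes of premise integration: `truth` (the putative assertion
#' holds in every model of the premises), `falsity` (in none),
#' `weak_falsification` (holds in the deterministically constructed initial
#' model but not in all models, i.e. initially appeared valid but can be
#' refuted), and `weak_truthification` (fails in the initial model, but
#' reinterpreting the premises yields some model in which it holds).
#'
#' @param premises List of premises integrated so far.
#' @param putative A premise whose terms occur in `premises`.
#' @return One of `"truth"`, `"falsity"`, `"weak_falsification"`,
#'   `"weak_truthification"`.
#' @export
#' @examples
#' sr_integrate(list(premise("left", "A", "B"), premise("left", "A", "C")),
#'              premise("left", "B", "C"))  # "weak_falsification"
sr_integrate <- function(premises, putative) {
  terms <- premise_terms(premises)
  if (!all(c(putative$s, putative$o) %in% terms))
    stop("putative premise term not in the premises: ",
         setdiff(c(putative$s, putative$o), terms)[1L], call. = FALSE)
  key <- paste("srint", premises_key(premises), format_premise(putative),
               sep = "|")
  cached(key, {
    models <- enumerate_models(premises)
    if (length(models) == 0L) return("falsity")
    holds <- vapply(models, holds_in_model, logical(1L), p = putative)
    if (all(holds)) return("truth")
    if (!any(holds)) return("falsity")
    init <- sr_build_model(premises)
    d <- init$coords[putative$s, 1:2] - init$coords[putative$o, 1:2]
    in_initial <- all(sign(d) == encode_relation(putative$rel)$vec)
    if (in_initial) "weak_falsification" else "weak_truthification"
  })
}

sr_accepted_outcomes <- function(variant) {
  switch(variant,
    skeptical = "truth",
    credulous = c("truth", "weak_falsification", "weak_truthification"),
    initial   = c("truth", "weak_falsification"),
    stop("no accepted-outcome set for variant '", variant, "'", call. = FALSE)
  )
}

#' The SpatialReasoner model family
#'
#' A predictive model built on [sr_integrate()]'s four validity outcomes.
#' `skeptical` accepts only conclusions that necessarily follow; `credulous`
#' accepts everything that can possibly follow; `initial` accepts what holds
#' in the initial model; `adapted` selects, per participant, whichever of the
#' three fits that participant's responses best (ties resolved in the order
#' skeptical, initial, credulous).
#'
#' @param variant `"skeptical"`, `"credulous"`, `"initial"`, or `"adapted"`.
#' @return A `spatial_model` of class `sr_model`.
#' @export
#' @examples
#' m <- spatial_reasoner("credulous")
#' p <- parse_task("left;A;B/left;A;C", "verify", "left;B;C")
#' predict(m, p)
spatial_reasoner <- function(variant = c("adapted", "skeptical", "credulous",
                                         "initial")) {
  variant <- match.arg(variant)
  structure(
    list(name = paste0("sr-", variant), variant = variant,
         fitted_variant = NULL),
    class = c("sr_model", "spatial_model")
  )
}

sr_effective_variant <- function(model) {
  if (model$variant != "adapted") model$variant
  else if (!is.null(model$fitted_variant)) model$fitted_variant
  else "skeptical"
}

#' @export
predict_cache_key.sr_model <- function(model, problem) {
  paste("sr", sr_effective_variant(model), sep = "|")
}

#' @export
predict.sr_model <- function(object, problem, ...) {
  variant <- sr_effective_variant(object)
  accepted <- sr_accepted_outcomes(variant)
  if (problem$task_type == "verification") {
    # arrangement verification treats the assertions as sequential putative
    # premises; all of them must be accepted
    prems <- problem$premises
    for (concl in problem$conclusion) {
      out <- sr_integrate(prems, concl)
      if (!out %in% accepted) return("False")
      prems <- c(prems, list(concl))
    }
    "True"
  } else {
    outcomes <- vapply(problem$choices, function(ch)
      sr_integrate(problem$premises, ch), character(1L))
    i <- which(outcomes == "truth")
    if (length(i) == 0L) i <- which(outcomes %in% accepted)
    if (length(i) == 0L) i <- 1L
    format_premise(problem$choices[[i[1L]]])
  }
}

#' @rdname spatial_reasoner
#' @param model An `sr_model` with `variant = "adapted"`.
#' @param trials A participant's trials (dataset rows with responses).
#' @export
fit_person.sr_model <- function(model, trials) {
  if (model$variant != "adapted") return(model)
  if (is.null(trials) || nrow(trials) == 0L) {
    model$fitted_variant <- "skeptical"
    return(model)
  }
  order <- c("skeptical", "initial", "credulous")  # tie-break order
  accs <- vapply(order, function(v) {
    model_accuracy(spatial_reasoner(v), trials)
  }, numeric(1L))
  model$fitted_variant <- order[which.max(accs)]
  model
}
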