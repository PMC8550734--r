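# Qualitative spatial vocabulary shared by every model: relation names, their
# integer vector encodings, converses, and the task-string dialect.

# Coordinate frame: x grows rightward/eastward, y grows northward.
.VOCAB_1D <- c(left = -1L, right = 1L)

.VOCAB_CARDINAL <- list(
  "north"      = c(0L,  1L),
  "north-east" = c(1L,  1L),
  "east"       = c(1L,  0L),
  "south-east" = c(1L, -1L),
  "south"      = c(0L, -1L),
  "south-west" = c(-1L, -1L),
  "west"       = c(-1L,  0L),
  "north-west" = c(-1L,  1L)
)

#' Relation vocabularies
#'
#' The package works with two disjoint qualitative vocabularies: the
#' one-dimensional relations `left`/`right` and the eight cardinal direction
#' relations. Even though e.g. `left` and `west` share the encoding `(-1, 0)`,
#' a problem always declares which vocabulary it uses.
#'
#' @param vocabulary `"1D"` or `"cardinal"`.
#' @return Character vector of relation names in canonical order.
#' @export
#' @examples
#' relation_names("cardinal")
relation_names <- function(vocabulary = c("1D", "cardinal")) {
  vocabulary <- match.arg(vocabulary)
  if (vocabulary == "1D") names(.VOCAB_1D) else names(.VOCAB_CARDINAL)
}

#' Encode a relation name as a signed integer vector
#'
#' Each relation constrains both axes exactly: "A north B" means the x
#' coordinates are equal and A's y coordinate is strictly larger ("exact-axis"
#' semantics). The encoding is the sign pattern `(dx, dy)` of
#' `position(subject) - position(object)`.
#'
#' @param name Relation name.
#' @param vocabulary `"1D"` or `"cardinal"`; if missing it is inferred from the
#'   name (names are unambiguous across the two vocabularies).
#' @return A list with elements `name`, `vec` (integer 2-vector) and
#'   `vocabulary`.
#' @export
#' @examples
#' encode_relation("south-east")$vec  # c(1, -1)
encode_relation <- function(name, vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- if (name %in% names(.VOCAB_1D)) "1D"
      else if (name %in% names(.VOCAB_CARDINAL)) "cardinal"
      else stop("unknown relation name: '", name, "'", call. = FALSE)
  }
  vec <- switch(vocabulary,
    "1D" = {
      if (!name %in% names(.VOCAB_1D))
        stop("unknown 1D relation: '", name, "'", call. = FALSE)
      c(.VOCAB_1D[[name]], 0L)
    },
    "cardinal" = {
      if (!name %in% names(.VOCAB_CARDINAL))
        stop("unknown cardinal relation: '", name, "'", call. = FALSE)
      .VOCAB_CARDINAL[[name]]
    },
    stop("unknown vocabulary: ", vocabulary, call. = FALSE)
  )
  list(name = name, vec = vec, vocabulary = vocabulary)
}

#' @rdname encode_relation
#' @param vec Integer 2-vector of axis signs, not both zero.
#' @export
decode_relation <- function(vec, vocabulary = c("1D", "cardinal")) {
  vocabulary <- match.arg(vocabulary)
  stopifnot(length(vec) == 2L, !all(vec == 0L))
  if (vocabulary == "1D") {
    if (vec[2L] != 0L || vec[1L] == 0L)
      stop("vector ", paste(vec, collapse = ","),
           " has no 1D relation name", call. = FALSE)
    return(if (vec[1L] < 0L) "left" else "right")
  }
  for (nm in names(.VOCAB_CARDINAL))
    if (all(.VOCAB_CARDINAL[[nm]] == vec)) return(nm)
  stop("vector has no cardinal name", call. = FALSE)  # unreachable
}

#' Converse of a relation
#'
#' Mirrors a relation through the origin within its own vocabulary:
#' `converse("north-east") == "south-west"`. An involution.
#'
#' @param name Relation name.
#' @param vocabulary Optional vocabulary, inferred from the name by default.
#' @return The converse relation name.
#' @export
converse_relation <- function(name, vocabulary = NULL) {
  r <- encode_relation(name, vocabulary)
  decode_relation(-r$vec, r$vocabulary)
}

#' Premise constructors
#'
#' A premise is a triple "subject RELATION object", with the fixed semantics
#' that `position(subject) - position(object)` has the sign pattern of the
#' relation's encoding on both axes.
#'
#' @param relation Relation name.
#' @param subject,object Distinct term labels.
#' @return A list with elements `rel`, `s`, `o`.
#' @export
#' @examples
#' premise("left", "A", "B")
premise <- function(relation, subject, object) {
  if (identical(subject, object))
    stop("self-referential premise: '", subject, " ", relation, " ",
         subject, "'", call. = FALSE)
  list(rel = relation, s = subject, o = object)
}

premise_terms <- function(premises) {
  unique(unlist(lapply(premises, function(p) c(p$s, p$o)), use.names = FALSE))
}

format_premise <- function(p) paste(p$rel, p$s, p$o, sep = ";")

parse_premise <- function(s, vocabulary = NULL) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || any(!nzchar(parts)))
    stop("malformed premise triple: '", s, "'", call. = FALSE)
  encode_relation(parts[1L], vocabulary)  # validates the relation name
  premise(parts[1L], parts[2L], parts[3L])
}

infer_vocabulary <- function(rel_names) {
  if (all(rel_names %in% names(.VOCAB_1D))) return("1D")
  if (all(rel_names %in% names(.VOCAB_CARDINAL))) return("cardinal")
  stop("premises mix the 1D and cardinal vocabularies", call. = FALSE)
}

#' Reasoning problems
#'
#' A problem bundles an ordered premise list with a task type: either
#' `verification` (a single putative conclusion, answered "True"/"False";
#' arrangement-verification problems carry several conclusion assertions) or
#' `single_choice` (a set of candidate conclusions, one of which is returned).
#'
#' @param premises List of [premise()] triples.
#' @param task_type `"verification"` or `"single_choice"`.
#' @param conclusion For verification tasks: a premise, or a list of premises
#'   for arrangement verification.
#' @param choices For single-choice tasks: a list of at least two premises.
#' @param vocabulary `"1D"` or `"cardinal"`; inferred when `NULL`.
#' @return An object of class `spatial_problem`.
#' @export
problem <- function(premises, task_type = c("verification", "single_choice"),
                    conclusion = NULL, choices = NULL, vocabulary = NULL) {
  task_type <- match.arg(task_type)
  stopifnot(length(premises) >= 1L)
  if (!is.null(conclusion) && !is.null(conclusion$rel))
    conclusion <- list(conclusion)
  if (is.null(vocabulary)) {
    rels <- vapply(premises, `[[`, "", "rel")
    vocabulary <- infer_vocabulary(rels)
  }
  terms <- premise_terms(premises)
  if (task_type == "verification") {
    if (is.null(conclusion) || length(conclusion) < 1L)
      stop("verification problems need a conclusion", call. = FALSE)
  } else {
    if (is.null(choices) || length(choices) < 2L)
      stop("single-choice problems need at least two choices", call. = FALSE)
    for (ch in choices)
      if (!all(c(ch$s, ch$o) %in% terms))
        stop("choice '", format_premise(ch),
             "' uses terms absent from the premises", call. = FALSE)
  }
  structure(
    list(premises = premises, task_type = task_type, conclusion = conclusion,
         choices = choices, vocabulary = vocabulary),
    class = "spatial_problem"
  )
}

#' @export
print.spatial_problem <- function(x, ...) {
  cat("<spatial_problem> [", x$vocabulary, ", ", x$task_type, "]\n", sep = "")
  for (p in x$premises) cat("  ", p$s, " ", p$rel, " ", p$o, "\n", sep = "")
  if (!is.null(x$conclusion))
    cat("  ? ", paste(vapply(x$conclusion, format_premise, ""),
                      collapse = " / "), "\n", sep = "")
  if (!is.null(x$choices))
    cat("  choices: ", paste(vapply(x$choices, format_premise, ""),
                             collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Task-string dialect
#'
#' Problems travel through datasets as compact strings: premises joined by
#' `/`, each premise `relation;subject;object`; choices joined by `|`.
#' `parse_task()` and `format_task()` are exact inverses.
#'
#' @param task Task string (the premise part; for verification tasks the
#'   conclusion assertions are appended as the final premises of the `choices`
#'   field's absence — see `conclusion_str`).
#' @param response_type `"verify"` or `"single-choice"` (dataset dialect).
#' @param choices_str For single-choice rows the `|`-joined choice triples;
#'   for verification rows the conclusion triple(s), `/`-joined.
#' @return A [problem()].
#' @export
#' @examples
#' p <- parse_task("left;A;B/left;B;C", "verify", "left;A;C")
#' format_task(p)
parse_task <- function(task, response_type = c("verify", "single-choice"),
                       choices_str = "") {
  response_type <- match.arg(response_type)
  prem_strs <- strsplit(task, "/", fixed = TRUE)[[1L]]
  if (length(prem_strs) < 1L || !nzchar(task))
    stop("empty task string", call. = FALSE)
  premises <- lapply(prem_strs, parse_premise)
  vocab <- infer_vocabulary(vapply(premises, `[[`, "", "rel"))
  if (response_type == "verify") {
    if (!nzchar(choices_str))
      stop("verification task without a conclusion", call. = FALSE)
    concl <- lapply(strsplit(choices_str, "/", fixed = TRUE)[[1L]],
                    parse_premise, vocabulary = vocab)
    problem(premises, "verification", conclusion = concl, vocabulary = vocab)
  } else {
    if (!nzchar(choices_str))
      stop("single-choice task without choices", call. = FALSE)
    chs <- lapply(strsplit(choices_str, "|", fixed = TRUE)[[1L]],
                  parse_premise, vocabulary = vocab)
    problem(premises, "single_choice", choices = chs, vocabulary = vocab)
  }
}

#' @rdname parse_task
#' @param p A [problem()].
#' @export
format_task <- function(p) {
  paste(vapply(p$premises, format_premise, ""), collapse = "/")
}

#' @rdname parse_task
#' @export
format_choices <- function(p) {
  if (p$task_type == "single_choice")
    paste(vapply(p$choices, format_premise, ""), collapse = "|")
  else
    paste(vapply(p$conclusion, format_premise, ""), collapse = "/")
}

# Stable cache/identity key for a problem (premise order is part of the
# identity: presentation order matters for the continuity effect).
problem_key <- function(p) {
  paste(p$task_type, p$vocabulary, format_task(p), format_choices(p),
        sep = "||")
}

premises_key <- function(premises) {
  paste(vapply(premises, format_premise, ""), collapse = "/")
}
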