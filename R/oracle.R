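# Ground-truth relational reasoning: composition of qualitative relations
# under exact-axis semantics, brute-force enumeration of qualitative models,
# a path-consistency closure table, and conclusion verification. This module
# is both the engine of the TransitiveClosure baseline and the correctness
# oracle against which the cognitive models are tested.

#' Compose two qualitative relations
#'
#' Given premises "A r1 B" and "B r2 C", returns every relation that can hold
#' between A and C. Composition works axis-wise on the signed encodings: an
#' axis is determined when the two constraints agree or one of them is zero;
#' opposite signs leave the axis unconstrained. The result is the set of
#' relations whose encoding matches every determined axis; when no axis is
#' determined the full vocabulary is returned (fully indeterminate problem).
#'
#' @param r1,r2 Relation names from the same vocabulary.
#' @param vocabulary Optional; inferred from `r1` by default.
#' @return Character vector of relation names, in canonical vocabulary order.
#' @export
#' @examples
#' compose_relations("south-east", "south-east")  # "south-east"
#' compose_relations("south-west", "north-east")  # all eight relations
compose_relations <- function(r1, r2, vocabulary = NULL) {
  e1 <- encode_relation(r1, vocabulary)
  e2 <- encode_relation(r2, e1$vocabulary)
  if (!is.null(vocabulary) && e2$vocabulary != e1$vocabulary)
    stop("cannot compose relations from different vocabularies", call. = FALSE)
  key <- paste("compose", e1$vocabulary, r1, r2, sep = "|")
  cached(key, {
    det <- integer(2L)   # determined sign per axis
    free <- logical(2L)  # axis unconstrained?
    for (ax in 1:2) {
      a <- e1$vec[ax]; b <- e2$vec[ax]
      if (a == 0L) det[ax] <- b
      else if (b == 0L || a == b) det[ax] <- a
      else free[ax] <- TRUE
    }
    nms <- relation_names(e1$vocabulary)
    if (all(free)) return(nms)
    keep <- vapply(nms, function(nm) {
      v <- encode_relation(nm, e1$vocabulary)$vec
      all(free | v == det)
    }, logical(1L))
    nms[keep]
  })
}

# ---- qualitative model enumeration -----------------------------------------

# All dense-rank ("weak order") assignments of n terms along one axis that
# satisfy the per-axis sign constraints. Returns a matrix, one row per
# qualitative order, columns in term order.
axis_orders <- function(n, constraints) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  keep <- rep(TRUE, nrow(grid))
  for (cn in constraints) {
    d <- grid[, cn$i] - grid[, cn$j]
    keep <- keep & if (cn$sign == 0L) d == 0L else sign(d) == cn$sign
  }
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  # canonicalize to dense ranks and deduplicate
  ranked <- t(apply(grid, 1L, function(v) match(v, sort(unique(v)))))
  ranked[!duplicated(apply(ranked, 1L, paste, collapse = ",")), ,
         drop = FALSE]
}

#' Enumerate all qualitative models of a premise set
#'
#' Exhaustively lists every arrangement of the terms on the integer plane that
#' satisfies all premises under exact-axis semantics, with terms occupying
#' distinct cells. Models are canonicalized by per-axis dense rank order and
#' translated so the first term sits at the origin, which makes the result
#' finite and independent of placement scale. An empty list means the premises
#' are inconsistent.
#'
#' @param premises List of [premise()] triples (at most 6 distinct terms).
#' @param grid_half_width Unused placement bound retained for interface
#'   stability; rank canonicalization already bounds coordinates by the number
#'   of terms.
#' @return List of models; each model is an integer matrix with one row per
#'   term (rownames) and columns `x`, `y`.
#' @export
#' @examples
#' length(enumerate_models(list(premise("left", "A", "B"),
#'                              premise("left", "A", "C"))))  # 2
enumerate_models <- function(premises, grid_half_width = NULL) {
  key <- paste("enum", premises_key(premises), sep = "|")
  cached(key, {
    terms <- premise_terms(premises)
    n <- length(terms)
    if (n > 6L) stop("model enumeration supports at most 6 terms",
                     call. = FALSE)
    cons <- lapply(1:2, function(ax) {
      lapply(premises, function(p) {
        v <- encode_relation(p$rel)$vec
        list(i = match(p$s, terms), j = match(p$o, terms), sign = v[ax])
      })
    })
    xs <- axis_orders(n, cons[[1L]])
    ys <- axis_orders(n, cons[[2L]])
    out <- list()
    for (ix in seq_len(nrow(xs))) for (iy in seq_len(nrow(ys))) {
      x <- xs[ix, ]; y <- ys[iy, ]
      if (anyDuplicated(paste(x, y))) next  # two terms in one cell
      m <- cbind(x = x - x[1L], y = y - y[1L])
      rownames(m) <- terms
      out[[length(out) + 1L]] <- m
    }
    out
  })
}

# Does a premise hold in a concrete model? (sign pattern on both axes)
holds_in_model <- function(model, p) {
  d <- model[p$s, ] - model[p$o, ]
  all(sign(d) == encode_relation(p$rel)$vec)
}

# Qualitative signature of a model: per-axis dense ranks. Two models with the
# same signature are the same qualitative arrangement.
model_signature <- function(model) {
  paste(
    paste(match(model[, "x"], sort(unique(model[, "x"]))), collapse = ","),
    paste(match(model[, "y"], sort(unique(model[, "y"]))), collapse = ","),
    sep = ";"
  )
}

#' Verify a conclusion against a premise set
#'
#' @param premises List of premises.
#' @param conclusion A premise whose terms occur in `premises`.
#' @return `"valid"` (holds in every model), `"contradicted"` (holds in none,
#'   or the premises themselves are inconsistent), or `"indeterminate"`.
#' @export
#' @examples
#' verify_conclusion(list(premise("left", "A", "B")), premise("right", "B", "A"))
verify_conclusion <- function(premises, conclusion) {
  terms <- premise_terms(premises)
  if (!all(c(conclusion$s, conclusion$o) %in% terms))
    stop("conclusion term not mentioned in the premises: ",
         setdiff(c(conclusion$s, conclusion$o), terms)[1L], call. = FALSE)
  models <- enumerate_models(premises)
  if (length(models) == 0L) return("contradicted")
  holds <- vapply(models, holds_in_model, logical(1L), p = conclusion)
  if (all(holds)) "valid" else if (!any(holds)) "contradicted"
  else "indeterminate"
}

#' Relations possible between an ordered term pair
#'
#' @param premises List of premises.
#' @param s,o Terms occurring in the premises.
#' @param vocabulary Vocabulary of the answer set; inferred from the premises
#'   by default.
#' @return Character vector of relation names `r` such that "`s` `r` `o`"
#'   holds in at least one model, in canonical vocabulary order.
#' @export
possible_relations <- function(premises, s, o, vocabulary = NULL) {
  if (is.null(vocabulary))
    vocabulary <- infer_vocabulary(vapply(premises, `[[`, "", "rel"))
  nms <- relation_names(vocabulary)
  models <- enumerate_models(premises)
  pats <- unique(vapply(models, function(m) {
    paste(sign(m[s, ] - m[o, ]), collapse = ",")
  }, character(1L)))
  keep <- vapply(nms, function(nm) {
    paste(encode_relation(nm, vocabulary)$vec, collapse = ",") %in% pats
  }, logical(1L))
  nms[keep]
}

#' Are the premises (optionally plus extra assertions) satisfiable?
#'
#' @param premises List of premises.
#' @return `TRUE` iff at least one qualitative model exists.
#' @export
premises_consistent <- function(premises) {
  length(enumerate_models(premises)) > 0L
}

# ---- closure table ---------------------------------------------------------

#' Transitive-closure table of a premise set
#'
#' Repeatedly applies the composition rule ([compose_relations()]) to narrow
#' down, for every ordered pair of terms, the set of relations that can hold
#' between them (path consistency). The table starts from the premises' stated
#' relations and the full vocabulary for unmentioned pairs.
#'
#' @param premises List of premises.
#' @return An object of class `closure_table`: a list with `terms`,
#'   `vocabulary`, and `pairs` (named list, key `"X|Y"`, value the character
#'   vector of possible relations; empty means contradicted). Pair status is
#'   available via [closure_status()].
#' @export
closure_table <- function(premises) {
  key <- paste("closure", premises_key(premises), sep = "|")
  cached(key, {
    terms <- premise_terms(premises)
    vocab <- infer_vocabulary(vapply(premises, `[[`, "", "rel"))
    full <- relation_names(vocab)
    pairs <- list()
    for (a in terms) for (b in terms) if (a != b)
      pairs[[paste(a, b, sep = "|")]] <- full
    for (p in premises) {
      k <- paste(p$s, p$o, sep = "|")
      pairs[[k]] <- intersect(pairs[[k]], p$rel)
      kc <- paste(p$o, p$s, sep = "|")
      pairs[[kc]] <- intersect(pairs[[kc]], converse_relation(p$rel))
    }
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in terms) for (k in terms) for (j in terms) {
        if (i == k || k == j || i == j) next
        rik <- pairs[[paste(i, k, sep = "|")]]
        rkj <- pairs[[paste(k, j, sep = "|")]]
        if (length(rik) == 0L || length(rkj) == 0L) next
        poss <- unique(unlist(lapply(rik, function(a)
          lapply(rkj, function(b) compose_relations(a, b, vocab)))))
        kij <- paste(i, j, sep = "|")
        new <- intersect(pairs[[kij]], poss)
        if (length(new) < length(pairs[[kij]])) {
          pairs[[kij]] <- new
          pairs[[paste(j, i, sep = "|")]] <-
            vapply(new, converse_relation, character(1L), USE.NAMES = FALSE)
          changed <- TRUE
        }
      }
    }
    structure(list(terms = terms, vocabulary = vocab, pairs = pairs),
              class = "closure_table")
  })
}

#' @rdname closure_table
#' @param table A `closure_table`.
#' @param s,o Terms.
#' @return `closure_status()`: `"determinate"`, `"indeterminate"`, or
#'   `"contradicted"`.
#' @export
closure_status <- function(table, s, o) {
  rs <- table$pairs[[paste(s, o, sep = "|")]]
  if (is.null(rs)) stop("unknown term pair: ", s, ", ", o, call. = FALSE)
  if (length(rs) == 0L) "contradicted"
  else if (length(rs) == 1L) "determinate"
  else "indeterminate"
}

#' @export
print.closure_table <- function(x, ...) {
  cat("<closure_table> ", length(x$terms), " terms (",
      paste(x$terms, collapse = ", "), "), vocabulary ", x$vocabulary,
      "\n", sep = "")
  for (k in names(x$pairs)) {
    cat("  ", format(k, width = 12L), " {",
        paste(x$pairs[[k]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}
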