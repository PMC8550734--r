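# Queue-based verbal reasoning model: two candidate orientations from the
# first premise, placement rules (behind -> append at the queue end, in front
# -> insert directly before the reference object), a mental cost metric
# (breaking a link costs more than creating one), and a cardinal-direction
# extension with per-link direction encodings.

# A queue: terms in traversal order from the start side; enc[[i]] is the
# direction encoding of the link terms[i] -> terms[i+1] (premise-derived,
# never zero); pos accumulates each term's premise-vector position (used by
# the cardinal conclusion rule); start is the first-inserted term.
new_queue <- function(terms, enc, pos, start) {
  list(terms = terms, enc = enc, pos = pos, start = start)
}

#' The two candidate queues for a problem's first premise
#'
#' The first object inserted is the queue's starting point; either premise
#' term can be inserted first, giving two orientations. For
#' "apple left mango": `apple* -> mango` and `apple <- mango*` (the asterisk
#' marks the start).
#'
#' @param p The first [premise()] of a problem.
#' @return List of two queues (subject-first orientation first).
#' @export
verbal_candidates <- function(p) {
  v <- encode_relation(p$rel)$vec
  pos <- list(c(0L, 0L), -v); names(pos) <- c(p$s, p$o)
  list(
    new_queue(c(p$s, p$o), list(-v), pos, p$s),
    new_queue(c(p$o, p$s), list(v), pos, p$o)
  )
}

# Direction of the queue at a reference term: the encoding of the adjacent
# link (incoming if the reference has one, else outgoing). Equals the initial
# link in three-term problems.
queue_direction_at <- function(q, ref) {
  i <- match(ref, q$terms)
  if (is.na(i)) stop("term '", ref, "' not in queue", call. = FALSE)
  if (i > 1L) q$enc[[i - 1L]] else q$enc[[i]]
}

#' Insert a premise into a queue
#'
#' Exactly one premise term must be new. The new object's direction relative
#' to its reference is compared with the queue direction at the reference
#' (sign of the dot product, the >90-degree test): a negative dot product
#' places the new object directly in front of the reference (severing an
#' existing link, if any, at `cost_break`), otherwise it is appended at the
#' end of the queue (`cost_create`). This single rule covers both the 1D
#' placement rules and the cardinal extension.
#'
#' @param q A queue.
#' @param p A premise with exactly one term not yet in the queue.
#' @param cost_create,cost_break Positive costs, `cost_break > cost_create`.
#' @return List with the updated `queue` and the `cost` charged.
#' @export
verbal_insert <- function(q, p, cost_create = 1, cost_break = 2) {
  stopifnot(cost_break > cost_create)
  s_in <- p$s %in% q$terms; o_in <- p$o %in% q$terms
  if (s_in && o_in) return(list(queue = q, cost = 0))
  if (!s_in && !o_in)
    stop("both premise terms are new; buffer the premise", call. = FALSE)
  vec <- encode_relation(p$rel)$vec
  if (s_in) { new <- p$o; ref <- p$s; v <- -vec } else {
    new <- p$s; ref <- p$o; v <- vec     # v = direction of new relative to ref
  }
  q$pos[[new]] <- q$pos[[ref]] + v
  dir <- queue_direction_at(q, ref)
  if (sum(v * dir) >= 0) {
    # behind: append at the end of the queue
    q$enc[[length(q$enc) + 1L]] <- v
    q$terms <- c(q$terms, new)
    list(queue = q, cost = cost_create)
  } else {
    # in front: insert directly before the reference object
    i <- match(ref, q$terms)
    cost <- cost_create
    if (i == 1L) {
      q$terms <- c(new, q$terms)
      q$enc <- c(list(-v), q$enc)
    } else {
      broken <- q$enc[[i - 1L]]  # link predecessor -> ref must be severed
      cost <- cost + cost_break
      q$terms <- append(q$terms, new, after = i - 1L)
      q$enc <- append(q$enc, list(broken), after = i - 2L)
      q$enc[[i]] <- -v
    }
    list(queue = q, cost = cost)
  }
}

#' Preferred queue of a premise set
#'
#' Both candidate orientations of the first premise are pursued; the
#' remaining premises are inserted by [verbal_insert()] (premises with two
#' new terms are buffered until linkable). The queue with the lower
#' accumulated cost is preferred; on a tie the search preference decides
#' (`"left-to-right"` keeps the subject-first orientation).
#'
#' @param premises List of premises (connected).
#' @param cost_create,cost_break Costs, see [verbal_insert()].
#' @param preference `"left-to-right"` or `"right-to-left"`.
#' @return List with `queue`, `cost`, `candidates` (both queues with costs)
#'   and `consistent` (oracle consistency of the premises).
#' @export
#' @examples
#' pq <- verbal_preferred(list(premise("left", "apple", "mango"),
#'                             premise("left", "apple", "pear")))
#' pq$queue$terms  # apple, mango, pear
verbal_preferred <- function(premises, cost_create = 1, cost_break = 2,
                             preference = c("left-to-right", "right-to-left")) {
  preference <- match.arg(preference)
  key <- paste("verbal", premises_key(premises), cost_create, cost_break,
               preference, sep = "|")
  cached(key, {
    cands <- verbal_candidates(premises[[1L]])
    runs <- lapply(cands, function(q) {
      cost <- cost_create  # the first link
      buffer <- premises[-1L]
      repeat {
        if (length(buffer) == 0L) break
        linkable <- vapply(buffer, function(p)
          (p$s %in% q$terms) || (p$o %in% q$terms), logical(1L))
        if (!any(linkable)) break  # disconnected remainder
        i <- which(linkable)[1L]
        step <- verbal_insert(q, buffer[[i]], cost_create, cost_break)
        q <- step$queue; cost <- cost + step$cost
        buffer[[i]] <- NULL
      }
      list(queue = q, cost = cost)
    })
    costs <- vapply(runs, `[[`, numeric(1L), "cost")
    pick <- if (preference == "left-to-right") which.min(costs)
            else length(costs) + 1L - which.min(rev(costs))
    list(queue = runs[[pick]]$queue, cost = costs[pick], candidates = runs,
         consistent = premises_consistent(premises))
  })
}

# Spatial left-to-right order implied by a 1D queue: traversal order if the
# links point east, reversed if they point west.
queue_spatial_order <- function(q) {
  xs <- vapply(q$enc, `[[`, integer(1L), 1L)
  if (all(xs >= 0L)) q$terms else if (all(xs <= 0L)) rev(q$terms)
  else stop("queue has mixed 1D link directions", call. = FALSE)
}

#' Conclude a relation between two queue terms
#'
#' For cardinal problems, sums the premise direction encodings accumulated
#' between the two objects (their position difference) and decodes the sign
#' pattern: the result `r` means "`to` `r` `from`". When both component sums
#' are zero (fully indeterminate problems, e.g. opposite relations in the two
#' premises) a forced-choice fallback fires: by default the decoded encoding
#' of the link incident to `from` on the path toward `to`
#' (`fallback = "link"`); `fallback = "random"` draws a relation uniformly
#' from the vocabulary using the current RNG stream.
#'
#' For 1D queues the conclusion is read off the queue's spatial order.
#'
#' @param q A queue from [verbal_preferred()].
#' @param from,to Terms in the queue; the answer relates `to` to `from`.
#' @param vocabulary `"1D"` or `"cardinal"`.
#' @param fallback `"link"` or `"random"`.
#' @return A relation name `r` such that the model concludes "`to` `r`
#'   `from`".
#' @export
verbal_conclude <- function(q, from, to, vocabulary = "cardinal",
                            fallback = c("link", "random")) {
  fallback <- match.arg(fallback)
  if (!all(c(from, to) %in% q$terms))
    stop("term not in queue: ",
         setdiff(c(from, to), q$terms)[1L], call. = FALSE)
  if (vocabulary == "1D") {
    ord <- queue_spatial_order(q)
    return(if (match(to, ord) < match(from, ord)) "left" else "right")
  }
  d <- sign(q$pos[[to]] - q$pos[[from]])
  if (!all(d == 0L)) return(decode_relation(d, vocabulary))
  if (fallback == "random")
    return(sample(relation_names(vocabulary), 1L))
  # local-information heuristic: the link incident to the reference term
  i <- match(from, q$terms); j <- match(to, q$terms)
  enc <- if (j > i) q$enc[[i]] else -q$enc[[i - 1L]]
  decode_relation(sign(enc), vocabulary)
}

#' The verbal reasoning predictive model
#'
#' Builds the preferred queue of the premises and answers from it:
#' verification accepts a conclusion iff it holds in the preferred queue;
#' arrangement verification accepts an arrangement iff it equals the
#' preferred queue's spatial order; single-choice answers decode the queried
#' pair's relation by [verbal_conclude()].
#'
#' @param cost_create,cost_break Costs, see [verbal_insert()].
#' @param preference Search preference, see [verbal_preferred()].
#' @param fallback Forced-choice policy for fully indeterminate problems,
#'   see [verbal_conclude()].
#' @return A `spatial_model` of class `verbal_model`.
#' @export
verbal_model <- function(cost_create = 1, cost_break = 2,
                         preference = "left-to-right", fallback = "link") {
  structure(
    list(name = "verbal", cost_create = cost_create, cost_break = cost_break,
         preference = preference, fallback = fallback),
    class = c("verbal_model", "spatial_model")
  )
}

#' @export
predict_cache_key.verbal_model <- function(model, problem) {
  if (model$fallback != "link") return(NULL)  # stochastic fallback
  paste("verbal", model$cost_create, model$cost_break, model$preference,
        sep = "|")
}

#' @export
predict.verbal_model <- function(object, problem, ...) {
  pq <- verbal_preferred(problem$premises, object$cost_create,
                         object$cost_break, object$preference)
  q <- pq$queue
  if (problem$task_type == "single_choice") {
    ch1 <- problem$choices[[1L]]
    r <- verbal_conclude(q, from = ch1$o, to = ch1$s, problem$vocabulary,
                         object$fallback)
    for (ch in problem$choices)
      if (ch$rel == r && ch$s == ch1$s && ch$o == ch1$o)
        return(format_premise(ch))
    return(format_premise(ch1))
  }
  if (length(problem$conclusion) > 1L) {
    # arrangement verification against the queue's spatial order
    arr_models <- enumerate_models(problem$conclusion)
    if (length(arr_models) == 0L) return("False")
    ord <- model_term_order(arr_models[[1L]])
    qord <- queue_spatial_order(q)
    return(if (identical(ord, qord)) "True" else "False")
  }
  concl <- problem$conclusion[[1L]]
  if (!all(c(concl$s, concl$o) %in% q$terms)) return("False")
  r <- verbal_conclude(q, from = concl$o, to = concl$s, problem$vocabulary,
                       object$fallback)
  if (r == concl$rel) "True" else "False"
}
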