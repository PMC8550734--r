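# PRISM: preferred-model construction on a discrete spatial array by a focus
# with operation-cost accounting, the ff/fff/mix insertion strategies, model
# variation by minimal change, and prediction.

#' PRISM operation costs
#'
#' Construction difficulty is measured by focus operations. The weights are
#' configurable: a focus move of one cell costs `move`, writing a term costs
#' `write`, relocating an already-placed term costs `relocate` per term
#' (pick up plus put down).
#'
#' @param move,write,relocate Positive weights.
#' @return A named numeric vector of weights.
#' @export
prism_costs <- function(move = 1, write = 1, relocate = 2) {
  c(move = move, write = write, relocate = relocate)
}

new_prism_array <- function() {
  list(pos = list(), occ = list(), focus = c(0L, 0L),
       ledger = c(moves = 0, writes = 0, relocs = 0), consistent = TRUE)
}

array_place <- function(arr, term, cell) {
  arr$pos[[term]] <- cell
  arr$occ[[paste(cell, collapse = ",")]] <- term
  arr$focus <- cell
  arr$ledger[["writes"]] <- arr$ledger[["writes"]] + 1
  arr
}

# Move the focus to a target cell; cost = Chebyshev distance (diagonal moves
# are single focus steps, matching diagonal premise directions).
array_move_focus <- function(arr, cell) {
  arr$ledger[["moves"]] <- arr$ledger[["moves"]] +
    max(abs(cell - arr$focus))
  arr$focus <- cell
  arr
}

#' Insert one premise term into a PRISM spatial array
#'
#' Under `fff` (first free fit) the focus scans from the reference term in the
#' required direction to the first free cell and writes there. Under `ff`
#' (first fit) the new term is written into the cell directly adjacent to the
#' reference term in the required direction; the contiguous run of occupants
#' from that cell outward is shifted one cell further, at a relocation cost
#' per shifted term. The grid is unbounded (integer lattice), so insertion
#' never fails.
#'
#' @param arr Array state as built by [prism_construct()].
#' @param p A [premise()]; at least one of its terms must already be placed
#'   unless the array is empty.
#' @param strategy `"ff"` or `"fff"`.
#' @return The updated array state (with an updated cost ledger).
#' @export
prism_insert <- function(arr, p, strategy = c("fff", "ff")) {
  strategy <- match.arg(strategy)
  v <- encode_relation(p$rel)$vec
  s_in <- !is.null(arr$pos[[p$s]]); o_in <- !is.null(arr$pos[[p$o]])
  insert_new <- function(arr, new, ref, dir) {
    arr <- array_move_focus(arr, arr$pos[[ref]])
    if (strategy == "fff") {
      cell <- scan_free(arr$occ, arr$pos[[ref]], dir)
      arr$ledger[["moves"]] <- arr$ledger[["moves"]] +
        max(abs(cell - arr$pos[[ref]]))
      arr$focus <- cell
      arr <- array_place(arr, new, cell)
    } else {
      cell <- arr$pos[[ref]] + dir
      arr$ledger[["moves"]] <- arr$ledger[["moves"]] + 1
      arr$focus <- cell
      # shift the contiguous run of occupants outward, farthest first
      run <- character(0L)
      probe <- cell
      while (!is.null(arr$occ[[paste(probe, collapse = ",")]])) {
        run <- c(run, arr$occ[[paste(probe, collapse = ",")]])
        probe <- probe + dir
      }
      for (t in rev(run)) {
        old <- arr$pos[[t]]
        arr$occ[[paste(old, collapse = ",")]] <- NULL
        arr$pos[[t]] <- old + dir
        arr$occ[[paste(old + dir, collapse = ",")]] <- t
        arr$ledger[["relocs"]] <- arr$ledger[["relocs"]] + 1
      }
      arr <- array_place(arr, new, cell)
    }
    arr
  }
  if (!s_in && !o_in) {
    if (length(arr$pos) > 0L)
      stop("disconnected premise reached prism_insert; buffer it first",
           call. = FALSE)
    arr <- array_place(arr, p$s, arr$focus)
    arr <- insert_new(arr, p$o, p$s, -v)
  } else if (o_in && !s_in) {
    arr <- insert_new(arr, p$s, p$o, v)
  } else if (s_in && !o_in) {
    arr <- insert_new(arr, p$o, p$s, -v)
  } else {
    d <- arr$pos[[p$s]] - arr$pos[[p$o]]
    if (!all(sign(d) == v)) arr$consistent <- FALSE
  }
  arr
}

#' Construct PRISM's preferred mental model
#'
#' Inserts the premises in presentation order with a fixed insertion strategy
#' (`mix` constructs with `fff`; see [prism_model()] for what `mix` means at
#' prediction time). Premises not yet linkable to the array are buffered, as
#' in [sr_build_model()].
#'
#' @param premises List of premises.
#' @param strategy `"fff"`, `"ff"`, or a character vector with one entry per
#'   premise for an explicit per-premise choice sequence.
#' @param costs Cost weights from [prism_costs()].
#' @return A list with `coords` (matrix, rownames = terms), `order`
#'   (insertion order), `cost` (ledger with `total`), `consistent`.
#' @export
#' @examples
#' prism_construct(list(premise("left", "pliers", "saw")), "fff")$coords
prism_construct <- function(premises, strategy = "fff",
                            costs = prism_costs()) {
  if (length(strategy) == 1L && strategy == "mix") strategy <- "fff"
  strat_seq <- if (length(strategy) == 1L)
    rep(strategy, length(premises)) else strategy
  stopifnot(length(strat_seq) == length(premises))
  key <- paste("prism", premises_key(premises),
               paste(strat_seq, collapse = ","), sep = "|")
  res <- cached(key, {
    arr <- new_prism_array()
    buffer <- list(); buffer_strat <- character(0L)
    for (i in seq_along(premises)) {
      p <- premises[[i]]
      if (length(arr$pos) > 0L && is.null(arr$pos[[p$s]]) &&
          is.null(arr$pos[[p$o]])) {
        buffer[[length(buffer) + 1L]] <- p
        buffer_strat <- c(buffer_strat, strat_seq[i])
      } else {
        arr <- prism_insert(arr, p, strat_seq[i])
      }
      repeat {
        linkable <- vapply(buffer, function(b)
          !is.null(arr$pos[[b$s]]) || !is.null(arr$pos[[b$o]]), logical(1L))
        if (!any(linkable)) break
        j <- which(linkable)[1L]
        arr <- prism_insert(arr, buffer[[j]], buffer_strat[j])
        buffer[[j]] <- NULL; buffer_strat <- buffer_strat[-j]
      }
    }
    coords <- do.call(rbind, arr$pos)
    colnames(coords) <- c("x", "y")
    ledger <- arr$ledger
    list(coords = coords, order = names(arr$pos), ledger = ledger,
         consistent = arr$consistent)
  })
  w <- costs
  total <- res$ledger[["moves"]] * w[["move"]] +
    res$ledger[["writes"]] * w[["write"]] +
    res$ledger[["relocs"]] * w[["relocate"]]
  res$cost <- c(res$ledger, total = total)
  res
}

# Left-to-right (west-to-east) term order of a one-dimensional model.
model_term_order <- function(coords) {
  rownames(coords)[order(coords[, "x"])]
}

#' Alternative models by minimal variation of the preferred model
#'
#' Lists the other qualitative models of the premises ordered by revision
#' distance from the preferred model, where the distance is the number of
#' terms whose per-axis rank order changed. At most `depth` alternatives are
#' returned; `depth = 0` means no search.
#'
#' @param model A model as returned by [prism_construct()] (or its `coords`).
#' @param premises The premises.
#' @param depth Non-negative integer.
#' @return List of alternative models (integer coordinate matrices).
#' @export
prism_vary <- function(model, premises, depth) {
  stopifnot(depth >= 0)
  if (depth == 0L) return(list())
  coords <- if (is.list(model) && !is.null(model$coords)) model$coords
            else model
  pref_sig <- model_signature_sorted(coords)
  pref_ranks <- term_ranks(coords)
  alts <- Filter(function(m) model_signature_sorted(m) != pref_sig,
                 enumerate_models(premises))
  if (length(alts) == 0L) return(list())
  dist <- vapply(alts, function(m) {
    r <- term_ranks(m)
    sum(rowSums(r[rownames(pref_ranks), , drop = FALSE] != pref_ranks) > 0L)
  }, numeric(1L))
  sig <- vapply(alts, model_signature_sorted, character(1L))
  alts <- alts[order(dist, sig)]
  alts[seq_len(min(depth, length(alts)))]
}

# Per-axis dense ranks, rows sorted by term name (rename-stable comparison).
term_ranks <- function(coords) {
  coords <- coords[order(rownames(coords)), 1:2, drop = FALSE]
  r <- apply(coords, 2L, function(v) match(v, sort(unique(v))))
  rownames(r) <- rownames(coords)
  r
}

model_signature_sorted <- function(coords) {
  r <- term_ranks(coords)
  paste(rownames(r)[1L], paste(t(r), collapse = ","), sep = ":")
}

# All qualitative orders constructible by some per-premise ff/fff sequence.
prism_constructible_signatures <- function(premises) {
  key <- paste("prismmix", premises_key(premises), sep = "|")
  cached(key, {
    n <- length(premises)
    combos <- expand.grid(rep(list(c("ff", "fff")), n),
                          stringsAsFactors = FALSE)
    unique(vapply(seq_len(nrow(combos)), function(i) {
      m <- prism_construct(premises, unlist(combos[i, ], use.names = FALSE))
      model_signature_sorted(m$coords)
    }, character(1L)))
  })
}

#' The PRISM predictive model
#'
#' Verification answers are read off the preferred model, with up to
#' `variation_depth` alternative models consulted when the conclusion fails
#' there (a preferred-model "True" is never overturned). Single-choice answers
#' decode the queried pair's relation directly from the preferred model's
#' coordinates. Arrangement verification accepts an arrangement equal to the
#' preferred model's qualitative order or to any model within
#' `variation_depth`; under `strategy = "mix"` an arrangement constructible by
#' any per-premise ff/fff sequence is accepted (construction for production
#' tasks is `fff`).
#'
#' @param strategy `"fff"`, `"ff"` or `"mix"`.
#' @param variation_depth Non-negative integer; 0 = preferred model only.
#' @param adapt If `TRUE` (default), [fit_person()] grid-searches
#'   strategy and depth (0--3) for the participant; ties prefer the lower
#'   depth, then fff over ff over mix.
#' @param costs Cost weights, see [prism_costs()].
#' @return A `spatial_model` of class `prism_model`.
#' @export
#' @examples
#' m <- prism_model("fff", 0, adapt = FALSE)
#' p <- parse_task("south-east;frankfurt;berlin/south-east;berlin;stockholm",
#'                 "single-choice",
#'                 paste(paste0(relation_names("cardinal"),
#'                              ";frankfurt;stockholm"), collapse = "|"))
#' predict(m, p)
prism_model <- function(strategy = c("fff", "ff", "mix"), variation_depth = 0L,
                        adapt = TRUE, costs = prism_costs()) {
  strategy <- match.arg(strategy)
  stopifnot(variation_depth >= 0L)
  structure(
    list(name = "prism", strategy = strategy,
         variation_depth = as.integer(variation_depth), adapt = adapt,
         costs = costs),
    class = c("prism_model", "spatial_model")
  )
}

#' @export
predict_cache_key.prism_model <- function(model, problem) {
  paste("prism", model$strategy, model$variation_depth, sep = "|")
}

#' @export
predict.prism_model <- function(object, problem, ...) {
  pref <- prism_construct(problem$premises, object$strategy, object$costs)
  depth <- object$variation_depth
  if (problem$task_type == "single_choice") {
    ch1 <- problem$choices[[1L]]
    d <- sign(pref$coords[ch1$s, ] - pref$coords[ch1$o, ])
    if (all(d == 0L))
      stop("two terms occupy one cell; violates the array invariant",
           call. = FALSE)
    want <- decode_relation(d, problem$vocabulary)
    for (ch in problem$choices)
      if (ch$rel == want && ch$s == ch1$s && ch$o == ch1$o)
        return(format_premise(ch))
    return(format_premise(ch1))
  }
  if (length(problem$conclusion) > 1L) {
    # arrangement verification: compare qualitative orders
    arr_models <- enumerate_models(problem$conclusion)
    if (length(arr_models) == 0L) return("False")
    arr_sig <- model_signature_sorted(arr_models[[1L]])
    if (object$strategy == "mix") {
      if (arr_sig %in% prism_constructible_signatures(problem$premises))
        return("True")
    } else if (arr_sig == model_signature_sorted(pref$coords)) {
      return("True")
    }
    if (depth > 0L) {
      alts <- prism_vary(pref$coords, problem$premises, depth)
      for (m in alts)
        if (model_signature_sorted(m) == arr_sig) return("True")
    }
    return("False")
  }
  concl <- problem$conclusion[[1L]]
  d <- pref$coords[concl$s, ] - pref$coords[concl$o, ]
  if (all(sign(d) == encode_relation(concl$rel)$vec)) return("True")
  if (depth > 0L) {
    for (m in prism_vary(pref$coords, problem$premises, depth))
      if (holds_in_model(m, concl)) return("True")
  }
  "False"
}

#' @rdname prism_model
#' @param model A `prism_model`.
#' @param trials A participant's trials.
#' @export
fit_person.prism_model <- function(model, trials) {
  if (!model$adapt) return(model)
  if (is.null(trials) || nrow(trials) == 0L) {
    model$strategy <- "fff"; model$variation_depth <- 0L
    return(model)
  }
  grid <- expand.grid(strategy = c("fff", "ff", "mix"), depth = 0:3,
                      stringsAsFactors = FALSE)
  # tie-break: lower depth first, then fff > ff > mix -- encode by row order
  grid <- grid[order(grid$depth, match(grid$strategy, c("fff", "ff", "mix"))), ]
  accs <- vapply(seq_len(nrow(grid)), function(i) {
    cand <- prism_model(grid$strategy[i], grid$depth[i], adapt = FALSE,
                        costs = model$costs)
    model_accuracy(cand, trials)
  }, numeric(1L))
  best <- which.max(accs)
  model$strategy <- grid$strategy[best]
  model$variation_depth <- as.integer(grid$depth[best])
  model
}
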