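# Generators for the four benchmark designs (figural, continuity, cardinal
# preference, small/large-scale arrangement verification) plus simulated
# responders. These replace the external participant files for all tests:
# the task structure, per-participant trial counts and consistency ratios
# follow the published designs; responses come from a configured generating
# model corrupted at a given error rate.

.FRUITS <- c("apple", "mango", "pear", "kiwi", "cherry", "fig", "apricot",
             "peach", "plum", "grape", "lemon", "melon", "banana", "orange")
.BUILDINGS <- c("bank", "castle", "church", "cinema", "hospital", "hotel",
                "library", "museum", "palace", "school", "station", "theater")
.TREES <- c("apricot-tree", "pear-tree", "fig-tree", "kiwi-tree",
            "cherry-tree", "apple-tree", "plum-tree", "peach-tree")

# Mix a run seed with a participant index into a fresh 31-bit block seed.
block_seed <- function(seed, ...) {
  h <- sum(utf8ToInt(paste(seed, ..., sep = "\r")) *
             seq_along(utf8ToInt(paste(seed, ..., sep = "\r")))) %% 2147482951
  as.integer((h * 48271 + seed * 16807) %% 2147483647 + 1)
}

trial_frame <- function(id, tasks, response_type, choices, condition) {
  data.frame(
    id = id, sequence = seq_along(tasks), task = tasks,
    response_type = response_type, choices = choices, response = "",
    condition = condition, stringsAsFactors = FALSE
  )
}

shuffle_trials <- function(df) {
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  df$sequence <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Generate figural-effect three-term problems
#'
#' Sixteen verification problems per participant: the four two-premise
#' figures (I: A left B / B left C; II: A left B / C right B; III: B right A
#' / B left C; IV: B right A / C right B) each appear four times over random
#' fruit triples, with a putative conclusion about the first and last
#' objects; half the items are consistent (conclusion follows) and half
#' inconsistent (conclusion contradicts). Problem order is shuffled per
#' participant.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Run seed; every participant's trial order derives from it.
#' @return A dataset data frame without responses (see
#'   [simulate_responses()]).
#' @export
gen_figural <- function(n_participants, seed = 1L) {
  figures <- list(
    I   = function(a, b, ch) c(sprintf("left;%s;%s", a, b),
                               sprintf("left;%s;%s", b, ch)),
    II  = function(a, b, ch) c(sprintf("left;%s;%s", a, b),
                               sprintf("right;%s;%s", ch, b)),
    III = function(a, b, ch) c(sprintf("right;%s;%s", b, a),
                               sprintf("left;%s;%s", b, ch)),
    IV  = function(a, b, ch) c(sprintf("right;%s;%s", b, a),
                               sprintf("right;%s;%s", ch, b))
  )
  out <- list()
  for (pid in seq_len(n_participants)) {
    set.seed(block_seed(seed, "figural", pid))
    tasks <- character(0L); concls <- character(0L); conds <- character(0L)
    for (fig in names(figures)) {
      for (k in 1:4) {
        t3 <- sample(.FRUITS, 3L)
        a <- t3[1L]; b <- t3[2L]; cc <- t3[3L]
        tasks <- c(tasks, paste(figures[[fig]](a, b, cc), collapse = "/"))
        consistent <- k <= 2L
        concls <- c(concls, if (consistent) {
          sample(c(sprintf("left;%s;%s", a, cc),
                   sprintf("right;%s;%s", cc, a)), 1L)
        } else {
          sample(c(sprintf("right;%s;%s", a, cc),
                   sprintf("left;%s;%s", cc, a)), 1L)
        })
        conds <- c(conds, fig)
      }
    }
    df <- trial_frame(paste0("p", pid), tasks, "verify", concls, conds)
    out[[pid]] <- shuffle_trials(df)
  }
  do.call(rbind, out)
}

#' Generate continuity-effect four-term problems
#'
#' Forty-eight verification problems per participant (24 consistent, 24
#' inconsistent), sixteen per assertion order: continuous (A-B, B-C, C-D),
#' semi-continuous (B-C, C-D, A-B) and discontinuous (C-D, A-B, B-C), over
#' random fruit quadruples with "left" premises. The conclusion relates the
#' first and the last introduced term; for the semi-/dis-continuous orders
#' that pair coincides with a premise pair, so the inconsistent items state a
#' premise with its terms swapped and are flagged as filter items in the
#' condition column.
#'
#' @inheritParams gen_figural
#' @return A dataset data frame without responses.
#' @export
gen_continuity <- function(n_participants, seed = 1L) {
  orders <- list(
    "continuous"      = list(pairs = list(c(1, 2), c(2, 3), c(3, 4)),
                             concl = c(1, 4)),
    "semi-continuous" = list(pairs = list(c(2, 3), c(3, 4), c(1, 2)),
                             concl = c(2, 1)),
    "discontinuous"   = list(pairs = list(c(3, 4), c(1, 2), c(2, 3)),
                             concl = c(3, 2))
  )
  out <- list()
  for (pid in seq_len(n_participants)) {
    set.seed(block_seed(seed, "continuity", pid))
    rows <- list()
    for (ord in names(orders)) {
      spec <- orders[[ord]]
      for (k in 1:16) {
        t4 <- sample(.FRUITS, 4L)  # t4[i] is the i-th term left to right
        prems <- vapply(spec$pairs, function(pr)
          sprintf("left;%s;%s", t4[pr[1L]], t4[pr[2L]]), character(1L))
        task <- paste(prems, collapse = "/")
        first <- spec$concl[1L]; last <- spec$concl[2L]
        consistent <- k <= 8L
        rel <- if (first < last) "left" else "right"   # true relation
        concl <- if (consistent) sprintf("%s;%s;%s", rel, t4[first], t4[last])
          else sprintf("%s;%s;%s",
                       if (rel == "left") "right" else "left",
                       t4[first], t4[last])
        filter <- !consistent && any(vapply(spec$pairs, function(pr)
          setequal(pr, spec$concl), logical(1L)))
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, choices = concl,
          condition = paste0(ord, if (filter) "-filter" else ""),
          stringsAsFactors = FALSE)
      }
    }
    rows <- do.call(rbind, rows)
    df <- trial_frame(paste0("p", pid), rows$task, "verify", rows$choices,
                      rows$condition)
    out[[pid]] <- shuffle_trials(df)
  }
  do.call(rbind, out)
}

#' Generate cardinal-direction preference problems
#'
#' Sixty-four single-choice problems per participant: one for every ordered
#' pair (r1, r2) of the eight cardinal relations, in the form "A r1 B. B r2
#' C." over random building triples. The participant picks a relation holding
#' between C and A out of eight options (forced choice; fully indeterminate
#' problems such as opposite relations offer no escape option). The condition
#' column records "r1_r2".
#'
#' @inheritParams gen_figural
#' @return A dataset data frame without responses.
#' @export
gen_cardinal <- function(n_participants, seed = 1L) {
  rels <- relation_names("cardinal")
  out <- list()
  for (pid in seq_len(n_participants)) {
    set.seed(block_seed(seed, "cardinal", pid))
    tasks <- character(0L); chs <- character(0L); conds <- character(0L)
    for (r1 in rels) for (r2 in rels) {
      t3 <- sample(.BUILDINGS, 3L)
      tasks <- c(tasks, sprintf("%s;%s;%s/%s;%s;%s",
                                r1, t3[1L], t3[2L], r2, t3[2L], t3[3L]))
      chs <- c(chs, paste(sprintf("%s;%s;%s", rels, t3[3L], t3[1L]),
                          collapse = "|"))
      conds <- c(conds, paste(r1, r2, sep = "_"))
    }
    df <- trial_frame(paste0("p", pid), tasks, "single-choice", chs, conds)
    out[[pid]] <- shuffle_trials(df)
  }
  do.call(rbind, out)
}

# The four structurally distinct five-term premise templates (term indices
# are left-to-right positions of the generating arrangement).
.SL_TEMPLATES <- list(
  list(prems = list(c("left", 2, 1), c("left", 3, 2), c("left", 4, 2),
                    c("left", 5, 4)), scale = "small"),
  list(prems = list(c("right", 2, 1), c("right", 3, 2), c("right", 4, 2),
                    c("right", 5, 4)), scale = "large"),
  list(prems = list(c("left", 2, 1), c("left", 3, 2), c("left", 4, 2),
                    c("left", 5, 2)), scale = "small"),
  list(prems = list(c("right", 2, 1), c("right", 3, 1), c("right", 4, 3),
                    c("right", 5, 3)), scale = "large")
)

sl_problem_premises <- function(template, terms) {
  lapply(template$prems, function(pr)
    premise(pr[[1L]], terms[as.integer(pr[[2L]])], terms[as.integer(pr[[3L]])]))
}

arrangement_choices <- function(ord) {
  paste(sprintf("left;%s;%s", ord[-length(ord)], ord[-1L]), collapse = "/")
}

# Deterministic foils: lexicographically first inconsistent orders.
sl_foils <- function(premises, terms, n_foils = 3L) {
  perms <- all_permutations(sort(terms))
  found <- list()
  for (p in perms) {
    if (!premises_consistent(c(premises, arrangement_premises(p)))) {
      found[[length(found) + 1L]] <- p
      if (length(found) == n_foils) break
    }
  }
  found
}

arrangement_premises <- function(ord) {
  lapply(seq_len(length(ord) - 1L), function(i)
    premise("left", ord[i], ord[i + 1L]))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Generate small/large-scale arrangement-verification problems
#'
#' Four structurally distinct four-premise problems over five terms (two with
#' fruit vocabulary, "small" scale; two with tree vocabulary, "large" scale;
#' the first problem is the classic apricot/pear/fig/kiwi/cherry item). For
#' each problem six candidate arrangements are offered: the first-fit (ff),
#' first-free-fit (fff) and mixed-strategy constructions plus three
#' inconsistent foils -- 24 problem-arrangement combinations, each presented
#' twice, for 48 trials per participant. The arrangement is encoded as four
#' adjacent "left" assertions; the condition column records
#' `scale:arrangement-class`.
#'
#' @inheritParams gen_figural
#' @return A dataset data frame without responses.
#' @export
gen_smalllarge <- function(n_participants, seed = 1L) {
  base <- list()
  for (ti in seq_along(.SL_TEMPLATES)) {
    tmpl <- .SL_TEMPLATES[[ti]]
    terms <- if (tmpl$scale == "small") {
      if (ti == 1L) c("apricot", "pear", "fig", "kiwi", "cherry")
      else c("apple", "mango", "peach", "plum", "grape")
    } else if (ti == 2L) .TREES[1:5] else .TREES[4:8]
    prems <- sl_problem_premises(tmpl, terms)
    task <- paste(vapply(prems, format_premise, ""), collapse = "/")
    ffo  <- model_term_order(prism_construct(prems, "ff")$coords)
    fffo <- model_term_order(prism_construct(prems, "fff")$coords)
    mixo <- sl_mix_order(prems, ffo, fffo)
    foils <- sl_foils(prems, terms)
    arrangements <- c(list(ff = ffo, fff = fffo, mix = mixo),
                      stats::setNames(foils, paste0("foil", seq_along(foils))))
    for (cls in names(arrangements)) {
      base[[length(base) + 1L]] <- data.frame(
        task = task, choices = arrangement_choices(arrangements[[cls]]),
        condition = paste0(tmpl$scale, ":", sub("[0-9]$", "", cls)),
        stringsAsFactors = FALSE)
    }
  }
  base <- do.call(rbind, base)
  base <- rbind(base, base)  # every combination is presented twice
  out <- list()
  for (pid in seq_len(n_participants)) {
    set.seed(block_seed(seed, "smalllarge", pid))
    df <- trial_frame(paste0("p", pid), base$task, "verify", base$choices,
                      base$condition)
    out[[pid]] <- shuffle_trials(df)
  }
  do.call(rbind, out)
}

# First per-premise ff/fff sequence whose order differs from both pure
# strategies (such an order exists for all four templates).
sl_mix_order <- function(prems, ffo, fffo) {
  n <- length(prems)
  combos <- expand.grid(rep(list(c("ff", "fff")), n),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ord <- model_term_order(
      prism_construct(prems, unlist(combos[i, ], use.names = FALSE))$coords)
    if (!identical(ord, ffo) && !identical(ord, fffo)) return(ord)
  }
  stop("template admits no mixed-strategy arrangement", call. = FALSE)
}

#' Simulate participant responses from a generating model
#'
#' Every trial is answered by the generating model; with probability
#' `error_rate` the answer is replaced by a uniform draw over the *other*
#' response options. Reproducible under the seed (two runs with the same
#' inputs give identical datasets).
#'
#' @param trials A dataset data frame from one of the generators.
#' @param model A `spatial_model` (used as-is; no fitting).
#' @param error_rate Probability in `[0, 1)` of corrupting a response.
#' @param seed Seed for the corruption draws and any model-internal draws.
#' @return The data frame with the `response` column filled in.
#' @export
#' @examples
#' d <- simulate_responses(gen_figural(1, seed = 7), closure_model(), 0, 7)
#' head(d$response)
simulate_responses <- function(trials, model, error_rate = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  set.seed(block_seed(seed, "responses", model_name(model), error_rate))
  resp <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    p <- row_problem(trials[i, ])
    r <- predict(model, p)
    if (error_rate > 0 && stats::runif(1L) < error_rate) {
      others <- setdiff(response_options(p), r)
      r <- others[sample.int(length(others), 1L)]
    }
    resp[i] <- r
  }
  trials$response <- resp
  trials
}

#' One-call benchmark dataset generation
#'
#' @param design One of `"figural"`, `"continuity"`, `"cardinal"`,
#'   `"smalllarge"`.
#' @param n_participants Number of participants.
#' @param model Generating model (default: the transitive-closure logic
#'   model, i.e. logically correct responders up to forced guesses).
#' @param error_rate Response corruption rate.
#' @param seed Run seed.
#' @return A complete dataset data frame.
#' @export
generate_dataset <- function(design = c("figural", "continuity", "cardinal",
                                        "smalllarge"),
                             n_participants, model = closure_model(),
                             error_rate = 0, seed = 1L) {
  design <- match.arg(design)
  gen <- switch(design, figural = gen_figural, continuity = gen_continuity,
                cardinal = gen_cardinal, smalllarge = gen_smalllarge)
  simulate_responses(gen(n_participants, seed), model, error_rate, seed)
}
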