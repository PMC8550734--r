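# Shared fixtures, all built in code.

# The classic five-fruit arrangement-verification premises.
example3_premises <- function() {
  list(premise("left", "pear", "apricot"),
       premise("left", "fig", "pear"),
       premise("left", "kiwi", "pear"),
       premise("left", "cherry", "kiwi"))
}

# Two-premise cardinal chain "A r1 B. B r2 C." as a premise list.
cardinal_chain <- function(r1, r2, terms = c("A", "B", "C")) {
  list(premise(r1, terms[1], terms[2]), premise(r2, terms[2], terms[3]))
}

# Single-choice problem for a cardinal chain: all eight relations offered
# for the pair (C, A).
cardinal_problem <- function(r1, r2, terms = c("A", "B", "C")) {
  problem(cardinal_chain(r1, r2, terms), "single_choice",
          choices = lapply(relation_names("cardinal"), function(r)
            premise(r, terms[3], terms[1])))
}

# Random connected premise chain (always consistent) plus a random putative
# conclusion between two distinct terms. Uses the current RNG stream.
random_chain_problem <- function(n_terms = sample(3:5, 1),
                                 vocabulary = sample(c("1D", "cardinal"), 1)) {
  terms <- sample(LETTERS, n_terms)
  rels <- relation_names(vocabulary)
  premises <- lapply(seq_len(n_terms - 1L), function(i)
    premise(sample(rels, 1), terms[i + 1L], terms[i]))
  pair <- sample(terms, 2L)
  list(premises = premises,
       putative = premise(sample(rels, 1), pair[1L], pair[2L]),
       vocabulary = vocabulary)
}

# Left-to-right term order of a one-dimensional coordinate model.
order_of <- function(coords) rownames(coords)[order(coords[, "x"])]

# Accuracy of a model on a simulated dataset restricted to one participant.
first_person <- function(dataset) {
  p <- dataset$id[1L]
  dataset[dataset$id == p, , drop = FALSE]
}
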