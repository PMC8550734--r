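test_that("figural design: counts, figure encodings and oracle labels", {
  d <- gen_figural(3, seed = 71)
  expect_identical(nrow(d), 48L)
  one <- first_person(d)
  expect_identical(nrow(one), 16L)
  expect_identical(sort(unique(one$condition)), c("I", "II", "III", "IV"))
  expect_true(all(table(one$condition) == 4L))

  status <- vapply(seq_len(nrow(one)), function(i) {
    p <- spatialmm:::row_problem(one[i, ])
    verify_conclusion(p$premises, p$conclusion[[1L]])
  }, character(1L))
  expect_identical(sum(status == "valid"), 8L)
  expect_identical(sum(status == "contradicted"), 8L)

  # Figure II rows encode "A left B / C right B"
  fig2 <- one[one$condition == "II", ][1L, ]
  rels <- vapply(strsplit(fig2$task, "/")[[1L]], function(s)
    strsplit(s, ";")[[1L]][1L], character(1L), USE.NAMES = FALSE)
  expect_identical(rels, c("left", "right"))
})

test_that("continuity design: orders, filter items and consistency split", {
  d <- gen_continuity(2, seed = 72)
  one <- first_person(d)
  expect_identical(nrow(one), 48L)
  base <- sub("-filter$", "", one$condition)
  expect_true(all(table(base) == 16L))

  status <- vapply(seq_len(nrow(one)), function(i) {
    p <- spatialmm:::row_problem(one[i, ])
    verify_conclusion(p$premises, p$conclusion[[1L]])
  }, character(1L))
  expect_identical(sum(status == "valid"), 24L)
  expect_identical(sum(status == "contradicted"), 24L)

  # discontinuous premises pair terms (C,D), (A,B), (B,C) in that order
  disc <- one[base == "discontinuous", ][1L, ]
  prems <- lapply(strsplit(disc$task, "/")[[1L]], spatialmm:::parse_premise)
  ord <- order_of(enumerate_models(prems)[[1L]])  # A B C D left to right
  pair_idx <- lapply(prems, function(p) sort(match(c(p$s, p$o), ord)))
  expect_identical(pair_idx, list(c(3L, 4L), c(1L, 2L), c(2L, 3L)))

  # filter items state a premise with its terms swapped
  filt <- one[grepl("-filter$", one$condition), ]
  expect_identical(nrow(filt), 16L)
  for (i in seq_len(nrow(filt))) {
    concl <- spatialmm:::parse_premise(filt$choices[i])
    swapped <- paste(concl$rel, concl$o, concl$s, sep = ";")
    expect_true(swapped %in% strsplit(filt$task[i], "/")[[1L]])
  }
})

test_that("cardinal design: full relation cross, eight options each", {
  d <- gen_cardinal(2, seed = 73)
  one <- first_person(d)
  expect_identical(nrow(one), 64L)
  expect_identical(length(unique(one$condition)), 64L)
  for (i in seq_len(nrow(one))) {
    p <- spatialmm:::row_problem(one[i, ])
    expect_length(p$choices, 8L)
  }
  # opposite relations are fully indeterminate under the oracle
  sw_ne <- one[one$condition == "south-west_north-east", ]
  p <- spatialmm:::row_problem(sw_ne)
  expect_setequal(possible_relations(p$premises, p$choices[[1L]]$s,
                                     p$choices[[1L]]$o),
                  relation_names("cardinal"))
})

test_that("small-large design: 24 combinations twice, labelled by oracle", {
  d <- gen_smalllarge(2, seed = 74)
  one <- first_person(d)
  expect_identical(nrow(one), 48L)
  combos <- unique(paste(one$task, one$choices))
  expect_identical(length(combos), 24L)
  expect_true(all(table(paste(one$task, one$choices)) == 2L))
  expect_setequal(sub(":.*$", "", one$condition), c("small", "large"))

  consistent <- vapply(seq_len(nrow(one)), function(i) {
    p <- spatialmm:::row_problem(one[i, ])
    premises_consistent(c(p$premises, p$conclusion))
  }, logical(1L))
  cls <- sub("^.*:", "", one$condition)
  expect_true(all(consistent[cls %in% c("ff", "fff", "mix")]))
  expect_true(all(!consistent[cls == "foil"]))
  expect_identical(sum(consistent), 24L)

  # the classic item appears with its ff arrangement as a consistent trial
  classic <- one[grepl("left;pear;apricot", one$task) &
                   grepl("left;fig;cherry", one$choices), ]
  expect_gt(nrow(classic), 0L)
  expect_identical(unique(classic$condition), "small:ff")
})

test_that("simulated responses are reproducible and hit the error rate", {
  d1 <- generate_dataset("smalllarge", 6, closure_model(), 0, seed = 75)
  # a noiseless logic responder is covered perfectly by the logic model
  expect_identical(model_accuracy(closure_model(), first_person(d1)), 1)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1)
  write_dataset(generate_dataset("smalllarge", 6, closure_model(), 0,
                                 seed = 75), f2)
  expect_identical(readLines(f1), readLines(f2))

  d2 <- generate_dataset("smalllarge", 12,
                         prism_model("ff", 0, adapt = FALSE), 0.1, seed = 76)
  acc <- model_accuracy(prism_model("ff", 0, adapt = FALSE), d2)
  se <- sqrt(0.9 * 0.1 / nrow(d2))
  expect_lt(abs(acc - 0.9), 4 * se)
})
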