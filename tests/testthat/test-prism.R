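test_that("insertion strategies reproduce the three printed arrangements", {
  prems <- example3_premises()
  expect_identical(
    paste(order_of(prism_construct(prems, "ff")$coords), collapse = " "),
    "fig cherry kiwi pear apricot")
  expect_identical(
    paste(order_of(prism_construct(prems, "fff")$coords), collapse = " "),
    "cherry kiwi fig pear apricot")
  expect_identical(
    paste(order_of(prism_construct(prems, c("ff", "ff", "ff", "fff"))$coords),
          collapse = " "),
    "cherry fig kiwi pear apricot")
})

test_that("a single premise places both terms from the focus", {
  m <- prism_construct(list(premise("left", "pliers", "saw")), "fff")
  expect_equal(unname(m$coords["pliers", ]), c(0, 0))
  expect_equal(unname(m$coords["saw", ]), c(1, 0))
})

test_that("first-fit relocations make the ff model costlier than fff", {
  prems <- example3_premises()
  ff <- prism_construct(prems, "ff")
  fff <- prism_construct(prems, "fff")
  expect_gt(ff$cost[["total"]], fff$cost[["total"]])
  expect_gt(ff$cost[["relocs"]], 0)
  expect_identical(unname(fff$cost[["relocs"]]), 0)
})

test_that("the focus scans past occupied cells on opposite-relation problems", {
  prems <- cardinal_chain("south-west", "north-east",
                          c("frankfurt", "amsterdam", "paris"))
  m <- prism_construct(prems, "fff")
  expect_true(m$consistent)
  d <- sign(m$coords["paris", ] - m$coords["frankfurt", ])
  expect_false(all(d == 0))  # a concrete preferred relation exists
  expect_identical(decode_relation(d, "cardinal"), "south-west")
})

test_that("model variation lists alternatives by revision distance", {
  det <- list(premise("left", "A", "B"), premise("left", "B", "C"))
  pref <- prism_construct(det, "fff")
  expect_length(prism_vary(pref$coords, det, 3), 0L)

  indet <- list(premise("left", "A", "B"), premise("left", "A", "C"))
  pref2 <- prism_construct(indet, "fff")
  expect_length(prism_vary(pref2$coords, indet, 0), 0L)
  alts <- prism_vary(pref2$coords, indet, 1)
  expect_length(alts, 1L)
  expect_false(identical(order_of(alts[[1L]]), order_of(pref2$coords)))
})

test_that("arrangement verification follows strategy and variation depth", {
  prems <- example3_premises()
  task <- paste(vapply(prems, spatialmm:::format_premise, ""), collapse = "/")
  arr_fff <- "left;cherry;kiwi/left;kiwi;fig/left;fig;pear/left;pear;apricot"
  arr_ff <- "left;fig;cherry/left;cherry;kiwi/left;kiwi;pear/left;pear;apricot"
  p_fff <- parse_task(task, "verify", arr_fff)
  p_ff <- parse_task(task, "verify", arr_ff)

  m0 <- prism_model("fff", 0, adapt = FALSE)
  expect_identical(predict(m0, p_fff), "True")
  expect_identical(predict(m0, p_ff), "False")

  m2 <- prism_model("fff", 2, adapt = FALSE)
  expect_identical(predict(m2, p_fff), "True")
  expect_identical(predict(m2, p_ff), "True")

  mix <- prism_model("mix", 0, adapt = FALSE)
  expect_identical(predict(mix, p_fff), "True")
  expect_identical(predict(mix, p_ff), "True")
})

test_that("single-choice answers decode the preferred model's relation", {
  # the chain is determinate: frankfurt is south-east of stockholm, so the
  # queried pair (stockholm, frankfurt) gets the converse relation
  p <- cardinal_problem("south-east", "south-east",
                        c("frankfurt", "berlin", "stockholm"))
  m <- prism_model("fff", 0, adapt = FALSE)
  expect_identical(predict(m, p), "north-west;stockholm;frankfurt")
})

test_that("the preferred model is always an oracle model of the premises", {
  set.seed(37)
  for (i in 1:40) {
    rp <- random_chain_problem()
    for (strat in c("fff", "ff")) {
      m <- prism_construct(rp$premises, strat)
      expect_true(all(vapply(rp$premises, function(p)
        all(sign(m$coords[p$s, ] - m$coords[p$o, ]) ==
              encode_relation(p$rel)$vec), logical(1L))))
    }
  }
})

test_that("determinate single-choice answers equal the oracle relation", {
  m <- prism_model("fff", 0, adapt = FALSE)
  rels <- relation_names("cardinal")
  for (r1 in rels) for (r2 in rels) {
    poss <- compose_relations(r1, r2)
    if (length(poss) != 1L) next
    want <- converse_relation(poss)  # answer relates C to A
    pred <- predict(m, cardinal_problem(r1, r2))
    expect_identical(pred, paste(want, "C", "A", sep = ";"))
  }
})

test_that("construction cost is invariant under term renaming", {
  prems <- example3_premises()
  renamed <- lapply(prems, function(p)
    premise(p$rel, toupper(p$s), toupper(p$o)))
  for (strat in c("ff", "fff"))
    expect_identical(prism_construct(prems, strat)$cost,
                     prism_construct(renamed, strat)$cost)
})

test_that("fitting recovers a noiseless generating parameterization", {
  d <- simulate_responses(gen_smalllarge(1, seed = 21),
                          prism_model("ff", 0, adapt = FALSE), 0, seed = 21)
  fitted <- fit_person(prism_model(), d)
  expect_identical(fitted$strategy, "ff")
  expect_identical(fitted$variation_depth, 0L)

  # a responder accepting every consistent arrangement needs deep variation
  d2 <- simulate_responses(gen_smalllarge(1, seed = 22), closure_model(), 0,
                           seed = 22)
  fitted2 <- fit_person(prism_model(), d2)
  expect_true(fitted2$variation_depth > 0L || fitted2$strategy == "mix")
  expect_gte(model_accuracy(prism_model(fitted2$strategy,
                                        fitted2$variation_depth,
                                        adapt = FALSE), d2),
             model_accuracy(prism_model("fff", 0, adapt = FALSE), d2))

  empty <- fit_person(prism_model(), gen_smalllarge(1, seed = 23)[0, ])
  expect_identical(empty$strategy, "fff")
  expect_identical(empty$variation_depth, 0L)
})
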