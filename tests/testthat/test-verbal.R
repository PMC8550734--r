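test_that("the first premise spawns two candidate orientations", {
  cands <- verbal_candidates(premise("left", "apple", "mango"))
  expect_identical(cands[[1L]]$terms, c("apple", "mango"))
  expect_identical(cands[[1L]]$start, "apple")
  expect_identical(cands[[2L]]$terms, c("mango", "apple"))
  expect_identical(cands[[2L]]$start, "mango")

  cn <- verbal_candidates(premise("north", "A", "B"))
  expect_equal(cn[[1L]]$enc[[1L]], c(0L, -1L))  # B lies south of A
  expect_equal(cn[[2L]]$enc[[1L]], c(0L, 1L))
  expect_error(verbal_candidates(premise("north", "A", "A")),
               "self-referential")
})

test_that("insertion appends behind and splices in front, with link costs", {
  p2 <- premise("left", "apple", "pear")
  cands <- verbal_candidates(premise("left", "apple", "mango"))

  behind <- verbal_insert(cands[[1L]], p2)
  expect_identical(behind$queue$terms, c("apple", "mango", "pear"))
  expect_identical(behind$cost, 1)

  front <- verbal_insert(cands[[2L]], p2)
  expect_identical(front$queue$terms, c("mango", "pear", "apple"))
  expect_identical(front$cost, 3)  # create + break of mango -> apple

  expect_error(verbal_insert(cands[[1L]], premise("left", "X", "Y")),
               "both premise terms are new")
})

test_that("the preferred queue minimizes construction cost", {
  pq <- verbal_preferred(list(premise("left", "apple", "mango"),
                              premise("left", "apple", "pear")))
  expect_identical(pq$queue$terms, c("apple", "mango", "pear"))
  expect_identical(pq$queue$start, "apple")
  costs <- vapply(pq$candidates, `[[`, numeric(1L), "cost")
  expect_identical(pq$cost, min(costs))

  det <- verbal_preferred(list(premise("left", "A", "B"),
                               premise("left", "B", "C")))
  expect_identical(det$queue$terms, c("A", "B", "C"))
})

test_that("exhaustive construction paths confirm global cost optimality", {
  set.seed(59)
  for (i in 1:25) {
    rp <- random_chain_problem(n_terms = sample(3:5, 1))
    pq <- verbal_preferred(rp$premises)
    costs <- vapply(pq$candidates, `[[`, numeric(1L), "cost")
    expect_identical(pq$cost, min(costs))
    # 1D preferred queues are oracle models of the premises
    if (rp$vocabulary == "1D") {
      ord <- spatialmm:::queue_spatial_order(pq$queue)
      idx <- stats::setNames(seq_along(ord), ord)
      expect_true(all(vapply(rp$premises, function(p)
        if (p$rel == "left") idx[p$s] < idx[p$o] else idx[p$s] > idx[p$o],
        logical(1L))))
    }
  }
})

test_that("cardinal insertion follows the >90-degree rule", {
  # queue A -> B with B south of A
  q <- verbal_candidates(premise("north", "A", "B"))[[1L]]
  south <- verbal_insert(q, premise("north", "B", "C"))  # C south of B
  expect_identical(south$queue$terms, c("A", "B", "C"))
  north <- verbal_insert(q, premise("south", "B", "C"))  # C north of B
  expect_identical(north$queue$terms, c("A", "C", "B"))
  # orthogonal direction (dot = 0): the "otherwise" clause appends
  east <- verbal_insert(q, premise("west", "B", "C"))
  expect_identical(east$queue$terms, c("A", "B", "C"))
  # both placements give the same conclusion sum for the outer pair
  expect_identical(verbal_conclude(east$queue, "A", "C"), "south-east")
})

test_that("conclusions sum direction encodings along the queue", {
  q <- verbal_insert(verbal_candidates(premise("north", "A", "B"))[[1L]],
                     premise("north", "B", "C"))$queue
  expect_identical(verbal_conclude(q, "A", "C"), "south")  # C south A

  pq <- verbal_preferred(cardinal_chain("south-east", "south-east",
                                        c("frankfurt", "berlin",
                                          "stockholm")))
  expect_identical(
    verbal_conclude(pq$queue, "stockholm", "frankfurt"), "south-east")
  expect_error(verbal_conclude(pq$queue, "frankfurt", "oslo"),
               "not in queue")
})

test_that("opposite-relation problems hit the zero-vector fallback", {
  pq <- verbal_preferred(cardinal_chain("south-west", "north-east",
                                        c("frankfurt", "amsterdam",
                                          "paris")))
  q <- pq$queue
  expect_equal(q$pos[["paris"]], q$pos[["frankfurt"]])  # zero sum
  r <- verbal_conclude(q, "frankfurt", "paris", fallback = "link")
  expect_identical(r, "south-west")  # the link incident to the reference
  set.seed(5)
  rr <- replicate(20, verbal_conclude(q, "frankfurt", "paris",
                                      fallback = "random"))
  expect_true(all(rr %in% relation_names("cardinal")))
  expect_gt(length(unique(rr)), 1L)
})

test_that("determinate conclusions agree with relation composition", {
  m <- verbal_model()
  rels <- relation_names("cardinal")
  for (r1 in rels) for (r2 in rels) {
    poss <- compose_relations(r1, r2)
    if (length(poss) != 1L) next
    pred <- predict(m, cardinal_problem(r1, r2))
    expect_identical(pred, paste(converse_relation(poss), "C", "A", sep = ";"))
  }
})

test_that("conclude is converse-symmetric when determinate", {
  set.seed(61)
  for (i in 1:20) {
    rp <- random_chain_problem(vocabulary = "cardinal")
    pq <- verbal_preferred(rp$premises)
    terms <- sample(pq$queue$terms, 2L)
    d <- sign(pq$queue$pos[[terms[2L]]] - pq$queue$pos[[terms[1L]]])
    if (all(d == 0L)) next
    expect_identical(
      verbal_conclude(pq$queue, terms[1L], terms[2L]),
      converse_relation(verbal_conclude(pq$queue, terms[2L], terms[1L])))
  }
})
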