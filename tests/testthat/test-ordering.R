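# Fitch reconstruction, branch placement, linear extensions.

test_that("Fitch handles constant, two-state and ambiguous sites", {
  chars <- matrix(c("A", "A", "A", "A"), 4, 1,
                  dimnames = list(c("t1", "t2", "t3", "t4"), "s1"))
  tr <- ape::read.tree(text = "(((t1,t2),t3),t4);")
  f <- fitch_parsimony(tr, chars, "s1")
  expect_equal(f$score, 0)
  expect_true(all(vapply(f$final, identical, logical(1), "A")))

  two <- ape::read.tree(text = "(t1,t2);")
  chars2 <- matrix(c("A", "C"), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
  expect_equal(fitch_parsimony(two, chars2, "s1")$score, 1)

  expect_error(fitch_parsimony(two, chars2[1, , drop = FALSE], "s1"),
               "unscored tip")
})

test_that("Fitch scores equal the exhaustive minimum over labelings", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    states <- sample(c("A", "C", "G"), n, replace = TRUE)
    chars <- matrix(states, n, 1, dimnames = list(tr$tip.label, "s1"))
    expect_equal(fitch_parsimony(tr, chars, "s1")$score,
                 brute_fitch_score(tr, states))
  }
})

test_that("Fitch scores agree with an independent parsimony implementation", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    states <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    chars <- matrix(states, n, 1, dimnames = list(tr$tip.label, "s1"))
    pd <- phangorn::phyDat(chars, type = "DNA")
    expect_equal(fitch_parsimony(tr, chars, "s1")$score,
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("the 15-taxon fixture places the substitutions in four branch groups", {
  fx <- s1_like_fixture()
  pl <- place_substitutions(fx$tree, fx$characters, "Human",
                            sites = fx$landscape$sites)
  expect_length(pl$excluded, 0)
  branches <- vapply(pl$placements, function(p) {
    expect_length(p$branches, 1)   # unambiguous on this instance
    p$branches
  }, integer(1))
  expect_equal(branches[["T93P"]], branches[["A114G"]])
  expect_equal(branches[["F49L"]], branches[["S118T"]])
  expect_equal(branches[["F46T"]], branches[["T52F"]])
  expect_true(branches[["T93P"]] < branches[["F86L"]])
  expect_true(branches[["F86L"]] < branches[["F49L"]])
  expect_true(branches[["F49L"]] < branches[["F46T"]])

  pos <- partial_orders(pl)
  expect_length(pos, 1)
  expect_equal(pos[[1]],
               list(c("T93P", "A114G"), "F86L", c("F49L", "S118T"),
                    c("F46T", "T52F")),
               ignore_attr = TRUE)

  # a site identical across taxa is excluded with a note
  chars <- fx$characters
  chars[, "F86L"] <- "F"
  pl2 <- place_substitutions(fx$tree, chars, "Human",
                             sites = fx$landscape$sites)
  expect_true("F86L" %in% names(pl2$excluded))
})

test_that("ambiguous reconstructions surface multi-branch candidate sets", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  # s1's derived state may have arisen on either of two branches; s2 is
  # unambiguous, so the two resolutions give different relative orders
  chars <- matrix(c("x", "z", "y", "y",
                    "b", "a", "a", "a"), 4, 2,
                  dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  pl <- place_substitutions(tr, chars, "A")
  expect_length(pl$placements$s1$branches, 2)
  expect_length(pl$placements$s2$branches, 1)
  pos <- partial_orders(pl)
  expect_length(pos, 2)
  # one resolution co-locates the sites, the other separates them
  expect_setequal(lengths(pos), c(1, 2))
})

test_that("linear extensions count and enumerate consistently", {
  po <- list(c("a", "b"), "c", c("d", "e"), c("f", "g"))
  le <- linear_extensions(po, enumerate = TRUE)
  expect_equal(le$count, 8)
  expect_equal(nrow(le$orderings), 8)
  expect_false(any(duplicated(apply(le$orderings, 1, paste, collapse = ","))))
  expect_equal(linear_extensions(list(letters[1:7]))$count, 5040)
  expect_equal(linear_extensions(as.list(letters[1:5]))$count, 1)
  expect_error(linear_extensions(list(c("a", "b"), "a")), "disjoint")
})

test_that("linear extensions compose with constrained path enumeration", {
  fx <- s1_like_fixture()
  le <- linear_extensions(fx$partial_order, enumerate = TRUE)
  cp <- constrained_paths(fx$landscape, fx$partial_order)
  from_cp <- sort(apply(cp$perm, 1, function(r)
    paste(fx$landscape$sites[r], collapse = ",")))
  from_le <- sort(apply(le$orderings, 1, paste, collapse = ","))
  expect_equal(from_cp, from_le)
})
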