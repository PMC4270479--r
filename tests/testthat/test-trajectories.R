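# Enumeration, accessibility counting, step classification, variance split.

test_that("seven sites yield 5040 orderings and lethal-first paths stop at step 1", {
  fx <- s1_like_fixture()
  trj <- enumerate_trajectories(fx$landscape)
  expect_equal(nrow(trj$perm), 5040)
  lethal <- match("T52F", fx$landscape$sites)
  first_lethal <- trj$perm[, 1] == lethal
  expect_true(all(trj$status[first_lethal] == "terminated"))
  expect_true(all(trj$terminated_at[first_lethal] == 1))
  # profiles end before the first nonfunctional genotype
  expect_true(all(is.na(trj$lambda[first_lethal, 2])))
  # and never use imputed phenotypes: the imputed double is NA in profiles
  imp_mask <- genotype_mask(c("F46T", "A114G"), fx$landscape$sites)
  hits <- which(trj$masks == imp_mask, arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  expect_true(all(is.na(trj$lambda[cbind(hits[, 1], hits[, 2] + 1)])))
})

test_that("accessibility conservation and per-first decomposition hold", {
  set.seed(5)
  for (rep in 1:30) {
    L <- sample(3:6, 1)
    ls <- random_lethal_landscape(L, p_nf = stats::runif(1, 0.1, 0.5))
    s <- count_accessible(ls)
    expect_equal(s$accessible + s$terminated, factorial(L))
    expect_equal(sum(s$per_first_mutation), s$accessible)
  }
})

test_that("DP counts match explicit enumeration, including edge cases", {
  set.seed(9)
  for (rep in 1:40) {
    L <- sample(3:6, 1)
    ls <- random_lethal_landscape(L, p_nf = stats::runif(1, 0, 0.6))
    expect_equal(count_accessible(ls)$accessible, brute_accessible_count(ls))
  }
  # all functional: L! accessible
  ls <- random_functional_landscape(4)
  expect_equal(count_accessible(ls)$accessible, 24)
  # nonfunctional endpoint blocks everything
  lam <- ls$lambda; fun <- ls$functional
  lam[16] <- NA; fun[16] <- FALSE
  blocked <- landscape(ls$sites, ls$lambda_anc, lambda = lam, functional = fun)
  expect_equal(count_accessible(blocked)$accessible, 0)
  # one lethal single mutant out of 7 removes exactly 6! starts
  fx <- s1_like_fixture()
  lam <- fx$landscape$lambda; fun <- fx$landscape$functional
  keep <- genotype_mask(c("F46T", "A114G"), fx$landscape$sites)
  fun[keep + 1] <- TRUE; lam[keep + 1] <- 356   # leave only the lethal single
  one_nf <- landscape(fx$landscape$sites, 357, lambda = lam, functional = fun)
  expect_equal(count_accessible(one_nf)$accessible, 5040 - 720)
})

test_that("step classification thresholds behave literally", {
  fx <- s1_like_fixture()
  trj <- enumerate_trajectories(fx$landscape)
  all_pass <- classify_by_step(trj, threshold_nm = Inf)
  expect_equal(all_pass$n_within, sum(trj$status == "complete"))
  expect_error(classify_by_step(trj, threshold_nm = 0), "positive")

  # additive landscape: every step equals a single effect
  theta <- numeric(16)
  theta[2^(0:3) + 1] <- c(3, -4, 10, 2)
  lam <- vapply(0:15, function(m) 400 + sum(theta[submasks(m) + 1]), numeric(1))
  add <- landscape(letters[1:4], 400, lambda = lam, functional = rep(TRUE, 16))
  at <- enumerate_trajectories(add)
  expect_equal(classify_by_step(at, threshold_nm = 11)$n_within, 24)
  expect_equal(classify_by_step(at, threshold_nm = 10)$n_within, 0)   # strict
  expect_equal(classify_by_step(at, threshold_nm = 10, strict = FALSE)$n_within, 24)
})

test_that("per-path step variance matches hand arithmetic and the split partitions", {
  # additive landscape whose every path steps through the same delta multiset
  deltas <- c(0, 0, 20, 0, 20, 0, 14)
  theta <- numeric(2^7)
  theta[2^(0:6) + 1] <- deltas
  lam <- vapply(0:127, function(m) 357 + sum(theta[submasks(m) + 1]), numeric(1))
  add <- landscape(paste0("m", 1:7), 357, lambda = lam,
                   functional = rep(TRUE, 128))
  trj <- enumerate_trajectories(add)
  expect_equal(unique(trj$step_variance), 676 / 7, tolerance = 1e-12)
  vs <- path_variance_distribution(trj, split_threshold_nm = 30)
  expect_equal(length(vs$with_large) + length(vs$without_large), 5040)
  expect_equal(length(vs$with_large), 0)    # no step exceeds 30
  vs15 <- path_variance_distribution(trj, split_threshold_nm = 15)
  expect_equal(length(vs15$without_large), 0)
  # population denominator rescales by (n-1)/n
  vp <- path_variance_distribution(trj, split_threshold_nm = 30,
                                   population = TRUE)
  expect_equal(unname(vp$without_large[1]), (676 / 7) * 6 / 7)
})

test_that("constrained enumeration respects the partial order", {
  fx <- s1_like_fixture()
  cp <- constrained_paths(fx$landscape, fx$partial_order)
  expect_equal(nrow(cp$perm), 8)
  expect_true(all(cp$status == "complete"))
  # group order: T93P/A114G before F86L before F49L/S118T before F46T/T52F
  g1 <- match(c("T93P", "A114G"), fx$landscape$sites)
  g4 <- match(c("F46T", "T52F"), fx$landscape$sites)
  expect_true(all(cp$perm[, 1:2] %in% g1))
  expect_true(all(cp$perm[, 6:7] %in% g4))
  # the epistasis-only prediction tracks the observed profile closely
  expect_true(all(abs(cp$lambda_epistasis - cp$lambda) <= 8))

  # fully ordered chain -> exactly one path; one group of L -> L! paths
  chain <- as.list(fx$landscape$sites)
  expect_equal(nrow(constrained_paths(fx$landscape, chain)$perm), 1)
  hm <- human_m_fixture()
  expect_equal(nrow(constrained_paths(hm, list(hm$sites))$perm), 6)
  expect_error(constrained_paths(hm, list(c("S180A", "S180A"), "Y277F")),
               "disjoint")
  expect_error(constrained_paths(hm, list("S180A")), "cover exactly")
})

test_that("enumeration refuses landscapes too large to brute-force", {
  lam <- c(100, rep(NA, 2^11 - 1))
  fun <- c(TRUE, rep(FALSE, 2^11 - 1))
  big <- landscape(paste0("m", 1:11), 100, lambda = lam, functional = fun)
  expect_error(enumerate_trajectories(big), "count_accessible")
})
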