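# Factorial decomposition, imputation, reconstruction, uncertainty.

theta_of <- function(effects, label) {
  effects$theta[match(label, effects$subset)]
}

test_that("three-site long-wavelength fixture decomposes to the known effects", {
  fit <- decompose(human_m_fixture())
  ef <- fit$effects
  expect_equal(theta_of(ef, "S180A"), -5)
  expect_equal(theta_of(ef, "Y277F"), -10)
  expect_equal(theta_of(ef, "T285A"), -17)
  expect_equal(theta_of(ef, "S180A+Y277F"), 0)
  expect_equal(theta_of(ef, "S180A+T285A"), -2)
  expect_equal(theta_of(ef, "Y277F+T285A"), 1)
  expect_equal(theta_of(ef, "S180A+Y277F+T285A"), 4)
  expect_equal(sum(ef$theta), -29)
  expect_false(any(ef$imputed))
})

test_that("nonfunctional genotypes get zero theta and a cascaded imputed lambda", {
  # lethal single mutant: its effect is pinned to zero, lambda to the ancestor
  sites <- c("F46T", "T52F", "A114G")
  theta <- numeric(8)
  theta[genotype_mask("F46T", sites) + 1] <- -2
  theta[genotype_mask("A114G", sites) + 1] <- 1
  lam <- vapply(0:7, function(m) 357 + sum(theta[submasks(m) + 1]), numeric(1))
  fun <- rep(TRUE, 8)
  nf <- c(genotype_mask("T52F", sites), genotype_mask(c("F46T", "A114G"), sites))
  fun[nf + 1] <- FALSE
  lam[nf + 1] <- NA
  ls <- landscape(sites, 357, lambda = lam, functional = fun)

  fit <- decompose(ls)
  expect_equal(theta_of(fit$effects, "T52F"), 0)
  expect_true(fit$effects$imputed[match("T52F", fit$effects$subset)])
  expect_equal(landscape_lambda(fit$landscape, "T52F"), 357)
  expect_identical(fit$landscape$source[genotype_mask("T52F", sites) + 1],
                   "imputed")
  # second worked example: singles -2 and +1, lethal double -> imputed 356
  expect_equal(theta_of(fit$effects, "F46T+A114G"), 0)
  expect_equal(landscape_lambda(fit$landscape, c("F46T", "A114G")), 356)

  # cascade: a nonfunctional genotype above another nonfunctional genotype
  fun2 <- fun; lam2 <- lam
  m <- genotype_mask(c("T52F", "A114G"), sites)
  fun2[m + 1] <- FALSE; lam2[m + 1] <- NA
  ls2 <- landscape(sites, 357, lambda = lam2, functional = fun2)
  fit2 <- decompose(ls2)
  # uses the already-imputed theta_52 = 0: lambda = 357 + 0 + 1 + 0
  expect_equal(landscape_lambda(fit2$landscape, c("T52F", "A114G")), 358)
})

test_that("reconstruction reproduces every lambda and supports min_order", {
  fit <- decompose(human_m_fixture())
  expect_equal(reconstruct(fit$effects, c("S180A", "Y277F")), 545)
  expect_equal(reconstruct(fit$effects, c("S180A", "Y277F", "T285A")), 531)
  expect_equal(reconstruct(fit$effects, "ancestor"), 560)
  expect_equal(reconstruct(fit$effects, "ancestor", min_order = 2), 560)
  # epistasis-only prediction drops the mains
  expect_equal(reconstruct(fit$effects, c("S180A", "Y277F"), min_order = 2),
               560 + 0)
  expect_equal(reconstruct(fit$effects,
                           c("S180A", "Y277F", "T285A"), min_order = 2),
               560 + 0 - 2 + 1 + 4)
  expect_error(reconstruct(fit$effects, "Z1X"), "unknown mutation")
})

test_that("exact roundtrip holds for measured and imputed genotypes", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(2:6, 1)
    ls <- random_lethal_landscape(L, p_nf = 0.25)
    fit <- decompose(ls)
    for (m in 0:(2^L - 1)) {
      expect_equal(reconstruct(fit$effects, m), fit$landscape$lambda[m + 1],
                   tolerance = 1e-12)
    }
    expect_true(all(fit$effects$theta[fit$effects$imputed] == 0))
  }
})

test_that("Moebius inversion agrees exactly with forward substitution", {
  set.seed(7)
  for (rep in 1:40) {
    L <- sample(2:6, 1)
    # integer lambdas (the assay reports whole nm): bit-identical results
    ls <- random_functional_landscape(L)
    expect_identical(mobius_decompose(ls)$theta, decompose(ls)$effects$theta)
  }
  for (rep in 1:10) {
    ls <- random_functional_landscape(5, integer = FALSE)
    expect_equal(mobius_decompose(ls)$theta, decompose(ls)$effects$theta,
                 tolerance = 1e-9)
  }
  # flat landscape: every effect zero
  flat <- landscape(c("a", "b", "c"), 400, lambda = rep(400, 8),
                    functional = rep(TRUE, 8))
  expect_true(all(mobius_decompose(flat)$theta == 0))
})

test_that("design system is unit lower-triangular subset incidence", {
  ls <- random_functional_landscape(3)
  sys <- build_design_system(ls)
  expect_equal(dim(sys$C), c(8, 8))
  expect_true(all(diag(sys$C) == 1))
  expect_true(all(sys$C[upper.tri(sys$C)] == 0))
  # row for the full genotype includes every column
  expect_true(all(sys$C[8, ] == 1))
  # solving the system is the decomposition
  x <- solve(sys$C, sys$Y)
  fit <- decompose(ls)
  expect_equal(unname(x[-1]), fit$effects$theta, tolerance = 1e-10)
})

test_that("standard errors follow the 2^(|S|/2) closed form under V = I", {
  for (L in 2:8) {
    ls <- random_functional_landscape(L)
    sys <- build_design_system(ls)
    se <- standard_errors(sys)
    expect_equal(unname(se), 2^(popcount(sys$masks) / 2), tolerance = 1e-10)
  }
  # no observation noise -> no uncertainty
  ls <- random_functional_landscape(3)
  sys0 <- build_design_system(ls, V = matrix(0, 8, 8))
  expect_true(all(standard_errors(sys0) == 0))
})

test_that("significance gives two-sided normal p-values with star flags", {
  fit <- decompose(human_m_fixture())
  ef <- significance(fit$effects)   # closed-form SE 2^(order/2)
  i285 <- match("T285A", ef$subset)
  expect_equal(ef$se[i285], sqrt(2))
  expect_lt(ef$p[i285], 0.01)
  expect_identical(ef$stars[i285], "**")
  i0 <- match("S180A+Y277F", ef$subset)   # theta = 0
  expect_equal(ef$p[i0], 1)
  expect_identical(ef$stars[i0], "")
  # |z| = 1.96 sits at the 0.05 boundary
  ef2 <- significance(fit$effects, se = abs(fit$effects$theta) / 1.96)
  expect_equal(ef2$p[i285], 0.05, tolerance = 1e-3)
  # zero SE with nonzero theta -> p = 0 with a warning
  expect_warning(ef3 <- significance(fit$effects, se = 0), "zero SE")
  expect_equal(ef3$p[i285], 0)
  expect_equal(ef3$p[i0], 1)
})

test_that("stable-only analysis returns exactly the full-analysis values", {
  # all functional: identical tables
  ls <- random_functional_landscape(4)
  full <- decompose(ls)$effects
  red <- decompose_stable_only(ls)
  expect_equal(red$theta, full$theta)

  # lethal single: its theta absent, everything estimable matches
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(3:6, 1)
    ls <- random_lethal_landscape(L, p_nf = 0.3)
    full <- decompose(ls)$effects
    red <- decompose_stable_only(ls)
    expect_false(any(mask_label(which(!ls$functional) - 1, ls$sites)
                     %in% red$subset))
    idx <- match(red$mask, full$mask)
    expect_equal(red$theta, full$theta[idx], tolerance = 1e-12)
  }
})
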