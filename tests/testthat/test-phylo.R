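test_that("conditional error probabilities reproduce all printed pairs", {
  expect_equal(round(100 * conditional_error_probability(0.05)), 29)
  expect_equal(round(100 * conditional_error_probability(0.001), 2), 1.84)
  pairs <- rbind(
    c(0.0014, 0.0244), c(0.0004, 0.0084), c(0.0024, 0.0379),
    c(0.0013, 0.0229), c(0.0011, 0.0200), c(0.0005, 0.0102),
    c(0.9421, 0.1325), c(0.9301, 0.1548), c(0.7044, 0.4015),
    c(0.6938, 0.4081), c(0.077, 0.3492))
  for (i in seq_len(nrow(pairs)))
    expect_equal(round(conditional_error_probability(pairs[i, 1]), 4),
                 pairs[i, 2], info = paste("p =", pairs[i, 1]))
})

test_that("alpha(p) is 1/2 at p = 1/e, monotone below, and domain-checked", {
  expect_equal(conditional_error_probability(exp(-1)), 0.5,
               tolerance = 1e-12)
  p <- seq(0.001, exp(-1), length.out = 50)
  expect_true(all(diff(conditional_error_probability(p)) > 0))
  expect_error(conditional_error_probability(0), "between 0 and 1")
  expect_error(conditional_error_probability(1), "between 0 and 1")
  expect_error(conditional_error_probability(-0.1), "between 0 and 1")
})

test_that("calibration yields positive branches and honours occurrence ages", {
  topo <- ape::read.tree(text = "(A,B);")
  occ <- data.frame(tip = c("A", "B"), fad_ma = c(80, 75),
                    lad_ma = c(78, 70))
  tree <- calibrate_tree(topo, occ)
  expect_true(all(tree$edge.length > 0))
  ages <- attr(tree, "ages")
  expect_gte(ages[3], 80)  # root at least as old as the oldest FAD

  expect_error(calibrate_tree(topo, occ[1, , drop = FALSE]), "B")
  bad <- occ; bad$fad_ma[1] <- 60
  expect_error(calibrate_tree(topo, bad), "postdate")
})

test_that("same-species polytomies keep near-equal tip covariances", {
  topo <- ape::read.tree(text = "((S1,S2,S3),Out);")
  occ <- data.frame(tip = c("S1", "S2", "S3", "Out"),
                    fad_ma = c(70, 70, 70, 95),
                    lad_ma = c(66, 66, 66, 90))
  tree <- calibrate_tree(topo, occ, padding = 1, epsilon = 0.001)
  expect_true(ape::is.binary(tree))
  expect_true(all(tree$edge.length > 0))
  V <- ape::vcv(tree)
  offd <- c(V["S1", "S2"], V["S1", "S3"], V["S2", "S3"])
  expect_lt(diff(range(offd)), 0.01)
})

test_that("calibrated patristic distances match brute-force path sums", {
  topo <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  occ <- data.frame(tip = LETTERS[1:6],
                    fad_ma = c(70, 68, 80, 75, 90, 85),
                    lad_ma = c(65, 66, 74, 70, 82, 80))
  tree <- calibrate_tree(topo, occ)
  expect_equal(unname(as.matrix(stats::cophenetic(tree))[LETTERS[1:6],
                                                         LETTERS[1:6]]),
               unname(path_sum_distances(tree)[LETTERS[1:6], LETTERS[1:6]]),
               tolerance = 1e-9)
})

test_that("precalibrated trees bypass calibration; datable trees need dates", {
  tree <- simulate_bm_tree(8, seed = 3)
  expect_identical(calibrate_tree(tree, NULL), tree)
  tree$edge.length <- NULL
  expect_error(calibrate_tree(tree, NULL), "branch lengths")
})

test_that("lambda transform scales only the off-diagonal covariances", {
  tree <- balanced_tree4()
  V1 <- bm_covariance(tree, 1)
  expect_equal(V1, ape::vcv(tree))
  ## hand-computed shared path lengths on the drawn tree
  expect_equal(V1["A", "B"], 2)
  expect_equal(V1["C", "D"], 1.5)
  expect_equal(V1["A", "C"], 0)
  expect_equal(diag(V1), c(A = 3, B = 3, C = 3, D = 3))
  V0 <- bm_covariance(tree, 0)
  expect_true(all(V0[upper.tri(V0)] == 0))
  expect_equal(diag(V0), diag(V1))
  Vh <- bm_covariance(tree, 0.6)
  expect_equal(Vh["A", "B"], 1.2, tolerance = 1e-12)
  expect_error(bm_covariance(tree, 1.2), "\\[0, 1\\]")
})

test_that("the lambda covariance is symmetric positive semi-definite", {
  tree <- simulate_bm_tree(15, seed = 8)
  for (lam in c(0, 0.3, 0.7, 1)) {
    V <- bm_covariance(tree, lam)
    expect_equal(V, t(V))
    expect_true(all(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("lambda likelihood at 1 equals an independent plain-BM GLS value", {
  tree <- simulate_bm_tree(12, seed = 5)
  tr <- simulate_traits(tree, lambda = 1, slope = 0, intercept = 2,
                        rate = 1e-4, seed = 6)
  y <- setNames(tr$y, tr$tip)
  fit <- estimate_lambda(y, tree)
  ## independent evaluation of the profiled BM likelihood by direct solve
  V <- ape::vcv(tree)
  Vi <- solve(V)
  one <- rep(1, length(y))
  mu <- sum(Vi %*% y) / sum(Vi)
  n <- length(y)
  s2 <- drop(t(y - mu * one) %*% Vi %*% (y - mu * one)) / n
  ll1 <- -0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus + n)
  expect_equal(fit$logLik1, as.numeric(ll1), tolerance = 1e-8)
  expect_gte(fit$logLik, fit$logLik0)
  expect_gte(fit$logLik, fit$logLik1)
})

test_that("lambda estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tree <- simulate_bm_tree(40, seed = 21)
  tr <- simulate_traits(tree, lambda = 0.7, slope = 0, intercept = 0,
                        rate = 1e-4, seed = 22)
  y <- setNames(tr$y, tr$tip)
  ours <- estimate_lambda(y, tree)
  ref <- phytools::phylosig(tree, y, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-4)
  expect_equal(ours$logLik, ref$logL, tolerance = 1e-4)
})

test_that("signal is recovered when present and absent when destroyed", {
  tree <- simulate_bm_tree(50, depth = 100, seed = 7)
  set.seed(99)
  lams <- replicate(60, {
    tr <- simulate_traits(tree, lambda = 1, slope = 0, intercept = 0,
                          rate = 1e-4)
    estimate_lambda(setNames(tr$y, tr$tip), tree)$lambda
  })
  expect_lt(abs(median(lams) - 1), 0.05)
  tr <- simulate_traits(tree, lambda = 1, slope = 0, intercept = 0,
                        rate = 1e-4, seed = 100)
  perm <- setNames(sample(tr$y), tr$tip)
  expect_lt(estimate_lambda(perm, tree)$lambda, 0.2)
  expect_warning(estimate_lambda(setNames(rep(1, 50), tree$tip.label),
                                 tree), "constant")
})

test_that("PGLS with a hand-built covariance matches explicit GLS algebra", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,((C:1,D:1):0.5,E:1.5):1.5);")
  set.seed(14)
  x <- setNames(rnorm(5), tree$tip.label)
  y <- setNames(2 - x + rnorm(5, sd = 0.3), tree$tip.label)
  fit <- pgls_fit(y, x, tree, lambda = 0.8)
  V <- bm_covariance(tree, 0.8)
  X <- cbind(1, x[tree$tip.label])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[tree$tip.label])
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-10)
  e <- y[tree$tip.label] - X %*% beta
  s2 <- drop(t(e) %*% Vi %*% e) / (5 - 2)
  expect_equal(unname(fit$se),
               sqrt(diag(s2 * solve(t(X) %*% Vi %*% X))),
               tolerance = 1e-10)
})

test_that("PGLS equals OLS on ultrametric trees at lambda 0 and star trees", {
  tree <- simulate_bm_tree(20, seed = 31)       # ultrametric
  tr <- simulate_traits(tree, lambda = 1, seed = 32)
  y <- setNames(tr$y, tr$tip); x <- setNames(tr$x, tr$tip)
  fit0 <- pgls_fit(y, x, tree, lambda = 0)
  ols <- lm(y[tree$tip.label] ~ x[tree$tip.label])
  expect_equal(unname(fit0$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  ## star tree: OLS for any lambda
  star <- ape::stree(12, "star")
  star$edge.length <- rep(2, 12)
  trs <- simulate_traits(star, lambda = 1, seed = 33)
  ys <- setNames(trs$y, trs$tip); xs <- setNames(trs$x, trs$tip)
  for (lam in c(0, 0.5, 1)) {
    f <- pgls_fit(ys, xs, star, lambda = lam)
    expect_equal(unname(f$coefficients),
                 unname(coef(lm(ys[star$tip.label] ~ xs[star$tip.label]))),
                 tolerance = 1e-10)
  }
  expect_error(pgls_fit(y, setNames(rep(1, 20), tree$tip.label), tree),
               "rank deficient")
})

test_that("PGLS confidence intervals cover the true slope at near-nominal rate", {
  tree <- simulate_bm_tree(40, depth = 100, seed = 41)
  set.seed(42)
  cover <- replicate(300, {
    tr <- simulate_traits(tree, lambda = 1, slope = -1, intercept = 2.9,
                          rate = 1e-4)
    fit <- pgls_fit(setNames(tr$y, tr$tip), setNames(tr$x, tr$tip), tree,
                    lambda = 1)
    lo <- fit$coefficients[2] - qt(0.975, fit$df_residual) * fit$se[2]
    hi <- fit$coefficients[2] + qt(0.975, fit$df_residual) * fit$se[2]
    lo <= -1 && -1 <= hi
  })
  expect_gte(mean(cover), 0.93)
})

test_that("prediction intervals contain the data at a sensible rate", {
  tree <- simulate_bm_tree(30, depth = 100, seed = 51)
  tr <- simulate_traits(tree, lambda = 1, slope = -1, intercept = 2.9,
                        rate = 1e-4, seed = 52)
  fit <- pgls_fit(setNames(tr$y, tr$tip), setNames(tr$x, tr$tip), tree)
  iv <- fit$intervals
  expect_true(all(iv$pi_lwr < iv$ci_lwr & iv$ci_upr < iv$pi_upr))
  expect_gte(mean(iv$y >= iv$pi_lwr & iv$y <= iv$pi_upr), 0.9)
})

test_that("grade F-tests detect an injected grade offset", {
  tree <- simulate_bm_tree(20, depth = 100, seed = 61)
  clade <- ape::extract.clade(tree, ape::getMRCA(tree, c(1, 5)))$tip.label
  if (length(clade) < 3 || length(clade) > 15)
    clade <- tree$tip.label[1:6]
  grp <- setNames(ifelse(tree$tip.label %in% clade, "focal", "rest"),
                  tree$tip.label)
  cmp <- list(focal_vs_rest = list(
    reduced = NULL, full = c(focal = "focal", rest = "rest")))
  set.seed(62)
  ps <- replicate(30, {
    tr <- simulate_traits(tree, lambda = 1, slope = -1, intercept = 2.9,
                          rate = 1e-4, grade_offsets = c(focal = 0.4),
                          groups = grp)
    phyl_ancova(setNames(tr$y, tr$tip), setNames(tr$x, tr$tip), tree,
                grp, comparisons = cmp)$p
  })
  expect_gt(mean(ps < 0.001), 0.5)
})

test_that("grade F-tests are invariant to affine rescaling of the response", {
  tree <- simulate_bm_tree(18, seed = 71)
  grp <- setNames(rep(c("a", "b", "c"), each = 6), tree$tip.label)
  cmp <- list(among = list(reduced = NULL,
                           full = c(a = "a", b = "b", c = "c")))
  tr <- simulate_traits(tree, lambda = 1, seed = 72)
  y <- setNames(tr$y, tr$tip); x <- setNames(tr$x, tr$tip)
  r1 <- phyl_ancova(y, x, tree, grp, comparisons = cmp, lambda = 1)
  r2 <- phyl_ancova(5 + 3 * y, x, tree, grp, comparisons = cmp, lambda = 1)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("degenerate and underpowered comparisons are handled", {
  tree <- simulate_bm_tree(12, seed = 81)
  grp <- setNames(rep(c("a", "b"), each = 6), tree$tip.label)
  tr <- simulate_traits(tree, seed = 82)
  y <- setNames(tr$y, tr$tip); x <- setNames(tr$x, tr$tip)
  ## full identical to reduced: zero extra parameters, F = 0, p = 1
  cmp <- list(null = list(reduced = c(a = "g", b = "g"),
                          full = c(a = "g", b = "g")))
  r <- phyl_ancova(y, x, tree, grp, comparisons = cmp, lambda = 1)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_true(is.na(r$alpha_p))
  ## a grade with fewer than 2 tips is refused
  grp2 <- grp; grp2[1] <- "c"; grp2[-1] <- "a"
  cmp2 <- list(bad = list(reduced = NULL,
                          full = c(a = "a", c = "c")))
  expect_error(phyl_ancova(y, x, tree, grp2, comparisons = cmp2,
                           lambda = 1), "insufficient")
})

test_that("default comparisons ladder matches the canonical grouping", {
  cmps <- default_agility_comparisons()
  expect_named(cmps, c("among_groups", "juvenile_vs_adult",
                       "tyrannosaurs_vs_others"))
  tree <- simulate_bm_tree(21, seed = 91)
  grp <- setNames(rep(c("tyrannosaurid_adult", "tyrannosaurid_juvenile",
                        "other"), each = 7), tree$tip.label)
  tr <- simulate_traits(tree, seed = 92)
  rep_tab <- phyl_ancova(setNames(tr$y, tr$tip), setNames(tr$x, tr$tip),
                         tree, grp)
  expect_equal(rep_tab$comparison,
               c("among_groups", "juvenile_vs_adult",
                 "tyrannosaurs_vs_others"))
  expect_equal(rep_tab$df1, c(2L, 1L, 1L))
  expect_true(all(rep_tab$F >= 0))
  expect_true(all(rep_tab$p > 0 & rep_tab$p <= 1))
  lam <- attr(rep_tab, "lambda")
  expect_gte(lam, 0); expect_lte(lam, 1)
})
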