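test_that("AUC pair counting matches known cases and the brute-force
          oracle", {
  expect_equal(auc_effect(5, 5), 0.5)              # all ties
  expect_equal(auc_effect(c(1, 2, 3), c(4, 5, 6)), 1)  # separation
  expect_equal(auc_effect(c(1, 3), c(2, 4)), 0.75)
  set.seed(50)
  for (rep in 1:30) {
    a <- sample(1:20, sample(2:50, 1), replace = TRUE)
    b <- sample(1:20, sample(2:50, 1), replace = TRUE)
    expect_equal(auc_effect(a, b), oracle_auc(a, b))
    # complement identity (holds with ties too, by half-weighting)
    expect_equal(auc_effect(a, b) + auc_effect(b, a), 1)
  }
  expect_error(auc_effect(numeric(0), 1), "non-empty")
})

test_that("AUC is invariant under common strictly increasing
          transforms", {
  set.seed(51)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  expect_equal(auc_effect(exp(a), exp(b)), auc_effect(a, b))
  expect_equal(auc_effect(2 * a + 3, 2 * b + 3), auc_effect(a, b))
})

test_that("effect magnitudes are mirrored and labelled on the academic
          scale", {
  m <- auc_magnitude(0.15)
  expect_equal(m$magnitude, 0.85)
  expect_equal(m$label, "good/excellent")
  expect_equal(auc_magnitude(0.95)$label, "excellent/outstanding")
  expect_equal(auc_magnitude(0.72)$label, "fair/acceptable")
  expect_equal(auc_magnitude(0.62)$label, "poor")
  expect_equal(auc_magnitude(0.5)$label, "none")
})

test_that("bootstrap CI flags well-separated groups and satisfies the
          EffectSize invariants", {
  set.seed(52)
  a <- rnorm(8); b <- rnorm(8, 3)  # 3 SD apart
  es <- bootstrap_auc_ci(a, b, n_boot = 2000)
  expect_true(es$significant)
  expect_lte(es$ci_low, es$auc)
  expect_gte(es$ci_high, es$auc)
  expect_identical(es$significant, es$ci_low > 0.5 || es$ci_high < 0.5)
  expect_error(bootstrap_auc_ci(1, c(1, 2)), "at least 2")
})

test_that("bootstrap draws are reproducible under a fixed seed", {
  a <- rnorm(7); b <- rnorm(8)
  e1 <- bootstrap_auc_ci(a, b, n_boot = 500, seed = 9)
  e2 <- bootstrap_auc_ci(a, b, n_boot = 500, seed = 9)
  expect_identical(e1, e2)
})

test_that("the neighbor rule masks isolated bins and keeps runs", {
  set.seed(53)
  # build spectra where bins 3 and 7:9 differ strongly between groups
  nb <- 12
  a <- matrix(rnorm(8 * nb, 0, 0.05), nrow = 8)
  b <- matrix(rnorm(8 * nb, 0, 0.05), nrow = 8)
  b[, 3] <- b[, 3] + 1       # isolated significant bin
  b[, 7:9] <- b[, 7:9] + 1   # run of three
  mask <- spectral_auc_mask(a, b, n_boot = 500, seed = 1)
  expect_true(mask$significant[3])
  expect_false(mask$masked[3])            # isolated bin masked out
  expect_true(all(mask$masked[7:9]))      # run retained
  expect_true(all(!mask$masked | mask$significant))  # subset property
  r <- rle(mask$masked)
  expect_true(all(r$lengths[r$values] >= 2))
  expect_error(spectral_auc_mask(a, b[, 1:5]), "grids")
})

test_that("Anderson-Darling test accepts identical samples and rejects
          a location-scaled alternative", {
  set.seed(54)
  x <- rlnorm(30, 4, 0.8)
  perm <- anderson_darling_2samp(x, x, method = "permutation",
                                 n_perm = 499, seed = 1)
  expect_gt(perm$p, 0.9)
  a <- rlnorm(100, 4, 0.8); b <- rlnorm(100, 4 - log(2), 0.8)
  expect_lt(anderson_darling_2samp(a, b)$p, 0.01)
  expect_error(anderson_darling_2samp(1, c(1, 2)), "at least 2")
})

test_that("asymptotic AD p-values sit near the published critical
          points", {
  # at T = t_1(0.05) = 1.961 the interpolated p is ~0.05
  expect_equal(sleeparch:::ad_pvalue_interp(1.961), 0.05,
               tolerance = 0.002)
  expect_equal(sleeparch:::ad_pvalue_interp(3.752), 0.01,
               tolerance = 0.002)
})

test_that("small samples fall back to permutation automatically", {
  set.seed(55)
  res <- anderson_darling_2samp(rnorm(3), rnorm(4))
  expect_equal(res$method, "permutation")
})

test_that("two-way ANOVA reproduces hand-computed sums of squares on a
          2x2 fixture", {
  # cells: (g1,t1)=c(1,2,3) (g1,t2)=c(2,3,4) (g2,t1)=c(3,4,5)
  # (g2,t2)=c(6,7,8); hand computation: SS_g=27, SS_t=12, SS_gt=3,
  # SS_e=8 with df 1,1,1,8 -> F_g=27, F_t=12, F_gt=3
  d <- data.frame(
    proportion = c(1, 2, 3, 2, 3, 4, 3, 4, 5, 6, 7, 8),
    group = rep(c("g1", "g2"), each = 6),
    time = rep(rep(c("t1", "t2"), each = 3), 2))
  res <- proportions_anova(d)
  expect_equal(res$table$F[1:3], c(27, 12, 3), tolerance = 1e-9)
  expect_equal(res$table$df, c(1, 1, 1, 8))
  # identical groups, no variance: F for group is 0
  d2 <- d; d2$proportion <- rep(c(1, 2, 3), 4)
  expect_equal(proportions_anova(d2)$table$F[1], 0, tolerance = 1e-9)
  expect_error(proportions_anova(d[d$group == "g1", ]), "2 levels")
})

test_that("Dunn-Sidak adjustment has the closed form", {
  expect_equal(sidak_alpha(0.05, 12), 1 - 0.95^(1 / 12))
  expect_equal(sidak_alpha(0.05, 1), 0.05)
})

test_that("chi-squared on 2x2 counts reports both variants and matches
          the closed form", {
  res <- chisq_counts(c(3, 4), c(2, 6))
  # closed form: sum (O-E)^2/E on the 2x2 table
  o <- c(3, 4, 2, 6)
  e <- c(7 * 5 / 15, 7 * 10 / 15, 8 * 5 / 15, 8 * 10 / 15)
  expect_equal(res$statistic, sum((o - e)^2 / e))
  expect_lt(res$p_yates, 1)
  expect_gt(res$p_yates, res$p * 0.99)  # correction never lowers p here
  eq <- chisq_counts(c(5, 5), c(5, 5))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_lt(chisq_counts(c(10, 0), c(0, 10))$p, 0.001)
  expect_error(chisq_counts(c(0, 0), c(1, 1)), "marginal")
})

test_that("Grubbs test flags gross outliers and spares clean normal
          samples", {
  expect_equal(grubbs_test(c(1, 1.1, 0.9, 10)), 4L)
  set.seed(56)
  flagged <- vapply(1:200, function(i) {
    length(grubbs_test(rnorm(20))) > 0
  }, logical(1))
  expect_lt(mean(flagged), 0.12)  # ~alpha-level false positives
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
  expect_error(grubbs_test(rep(2, 5)), "constant")
})
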