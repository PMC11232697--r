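test_that("the observed sex contrast yields a positive verdict", {
  h_focal <- c(rep(0.027, 7), rep(0.006, 3))
  h_auto <- rep(0.006, 10)
  sexes <- c(rep("female", 7), rep("male", 3))
  res <- sex_contrast_heterozygosity(h_focal, h_auto, sexes,
                                     factor_threshold = 3)
  expect_true(res$verdict)
  expect_equal(res$mean_female_focal, 0.027)
  expect_equal(res$ratio, 4.5)
})

test_that("equal heterozygosity in both sexes gives a negative verdict", {
  res <- sex_contrast_heterozygosity(rep(0.01, 6), rep(0.01, 6),
                                     rep(c("female", "male"), 3))
  expect_false(res$verdict)
  res0 <- sex_contrast_heterozygosity(rep(0, 6), rep(0, 6),
                                      rep(c("female", "male"), 3))
  expect_false(res0$verdict)
  expect_equal(res0$flag, "uninformative")
})

test_that("the verdict is invariant to scaling all H by a constant", {
  h_focal <- c(0.027, 0.03, 0.025, 0.006, 0.005)
  h_auto <- rep(0.006, 5)
  sexes <- c("female", "female", "female", "male", "male")
  r1 <- sex_contrast_heterozygosity(h_focal, h_auto, sexes)
  r2 <- sex_contrast_heterozygosity(h_focal * 7.3, h_auto * 7.3, sexes)
  expect_equal(r1$verdict, r2$verdict)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("PCA separates constructed clusters with score 1", {
  set.seed(2)
  base <- rbinom(40, 1, 0.5)
  m <- rbind(matrix(rep(base, 4), 4, byrow = TRUE),
             matrix(rep(1 - base, 4), 4, byrow = TRUE))
  rownames(m) <- paste0("s", 1:8)
  sexes <- rep(c("female", "male"), each = 4)
  p <- genotype_pca(m, sexes = sexes)
  expect_equal(p$sep_score, 1)
  expect_gt(p$var_explained[1], 0.9)
})

test_that("unstructured genotypes give near-chance separation", {
  set.seed(3)
  scores <- replicate(50, {
    m <- matrix(rbinom(10 * 60, 2, 0.3), 10, 60)
    rownames(m) <- paste0("s", 1:10)
    genotype_pca(m, sexes = rep(c("female", "male"), each = 5))$sep_score
  })
  # best-threshold score on 10 samples is biased above 0.5 by optimization,
  # but should stay well below perfect separation on average
  expect_lt(mean(scores), 0.85)
  expect_gt(mean(scores), 0.5)
})

test_that("PCA coordinates are invariant (up to sign) to sample order", {
  set.seed(4)
  m <- matrix(rbinom(6 * 50, 2, 0.4), 6, 50)
  rownames(m) <- paste0("s", 1:6)
  p1 <- genotype_pca(m)
  perm <- c(4, 2, 6, 1, 3, 5)
  p2 <- genotype_pca(m[perm, ])
  pc1_a <- p1$scores$PC1[perm]
  pc1_b <- p2$scores$PC1
  expect_true(isTRUE(all.equal(pc1_a, pc1_b, tolerance = 1e-6)) ||
                isTRUE(all.equal(pc1_a, -pc1_b, tolerance = 1e-6)))
})

test_that("simulated fused chromosome clusters by sex, autosome does not", {
  d <- mini_dataset()
  flt <- filter_variants(d$variants, d$mask, mean_depth = 20)
  ib <- d$samples$id[d$samples$population == "Iberia"]
  p_foc <- genotype_pca(vt_subset(flt$variants,
                                  flt$variants$sites$chrom == "chrNeo", ib))
  p_aut <- genotype_pca(vt_subset(flt$variants,
                                  flt$variants$sites$chrom == "chrA1", ib))
  expect_equal(p_foc$sep_score, 1)
  expect_lt(p_aut$sep_score, 1)
})

test_that("the carrier-frequency CI matches the printed bound for 7 of 7", {
  ci <- binomial_frequency_ci(7, 7, 0.95)
  expect_equal(round(ci$lower, 2), 0.59)
  expect_equal(ci$upper, 1)
  expect_equal(ci$lower, (0.025)^(1 / 7))
})

test_that("Clopper-Pearson bounds invert the binomial tails", {
  expect_equal(binomial_frequency_ci(0, 7)$lower, 0)
  ci <- binomial_frequency_ci(3, 10, 0.95)
  # independent oracle: numeric inversion of the binomial CDF
  lower <- uniroot(function(p) 1 - pbinom(2, 10, p) - 0.025,
                   c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  upper <- uniroot(function(p) pbinom(3, 10, p) - 0.025,
                   c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(ci$lower, lower, tolerance = 1e-8)
  expect_equal(ci$upper, upper, tolerance = 1e-8)
  expect_error(binomial_frequency_ci(3, 0), "positive")
})

test_that("the lower bound at k = n increases with sample size", {
  lows <- vapply(3:15, function(n) binomial_frequency_ci(n, n)$lower,
                 numeric(1))
  expect_true(all(diff(lows) > 0))
})
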