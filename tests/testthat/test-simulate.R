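test_that("simulation is deterministic under a fixed seed", {
  cfg <- mini_cfg()
  a <- simulate_dataset(cfg, seed = 7)
  b <- simulate_dataset(cfg, seed = 7)
  expect_identical(a$variants$sites, b$variants$sites)
  expect_identical(a$variants$a1, b$variants$a1)
  expect_identical(a$coverage$depth, b$coverage$depth)
  expect_identical(a$truth$w_tree, b$truth$w_tree)
  c <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(a$variants$sites, c$variants$sites))
})

test_that("a vanishing neo-W size collapses the clade to a star of depth ~ 0", {
  cfg <- mini_cfg(ne_neo_w = 1e-3)
  w <- simulate_w_genealogy(cfg, seed = 1)
  expect_lt(w$tmrca, 1)
  g <- simulate_neo_sex_genealogy(cfg, 1, n_blocks = 50, seed = 2)
  wcols <- g$haplotypes[, 1:7, drop = FALSE]
  # all neo-W tips identical at every site
  expect_true(all(apply(wcols, 1, function(x) length(unique(x)) == 1)))
})

test_that("neo-W/neo-Z divergence matches the closed-form coalescent mean", {
  cfg <- mini_cfg()
  for (k in c(1, 3)) {
    g <- simulate_neo_sex_genealogy(cfg, k, n_blocks = 3000, seed = 10 + k)
    L <- 3000 * cfg$block_length
    p_w <- colMeans(t(g$haplotypes[, 1:7, drop = FALSE]))
    # mean pairwise divergence between neo-W and neo-Z tips
    pw <- rowMeans(g$haplotypes[, 1:7, drop = FALSE])
    pz <- rowMeans(g$haplotypes[, 8:20, drop = FALSE])
    dxy <- sum(pw * (1 - pz) + pz * (1 - pw)) / L
    expected <- 2 * cfg$mu * (cfg$plateau_t[k] + 2 * cfg$ne_anc_plateau[k])
    expect_lt(abs(dxy / expected - 1), 0.08)
  }
})

test_that("younger plateaus have strictly lower divergence in expectation", {
  cfg <- mini_cfg()
  dd <- vapply(1:3, function(k) {
    g <- simulate_neo_sex_genealogy(cfg, k, n_blocks = 1000, seed = 40 + k)
    pw <- rowMeans(g$haplotypes[, 1:7, drop = FALSE])
    pz <- rowMeans(g$haplotypes[, 8:20, drop = FALSE])
    sum(pw * (1 - pz) + pz * (1 - pw)) / (1000 * cfg$block_length)
  }, numeric(1))
  expect_true(dd[1] > dd[2] && dd[2] > dd[3])
})

test_that("single-population diversity matches the neutral expectation", {
  ne <- 0.01 / (4 * MU)  # theta = 0.01
  d <- simulate_neutral_blocks(10, ne, MU, 64, 5000, seed = 5)
  pi <- pi_from_haplotypes(t(d$carriers), 5000 * 64)
  expect_lt(abs(pi / 0.01 - 1), 0.1)
})

test_that("two-epoch within-population diversity follows the closed form", {
  # pairs escaping into a larger ancestral population gain diversity
  ne1 <- 6.47e5; ne_anc <- 1.1e6; t_split <- 1.5e6
  d <- simulate_div_blocks(14, 4, ne1, 1.724e6, ne_anc, t_split, MU,
                           n_blocks = 8000, seed = 11)
  pi1 <- pi_from_haplotypes(t(d$carriers[, 1:14]), 8000 * 64)
  e <- exp(-t_split / (2 * ne1))
  expected <- 2 * MU * (2 * ne1 * (1 - e) + e * 2 * ne_anc)
  expect_lt(abs(pi1 / expected - 1), 0.1)
})

test_that("female heterozygosity far exceeds male on the fused chromosome", {
  d <- mini_dataset()
  flt <- filter_variants(d$variants, d$mask, mean_depth = 20)
  ib <- d$samples$id[d$samples$population == "Iberia"]
  foc <- diversity_stats(flt$variants, flt$mask, groups = list(ib = ib),
                         chrom = "chrNeo")$per_sample
  aut <- diversity_stats(flt$variants, flt$mask, groups = list(ib = ib),
                         chrom = "chrA1")$per_sample
  hf <- mean(foc$h[foc$sex == "female"])
  hm <- mean(foc$h[foc$sex == "male"])
  expect_gt(hf / hm, 3)
  expect_lt(abs(log(hm / mean(aut$h[aut$sex == "male"]))), log(3))
})

test_that("loss-of-function injection follows 1 - exp(-rate * age)", {
  gm <- make_gene_models(400, "g", starts = (0:399) * 600L, codons = 60L)
  ref <- paste(sample(c("A", "C", "G", "T"), 400 * 600 + 600, TRUE),
               collapse = "")
  refchars <- strsplit(ref, "")[[1]]
  refchars <- neosexkit:::splice_genes_into_ref(refchars, gm$genes,
                                                gm$cds_seq)
  ref <- stats::setNames(paste(refchars, collapse = ""), "g")
  rate <- 2.25e-7
  inj0 <- inject_lof(gm$genes, ref, age = 1.4e6, lof_rate = 0, seed = 1)
  expect_equal(nrow(inj0$variants), 0)
  for (age in c(1.4e6, 5e5)) {
    inj <- inject_lof(gm$genes, ref, age = age, lof_rate = rate, seed = 2)
    p_hat <- length(unique(inj$truth$gene_id)) / 400
    p_exp <- 1 - exp(-rate * age)
    expect_lt(abs(p_hat - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 400))
  }
})

test_that("coverage model gives the configured female depth ratios", {
  cfg <- mini_cfg(mapping_rate = c(1, 1, 1))
  ce <- simulate_coverage_expression(cfg, seed = 3)
  prof <- coverage_profile(ce$coverage, cfg$samples, "chrNeo", "chrA1",
                           populations = "Iberia")
  f <- prof$per_sample$ratio[prof$per_sample$sex == "female"]
  expect_lt(max(abs(f - 1)), 0.05)

  cfg2 <- mini_cfg(mapping_rate = c(0.8, 0.8, 0.8))
  ce2 <- simulate_coverage_expression(cfg2, seed = 3)
  prof2 <- coverage_profile(ce2$coverage, cfg2$samples, "chrNeo", "chrA1",
                            populations = "Iberia")
  f2 <- prof2$per_sample$ratio[prof2$per_sample$sex == "female"]
  m2 <- prof2$per_sample$ratio[prof2$per_sample$sex == "male"]
  expect_lt(max(abs(f2 - 0.9)), 0.05)
  expect_lt(max(abs(m2 - 1)), 0.05)
})

test_that("expression folds have the configured median", {
  cfg <- mini_cfg(n_genes = 500L, plateau_windows = c(300L, 150L, 100L),
                  expr_fold = 1.5)
  ce <- simulate_coverage_expression(cfg, seed = 4)
  ase <- ase_expression(ce$expression)
  expect_lt(abs(ase$median_fold / 1.5 - 1), 0.05)
})

test_that("diagnostic-site truth matches the realized genotype pattern", {
  d <- mini_dataset()
  tr <- d$truth$diagnostic
  ib <- d$samples$id[d$samples$population == "Iberia"]
  vt <- vt_subset(d$variants, d$variants$sites$chrom == "chrNeo", ib)
  dos <- vt_dosage(vt)
  f <- vt$samples$sex == "female"
  w_linked <- rowSums(d$truth$hap[, 1:7, drop = FALSE] == 1) == 7
  ok <- vt$sites$is_snp & w_linked &
    rowSums(dos[, f, drop = FALSE] == 1) == sum(f) &
    rowSums(dos[, !f, drop = FALSE] == 0) == sum(!f)
  expect_setequal(tr$pos, vt$sites$pos[ok])
})

test_that("neo-W variation is block-consistent with the single genealogy", {
  d <- mini_dataset()
  hm <- d$w_calls
  seg <- colSums(hm$mat == 1) > 0 & colSums(hm$mat == 1) < nrow(hm$mat)
  snp <- nchar(hm$sites$ref) == 1 & nchar(hm$sites$alt) == 1
  spec <- folded_spectrum(hm_subset(hm, which(seg & snp)))
  tree <- perfect_phylogeny_tree(spec)
  expect_equal(tree$consistency, 1)
})
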