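diag_vt <- function() {
  # 7 females + 3 males; site 1 diagnostic, site 2 violates single-copy,
  # site 3 has a carrying male, site 4 has a missing female
  gt <- rbind(c(rep("0/1", 7), rep("0/0", 3)),
              c("1/1", rep("0/1", 6), rep("0/0", 3)),
              c(rep("0/1", 7), "0/1", "0/0", "0/0"),
              c("./.", rep("0/1", 6), rep("0/0", 3)))
  toy_vt(gt, pos = c(10L, 20L, 30L, 40L),
         sex = c(rep("female", 7), rep("male", 3)))
}

test_that("the diagnostic criterion keeps exactly the qualifying sites", {
  d <- find_w_diagnostic_sites(diag_vt())
  expect_equal(d$pos, 10L)
  expect_equal(d$w_allele, "T")
  d1 <- find_w_diagnostic_sites(diag_vt(), max_missing_females = 1)
  expect_setequal(d1$pos, c(10L, 40L))
})

test_that("the criterion needs males and tolerates sample reordering", {
  vt <- diag_vt()
  expect_error(find_w_diagnostic_sites(
    vt_subset(vt, sample_ids = paste0("s", 1:7))), "males")
  perm <- c(3, 1, 7, 2, 6, 4, 5, 10, 8, 9)
  d2 <- find_w_diagnostic_sites(vt_subset(vt, sample_ids =
                                            paste0("s", perm)))
  expect_equal(d2$pos, find_w_diagnostic_sites(vt)$pos)
})

test_that("phasing assigns W and Z alleles that reconstruct the genotypes", {
  vt <- diag_vt()
  diag <- find_w_diagnostic_sites(vt, max_missing_females = 1)
  ph <- phase_neo_w(vt, diag)
  expect_equal(dim(ph$w$mat), c(7, 2))
  # W carries the alt, the complement carries the ref
  expect_true(all(ph$w$mat == 1, na.rm = TRUE))
  expect_true(all(ph$z$mat[1:7, ] == 0, na.rm = TRUE))
  # missing genotype stays missing, not imputed
  expect_true(is.na(ph$w$mat["s1_W", 2]))
  # reconstruction: W + Z dosage equals the female genotype dosage
  dos <- vt_dosage(vt)[match(diag$pos, vt$sites$pos), 1:7]
  rec <- t(ph$w$mat) + t(ph$z$mat[1:7, ])
  expect_equal(unname(rec[!is.na(rec)]), unname(dos[!is.na(rec)]))
})

test_that("pseudo-diploids of identical haplotypes are fully homozygous", {
  w <- toy_hm(matrix(1L, 4, 5))
  pd <- pseudo_diploids(w)
  expect_equal(nrow(pd$pairs), 2)
  expect_true(all(pd$a1 == pd$a2))
})

test_that("paired-haplotype pi equals pseudo-diploid heterozygosity", {
  set.seed(6)
  m <- matrix(rbinom(6 * 40, 1, 0.3), 6, 40)
  w <- toy_hm(m)
  pd <- pseudo_diploids(w)
  het <- mean(colMeans(pd$a1 != pd$a2))
  pair_diff <- mean(vapply(seq_len(nrow(pd$pairs)), function(k) {
    mean(m[2 * k - 1, ] != m[2 * k, ])
  }, numeric(1)))
  expect_equal(het, pair_diff)
})

test_that("simulated diagnostic sites and W haplotypes are recovered exactly", {
  d <- mini_dataset()
  flt <- filter_variants(d$variants, d$mask, mean_depth = 20)
  ib <- d$samples$id[d$samples$population == "Iberia"]
  vt_ib <- vt_subset(flt$variants, flt$variants$sites$chrom == "chrNeo", ib)
  diag <- find_w_diagnostic_sites(vt_ib)
  # truth minus sites lost to the hard filters (e.g. SNPs near indels);
  # the genotype-level criterion may add the rare confounded site where a
  # neo-Z variant is private to all female complements
  truth_pos <- intersect(d$truth$diagnostic$pos, vt_ib$sites$pos)
  expect_true(all(truth_pos %in% diag$pos))
  extras <- setdiff(diag$pos, truth_pos)
  expect_lte(length(extras), 0.02 * length(truth_pos))
  ph <- phase_neo_w(vt_ib, diag)
  # phased W haplotypes match the simulated truth at true diagnostic sites
  keep <- diag$pos %in% truth_pos
  focal_pos <- d$variants$sites$pos[d$variants$sites$chrom == "chrNeo"]
  truth_w <- d$truth$hap[match(diag$pos[keep], focal_pos), 1:7, drop = FALSE]
  expect_identical(unname(t(ph$w$mat[, keep, drop = FALSE])),
                   unname(truth_w))
})
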