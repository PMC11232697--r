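test_that("codon degeneracy matches the code table on known codons", {
  # gene: ATG GGG TAC TAA on the plus strand
  ref <- c(chr1 = "NNATGGGGTACTAANN")
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 2L, end = 14L, phase = 0L)
  dm <- classify_site_degeneracy(ref, genes)
  expect_equal(nrow(dm), 12)
  # ATG: all positions 0D
  expect_equal(dm$degeneracy[dm$pos %in% 3:5], rep("0D", 3))
  # GGG (Gly): third position 4D
  expect_equal(dm$degeneracy[dm$pos == 8], "4D")
})

test_that("degeneracy counts agree with brute-force code enumeration", {
  set.seed(42)
  code <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(code), names(code)[code == "*"])
  codons <- c("ATG", sample(sense, 60, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  for (strand in c("+", "-")) {
    seq_genomic <- if (strand == "+") cds else
      paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
            collapse = "")
    ref <- c(chr1 = paste0("AAAA", seq_genomic, "AAAA"))
    genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = strand,
                            start = 4L, end = 4L + nchar(cds), phase = 0L)
    dm <- classify_site_degeneracy(ref, genes)
    # independent oracle: enumerate substitutions per codon position
    bases <- c("A", "C", "G", "T")
    expected <- character(0)
    for (cod in codons) {
      cs <- strsplit(cod, "")[[1]]
      for (p in 1:3) {
        nsyn <- 0
        for (b in setdiff(bases, cs[p])) {
          alt <- cs; alt[p] <- b
          if (code[paste(alt, collapse = "")] == code[cod]) nsyn <- nsyn + 1
        }
        expected <- c(expected, c("0D", "2D", "3D", "4D")[nsyn + 1])
      }
    }
    got <- dm$degeneracy[order(match(dm$pos, if (strand == "+")
      (genes$start + 1):genes$end else genes$end:(genes$start + 1)))]
    expect_equal(got, expected, info = strand)
  }
})

test_that("pi equals the explicit pairwise-difference oracle", {
  # 4 haplotypes = 2 diploid samples, enumerated by hand over 2 sites
  vt <- toy_vt(rbind(c("0/1", "1/1"), c("0/0", "0/1")), pos = c(10L, 20L),
               sex = c("female", "female"))
  mask <- toy_mask(end = 100L)
  ds <- diversity_stats(vt, mask, groups = list(g = c("s1", "s2")))
  # haplotypes: s1 = (0,0),(1,0); s2 = (1,0),(1,1)
  haps <- rbind(c(0, 0), c(1, 0), c(1, 0), c(1, 1))
  diffs <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    diffs <- c(diffs, sum(haps[i, ] != haps[j, ]))
  }
  expect_equal(ds$per_group$pi, mean(diffs) / 100)
  expect_equal(unname(ds$per_sample$h), c(1, 1) / 100)
})

test_that("random genotype tables match the brute-force pi oracle", {
  set.seed(9)
  for (rep in 1:5) {
    ns <- 4; nv <- 30
    a1 <- matrix(rbinom(nv * ns, 1, 0.3), nv, ns)
    a2 <- matrix(rbinom(nv * ns, 1, 0.3), nv, ns)
    gt <- matrix(paste0(a1, "/", a2), nv, ns)
    vt <- toy_vt(gt, pos = seq_len(nv) * 3L,
                 sex = rep("female", ns))
    ds <- diversity_stats(vt, toy_mask(end = 200L),
                          groups = list(g = paste0("s", 1:ns)))
    haps <- rbind(a1[, 1], a2[, 1], a1[, 2], a2[, 2], a1[, 3], a2[, 3],
                  a1[, 4], a2[, 4])
    diffs <- c()
    for (i in 1:7) for (j in (i + 1):8) {
      diffs <- c(diffs, sum(haps[i, ] != haps[j, ]))
    }
    expect_equal(ds$per_group$pi, mean(diffs) / 200)
  }
})

test_that("degenerate inputs are handled as specified", {
  vt <- toy_vt(rbind(c("0/0", "0/0")), sex = c("female", "male"))
  ds <- diversity_stats(vt, toy_mask(), groups = list(a = "s1", b = "s2"))
  expect_true(is.na(ds$per_group$pi[1]))  # single-sample group
  expect_equal(unname(ds$per_sample$h), c(0, 0))
  expect_equal(ds$pairwise$dxy, 0)
  expect_true(is.na(ds$pairwise$fst))  # monomorphic
  empty_mask <- toy_mask(chrom = "chrX")
  expect_error(diversity_stats(vt, empty_mask[0, ],
                               groups = list(a = "s1", b = "s2")),
               "callable")
})

test_that("dxy >= da and Hudson FST lies in [0,1] for random datasets", {
  set.seed(11)
  for (rep in 1:10) {
    gt <- matrix(paste0(rbinom(40 * 6, 1, 0.4), "/", rbinom(40 * 6, 1, 0.4)),
                 40, 6)
    vt <- toy_vt(gt, pos = seq_len(40) * 2L, sex = rep("female", 6))
    ds <- diversity_stats(vt, toy_mask(end = 200L),
                          groups = list(a = paste0("s", 1:3),
                                        b = paste0("s", 4:6)))
    pw <- ds$pairwise
    if (!is.na(pw$da)) expect_gte(pw$dxy, pw$da)
    within <- mean(ds$per_group$pi)
    if (!is.na(pw$fst) && within <= pw$dxy) {
      expect_gte(pw$fst, 0)
      expect_lte(pw$fst, 1)
    }
  }
})

test_that("window masking removes exactly the requested fraction, ties leftmost", {
  vt <- toy_vt(matrix("0/1", 10, 2), pos = as.integer(seq(50, 950, 100)))
  mask <- toy_mask(end = 1000L)
  w <- windowed_divergence(vt, mask, window_length = 100,
                           mask_fraction = 0.2)
  expect_equal(nrow(w), 10)
  expect_equal(sum(w$masked), ceiling(0.2 * 10))
  expect_equal(which(w$masked), c(1, 2))  # uniform coverage: leftmost first
  # constant H across windows
  expect_equal(length(unique(w$h[!is.na(w$h)])), 1)
})

test_that("windowed H averages back to whole-region H under uniform coverage", {
  d <- mini_dataset()
  flt <- filter_variants(d$variants, d$mask, mean_depth = 20)
  f_ids <- d$samples$id[d$samples$sex == "female" &
                          d$samples$population == "Iberia"]
  w <- windowed_divergence(flt$variants, flt$mask, 6400, samples = f_ids,
                           chrom = "chrNeo")
  ds <- diversity_stats(flt$variants, flt$mask, groups = list(f = f_ids),
                        chrom = "chrNeo")
  h_region <- mean(ds$per_sample$h)
  h_windows <- sum(w$n_het) / length(f_ids) / sum(w$callable)
  expect_equal(h_windows, h_region, tolerance = 1e-10)
})

test_that("moments split time reproduces the worked arithmetic", {
  expect_equal(moments_split_time(0.01, 0.01, MU)$t_hat, 0)
  est <- moments_split_time(0.022, 0.0132, MU)
  expect_equal(est$t_hat, (0.022 - 0.0132) / (2 * MU))
  expect_equal(est$t_hat, 1.517e6, tolerance = 0.001)
  expect_error(moments_split_time(-0.01, 0, MU), "non-negative")
  expect_equal(moments_split_time(0.001, 0.005, MU)$t_hat, 0)  # clamped
})
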