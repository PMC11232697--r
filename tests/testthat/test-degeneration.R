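# small CDS fixture shared by the classifier tests; gene layout:
# plus-strand gene ATG | GGG TGG TAC ... | TAA with known codon positions
lof_fixture <- function(strand = "+") {
  code <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(code), names(code)[code == "*"])
  set.seed(77)
  mid <- sample(setdiff(sense, c("TGG", "TAC")), 17, replace = TRUE)
  cds <- paste(c("ATG", "GGG", "TGG", mid, "TAA"), collapse = "")
  genomic <- if (strand == "+") cds else
    paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]), collapse = "")
  ref <- stats::setNames(paste0(strrep("A", 10), genomic, strrep("A", 10)),
                         "chrT")
  genes <- tibble::tibble(gene_id = "g1", chrom = "chrT", strand = strand,
                          start = 10L, end = 10L + nchar(cds), phase = 0L)
  list(ref = ref, genes = genes, cds = cds)
}

test_that("the coverage estimator reproduces the worked example", {
  expect_equal(neo_w_coverage(0.9, 1.0)$cov_w, 0.8)
  expect_equal(neo_w_coverage(1.0, 1.0)$cov_w, 1.0)
  clamped <- neo_w_coverage(0.3, 1.0)
  expect_equal(clamped$cov_w, 0)
  expect_true(clamped$clamped)
})

test_that("covW is linear in the female ratio: covW((1+m)/2, 1) = m", {
  m <- seq(0, 1, by = 0.05)
  expect_equal(neo_w_coverage((1 + m) / 2, 1)$cov_w, m)
})

test_that("SNP consequences are classified from the codon table", {
  fx <- lof_fixture("+")
  # TGG (codon 3, genomic 17..19) -> TGA by G>A at codon position 3
  vars <- tibble::tibble(
    chrom = "chrT",
    pos = c(19L, 12L, 10L + nchar(fx$cds) - 0L, 15L),
    ref = c("G", "T", "A", "G"),
    alt = c("A", "C", "C", "T"))
  # pos 19: premature stop; pos 12: start loss (ATG pos 2);
  # last pos: stop loss (TAA -> TAC at position 3); pos 15: GGG->GGT silent
  calls <- classify_lof(vars, fx$genes, fx$ref)
  expect_equal(calls$category[calls$pos == 19], "premature_stop")
  expect_equal(calls$category[calls$pos == 12], "start_loss")
  expect_equal(calls$category[calls$pos == 10 + nchar(fx$cds)], "stop_loss")
  expect_false(15 %in% calls$pos)
})

test_that("minus-strand genes are classified through the reverse complement", {
  fx <- lof_fixture("-")
  # codon 3 (TGG) sits at genomic positions: CDS index 7..9 from the far end
  L <- nchar(fx$cds)
  gpos <- (10L + L):(10L + 1L)  # translation order on the minus strand
  p <- gpos[9]                  # third base of codon 3
  # TGG -> TGA: CDS base G>A, genomic complement C>T
  vars <- tibble::tibble(chrom = "chrT", pos = p, ref = "C", alt = "T")
  calls <- classify_lof(vars, fx$genes, fx$ref)
  expect_equal(calls$category, "premature_stop")
})

test_that("indel frame rule: 1-2 bp shift is LoF, 3 bp is not", {
  fx <- lof_fixture("+")
  # genomic position 14 is CDS index 4; deletions of 2, 1 and 3 bases
  vars <- tibble::tibble(
    chrom = "chrT", pos = 14L,
    ref = c(substr(fx$cds, 4, 6), substr(fx$cds, 4, 5),
            substr(fx$cds, 4, 7)),
    alt = substr(fx$cds, 4, 4))
  calls <- classify_lof(vars, fx$genes, fx$ref)
  expect_equal(sum(calls$category == "frameshift"), 2)  # 2 bp and 1 bp dels
  # deletion spanning the CDS end is conservatively excluded
  L <- nchar(fx$cds)
  vars2 <- tibble::tibble(chrom = "chrT", pos = 10L + L,
                          ref = paste0(substr(fx$cds, L, L), "A"), alt = "A")
  expect_equal(nrow(classify_lof(vars2, fx$genes, fx$ref)), 0)
})

test_that("injected loss-of-function is recovered with full recall/precision", {
  gm <- make_gene_models(200, "chrT", starts = (0:199) * 500L, codons = 60L)
  set.seed(5)
  refchars <- sample(c("A", "C", "G", "T"), 200 * 500 + 500, replace = TRUE)
  refchars <- neosexkit:::splice_genes_into_ref(refchars, gm$genes,
                                               gm$cds_seq)
  ref <- stats::setNames(paste(refchars, collapse = ""), "chrT")
  inj <- inject_lof(gm$genes, ref, age = 3e6, lof_rate = 2.25e-7, seed = 6)
  hm <- haplotype_matrix(matrix(1L, 7, nrow(inj$variants)),
                         paste0("W", 1:7),
                         inj$variants[, c("chrom", "pos", "ref", "alt")])
  calls <- classify_lof(inj$variants, gm$genes, ref,
                        haplotypes = list(neo_w = hm))
  expect_gt(nrow(inj$truth), 50)
  key <- function(d) paste(d$chrom, d$pos, d$category)
  expect_setequal(key(calls), key(inj$truth))  # recall and precision = 1
  expect_true(all(calls$fixed))
})

test_that("fixed-LoF proportions carry exact binomial intervals", {
  calls <- tibble::tibble(gene_id = sprintf("g%03d", 1:25),
                          chrom = "c", pos = 1:25, ref = "A", alt = "T",
                          category = "premature_stop",
                          haplotype = "neo_w", fixed = TRUE)
  universe <- sprintf("g%03d", 1:100)
  pr <- fixed_lof_proportion(calls, universe)
  expect_equal(pr$proportion, 0.25)
  expect_equal(round(pr$lower, 2), 0.17)
  expect_equal(round(pr$upper, 2), 0.35)
  none <- fixed_lof_proportion(calls[0, ], sprintf("g%03d", 1:50))
  expect_equal(none$proportion, 0)
  expect_equal(none$lower, 0)
  # relaxing the gene filter can only add LoF genes (monotone counts)
  pr2 <- fixed_lof_proportion(calls, sprintf("g%03d", 1:60))
  expect_gte(pr$n_lof, pr2$n_lof)
  expect_gte(pr$n_genes, pr2$n_genes)
})

test_that("plateau age orders the fixed-LoF proportions", {
  gm <- make_gene_models(300, "chrT", starts = (0:299) * 500L, codons = 40L)
  set.seed(8)
  refchars <- sample(c("A", "C", "G", "T"), 300 * 500 + 500, replace = TRUE)
  refchars <- neosexkit:::splice_genes_into_ref(refchars, gm$genes,
                                               gm$cds_seq)
  ref <- stats::setNames(paste(refchars, collapse = ""), "chrT")
  ages <- rep(c(1.4e6, 5e5), each = 150)[seq_along(unique(gm$genes$gene_id))]
  wins <- 0
  for (s in 1:5) {
    inj <- inject_lof(gm$genes, ref, age = ages, lof_rate = 2.25e-7,
                      seed = 100 + s)
    old <- unique(gm$genes$gene_id)[ages == 1.4e6]
    young <- unique(gm$genes$gene_id)[ages == 5e5]
    p_old <- mean(old %in% inj$truth$gene_id)
    p_young <- mean(young %in% inj$truth$gene_id)
    wins <- wins + (p_old > p_young)
  }
  expect_equal(wins, 5)
})

test_that("expression bias handles equal, biased and W-silent genes", {
  eq <- ase_expression(tibble::tibble(gene_id = paste0("g", 1:20),
                                      z_count = 50L, w_count = 50L))
  expect_equal(eq$median_fold, 1)
  expect_true(all(eq$genes$z_fraction == 0.5))
  wz <- ase_expression(tibble::tibble(gene_id = c("a", "b", "c"),
                                      z_count = c(30L, 40L, 60L),
                                      w_count = c(30L, 0L, 20L)))
  expect_equal(wz$n_w_zero, 1)
  expect_equal(wz$genes$z_fraction[wz$genes$gene_id == "b"], 1)
  expect_equal(wz$median_fold, median(c(1, 3)))  # W-silent gene excluded
  low <- tibble::tibble(gene_id = "x", z_count = 2L, w_count = 1L)
  expect_error(ase_expression(low, min_total = 10), "excluded")
})
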