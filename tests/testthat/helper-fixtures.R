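# shared builders for the test suite; everything is generated in code

MU <- 2.9e-9

# tiny variant table from explicit genotype strings ("0/0", "0/1", "./.", ...)
toy_vt <- function(gt, chrom = "chr1", pos = NULL, ref = "A", alt = "T",
                   sex = NULL, population = "Iberia", gq = 60L, dp = 20L,
                   strand_ok = TRUE, placement_ok = TRUE) {
  gt <- as.matrix(gt)
  nv <- nrow(gt); ns <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(nv) * 10L
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = ns)
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))), nv, ns)
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))), nv, ns)
  expand <- function(x) if (is.matrix(x)) x else matrix(x, nv, ns)
  variant_table(
    tibble::tibble(chrom = chrom, pos = pos,
                   ref = rep_len(ref, nv), alt = rep_len(alt, nv),
                   strand_ok = rep_len(strand_ok, nv),
                   placement_ok = rep_len(placement_ok, nv)),
    a1, a2, expand(gq), expand(dp),
    tibble::tibble(id = paste0("s", seq_len(ns)), sex = sex,
                   population = rep_len(population, ns)))
}

toy_mask <- function(chrom = "chr1", start = 0L, end = 1000L) {
  callable_mask(tibble::tibble(chrom = chrom, start = start, end = end))
}

# small-but-complete simulation config for end-to-end style tests
mini_cfg <- function(...) {
  sim_config(plateau_windows = c(20L, 6L, 5L), n_windows_autosome = 12L,
             n_windows_z = 5L, blocks_per_window = 40L,
             window_length = 6400L, n_genes = 12L, ...)
}

# cache one mini dataset across test files (generation is deterministic)
mini_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(mini_cfg(), seed = 7)
    cache
  }
})

# haplotype matrix from a plain 0/1 matrix (haplotypes x sites)
toy_hm <- function(mat, labels = NULL, pos = NULL) {
  if (is.null(labels)) labels <- sprintf("h%02d", seq_len(nrow(mat)))
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 100L
  haplotype_matrix(mat, labels,
                   tibble::tibble(chrom = "chrNeo", pos = pos,
                                  ref = "A", alt = "T"))
}

# canonical split keys of an ape tree (independent of the package's
# perfect-phylogeny construction): one key per internal + terminal edge
tree_split_keys <- function(tree, labels) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  ord <- match(labels, tree$tip.label)
  keys <- character(0)
  for (i in seq_len(n)) {
    keys <- c(keys, canonical_split_key(which(ord == i), n))
  }
  for (p in parts) {
    side <- which(ord %in% p)
    k <- canonical_split_key(side, n)
    if (!is.na(k)) keys <- c(keys, k)
  }
  sort(unique(keys))
}
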