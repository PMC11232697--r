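#' Build a variant table
#'
#' The central genotype container: one row per bi-allelic variant record with
#' per-sample genotype (unphased allele pair), genotype quality and read
#' depth, plus the sample sheet (id, sex, population). Positions are 1-based
#' (VCF convention); all interval arithmetic elsewhere in the package is
#' 0-based half-open (BED convention), with conversion at the boundary.
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `strand_ok`, `placement_ok` (default `TRUE`).
#' @param a1,a2 integer matrices (variants x samples) of allele indices
#'   (0 = ref, 1 = alt), `NA` for missing genotypes.
#' @param gq,dp integer matrices (variants x samples) of genotype quality and
#'   read depth.
#' @param samples tibble with columns `id`, `sex` (`"female"`/`"male"`),
#'   `population`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, a1, a2, gq, dp, samples) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  ns <- nrow(samples)
  nv <- nrow(sites)
  assert_that(all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
              "sites must have chrom, pos, ref, alt")
  assert_that(all(c("id", "sex", "population") %in% names(samples)),
              "samples must have id, sex, population")
  assert_that(!anyDuplicated(samples$id), "sample ids must be unique")
  assert_that(all(samples$sex %in% c("female", "male")),
              "sex must be 'female' or 'male'")
  for (m in list(a1, a2, gq, dp)) {
    assert_that(is.matrix(m) && nrow(m) == nv && ncol(m) == ns,
                "genotype matrices must be variants x samples")
  }
  assert_that(all(nzchar(sites$ref)) && all(nzchar(sites$alt)),
              "ref/alt must be non-empty")
  if (!"strand_ok" %in% names(sites)) sites$strand_ok <- TRUE
  if (!"placement_ok" %in% names(sites)) sites$placement_ok <- TRUE
  sites$is_snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
  gq <- gq[ord, , drop = FALSE]; dp <- dp[ord, , drop = FALSE]
  dup <- duplicated(sites[, c("chrom", "pos")])
  assert_that(!any(dup), "positions must be unique within a chromosome")
  structure(
    list(sites = sites,
         a1 = `dimnames<-`(a1, list(NULL, samples$id)),
         a2 = `dimnames<-`(a2, list(NULL, samples$id)),
         gq = `dimnames<-`(gq, list(NULL, samples$id)),
         dp = `dimnames<-`(dp, list(NULL, samples$id)),
         samples = samples),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d records x %d samples (%d SNPs, %d indels)\n",
              nrow(x$sites), nrow(x$samples), sum(x$sites$is_snp),
              sum(!x$sites$is_snp)))
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a variant table by record index and/or sample id
#'
#' @param vt a [variant_table()].
#' @param rows logical or integer index over records.
#' @param sample_ids character vector of sample ids to keep.
#' @return A `variant_table`.
#' @export
vt_subset <- function(vt, rows = NULL, sample_ids = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(vt$sites))
  cols <- if (is.null(sample_ids)) vt$samples$id else sample_ids
  miss <- setdiff(cols, vt$samples$id)
  assert_that(length(miss) == 0, "unknown sample(s): %s",
              paste(miss, collapse = ", "))
  variant_table(vt$sites[rows, , drop = FALSE],
                vt$a1[rows, cols, drop = FALSE],
                vt$a2[rows, cols, drop = FALSE],
                vt$gq[rows, cols, drop = FALSE],
                vt$dp[rows, cols, drop = FALSE],
                vt$samples[match(cols, vt$samples$id), , drop = FALSE])
}

#' Genotype dosage matrix (count of alternate alleles)
#'
#' @param vt a [variant_table()].
#' @return Integer matrix (variants x samples); `NA` where the genotype is
#'   missing.
#' @export
vt_dosage <- function(vt) vt$a1 + vt$a2

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a variant table
#'
#' @param x a [variant_table()].
#' @param ... unused.
#' @return A tibble with one row per (record, sample) genotype.
#' @export
tidy.variant_table <- function(x, ...) {
  nv <- nrow(x$sites); ns <- nrow(x$samples)
  tibble(
    chrom = rep(x$sites$chrom, ns),
    pos = rep(x$sites$pos, ns),
    ref = rep(x$sites$ref, ns),
    alt = rep(x$sites$alt, ns),
    sample = rep(x$samples$id, each = nv),
    a1 = as.vector(x$a1), a2 = as.vector(x$a2),
    gq = as.vector(x$gq), dp = as.vector(x$dp))
}

#' @export
glance.variant_table <- function(x, ...) {
  tibble(n_records = nrow(x$sites), n_samples = nrow(x$samples),
         n_snps = sum(x$sites$is_snp), n_indels = sum(!x$sites$is_snp),
         n_chromosomes = length(unique(x$sites$chrom)),
         missing_rate = mean(is.na(x$a1)))
}
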