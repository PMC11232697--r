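#' Build a haplotype matrix
#'
#' Phased haplotypes over a set of sites: rows are haplotypes (labelled,
#' e.g. `IB_F1_W`), columns are sites; entries are allele indices
#' (0 = ref, 1 = alt) or `NA`.
#'
#' @param mat integer matrix (haplotypes x sites).
#' @param labels character haplotype labels.
#' @param sites tibble with `chrom`, `pos` and optionally `ref`, `alt`.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(mat, labels, sites) {
  sites <- as_tibble(sites)
  assert_that(nrow(mat) == length(labels),
              "labels must match haplotype rows")
  assert_that(ncol(mat) == nrow(sites), "sites must match matrix columns")
  rownames(mat) <- labels
  structure(list(mat = mat, labels = labels, sites = sites),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d sites\n",
              nrow(x$mat), ncol(x$mat)))
  cat("labels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$mat)

#' @export
tidy.haplotype_matrix <- function(x, ...) {
  nh <- nrow(x$mat); np <- ncol(x$mat)
  tibble(haplotype = rep(x$labels, np),
         chrom = rep(x$sites$chrom, each = nh),
         pos = rep(x$sites$pos, each = nh),
         allele = as.vector(x$mat))
}

#' Subset a haplotype matrix by site index
#'
#' @param hm a [haplotype_matrix()].
#' @param cols integer or logical site index.
#' @return A [haplotype_matrix()].
#' @export
hm_subset <- function(hm, cols) {
  haplotype_matrix(hm$mat[, cols, drop = FALSE], hm$labels,
                   hm$sites[cols, , drop = FALSE])
}

#' Write a haplotype matrix as a haploid VCF
#'
#' @param hm a [haplotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haploid_vcf <- function(hm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neosexkit-haploid",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", hm$labels), collapse = "\t"))
  s <- hm$sites
  ref <- if (is.null(s$ref)) rep("A", nrow(s)) else s$ref
  alt <- if (is.null(s$alt)) rep("T", nrow(s)) else s$alt
  g <- t(hm$mat)
  g[is.na(g)] <- "."
  body <- paste(s$chrom, s$pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(g, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a haploid VCF into a haplotype matrix
#'
#' @param path VCF with single-allele genotypes (e.g. phased neo-W calls).
#' @return A [haplotype_matrix()].
#' @export
read_haploid_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  labs <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  m <- suppressWarnings(matrix(as.integer(gt), nrow(fix), length(labs)))
  haplotype_matrix(t(m), labs,
                   tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT))
}
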