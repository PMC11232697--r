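#' Find neo-W-diagnostic sites
#'
#' A site is diagnostic for the neo-W when the alternate allele is present
#' in a single copy (heterozygous) in every non-missing female and absent
#' from every male. Only SNP records are considered. Missing female
#' genotypes are tolerated up to `max_missing_females`; a missing male
#' genotype disqualifies the site (absence cannot be verified).
#'
#' @param vt a [variant_table()] restricted to the candidate population
#'   (e.g. Iberian samples) and chromosome.
#' @param max_missing_females allowed number of missing female genotypes.
#' @return A tibble of class `diagnostic_sites`: `chrom`, `pos`, `ref`,
#'   `alt`, `w_allele`, `z_allele`; criteria stored in attributes.
#' @export
find_w_diagnostic_sites <- function(vt, max_missing_females = 0) {
  f <- vt$samples$sex == "female"
  m <- vt$samples$sex == "male"
  assert_that(any(m), "criterion undefined without males")
  assert_that(any(f), "need at least one female")
  dos <- vt_dosage(vt)
  df <- dos[, f, drop = FALSE]
  dm <- dos[, m, drop = FALSE]
  n_missing_f <- rowSums(is.na(df))
  ok <- vt$sites$is_snp &
    rowSums(df == 1, na.rm = TRUE) == (sum(f) - n_missing_f) &
    n_missing_f <= max_missing_females &
    rowSums(is.na(dm)) == 0 &
    rowSums(dm == 0) == sum(m)
  out <- vt$sites[ok, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$w_allele <- out$alt
  out$z_allele <- out$ref
  attr(out, "criteria") <- list(n_females = sum(f), n_males = sum(m),
                                max_missing_females = max_missing_females)
  class(out) <- c("diagnostic_sites", class(out))
  out
}

#' Phase neo-W haplotypes at diagnostic sites
#'
#' For each female the neo-W haplotype carries the W allele at every
#' diagnostic site and the neo-Z complement carries the other allele; male
#' genotypes at these sites are homozygous by construction and contribute
#' one collapsed neo-Z haplotype each. Missing female genotypes stay
#' missing (no imputation).
#'
#' @param vt a [variant_table()] (same population subset used to find the
#'   sites).
#' @param diag a [find_w_diagnostic_sites()] result.
#' @return A list: `w` ([haplotype_matrix()] of female neo-W haplotypes) and
#'   `z` (female neo-Z complements followed by collapsed male haplotypes).
#' @export
phase_neo_w <- function(vt, diag) {
  assert_that(nrow(diag) > 0, "no diagnostic sites")
  idx <- match(paste(diag$chrom, diag$pos),
               paste(vt$sites$chrom, vt$sites$pos))
  assert_that(!anyNA(idx), "diagnostic sites missing from the variant table")
  f_ids <- vt$samples$id[vt$samples$sex == "female"]
  m_ids <- vt$samples$id[vt$samples$sex == "male"]
  dos <- vt_dosage(vt)[idx, , drop = FALSE]
  # female neo-W carries the alt (W) allele wherever the genotype is called
  w <- vapply(f_ids, function(id) {
    g <- dos[, id]
    ifelse(is.na(g), NA_integer_, 1L)
  }, integer(nrow(diag)))
  z_f <- vapply(f_ids, function(id) {
    g <- dos[, id]
    ifelse(is.na(g), NA_integer_, 0L)
  }, integer(nrow(diag)))
  z_m <- vapply(m_ids, function(id) {
    g <- dos[, id]
    ifelse(is.na(g), NA_integer_, as.integer(g / 2))
  }, integer(nrow(diag)))
  w <- matrix(w, nrow = nrow(diag)); z_f <- matrix(z_f, nrow = nrow(diag))
  z_m <- matrix(z_m, nrow = nrow(diag))
  sites <- diag[, c("chrom", "pos", "ref", "alt")]
  list(w = haplotype_matrix(t(w), paste0(f_ids, "_W"), sites),
       z = haplotype_matrix(t(cbind(z_f, z_m)),
                            c(paste0(f_ids, "_Z"), paste0(m_ids, "_Z")),
                            sites))
}

#' Pair phased neo-W haplotypes into pseudo-diploids
#'
#' Consecutive females (sample-sheet order) are paired deterministically;
#' an odd haplotype is left unpaired. Pseudo-diploid heterozygosity at a
#' site equals the allelic difference of the paired haplotypes, which is
#' how divergence among neo-W chromosomes can be fed to diploid-based
#' estimators.
#'
#' @param w a neo-W [haplotype_matrix()].
#' @return A list: `a1`, `a2` (sites x pairs allele matrices), `pairs`
#'   tibble.
#' @export
pseudo_diploids <- function(w) {
  n <- nrow(w$mat)
  assert_that(n >= 2, "need at least two haplotypes")
  k <- n %/% 2
  i1 <- seq(1, 2 * k, by = 2)
  i2 <- i1 + 1
  list(a1 = t(w$mat[i1, , drop = FALSE]),
       a2 = t(w$mat[i2, , drop = FALSE]),
       pairs = tibble(pair = seq_len(k), hap1 = w$labels[i1],
                      hap2 = w$labels[i2]))
}
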