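#' Read a sample sheet
#'
#' Tab-separated file with columns `id`, `sex` (`female`/`male`) and
#' `population`.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  assert_that(all(c("id", "sex", "population") %in% names(s)),
              "sample sheet needs columns id, sex, population")
  assert_that(all(s$sex %in% c("female", "male")),
              "sample sheet sex must be female/male")
  assert_that(!anyDuplicated(s$id), "duplicate sample ids in sheet")
  s
}

#' Read a BED file as a callable mask
#' @param path file path.
#' @return A [callable_mask()] tibble (0-based half-open).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cii", progress = FALSE, comment = "#")
  callable_mask(b)
}

#' Write a callable mask as BED
#' @param mask a [callable_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  mask <- arrange(mask, .data$chrom, .data$start)
  readr::write_tsv(mask[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps CDS features only; the gene id is taken from the `Parent`
#' attribute (falling back to `ID`). Coordinates are converted to 0-based
#' half-open.
#'
#' @param path GFF3 file path.
#' @return A tibble with one row per CDS segment: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `phase`.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(g$Parent, ","))
  gene_id <- ifelse(nzchar(parent), parent, as.character(g$ID))
  out <- tibble(
    gene_id = sub("^(transcript|mRNA)[:.]", "", gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    strand = as.character(BiocGenerics::strand(g)),
    start = BiocGenerics::start(g) - 1L,
    end = BiocGenerics::end(g),
    phase = as.integer(as.character(g$phase)))
  out$phase[is.na(out$phase)] <- 0L
  arrange(out, .data$chrom, .data$gene_id, .data$start)
}

#' Write gene models as GFF3
#' @param genes gene-model tibble as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (gid in unique(genes$gene_id)) {
    d <- genes[genes$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tneosexkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              d$chrom[1], min(d$start) + 1L, max(d$end), d$strand[1],
              paste0("gene:", gid)),
      sprintf("%s\tneosexkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              d$chrom[1], min(d$start) + 1L, max(d$end), d$strand[1],
              gid, paste0("gene:", gid)),
      sprintf("%s\tneosexkit\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
              d$chrom, d$start + 1L, d$end, d$strand, d$phase, gid, gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table as VCF 4.2
#'
#' Deterministic ordering (chromosome, then position); the strand-support
#' and read-placement booleans are carried in the INFO fields `SBOK` and
#' `RPOK`.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param haploid optional logical matrix (variants x samples); where `TRUE`
#'   the genotype is written as a single allele.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, haploid = NULL) {
  s <- vt$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=neosexkit",
    "##INFO=<ID=SBOK,Number=1,Type=Integer,Description=\"Strand balance OK\">",
    "##INFO=<ID=RPOK,Number=1,Type=Integer,Description=\"Read placement OK\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples$id), collapse = "\t"))
  n <- nrow(s)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt <- matrix("", n, ncol(vt$a1))
  for (j in seq_len(ncol(gt))) {
    g <- ifelse(is.na(vt$a1[, j]) | is.na(vt$a2[, j]), "./.",
                paste0(vt$a1[, j], "/", vt$a2[, j]))
    if (!is.null(haploid))
      g <- ifelse(haploid[, j] & !is.na(vt$a1[, j]),
                  as.character(vt$a1[, j]), g)
    gt[, j] <- paste(g, ifelse(is.na(vt$gq[, j]), ".", vt$gq[, j]),
                     ifelse(is.na(vt$dp[, j]), ".", vt$dp[, j]), sep = ":")
  }
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                paste0("SBOK=", as.integer(s$strand_ok),
                       ";RPOK=", as.integer(s$placement_ok)),
                "GT:GQ:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Multi-allelic records are decomposed into bi-allelic records on load
#' (allele order as written); genotypes carrying a different alternate
#' allele are set to the reference in each decomposed record.
#'
#' @param path VCF file path.
#' @param samples sample sheet tibble (id, sex, population); every VCF sample
#'   must be present in the sheet.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  miss <- setdiff(vcf_samples, samples$id)
  assert_that(length(miss) == 0,
              "VCF sample(s) missing from the sample sheet: %s",
              paste(miss, collapse = ", "))
  samples <- samples[match(vcf_samples, samples$id), , drop = FALSE]
  ns <- length(vcf_samples)
  if (nrow(fix) == 0) {
    z <- matrix(integer(0), 0, ns)
    return(variant_table(tibble(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0)),
                         z, z, z, z, samples))
  }
  pos <- as.integer(fix$POS)
  for (ch in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == ch]
    assert_that(!is.unsorted(p, strictly = FALSE), "unsorted VCF (%s)", ch)
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(fix), ns)
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(fix), ns)
  sb <- vcf_info_flag(fix$INFO, "SBOK")
  rp <- vcf_info_flag(fix$INFO, "RPOK")

  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- sequence(n_alt)

  al1 <- sub("[/|].*", "", gt_raw)
  al2 <- sub(".*[/|]", "", gt_raw)
  suppressWarnings({
    al1 <- matrix(as.integer(al1), nrow(fix), ns)
    al2 <- matrix(as.integer(al2), nrow(fix), ns)
  })
  recode <- function(al, rows, k) {
    m <- al[rows, , drop = FALSE]
    out <- ifelse(is.na(m), NA_integer_, ifelse(m == k, 1L, 0L))
    matrix(as.integer(out), length(rows), ns)
  }
  a1 <- recode(al1, row_idx, alt_idx)
  a2 <- recode(al2, row_idx, alt_idx)
  sites <- tibble(chrom = fix$CHROM[row_idx], pos = pos[row_idx],
                  ref = fix$REF[row_idx],
                  alt = unlist(alts)[cumsum(n_alt)[row_idx] - n_alt[row_idx] +
                                       alt_idx],
                  strand_ok = sb[row_idx], placement_ok = rp[row_idx])
  keep <- !duplicated(paste(sites$chrom, sites$pos))  # decomposition tie-break
  variant_table(sites[keep, , drop = FALSE],
                a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                matrix(as.integer(round(gq[row_idx, , drop = FALSE][keep, ,
                                                                    drop = FALSE])),
                       sum(keep), ns),
                matrix(as.integer(round(dp[row_idx, , drop = FALSE][keep, ,
                                                                    drop = FALSE])),
                       sum(keep), ns),
                samples)
}

vcf_info_flag <- function(info, key) {
  val <- rep(TRUE, length(info))
  hit <- regmatches(info, regexpr(paste0(key, "=[01]"), info))
  has <- grepl(paste0(key, "="), info, fixed = TRUE)
  val[has] <- sub(paste0(key, "="), "", hit) == "1"
  val
}

#' Load a dataset (VCF + BED + GFF3 + sample sheet)
#'
#' @param vcf_path,bed_path,gff_path,sample_sheet_path file paths; `gff_path`
#'   may be `NULL` when no gene models are needed.
#' @return A list with `variants` ([variant_table()]), `mask`
#'   ([callable_mask()]) and `genes` (gene-model tibble or `NULL`).
#' @export
load_dataset <- function(vcf_path, bed_path, gff_path, sample_sheet_path) {
  samples <- read_sample_sheet(sample_sheet_path)
  list(variants = read_vcf(vcf_path, samples),
       mask = read_bed(bed_path),
       genes = if (is.null(gff_path)) NULL else read_gff3(gff_path))
}

#' Apply the hard variant filters
#'
#' Retained SNPs must have genotype quality >= `min_gq` and depth between
#' `min_dp` and `depth_factor` x the per-sample mean genome depth in every
#' non-missing genotype, pass the strand-balance and read-placement flags,
#' and lie more than `snp_gap` bp away from any non-SNP variant. Excluded
#' SNP positions are excised from the callable mask. Indels are dropped
#' unless `keep_indels = TRUE`, in which case they are retained under the
#' same depth/quality rules (without the proximity or strand rules).
#'
#' @param vt a [variant_table()].
#' @param mask a [callable_mask()].
#' @param mean_depth per-sample mean genome depth: single number or vector
#'   named by sample id.
#' @param keep_indels keep indels passing depth/quality rules?
#' @param min_gq,min_dp,depth_factor,snp_gap filter thresholds.
#' @return list with filtered `variants` and updated `mask`.
#' @export
filter_variants <- function(vt, mask, mean_depth, keep_indels = FALSE,
                            min_gq = 10, min_dp = 8, depth_factor = 3,
                            snp_gap = 2) {
  ns <- nrow(vt$samples)
  if (length(mean_depth) == 1) {
    mean_depth <- setNames(rep(mean_depth, ns), vt$samples$id)
  }
  assert_that(all(vt$samples$id %in% names(mean_depth)),
              "mean_depth must cover every sample")
  md <- mean_depth[vt$samples$id]
  assert_that(all(md > 0), "mean_depth must be positive")
  assert_that(!any(vt$dp < 0, na.rm = TRUE), "negative DP encountered")

  s <- vt$sites
  on_mask_chrom <- s$chrom %in% unique(mask$chrom)
  if (any(!on_mask_chrom)) {
    warnf("%d record(s) on chromosome(s) absent from the mask were dropped",
          sum(!on_mask_chrom))
  }

  max_dp <- matrix(rep(depth_factor * md, each = nrow(s)), nrow(s), ns)
  geno_ok <- (is.na(vt$a1) |
                (!is.na(vt$gq) & vt$gq >= min_gq &
                   !is.na(vt$dp) & vt$dp >= min_dp & vt$dp <= max_dp))
  rec_geno_ok <- rowSums(!geno_ok) == 0

  near_nonsnp <- rep(FALSE, nrow(s))
  nsnp <- which(!s$is_snp)
  if (length(nsnp) > 0) {
    for (ch in unique(s$chrom[nsnp])) {
      i_snp <- which(s$is_snp & s$chrom == ch)
      p_ind <- s$pos[nsnp[s$chrom[nsnp] == ch]]
      if (length(i_snp) == 0) next
      for (p in p_ind) {
        near_nonsnp[i_snp[abs(s$pos[i_snp] - p) <= snp_gap]] <- TRUE
      }
    }
  }

  snp_pass <- s$is_snp & rec_geno_ok & s$strand_ok & s$placement_ok &
    !near_nonsnp & on_mask_chrom
  indel_pass <- !s$is_snp & keep_indels & rec_geno_ok & on_mask_chrom
  keep <- snp_pass | indel_pass

  excluded_snps <- s[s$is_snp & !snp_pass & on_mask_chrom,
                     c("chrom", "pos"), drop = FALSE]
  mask2 <- mask_remove_positions(mask, excluded_snps)
  list(variants = vt_subset(vt, keep), mask = mask2)
}
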