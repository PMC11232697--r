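#' Relative neo-W coverage from sex-contrasted depth ratios
#'
#' Males carry two neo-Z chromosomes and females one neo-Z and one neo-W,
#' so the neo-W coverage relative to the neo-Z is
#' `covW = (covFemale - covMale/2) * 2`, with both inputs expressed as
#' focal:autosome depth ratios. Negative estimates are clamped at zero and
#' flagged.
#'
#' @param cov_female,cov_male focal:autosome depth ratios (vectorized).
#' @return A tibble: `cov_female`, `cov_male`, `cov_w`, `clamped`.
#' @export
neo_w_coverage <- function(cov_female, cov_male) {
  assert_that(all(cov_male > 0), "cov_male must be positive")
  raw <- (cov_female - cov_male / 2) * 2
  tibble(cov_female = cov_female, cov_male = cov_male,
         cov_w = pmax(raw, 0), clamped = raw < 0)
}

#' Per-sample and per-window coverage profile of a focal chromosome
#'
#' Normalizes each sample's depth by its own autosomal mean, averages the
#' normalized depth within sex per window of the focal chromosome, and
#' applies the [neo_w_coverage()] estimator per window.
#'
#' @param coverage tibble (`chrom`, `start`, `end`, `sample`, `depth`).
#' @param samples sample sheet tibble (`id`, `sex`, `population`).
#' @param focal_chrom focal chromosome name.
#' @param autosomes autosomal chromosome name(s) used for normalization.
#' @param populations optional population(s) whose samples are used
#'   (default: all).
#' @return A list: `per_sample` (sample, sex, focal and autosomal means,
#'   ratio) and `per_window` (`chrom`, `start`, `end`, `cov_female`,
#'   `cov_male`, `cov_w`).
#' @export
coverage_profile <- function(coverage, samples, focal_chrom, autosomes,
                             populations = NULL) {
  if (!is.null(populations)) {
    samples <- samples[samples$population %in% populations, , drop = FALSE]
    coverage <- coverage[coverage$sample %in% samples$id, , drop = FALSE]
  }
  auto_mean <- coverage |>
    filter(.data$chrom %in% autosomes) |>
    group_by(.data$sample) |>
    summarise(auto = mean(.data$depth), .groups = "drop")
  foc <- coverage |>
    filter(.data$chrom %in% focal_chrom) |>
    left_join(auto_mean, by = "sample") |>
    mutate(rel = .data$depth / .data$auto,
           sex = samples$sex[match(.data$sample, samples$id)])
  per_sample <- foc |>
    group_by(.data$sample, .data$sex) |>
    summarise(focal_mean = mean(.data$depth), .groups = "drop") |>
    left_join(auto_mean, by = "sample") |>
    mutate(ratio = .data$focal_mean / .data$auto)
  per_window <- foc |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(cov_female = mean(.data$rel[.data$sex == "female"]),
              cov_male = mean(.data$rel[.data$sex == "male"]),
              .groups = "drop")
  cw <- neo_w_coverage(per_window$cov_female, per_window$cov_male)
  per_window$cov_w <- cw$cov_w
  list(per_sample = per_sample, per_window = arrange(per_window,
                                                     .data$start))
}

#' Classify loss-of-function variants
#'
#' A CDS-aware deterministic classifier covering four categories: premature
#' stop codons (a SNP creating an in-frame stop before the annotated stop),
#' frameshifts (indel of length not divisible by 3 inside the CDS),
#' start-loss (initiator codon disrupted) and stop-loss (annotated stop
#' disrupted). Variants spanning a CDS boundary are conservatively excluded.
#' When haplotype call matrices are supplied, each call is annotated with
#' the haplotype class and whether it is fixed (carried by every haplotype
#' of the class with a non-missing call).
#'
#' @param vt a [variant_table()] (or a tibble with `chrom`, `pos`, `ref`,
#'   `alt`) including indels.
#' @param genes gene-model tibble.
#' @param ref reference sequences (named character or DNAStringSet).
#' @param haplotypes optional named list of [haplotype_matrix()] objects
#'   (e.g. `list(neo_w = ..., neo_z = ...)`).
#' @return A tibble of calls: `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `category`, and per haplotype class `haplotype`, `fixed` (one row per
#'   class carrying the variant) when `haplotypes` is given.
#' @export
classify_lof <- function(vt, genes, ref, haplotypes = NULL) {
  ref <- ref_as_character(ref)
  sites <- if (inherits(vt, "variant_table")) vt$sites else as_tibble(vt)
  layouts <- cds_layout(ref, genes)
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  calls <- list()
  for (lay in layouts) {
    hit <- which(sites$chrom == lay$chrom &
                   sites$pos >= min(lay$gpos) & sites$pos <= max(lay$gpos))
    if (length(hit) == 0) next
    n_cod <- length(lay$seq) / 3
    for (i in hit) {
      p <- sites$pos[i]; rf <- sites$ref[i]; al <- sites$alt[i]
      if (nchar(rf) == 1 && nchar(al) == 1) {
        ci <- match(p, lay$gpos)
        if (is.na(ci)) next  # intron
        b <- if (lay$strand == "-") rev_comp_chars(al) else al
        cod_i <- (ci - 1) %/% 3 + 1
        cod <- lay$seq[(3 * cod_i - 2):(3 * cod_i)]
        newcod <- cod
        newcod[(ci - 1) %% 3 + 1] <- b
        old_str <- paste(cod, collapse = "")
        new_str <- paste(newcod, collapse = "")
        category <- NA_character_
        if (cod_i == 1 && old_str == "ATG" && new_str != "ATG") {
          category <- "start_loss"
        } else if (cod_i == n_cod && old_str %in% stops &&
                     !(new_str %in% stops)) {
          category <- "stop_loss"
        } else if (cod_i < n_cod && !(old_str %in% stops) &&
                     new_str %in% stops) {
          category <- "premature_stop"
        }
        if (is.na(category)) next
      } else {
        # indel: all affected/flanking bases must lie inside the CDS
        len_diff <- abs(nchar(rf) - nchar(al))
        if (len_diff == 0 || len_diff %% 3 == 0) next
        span <- p:(p + max(nchar(rf) - 1, 1))
        if (!all(span %in% lay$gpos)) next  # spans a CDS boundary: excluded
        category <- "frameshift"
      }
      calls[[length(calls) + 1]] <- tibble(
        gene_id = lay$gene_id, chrom = lay$chrom, pos = p, ref = rf,
        alt = al, category = category)
    }
  }
  calls <- bind_rows(calls)
  if (nrow(calls) == 0) {
    calls <- tibble(gene_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0),
                    alt = character(0), category = character(0))
  }
  if (is.null(haplotypes) || nrow(calls) == 0) return(calls)
  out <- list()
  for (cls in names(haplotypes)) {
    hm <- haplotypes[[cls]]
    idx <- match(paste(calls$chrom, calls$pos),
                 paste(hm$sites$chrom, hm$sites$pos))
    present <- !is.na(idx)
    if (!any(present)) next
    sub <- calls[present, , drop = FALSE]
    mat <- hm$mat[, idx[present], drop = FALSE]
    carried <- colSums(mat == 1, na.rm = TRUE) > 0
    fixed <- vapply(seq_len(ncol(mat)), function(j) {
      x <- mat[, j]
      sum(!is.na(x)) > 0 && all(x[!is.na(x)] == 1)
    }, logical(1))
    sub$haplotype <- cls
    sub$fixed <- fixed
    out[[cls]] <- sub[carried, , drop = FALSE]
  }
  bind_rows(out)
}

#' Proportion of genes with fixed loss-of-function mutations
#'
#' @param calls output of [classify_lof()] with `haplotype`/`fixed` columns.
#' @param universe character vector of gene ids considered (e.g. genes with
#'   nonzero expression).
#' @param class haplotype class to evaluate (e.g. `"neo_w"`).
#' @param level confidence level for the exact binomial CI.
#' @return One-row tibble: `class`, `n_lof`, `n_genes`, `proportion`,
#'   `lower`, `upper`.
#' @export
fixed_lof_proportion <- function(calls, universe, class = "neo_w",
                                 level = 0.95) {
  assert_that(length(universe) > 0, "empty gene universe")
  hit <- calls$haplotype == class & calls$fixed &
    calls$gene_id %in% universe
  k <- length(unique(calls$gene_id[hit]))
  n <- length(unique(universe))
  ci <- binomial_frequency_ci(k, n, level)
  tibble(class = class, n_lof = k, n_genes = n, proportion = k / n,
         lower = ci$lower, upper = ci$upper)
}

#' Haplotype-specific expression bias
#'
#' Per-gene neo-Z fraction `Z / (Z + W)` (genes with total below
#' `min_total` excluded) and the median neo-Z : neo-W fold difference
#' (genes with zero neo-W count are reported with fraction 1 but excluded
#' from the fold median, since their ratio is undefined).
#'
#' @param counts tibble with `gene_id`, `z_count`, `w_count`.
#' @param min_total minimum total (Z + W) count per gene.
#' @return A list of class `ase_result`: `genes` tibble, `median_fold`,
#'   `n_w_zero`, `n_genes`.
#' @export
ase_expression <- function(counts, min_total = 10) {
  assert_that(all(counts$z_count >= 0) && all(counts$w_count >= 0),
              "counts must be non-negative")
  d <- counts[counts$z_count + counts$w_count >= min_total, , drop = FALSE]
  assert_that(nrow(d) > 0, "all genes excluded by the expression filter")
  d <- mutate(d, z_fraction = .data$z_count / (.data$z_count + .data$w_count),
              fold = ifelse(.data$w_count > 0,
                            .data$z_count / .data$w_count, NA_real_))
  structure(list(genes = as_tibble(d),
                 median_fold = median(d$fold, na.rm = TRUE),
                 n_w_zero = sum(d$w_count == 0), n_genes = nrow(d)),
            class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  cat(sprintf("<ase_result> %d genes; median neo-Z:neo-W fold = %.3g (%d neo-W-silent)\n",
              x$n_genes, x$median_fold, x$n_w_zero))
  invisible(x)
}

#' @export
glance.ase_result <- function(x, ...) {
  tibble(n_genes = x$n_genes, median_fold = x$median_fold,
         n_w_zero = x$n_w_zero,
         mean_z_fraction = mean(x$genes$z_fraction))
}
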