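#' Per-site codon degeneracy classes
#'
#' Labels every CDS site by how many of the three possible substitutions
#' preserve the amino acid under the standard genetic code: `4D` when all do
#' (synonymous whatever the change), `0D` when none does, `2D`/`3D` in
#' between. Classification is strand-aware and honours the per-segment CDS
#' phase.
#'
#' @param ref reference sequences: a named character vector or
#'   `Biostrings::DNAStringSet`, one entry per chromosome.
#' @param genes gene-model tibble (see [read_gff3()]).
#' @return A tibble with `chrom`, `pos` (1-based), `gene_id`, `degeneracy`.
#' @export
classify_site_degeneracy <- function(ref, genes) {
  ref <- ref_as_character(ref)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(unique(genes$gene_id)))
  k <- 0
  for (gid in unique(genes$gene_id)) {
    d <- genes[genes$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    chrom <- d$chrom[1]
    assert_that(chrom %in% names(ref), "chromosome %s not in reference", chrom)
    gpos <- unlist(lapply(seq_len(nrow(d)),
                          function(i) seq(d$start[i] + 1L, d$end[i])))
    seq <- extract_cds_chars(ref[[chrom]], d)
    if (d$strand[1] == "-") {
      gpos <- rev(gpos)
      seq <- rev_comp_chars(rev(seq))
    }
    ph <- if (d$strand[1] == "-") d$phase[nrow(d)] else d$phase[1]
    if (ph > 0) {
      gpos <- gpos[-seq_len(ph)]
      seq <- seq[-seq_len(ph)]
    }
    if (length(seq) %% 3 != 0) {
      warnf("gene %s: CDS length not divisible by 3 after phase; skipped", gid)
      next
    }
    n_cod <- length(seq) / 3
    cod <- matrix(seq, nrow = 3)
    aa <- code[paste0(cod[1, ], cod[2, ], cod[3, ])]
    if (any(aa[-n_cod] == "*", na.rm = TRUE)) {
      warnf("gene %s: internal stop codon in reference CDS", gid)
    }
    n_syn <- matrix(0L, 3, n_cod)
    for (p in 1:3) {
      for (b in bases) {
        alt <- cod
        hit <- alt[p, ] != b
        alt[p, ] <- b
        aa_alt <- code[paste0(alt[1, ], alt[2, ], alt[3, ])]
        n_syn[p, ] <- n_syn[p, ] + as.integer(hit & aa_alt == aa)
      }
    }
    cls <- c("0D", "2D", "3D", "4D")[n_syn + 1L]
    k <- k + 1
    out[[k]] <- tibble(chrom = chrom, pos = gpos, gene_id = gid,
                       degeneracy = as.vector(cls))
  }
  bind_rows(out[seq_len(k)])
}

ref_as_character <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    return(setNames(as.character(ref), names(ref)))
  }
  if (is.list(ref)) ref <- unlist(ref)
  assert_that(is.character(ref) && !is.null(names(ref)),
              "ref must be a named character vector or DNAStringSet")
  ref
}

# CDS characters in genomic order, extracted segment-wise (cheap on long
# chromosome strings)
extract_cds_chars <- function(refstr, d) {
  strsplit(paste(substring(refstr, d$start + 1L, d$end), collapse = ""),
           "")[[1]]
}

rev_comp_chars <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Diversity and divergence statistics
#'
#' Computes nucleotide diversity (pi, mean pairwise difference per callable
#' site), per-sample heterozygosity (H, heterozygous genotypes per callable
#' site), and for every pair of groups the absolute divergence dxy, Hudson's
#' FST (1 - mean within-pi / dxy) and the net divergence
#' da = dxy - mean within-pi. Missing genotypes are excluded pairwise (the
#' per-site allele count is adjusted). Only SNP records enter the counts.
#'
#' @param vt a [variant_table()].
#' @param mask a [callable_mask()] giving the denominator sites.
#' @param groups named list of sample-id vectors; default one group per
#'   population.
#' @param sites optional tibble (`chrom`, `pos`) restricting both the
#'   variants and the callable denominator (e.g. 4D sites from
#'   [classify_site_degeneracy()]).
#' @param chrom optional chromosome(s) to restrict to.
#' @return A list of tibbles: `per_group` (pi), `per_sample` (H),
#'   `pairwise` (dxy, fst, da).
#' @export
diversity_stats <- function(vt, mask, groups = NULL, sites = NULL,
                            chrom = NULL) {
  if (!is.null(chrom)) {
    vt <- vt_subset(vt, vt$sites$chrom %in% chrom)
    mask <- mask[mask$chrom %in% chrom, , drop = FALSE]
    if (!is.null(sites)) sites <- sites[sites$chrom %in% chrom, , drop = FALSE]
  }
  if (is.null(groups)) {
    groups <- split(vt$samples$id, vt$samples$population)
  }
  assert_that(length(groups) >= 1 && all(lengths(groups) >= 1),
              "need at least one sample per group")
  keep <- vt$sites$is_snp
  if (!is.null(sites)) {
    key <- paste(vt$sites$chrom, vt$sites$pos)
    keep <- keep & key %in% paste(sites$chrom, sites$pos)
    callable <- sum(mask_covers(mask, sites$chrom, sites$pos))
  } else {
    callable <- mask_length(mask)
  }
  assert_that(callable > 0, "zero callable sites")
  vt <- vt_subset(vt, keep)
  dos <- vt_dosage(vt)

  grp_counts <- function(ids) {
    m <- dos[, ids, drop = FALSE]
    alt <- rowSums(m, na.rm = TRUE)
    n <- 2L * rowSums(!is.na(m))
    list(alt = alt, n = n)
  }
  counts <- lapply(groups, grp_counts)

  per_group <- purrr::map2_dfr(names(groups), counts, function(g, ct) {
    if (length(groups[[g]]) < 2) {
      return(tibble(group = g, n_samples = length(groups[[g]]),
                    pi = NA_real_, callable = callable))
    }
    ok <- ct$n >= 2
    pi_sum <- sum(2 * ct$alt[ok] * (ct$n[ok] - ct$alt[ok]) /
                    (ct$n[ok] * (ct$n[ok] - 1)))
    tibble(group = g, n_samples = length(groups[[g]]),
           pi = pi_sum / callable, callable = callable)
  })

  all_ids <- unique(unlist(groups))
  het <- vt$a1[, all_ids, drop = FALSE] != vt$a2[, all_ids, drop = FALSE]
  per_sample <- tibble(
    sample = all_ids,
    sex = vt$samples$sex[match(all_ids, vt$samples$id)],
    n_het = colSums(het, na.rm = TRUE),
    callable = callable,
    h = colSums(het, na.rm = TRUE) / callable)

  pairs <- if (length(groups) > 1) utils::combn(names(groups), 2) else NULL
  pairwise <- if (is.null(pairs)) {
    tibble(group1 = character(0), group2 = character(0), dxy = numeric(0),
           fst = numeric(0), da = numeric(0))
  } else {
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      c1 <- counts[[g1]]; c2 <- counts[[g2]]
      ok <- c1$n > 0 & c2$n > 0
      p1 <- c1$alt[ok] / c1$n[ok]; p2 <- c2$alt[ok] / c2$n[ok]
      dxy <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / callable
      pw <- mean(c(per_group$pi[per_group$group == g1],
                   per_group$pi[per_group$group == g2]))
      tibble(group1 = g1, group2 = g2, dxy = dxy,
             fst = if (!is.na(pw) && dxy > 0) 1 - pw / dxy else NA_real_,
             da = if (!is.na(pw)) dxy - pw else NA_real_)
    })
  }
  list(per_group = per_group, per_sample = per_sample, pairwise = pairwise)
}

#' Nucleotide diversity from a haplotype matrix
#'
#' @param h haplotype matrix (haplotypes x sites) of 0/1 allele indices,
#'   `NA` allowed.
#' @param callable number of callable sites (denominator).
#' @return Mean pairwise difference per callable site.
#' @export
pi_from_haplotypes <- function(h, callable) {
  assert_that(callable > 0, "callable must be positive")
  if (ncol(h) == 0 || nrow(h) < 2) return(0)
  cnt <- colSums(h == 1, na.rm = TRUE)
  n <- colSums(!is.na(h))
  ok <- n >= 2
  sum(2 * cnt[ok] * (n[ok] - cnt[ok]) / (n[ok] * (n[ok] - 1))) / callable
}

#' Windowed heterozygosity landscape
#'
#' Tiles each chromosome into fixed windows, counts callable sites and
#' heterozygous genotypes, and reports the mean per-sample H per window.
#' When `mask_fraction > 0` the `ceiling(mask_fraction * n)` windows with the
#' lowest coverage value are flagged `masked` (ties broken leftmost-first);
#' these are meant to be excluded from change-point segmentation.
#'
#' @param vt a [variant_table()].
#' @param mask a [callable_mask()].
#' @param window_length window size in bp.
#' @param samples sample ids whose H is averaged (default: all samples).
#' @param coverage optional tibble (`chrom`, `start`, `end`, `cov`) of a
#'   per-window coverage statistic (e.g. estimated neo-W coverage) on the
#'   same window grid.
#' @param mask_fraction fraction of windows to mask (0 <= f < 1).
#' @param chrom optional chromosome restriction.
#' @return A tibble with one row per window: `chrom`, `window`, `start`,
#'   `end`, `callable`, `n_het`, `h`, `cov`, `masked`.
#' @export
windowed_divergence <- function(vt, mask, window_length, samples = NULL,
                                coverage = NULL, mask_fraction = 0,
                                chrom = NULL) {
  assert_that(window_length > 0, "window_length must be positive")
  assert_that(mask_fraction >= 0 && mask_fraction < 1,
              "mask_fraction must be in [0, 1)")
  if (!is.null(chrom)) {
    vt <- vt_subset(vt, vt$sites$chrom %in% chrom)
    mask <- mask[mask$chrom %in% chrom, , drop = FALSE]
  }
  if (is.null(samples)) samples <- vt$samples$id
  chroms <- unique(mask$chrom)
  wins <- bind_rows(lapply(chroms, function(ch) {
    len <- max(mask$end[mask$chrom == ch],
               vt$sites$pos[vt$sites$chrom == ch], 0L)
    n <- ceiling(len / window_length)
    tibble(chrom = ch, window = seq_len(n),
           start = (seq_len(n) - 1L) * as.integer(window_length),
           end = seq_len(n) * as.integer(window_length))
  }))
  wins$callable <- mask_callable_in_windows(mask, wins)
  assert_that(any(wins$callable > 0), "no windows with callable sites")

  snp <- vt$sites$is_snp
  het <- (vt$a1[, samples, drop = FALSE] != vt$a2[, samples, drop = FALSE])
  n_het_site <- rowSums(het, na.rm = TRUE) * snp
  widx <- match(paste(vt$sites$chrom,
                      (vt$sites$pos - 1L) %/% as.integer(window_length)),
                paste(wins$chrom, (wins$start %/% as.integer(window_length))))
  agg <- tapply(n_het_site, widx, sum)
  wins$n_het <- 0
  wins$n_het[as.integer(names(agg))] <- as.numeric(agg)
  wins$h <- ifelse(wins$callable > 0,
                   wins$n_het / length(samples) / wins$callable, NA_real_)
  if (!is.null(coverage)) {
    wins <- left_join(wins, coverage[, c("chrom", "start", "cov")],
                      by = c("chrom", "start"))
  } else {
    wins$cov <- NA_real_
  }
  wins$masked <- FALSE
  if (mask_fraction > 0) {
    k <- ceiling(mask_fraction * nrow(wins))
    cv <- if (all(is.na(wins$cov))) rep(0, nrow(wins)) else wins$cov
    ord <- order(cv, wins$chrom, wins$start)
    wins$masked[ord[seq_len(k)]] <- TRUE
  }
  wins
}

#' Moments estimator of a population split time
#'
#' The net-divergence estimator T = da / (2 mu) with
#' da = dxy - mean within-population pi, clamped at zero. It assumes that
#' the mean of the two within-population diversities is a fair proxy for
#' ancestral diversity; under strong size changes the estimate is biased
#' accordingly.
#'
#' @param dxy between-group divergence per site.
#' @param pi_within_mean mean of the two within-group diversities.
#' @param mu mutation rate per site per generation.
#' @return A one-row tibble: `t_hat` (generations), inputs echoed.
#' @export
moments_split_time <- function(dxy, pi_within_mean, mu) {
  assert_that(mu > 0, "mu must be positive")
  assert_that(dxy >= 0, "dxy must be non-negative")
  tibble(t_hat = pmax(0, (dxy - pi_within_mean) / (2 * mu)),
         dxy = dxy, pi_within = pi_within_mean, mu = mu)
}
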