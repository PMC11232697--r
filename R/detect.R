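#' Sex-contrasted heterozygosity test for a neo-W
#'
#' A fused, non-recombining neo-W makes heterogametic females carry two
#' diverged haplotypes on the focal chromosome, so female heterozygosity
#' reflects neo-W/neo-Z divergence while male heterozygosity stays at the
#' autosomal level. The verdict is `TRUE` when the female mean exceeds the
#' male mean by at least `factor_threshold` and the male focal:autosomal
#' ratio lies within `auto_band`. A Wilcoxon rank-sum p-value comparing
#' female and male focal H is reported descriptively.
#'
#' @param h_focal,h_auto numeric vectors of per-sample H (focal chromosome /
#'   autosomes), in the same sample order.
#' @param sexes character vector (`"female"`/`"male"`).
#' @param factor_threshold required female:male ratio (default 3).
#' @param auto_band allowed male focal:autosomal ratio band.
#' @return A list of class `sex_contrast`: group means, ratios, `p_value`,
#'   `verdict`, `flag`.
#' @export
sex_contrast_heterozygosity <- function(h_focal, h_auto, sexes,
                                        factor_threshold = 3,
                                        auto_band = c(1 / 3, 3)) {
  assert_that(length(h_focal) == length(sexes) &&
                length(h_auto) == length(sexes),
              "h_focal, h_auto and sexes must have equal length")
  assert_that(all(sexes %in% c("female", "male")), "bad sex labels")
  assert_that(any(sexes == "female") && any(sexes == "male"),
              "need at least one sample of each sex")
  f <- sexes == "female"
  mean_f <- mean(h_focal[f])
  mean_m <- mean(h_focal[!f])
  mean_auto <- mean(h_auto)
  flag <- "ok"
  if (mean_f == 0 && mean_m == 0) {
    verdict <- FALSE
    flag <- "uninformative"
    ratio <- NA_real_
    male_auto_ratio <- NA_real_
  } else {
    ratio <- if (mean_m > 0) mean_f / mean_m else Inf
    male_auto <- mean(h_auto[!f])
    male_auto_ratio <- if (male_auto > 0) mean_m / male_auto else NA_real_
    verdict <- isTRUE(ratio >= factor_threshold) &&
      isTRUE(male_auto_ratio >= auto_band[1] &&
               male_auto_ratio <= auto_band[2])
  }
  p <- if (sum(f) >= 1 && sum(!f) >= 1 && (mean_f > 0 || mean_m > 0)) {
    suppressWarnings(wilcox.test(h_focal[f], h_focal[!f])$p.value)
  } else NA_real_
  structure(list(mean_female_focal = mean_f, mean_male_focal = mean_m,
                 mean_autosomal = mean_auto, ratio = ratio,
                 male_auto_ratio = male_auto_ratio,
                 factor_threshold = factor_threshold, auto_band = auto_band,
                 p_value = p, verdict = verdict, flag = flag),
            class = "sex_contrast")
}

#' @export
print.sex_contrast <- function(x, ...) {
  cat(sprintf(
    "<sex_contrast> female H = %.4g, male H = %.4g (ratio %.2g), autosomal H = %.4g\n",
    x$mean_female_focal, x$mean_male_focal, x$ratio, x$mean_autosomal))
  cat(sprintf("verdict: %s (%s), Wilcoxon p = %.3g\n",
              if (x$verdict) "neo-W detected" else "no neo-W", x$flag,
              x$p_value))
  invisible(x)
}

#' @export
tidy.sex_contrast <- function(x, ...) {
  tibble(mean_female_focal = x$mean_female_focal,
         mean_male_focal = x$mean_male_focal,
         mean_autosomal = x$mean_autosomal, ratio = x$ratio,
         male_auto_ratio = x$male_auto_ratio, p_value = x$p_value,
         verdict = x$verdict, flag = x$flag)
}

#' Principal component analysis of a genotype matrix
#'
#' Centered (optionally unit-variance scaled) PCA of the dosage matrix.
#' When sexes are supplied, a sex-separation score on PC1 is computed: the
#' fraction of samples correctly partitioned by the best threshold on PC1
#' (1 = perfect separation).
#'
#' @param vt a [variant_table()] (restrict to one chromosome first), or a
#'   samples x sites dosage matrix.
#' @param sexes optional per-sample sex labels.
#' @param scale. unit-variance scaling per site (default `FALSE`).
#' @param k number of components to keep.
#' @return A list of class `genotype_pca`: `scores` tibble,
#'   `var_explained`, `sep_score`.
#' @export
genotype_pca <- function(vt, sexes = NULL, scale. = FALSE, k = 2) {
  if (inherits(vt, "variant_table")) {
    m <- t(vt_dosage(vt))
    if (is.null(sexes)) sexes <- vt$samples$sex
  } else {
    m <- vt
  }
  assert_that(nrow(m) >= 3, "need at least 3 samples")
  m[is.na(m)] <- 0
  keep <- apply(m, 2, function(x) length(unique(x)) > 1)
  assert_that(sum(keep) >= 2, "no variation: need >= 2 polymorphic sites")
  m <- m[, keep, drop = FALSE]
  p <- prcomp(m, center = TRUE, scale. = scale.)
  k <- min(k, ncol(p$x))
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(p$x[, seq_len(k), drop = FALSE])
  scores$sample <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  sep <- NA_real_
  if (!is.null(sexes)) {
    pc1 <- p$x[, 1]
    thr <- sort(unique(pc1))
    cuts <- c(-Inf, (head(thr, -1) + tail(thr, -1)) / 2, Inf)
    acc <- vapply(cuts, function(ct) {
      cl <- pc1 > ct
      max(mean(cl == (sexes == "female")), mean(cl == (sexes == "male")))
    }, numeric(1))
    sep <- max(acc)
  }
  structure(list(scores = scores, var_explained = ve, sep_score = sep,
                 sexes = sexes),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> PC1 explains %.1f%% of variance; sex-separation score %s\n",
              100 * x$var_explained[1],
              ifelse(is.na(x$sep_score), "NA",
                     sprintf("%.2f", x$sep_score))))
  invisible(x)
}

#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' @export
glance.genotype_pca <- function(x, ...) {
  tibble(pc1_var = x$var_explained[1],
         pc2_var = ifelse(length(x$var_explained) > 1,
                          x$var_explained[2], NA_real_),
         sep_score = x$sep_score)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Inverts the binomial tail probabilities; for `k = n` the lower bound is
#' `(alpha/2)^(1/n)` and the upper bound 1.
#'
#' @param k number of carriers observed.
#' @param n number sampled.
#' @param level confidence level (default 0.95).
#' @return A one-row tibble: `k`, `n`, `lower`, `upper`, `level`.
#' @export
binomial_frequency_ci <- function(k, n, level = 0.95) {
  assert_that(n > 0, "n must be positive")
  assert_that(k >= 0 && k <= n, "k must be in [0, n]")
  assert_that(level > 0 && level < 1, "level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  tibble(k = k, n = n, lower = lower, upper = upper, level = level)
}
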