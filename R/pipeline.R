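#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. By default the
#' pipeline runs on a synthetic dataset from [simulate_dataset()]; supply
#' `paths` to run on files instead (VCF, BED, GFF3, sample sheet, coverage
#' TSV, expression TSV, phased haplotype VCFs, FASTA).
#'
#' @param sim a [sim_config()] used when simulating.
#' @param paths optional named list of input paths (`vcf`, `bed`, `gff`,
#'   `sheet`, `coverage`, `expression`, `w_calls`, `z_calls`, `ref`).
#' @param seed master seed for the run.
#' @param focal_chrom,autosomes chromosome names.
#' @param mask_fraction fraction of lowest-coverage windows excluded from
#'   segmentation.
#' @param p0,w0,iterations,burn_in change-point sampler settings.
#' @param prob_threshold,min_windows plateau extraction settings.
#' @param factor_threshold,auto_band sex-contrast verdict settings.
#' @param out_dir optional output directory for the report and stage files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL, seed = 1,
                            focal_chrom = "chrNeo", autosomes = "chrA1",
                            mask_fraction = 0.2, p0 = 0.2, w0 = 0.2,
                            iterations = 550, burn_in = 50,
                            prob_threshold = 0.5, min_windows = 5,
                            factor_threshold = 3, auto_band = c(1 / 3, 3),
                            out_dir = NULL) {
  structure(list(sim = sim, paths = paths, seed = as.integer(seed),
                 focal_chrom = focal_chrom, autosomes = autosomes,
                 mask_fraction = mask_fraction, p0 = p0, w0 = w0,
                 iterations = iterations, burn_in = burn_in,
                 prob_threshold = prob_threshold, min_windows = min_windows,
                 factor_threshold = factor_threshold, auto_band = auto_band,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full neo-sex chromosome analysis
#'
#' Stages, in dependency order: simulate (or load) -> variant filtering ->
#' neo-W detection (sex-contrasted heterozygosity, genotype PCA, carrier
#' frequency CI) -> windowed divergence with coverage masking -> Bayesian
#' change-point segmentation into plateaus with moments split times ->
#' diagnostic-allele phasing -> single-genealogy (perfect phylogeny) test
#' with neutral-spectrum comparison, outgroup polarization and TMRCA ->
#' degeneration summaries (relative neo-W coverage, fixed loss-of-function
#' proportions per plateau, pi0/pi4, allele-specific expression).
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `neosex_report` with one element per stage and a
#'   `summary` tibble of headline statistics; written as JSON when
#'   `cfg$out_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  sim <- cfg$sim
  if (is.null(cfg$paths)) {
    dat <- simulate_dataset(sim, seed = cfg$seed)
  } else {
    dat <- load_pipeline_inputs(cfg$paths)
  }
  mu <- sim$mu
  s <- dat$samples
  ib_ids <- s$id[s$population == "Iberia"]

  # --- filtering -------------------------------------------------------------
  flt <- filter_variants(dat$variants, dat$mask, mean_depth = sim$depth_mean)
  flt_indel <- filter_variants(dat$variants, dat$mask,
                               mean_depth = sim$depth_mean,
                               keep_indels = TRUE)
  vt <- flt$variants
  mask <- flt$mask

  # --- detection -------------------------------------------------------------
  ds_foc <- diversity_stats(vt, mask, groups = list(Iberia = ib_ids),
                            chrom = cfg$focal_chrom)
  ds_aut <- diversity_stats(vt, mask, groups = list(Iberia = ib_ids),
                            chrom = cfg$autosomes)
  hs <- left_join(ds_foc$per_sample, ds_aut$per_sample,
                  by = c("sample", "sex"), suffix = c("_focal", "_auto"))
  contrast <- sex_contrast_heterozygosity(
    hs$h_focal, hs$h_auto, hs$sex,
    factor_threshold = cfg$factor_threshold, auto_band = cfg$auto_band)
  vt_ib_foc <- vt_subset(vt, vt$sites$chrom == cfg$focal_chrom, ib_ids)
  vt_ib_aut <- vt_subset(vt, vt$sites$chrom %in% cfg$autosomes, ib_ids)
  pca_foc <- genotype_pca(vt_ib_foc)
  pca_aut <- genotype_pca(vt_ib_aut)
  f_idx <- hs$sex == "female"
  carrier <- hs$h_focal[f_idx] >=
    cfg$factor_threshold * max(mean(hs$h_focal[!f_idx]), 1e-12)
  ci <- binomial_frequency_ci(sum(carrier), sum(f_idx), 0.95)

  # --- windowed divergence and plateaus -------------------------------------
  covp <- coverage_profile(dat$coverage, s, cfg$focal_chrom, cfg$autosomes,
                           populations = "Iberia")
  covw_win <- dplyr::rename(covp$per_window, cov = "cov_w")
  f_ib <- s$id[s$population == "Iberia" & s$sex == "female"]
  wins <- windowed_divergence(vt, mask, sim$window_length, samples = f_ib,
                              coverage = covw_win[, c("chrom", "start", "cov")],
                              mask_fraction = cfg$mask_fraction,
                              chrom = cfg$focal_chrom)
  unmasked <- wins[!wins$masked & wins$callable > 0, , drop = FALSE]
  pi_within <- 0
  if (!is.null(dat$w_calls)) {
    foc_callable <- mask_length(mask, cfg$focal_chrom)
    snp_w <- nchar(dat$w_calls$sites$ref) == 1 &
      nchar(dat$w_calls$sites$alt) == 1
    pi_w <- pi_from_haplotypes(dat$w_calls$mat[, snp_w, drop = FALSE],
                               foc_callable)
    pi_z <- pi_from_haplotypes(dat$z_calls$mat[, snp_w, drop = FALSE],
                               foc_callable)
    pi_within <- mean(c(pi_w, pi_z))
  }
  cp <- bcp_posterior(unmasked$h, p0 = cfg$p0, w0 = cfg$w0,
                      iterations = cfg$iterations, burn_in = cfg$burn_in,
                      seed = cfg$seed + 1L)
  plat <- extract_plateaus(cp, prob_threshold = cfg$prob_threshold,
                           min_windows = cfg$min_windows, mu = mu,
                           pi_within = pi_within)
  plat$start_bp <- unmasked$start[plat$start_win]
  plat$end_bp <- unmasked$end[plat$end_win]
  # coverage is averaged over every window in the plateau's span (the
  # low-coverage mask only serves the segmentation, and would bias covW up)
  plat$cov_w <- vapply(seq_len(nrow(plat)), function(i) {
    sel <- covw_win$start >= plat$start_bp[i] & covw_win$start < plat$end_bp[i]
    mean(covw_win$cov[sel])
  }, numeric(1))

  # --- phasing ---------------------------------------------------------------
  diag <- find_w_diagnostic_sites(vt_ib_foc)
  phased <- if (nrow(diag) > 0) phase_neo_w(vt_ib_foc, diag) else NULL

  # --- tree test -------------------------------------------------------------
  treetest <- NULL
  if (!is.null(dat$w_calls)) {
    hm <- dat$w_calls
    snp <- nchar(hm$sites$ref) == 1 & nchar(hm$sites$alt) == 1
    seg <- snp & {
      cnt <- colSums(hm$mat == 1, na.rm = TRUE)
      cnt > 0 & cnt < nrow(hm$mat)
    }
    hm_seg <- hm_subset(hm, which(seg))
    spec <- folded_spectrum(hm_seg)
    tree <- perfect_phylogeny_tree(spec)
    og <- maghreb_outgroup_alleles(vt, s, hm_seg$sites)
    foc_callable <- mask_length(mask, cfg$focal_chrom)
    pol <- polarize_and_tmrca(hm_seg, og, tree, mu, foc_callable)
    incons_keys <- tree$inconsistent$key
    site_keys <- vapply(seq_len(ncol(hm_seg$mat)), function(j)
      canonical_split_key(which(hm_seg$mat[, j] == 1), nrow(hm_seg$mat),
                          order(hm_seg$labels)[1]), character(1))
    runs <- runs_test_positions(hm_seg$sites$pos,
                                site_keys %in% incons_keys)
    treetest <- list(spectrum = spec, tree = tree, polarization = pol,
                     runs = runs,
                     n_types_expected_tree =
                       count_tree_branch_types(nrow(hm$mat)),
                     n_types_possible = count_possible_types(nrow(hm$mat)))
  }

  # --- degeneration ----------------------------------------------------------
  degen <- NULL
  if (!is.null(dat$genes)) {
    haps <- if (!is.null(dat$w_calls))
      list(neo_w = dat$w_calls, neo_z = dat$z_calls) else NULL
    lof <- classify_lof(flt_indel$variants, dat$genes, dat$ref,
                        haplotypes = haps)
    expr_universe <- if (!is.null(dat$expression)) {
      dat$expression$gene_id[dat$expression$z_count +
                               dat$expression$w_count > 0]
    } else unique(dat$genes$gene_id)
    gene_pos <- dat$genes |>
      group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                .groups = "drop")
    # degeneration specific to the neo-W: variants carried by every neo-W
    # haplotype and by no neo-Z haplotype (variants shared with the neo-Z
    # are ancestral polymorphism or reference-derived states, not decay)
    lof_w <- lof
    if (!is.null(haps) && nrow(lof) > 0) {
      zkey <- paste(lof$chrom, lof$pos)[lof$haplotype == "neo_z"]
      lof_w <- lof[lof$haplotype == "neo_w" &
                     !(paste(lof$chrom, lof$pos) %in% zkey), , drop = FALSE]
    }
    lof_overall <- if (!is.null(haps) && nrow(lof) > 0) {
      fixed_lof_proportion(lof_w, expr_universe, "neo_w")
    } else NULL
    lof_by_plateau <- NULL
    if (!is.null(haps)) {
      lof_by_plateau <- purrr::map_dfr(seq_len(nrow(plat)), function(i) {
        gg <- gene_pos$gene_id[gene_pos$chrom == cfg$focal_chrom &
                                 gene_pos$start >= plat$start_bp[i] &
                                 gene_pos$start < plat$end_bp[i]]
        gg <- intersect(gg, expr_universe)
        if (length(gg) == 0) return(NULL)
        mutate(fixed_lof_proportion(lof_w, gg, "neo_w"), plateau = i)
      })
    }
    degmap <- classify_site_degeneracy(dat$ref, dat$genes)
    pi04 <- pi0_pi4_by_class(dat, vt, mask, degmap, cfg$focal_chrom, s)
    ase <- if (!is.null(dat$expression))
      ase_expression(dat$expression) else NULL
    # plateau with the smallest divergence: does neo-W coverage still
    # differ from the neo-Z baseline?
    young <- which.min(plat$mean_div)
    ww <- unmasked$start[plat$start_win[young]:plat$end_win[young]]
    covs <- covp$per_window[covp$per_window$start %in% ww, , drop = FALSE]
    cov_test <- if (nrow(covs) >= 3) {
      suppressWarnings(wilcox.test(covs$cov_w, covs$cov_male)$p.value)
    } else NA_real_
    degen <- list(lof_calls = lof, lof_overall = lof_overall,
                  lof_by_plateau = lof_by_plateau, pi0_pi4 = pi04,
                  ase = ase, cov_wilcox_p_young_plateau = cov_test)
  }

  # --- autosomal split time --------------------------------------------------
  split_est <- NULL
  em_ids <- s$id[s$population == "EasternMaghreb"]
  if (length(em_ids) > 0) {
    ds2 <- diversity_stats(vt, mask,
                           groups = list(Iberia = ib_ids,
                                         EasternMaghreb = em_ids),
                           chrom = cfg$autosomes)
    pw <- ds2$pairwise[1, ]
    split_est <- moments_split_time(
      pw$dxy, mean(ds2$per_group$pi, na.rm = TRUE), mu)
  }

  report <- build_report(cfg, contrast, pca_foc, pca_aut, ci, wins, plat,
                         diag, treetest, degen, split_est, covp)
  out <- structure(
    list(config = cfg, data = dat, filtered = list(variants = vt, mask = mask),
         detection = list(contrast = contrast, pca_focal = pca_foc,
                          pca_autosome = pca_aut, carrier_ci = ci,
                          h = hs),
         windows = wins, changepoints = cp, plateaus = plat,
         phasing = list(diagnostic = diag, haplotypes = phased),
         treetest = treetest, degeneration = degen,
         split_time = split_est, coverage = covp, report = report),
    class = "neosex_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_json_stable(report, file.path(cfg$out_dir, "report.json"))
  }
  out
}

load_pipeline_inputs <- function(paths) {
  ds <- load_dataset(paths$vcf, paths$bed, paths$gff, paths$sheet)
  ref <- NULL
  if (!is.null(paths$ref)) {
    fa <- Biostrings::readDNAStringSet(paths$ref)
    ref <- setNames(as.character(fa), sub(" .*", "", names(fa)))
  }
  list(variants = ds$variants, mask = ds$mask, genes = ds$genes, ref = ref,
       coverage = if (is.null(paths$coverage)) NULL else
         readr::read_tsv(paths$coverage, show_col_types = FALSE,
                         progress = FALSE),
       expression = if (is.null(paths$expression)) NULL else
         readr::read_tsv(paths$expression, show_col_types = FALSE,
                         progress = FALSE),
       w_calls = if (is.null(paths$w_calls)) NULL else
         read_haploid_vcf(paths$w_calls),
       z_calls = if (is.null(paths$z_calls)) NULL else
         read_haploid_vcf(paths$z_calls),
       samples = read_sample_sheet(paths$sheet), truth = NULL)
}

maghreb_outgroup_alleles <- function(vt, samples, sites) {
  mg <- samples$id[samples$population %in%
                     c("EasternMaghreb", "WesternMaghreb")]
  if (length(mg) == 0) return(rep(0L, nrow(sites)))
  idx <- match(paste(sites$chrom, sites$pos),
               paste(vt$sites$chrom, vt$sites$pos))
  dos <- vt_dosage(vt)[, mg, drop = FALSE]
  out <- integer(nrow(sites))
  found <- !is.na(idx)
  alt_cnt <- rowSums(dos[idx[found], , drop = FALSE], na.rm = TRUE)
  n_all <- 2 * rowSums(!is.na(dos[idx[found], , drop = FALSE]))
  out[found] <- as.integer(alt_cnt > n_all / 2)
  out  # sites absent from the table are invariant reference in the Maghreb
}

pi0_pi4_by_class <- function(dat, vt, mask, degmap, focal_chrom, s) {
  classes <- list()
  d0 <- degmap[degmap$degeneracy == "0D", c("chrom", "pos")]
  d4 <- degmap[degmap$degeneracy == "4D", c("chrom", "pos")]
  if (nrow(d0) == 0 || nrow(d4) == 0) return(NULL)
  hap_pi <- function(hm, sites_sub) {
    key <- paste(hm$sites$chrom, hm$sites$pos)
    snp <- nchar(hm$sites$ref) == 1 & nchar(hm$sites$alt) == 1
    cols <- which(snp & key %in% paste(sites_sub$chrom, sites_sub$pos))
    denom <- sum(mask_covers(mask, sites_sub$chrom, sites_sub$pos))
    if (denom == 0) return(NA_real_)
    pi_from_haplotypes(hm$mat[, cols, drop = FALSE], denom)
  }
  rows <- list()
  if (!is.null(dat$w_calls)) {
    rows$neo_w <- tibble(class = "neo_w",
                         pi0 = hap_pi(dat$w_calls, d0),
                         pi4 = hap_pi(dat$w_calls, d4))
    rows$neo_z <- tibble(class = "neo_z",
                         pi0 = hap_pi(dat$z_calls, d0),
                         pi4 = hap_pi(dat$z_calls, d4))
  }
  mg <- s$id[s$population %in% c("EasternMaghreb", "WesternMaghreb")]
  if (length(mg) > 1) {
    ds0 <- diversity_stats(vt, mask, groups = list(maghreb = mg), sites = d0,
                           chrom = focal_chrom)
    ds4 <- diversity_stats(vt, mask, groups = list(maghreb = mg), sites = d4,
                           chrom = focal_chrom)
    rows$maghreb <- tibble(class = "maghreb_homolog",
                           pi0 = ds0$per_group$pi[1], pi4 = ds4$per_group$pi[1])
  }
  out <- bind_rows(rows)
  out$ratio <- out$pi0 / out$pi4
  out
}

build_report <- function(cfg, contrast, pca_foc, pca_aut, ci, wins, plat,
                         diag, treetest, degen, split_est, covp) {
  r <- list(
    seed = cfg$seed,
    detection = list(
      h_female_focal = contrast$mean_female_focal,
      h_male_focal = contrast$mean_male_focal,
      h_autosomal = contrast$mean_autosomal,
      female_male_ratio = contrast$ratio,
      verdict = if (contrast$verdict) "neo-W detected" else "no neo-W",
      wilcoxon_p = contrast$p_value,
      pca_focal_pc1_var = pca_foc$var_explained[1],
      pca_focal_sep_score = pca_foc$sep_score,
      pca_autosome_sep_score = pca_aut$sep_score,
      carrier_ci_lower = ci$lower, carrier_ci_upper = ci$upper),
    plateaus = list(
      n_plateaus = nrow(plat),
      table = as.data.frame(plat[, c("plateau", "start_win", "end_win",
                                     "n_windows", "mean_div", "t_hat",
                                     "start_bp", "end_bp", "cov_w")])),
    phasing = list(n_diagnostic_sites = nrow(diag)),
    windows = list(n_windows = nrow(wins), n_masked = sum(wins$masked)))
  if (!is.null(treetest)) {
    r$tree_test <- list(
      n_variants = treetest$tree$n_total,
      n_consistent = treetest$tree$n_consistent,
      consistency = treetest$tree$consistency,
      n_accepted_splits = sum(treetest$tree$splits$accepted),
      expected_types_single_tree = treetest$n_types_expected_tree,
      possible_types = treetest$n_types_possible,
      tmrca = treetest$polarization$tmrca,
      inconsistent_runs_p = treetest$runs$p_value)
  }
  if (!is.null(degen)) {
    r$degeneration <- list(
      lof_fixed_proportion = if (is.null(degen$lof_overall)) NULL else
        as.list(degen$lof_overall[, c("proportion", "lower", "upper",
                                      "n_lof", "n_genes")]),
      lof_by_plateau = if (is.null(degen$lof_by_plateau)) NULL else
        as.data.frame(degen$lof_by_plateau[, c("plateau", "proportion",
                                               "lower", "upper", "n_lof",
                                               "n_genes")]),
      pi0_pi4 = if (is.null(degen$pi0_pi4)) NULL else
        as.data.frame(degen$pi0_pi4),
      ase_median_fold = if (is.null(degen$ase)) NULL else
        degen$ase$median_fold,
      cov_wilcox_p_young_plateau = degen$cov_wilcox_p_young_plateau)
  }
  if (!is.null(split_est)) {
    r$autosomal_split <- list(dxy = split_est$dxy,
                              pi_within = split_est$pi_within,
                              t_hat = split_est$t_hat)
  }
  r
}

#' @export
print.neosex_report <- function(x, ...) {
  r <- x$report
  cat("== neo-sex chromosome analysis ==\n")
  cat(sprintf("detection: %s (female H = %.4g, male H = %.4g, autosomal H = %.4g)\n",
              r$detection$verdict, r$detection$h_female_focal,
              r$detection$h_male_focal, r$detection$h_autosomal))
  cat(sprintf("carrier frequency 95%% CI: %.2f-%.2f\n",
              r$detection$carrier_ci_lower, r$detection$carrier_ci_upper))
  cat(sprintf("plateaus: %d\n", r$plateaus$n_plateaus))
  print(x$plateaus)
  cat(sprintf("diagnostic sites: %d\n", r$phasing$n_diagnostic_sites))
  if (!is.null(r$tree_test)) {
    cat(sprintf("tree test: %.1f%% of %d variants consistent; TMRCA = %.3g\n",
                100 * r$tree_test$consistency, r$tree_test$n_variants,
                r$tree_test$tmrca))
  }
  if (!is.null(r$degeneration)) {
    if (!is.null(r$degeneration$lof_fixed_proportion)) {
      cat(sprintf("fixed LoF on neo-W: %.1f%% of genes\n",
                  100 * r$degeneration$lof_fixed_proportion$proportion))
    }
    if (!is.null(r$degeneration$ase_median_fold)) {
      cat(sprintf("expression bias: median neo-Z:neo-W fold = %.2f\n",
                  r$degeneration$ase_median_fold))
    }
  }
  if (!is.null(r$autosomal_split)) {
    cat(sprintf("autosomal split time (moments): %.3g generations\n",
                r$autosomal_split$t_hat))
  }
  invisible(x)
}
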