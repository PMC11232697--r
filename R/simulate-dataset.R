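#' Simulate a full synthetic dataset
#'
#' Generates one autosome, a Z chromosome and the fused neo-sex chromosome
#' as block-wise independent genealogies (no recombination within a block,
#' free recombination between blocks), assembles diploid genotypes
#' (Iberian females carry one neo-W and one neo-Z haplotype on the neo-sex
#' chromosome; males carry two neo-Z), injects fixed loss-of-function
#' mutations on the neo-W stem in proportion to plateau age, and emits
#' per-window coverage, haplotype-specific expression counts, phased neo-W /
#' neo-Z haplotype calls (the product of read-backed phasing, which the
#' generator can produce exactly), and a ground-truth record.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give identical outputs.
#' @param out_dir optional directory; when given, all standard-format files
#'   (VCF, BED, GFF3, FASTA, TSV, truth JSON) are written there.
#' @return A list: `variants` ([variant_table()]), `mask`, `genes`, `ref`
#'   (named character), `coverage`, `expression`, `w_calls`, `z_calls`
#'   ([haplotype_matrix()] or `NULL` without fusion), `truth`, `samples`.
#' @export
simulate_dataset <- function(cfg, seed = NULL, out_dir = NULL) {
  validate_sim_config(cfg)
  with_seed_if(seed, sim_dataset_impl(cfg, out_dir))
}

sim_dataset_impl <- function(cfg, out_dir) {
  bl <- as.integer(cfg$block_length)
  bpw <- as.integer(cfg$blocks_per_window)
  wl <- as.integer(cfg$window_length)
  mu <- cfg$mu
  spacing <- as.integer((0.78 * wl) %/% bpw)
  n_win <- c(chrA1 = cfg$n_windows_autosome, chrZ = cfg$n_windows_z,
             chrNeo = sum(cfg$plateau_windows))
  chrom_len <- as.integer(n_win * wl)
  names(chrom_len) <- names(n_win)
  bases <- c("A", "C", "G", "T")

  ref <- lapply(chrom_len, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""))

  # --- gene models on the focal chromosome ----------------------------------
  gene_offset <- as.integer(0.85 * wl)
  plat_of_win <- rep(seq_along(cfg$plateau_windows), cfg$plateau_windows)
  gene_info <- NULL
  genes <- NULL
  if (cfg$n_genes > 0) {
    footprint <- 3L * cfg$gene_codons + 100L
    assert_that(gene_offset + footprint <= wl,
                "window too short for gene footprint")
    alloc <- diff(round(c(0, cumsum(cfg$plateau_windows)) /
                          sum(cfg$plateau_windows) * cfg$n_genes))
    assert_that(all(alloc <= cfg$plateau_windows),
                "more genes than windows in a plateau")
    off <- c(0, cumsum(cfg$plateau_windows))
    gene_win <- unlist(lapply(seq_along(alloc), function(k) {
      if (alloc[k] == 0) return(integer(0))
      off[k] + unique(round(seq(1, cfg$plateau_windows[k],
                                length.out = alloc[k])))
    }))
    gm <- make_gene_models(length(gene_win), "chrNeo",
                           (gene_win - 1L) * wl + gene_offset,
                           codons = cfg$gene_codons)
    refN <- strsplit(ref[["chrNeo"]], "")[[1]]
    refN <- splice_genes_into_ref(refN, gm$genes, gm$cds_seq)
    ref[["chrNeo"]] <- paste(refN, collapse = "")
    genes <- gm$genes
    gene_info <- tibble(gene_id = unique(gm$genes$gene_id),
                        window = gene_win, plateau = plat_of_win[gene_win],
                        start = (gene_win - 1L) * wl + gene_offset,
                        footprint = gm$footprint)
  }

  # --- neo-W clade genealogy -------------------------------------------------
  w_tree <- NULL; w_tree_rescue <- NULL
  if (cfg$fusion) {
    w_tree <- w_tree_from_cpp(
      cpp_sim_tree(sum(cfg$samples$population == "Iberia" &
                         cfg$samples$sex == "female"),
                   cfg$ne_neo_w, cfg$neo_w_tmrca))
    if (length(cfg$rescue_windows) > 0) {
      for (i in 1:25) {
        w_tree_rescue <- w_tree_from_cpp(
          cpp_sim_tree(w_tree$n_tips, cfg$ne_neo_w, cfg$neo_w_tmrca))
        if (!identical(split_keys_of_tree(w_tree_rescue),
                       split_keys_of_tree(w_tree))) break
      }
    }
  }

  # --- per-chromosome simulation --------------------------------------------
  chrom_data <- list()
  chrom_data[["chrA1"]] <- sim_diploid_chrom(cfg, "chrA1", bl, bpw, wl,
                                             spacing, mu, ne_scale = 1,
                                             layout = autosome_layout(cfg))
  chrom_data[["chrZ"]] <- sim_diploid_chrom(cfg, "chrZ", bl, bpw, wl,
                                            spacing, mu, ne_scale = 0.75,
                                            layout = z_layout(cfg))
  if (cfg$fusion) {
    chrom_data[["chrNeo"]] <- sim_focal_chrom(cfg, bl, bpw, wl, spacing, mu,
                                              w_tree, w_tree_rescue,
                                              gene_info, genes, ref)
  } else {
    chrom_data[["chrNeo"]] <- sim_diploid_chrom(
      cfg, "chrNeo", bl, bpw, wl, spacing, mu, ne_scale = 1,
      layout = autosome_layout(cfg), gene_info = gene_info, genes = genes)
  }

  # --- variant table ---------------------------------------------------------
  s <- cfg$samples
  per_chrom <- lapply(names(chrom_data), function(ch) {
    cd <- chrom_data[[ch]]
    n_var <- length(cd$pos)
    if (n_var == 0) return(NULL)
    refc <- substring(ref[[ch]], cd$pos, cd$pos)
    alt <- cd$alt
    need <- is.na(alt)
    if (any(need)) {
      pick <- matrix(bases, 4, sum(need))
      alt[need] <- vapply(which(need), function(i)
        sample(setdiff(bases, refc[i]), 1), character(1))
      refc[need] <- refc[need]
    }
    refout <- ifelse(is.na(cd$ref), refc, cd$ref)
    a1 <- matrix(NA_integer_, n_var, nrow(s))
    a2 <- matrix(NA_integer_, n_var, nrow(s))
    for (j in seq_len(nrow(s))) {
      hp <- cd$sample_haps[[s$id[j]]]
      a1[, j] <- cd$hap[, hp[1]]
      a2[, j] <- cd$hap[, hp[2]]
    }
    list(sites = tibble(chrom = ch, pos = cd$pos, ref = refout, alt = alt),
         a1 = a1, a2 = a2, chrom = ch)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  sites <- bind_rows(lapply(per_chrom, `[[`, "sites"))
  a1 <- do.call(rbind, lapply(per_chrom, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(per_chrom, `[[`, "a2"))
  gq <- matrix(60L, nrow(sites), nrow(s))
  dp <- matrix(as.integer(round(cfg$depth_mean)), nrow(sites), nrow(s))
  vt <- variant_table(sites, a1, a2, gq, dp, s)

  # --- callable mask ---------------------------------------------------------
  mask <- bind_rows(lapply(names(n_win), function(ch) {
    wv <- rep(0:(n_win[[ch]] - 1L), each = bpw)
    bv <- rep(0:(bpw - 1L), n_win[[ch]])
    st <- wv * wl + bv * spacing
    tibble(chrom = ch, start = st, end = st + bl)
  }))
  if (!is.null(genes)) {
    mask <- bind_rows(mask, tibble(chrom = genes$chrom, start = genes$start,
                                   end = genes$end))
  }
  mask <- callable_mask(mask)

  # --- coverage and expression ----------------------------------------------
  covexp <- sim_coverage_expression_impl(cfg, gene_info, n_win, wl)

  # --- phased haplotype calls and truth --------------------------------------
  w_calls <- NULL; z_calls <- NULL
  truth <- list(config = cfg[setdiff(names(cfg), "samples")])
  focal <- chrom_data[["chrNeo"]]
  fsites <- sites[sites$chrom == "chrNeo", , drop = FALSE]
  if (cfg$fusion) {
    lay <- focal$layout
    w_calls <- haplotype_matrix(t(focal$hap[, lay$w_cols, drop = FALSE]),
                                paste0(lay$ib_f, "_W"), fsites)
    zf_cols <- length(lay$w_cols) + seq_along(lay$ib_f)
    z_calls <- haplotype_matrix(t(focal$hap[, zf_cols, drop = FALSE]),
                                paste0(lay$ib_f, "_Z"), fsites)
  }
  ib <- s$population == "Iberia"
  ibf <- which(ib & s$sex == "female")
  ibm <- which(ib & s$sex == "male")
  fa1 <- a1[sites$chrom == "chrNeo", , drop = FALSE]
  fa2 <- a2[sites$chrom == "chrNeo", , drop = FALSE]
  dosf <- fa1 + fa2
  is_snp_f <- nchar(fsites$ref) == 1 & nchar(fsites$alt) == 1
  # genuinely W-linked diagnostic sites: the alternate allele rides on every
  # neo-W haplotype, every female is heterozygous and every male lacks it.
  # (Genotype-level detection can additionally pick up the rare neo-Z
  # variant private to all female neo-Z complements; those confounded sites
  # are not truth.)
  w_linked <- if (cfg$fusion) {
    rowSums(focal$hap[, focal$layout$w_cols, drop = FALSE] == 1) ==
      length(focal$layout$w_cols)
  } else rep(FALSE, nrow(fsites))
  diag_true <- is_snp_f & w_linked &
    rowSums(dosf[, ibf, drop = FALSE] == 1) == length(ibf) &
    rowSums(dosf[, ibm, drop = FALSE] == 0) == length(ibm)
  win_edges <- cumsum(cfg$plateau_windows)
  truth$plateaus <- tibble(
    plateau = seq_along(cfg$plateau_t),
    win_start = c(1L, head(win_edges, -1) + 1L),
    win_end = win_edges,
    start = (c(1L, head(win_edges, -1) + 1L) - 1L) * wl,
    end = win_edges * wl,
    t_split = cfg$plateau_t,
    ne_anc = cfg$ne_anc_plateau,
    mapping_rate = if (cfg$fusion) cfg$mapping_rate else
      rep(1, length(cfg$plateau_t)))
  truth$w_tree <- if (cfg$fusion) w_tree$newick else NULL
  truth$w_tmrca <- if (cfg$fusion) w_tree$tmrca else NULL
  truth$rescue_windows <- cfg$rescue_windows
  truth$diagnostic <- fsites[diag_true, c("chrom", "pos"), drop = FALSE]
  truth$lof <- if (is.null(focal$lof)) {
    tibble(gene_id = character(0), chrom = character(0), pos = integer(0),
           category = character(0), plateau = integer(0))
  } else focal$lof
  truth$genes <- gene_info
  truth$hap <- if (cfg$fusion) focal$hap else NULL
  truth$hap_names <- if (cfg$fusion) focal$layout$hap_names else NULL

  out <- list(variants = vt, mask = mask, genes = genes,
              ref = unlist(ref), coverage = covexp$coverage,
              expression = covexp$expression, w_calls = w_calls,
              z_calls = z_calls, truth = truth, samples = s)
  if (!is.null(out_dir)) write_sim_dataset(out, out_dir)
  out
}

# diploid chromosome (autosome, Z, or unfused focal)
sim_diploid_chrom <- function(cfg, chrom, bl, bpw, wl, spacing, mu, ne_scale,
                              layout, gene_info = NULL, genes = NULL) {
  ev <- three_pop_events(cfg, ne_scale)
  ne <- c(cfg$ne_iberia, cfg$ne_maghreb_east, cfg$ne_maghreb_west) * ne_scale
  n_win <- switch(chrom, chrA1 = cfg$n_windows_autosome,
                  chrZ = cfg$n_windows_z, chrNeo = sum(cfg$plateau_windows))
  n_blocks <- n_win * bpw
  res <- cpp_sim_blocks(n_blocks, bl, mu, layout$tip_pop, layout$tip_time,
                        ne, ev$time, ev$from, ev$to, ev$ne)
  wv <- res$block %/% bpw
  bv <- res$block %% bpw
  pos <- wv * wl + bv * spacing + res$pos + 1L
  hap <- res$carriers
  refv <- rep(NA_character_, length(pos))
  altv <- rep(NA_character_, length(pos))
  lof <- NULL
  if (!is.null(gene_info) && nrow(gene_info) > 0) {
    g <- sim_gene_blocks(cfg, layout, ne, ev, gene_info, mu)
    pos <- c(pos, g$pos)
    hap <- rbind(hap, g$hap)
    refv <- c(refv, rep(NA_character_, length(g$pos)))
    altv <- c(altv, rep(NA_character_, length(g$pos)))
  }
  ord <- order(pos)
  sample_haps <- sample_hap_map(cfg, layout)
  list(pos = pos[ord], hap = hap[ord, , drop = FALSE], ref = refv[ord],
       alt = altv[ord], sample_haps = sample_haps, layout = layout, lof = lof)
}

# gene-footprint blocks simulated under the same demography
sim_gene_blocks <- function(cfg, layout, ne, ev, gene_info, mu) {
  res <- cpp_sim_blocks(nrow(gene_info), gene_info$footprint[1], mu,
                        layout$tip_pop, layout$tip_time, ne,
                        ev$time, ev$from, ev$to, ev$ne)
  list(pos = gene_info$start[res$block + 1L] + res$pos + 1L,
       hap = res$carriers, block = res$block)
}

# fused focal chromosome: per-plateau demography + shared neo-W clade
sim_focal_chrom <- function(cfg, bl, bpw, wl, spacing, mu, w_tree,
                            w_tree_rescue, gene_info, genes, ref) {
  layout <- focal_layout(cfg, w_tree$tmrca)
  n_w <- length(layout$w_cols)
  ne <- c(cfg$ne_neo_z, cfg$ne_maghreb_east, cfg$ne_maghreb_west,
          cfg$ne_neo_w)
  pos <- integer(0)
  hap <- matrix(0L, 0, layout$n_hap)
  plat_of_win <- rep(seq_along(cfg$plateau_windows), cfg$plateau_windows)
  win_offset <- c(0, cumsum(cfg$plateau_windows))
  for (k in seq_along(cfg$plateau_t)) {
    ev <- arrange(tibble(
      time = c(cfg$plateau_t[k], cfg$t_maghreb, cfg$t_split),
      from = c(3L, 2L, 1L), to = c(0L, 1L, 0L),
      ne = c(cfg$ne_anc_plateau[k], NA_real_, NA_real_)), .data$time)
    nb <- cfg$plateau_windows[k] * bpw
    res <- cpp_sim_blocks(nb, bl, mu, layout$tip_pop, layout$tip_time, ne,
                          ev$time, ev$from, ev$to, ev$ne)
    gblock <- res$block + win_offset[k] * bpw
    wv <- gblock %/% bpw
    p <- wv * wl + (gblock %% bpw) * spacing + res$pos + 1L
    h <- expand_focal_carriers(res$carriers, layout)
    # neo-W clade (within-clade) mutations, tree per window
    used <- split(res$pos, factor(res$block, levels = 0:(nb - 1)))
    win_of_block <- (res$block %/% bpw) + win_offset[k] + 1L
    blocks_win <- rep(win_offset[k] + seq_len(cfg$plateau_windows[k]),
                      each = bpw)
    wi <- w_internal_for(cfg, w_tree, w_tree_rescue, blocks_win, bl, mu, used)
    if (length(wi$pos) > 0) {
      gb <- wi$block + win_offset[k] * bpw
      pw <- (gb %/% bpw) * wl + (gb %% bpw) * spacing + wi$pos + 1L
      hz <- matrix(0L, length(wi$pos), layout$n_hap)
      hz[, layout$w_cols] <- wi$hap
      p <- c(p, pw)
      h <- rbind(h, hz)
    }
    pos <- c(pos, p)
    hap <- rbind(hap, h)
  }
  refv <- rep(NA_character_, length(pos))
  altv <- rep(NA_character_, length(pos))
  lof <- NULL
  if (!is.null(gene_info) && nrow(gene_info) > 0) {
    for (k in seq_along(cfg$plateau_t)) {
      gi <- gene_info[gene_info$plateau == k, , drop = FALSE]
      if (nrow(gi) == 0) next
      ev <- arrange(tibble(
        time = c(cfg$plateau_t[k], cfg$t_maghreb, cfg$t_split),
        from = c(3L, 2L, 1L), to = c(0L, 1L, 0L),
        ne = c(cfg$ne_anc_plateau[k], NA_real_, NA_real_)), .data$time)
      g <- sim_gene_blocks(cfg, layout, ne, ev, gi, mu)
      h <- expand_focal_carriers(g$hap, layout)
      used_g <- split(g$pos - gi$start[g$block + 1L] - 1L,
                      factor(g$block, levels = 0:(nrow(gi) - 1)))
      wi <- w_internal_for(cfg, w_tree, w_tree_rescue, gi$window,
                           gi$footprint[1], mu, used_g)
      if (length(wi$pos) > 0) {
        pw <- gi$start[wi$block + 1L] + wi$pos + 1L
        hz <- matrix(0L, length(wi$pos), layout$n_hap)
        hz[, layout$w_cols] <- wi$hap
        g$pos <- c(g$pos, pw)
        h <- rbind(h, hz)
      }
      pos <- c(pos, g$pos)
      hap <- rbind(hap, h)
      refv <- c(refv, rep(NA_character_, length(g$pos)))
      altv <- c(altv, rep(NA_character_, length(g$pos)))
    }
    # loss-of-function load on the neo-W stem
    inj <- inject_lof(genes, ref, cfg$plateau_t[gene_info$plateau],
                      cfg$lof_rate,
                      used_positions = tibble(chrom = "chrNeo", pos = pos))
    if (nrow(inj$variants) > 0) {
      hz <- matrix(0L, nrow(inj$variants), layout$n_hap)
      hz[, layout$w_cols] <- 1L
      pos <- c(pos, inj$variants$pos)
      hap <- rbind(hap, hz)
      refv <- c(refv, inj$variants$ref)
      altv <- c(altv, inj$variants$alt)
      lof <- mutate(inj$truth,
                    plateau = gene_info$plateau[
                      match(.data$gene_id, gene_info$gene_id)])
    }
  }
  ord <- order(pos)
  list(pos = pos[ord], hap = hap[ord, , drop = FALSE], ref = refv[ord],
       alt = altv[ord], sample_haps = sample_hap_map(cfg, layout),
       layout = layout, lof = lof)
}

expand_focal_carriers <- function(carriers, layout) {
  n <- nrow(carriers)
  h <- matrix(0L, n, layout$n_hap)
  if (n == 0) return(h)
  n_w <- length(layout$w_cols)
  n_other <- ncol(carriers) - 1L
  h[, n_w + seq_len(n_other)] <- carriers[, seq_len(n_other), drop = FALSE]
  stem <- carriers[, n_other + 1L] == 1
  h[stem, layout$w_cols] <- 1L
  h
}

# neo-W within-clade mutations, choosing the rescue topology inside
# rescue windows; `wins` gives the (1-based) window of each block
w_internal_for <- function(cfg, w_tree, w_tree_rescue, wins, block_length,
                           mu, used_by_block) {
  if (is.null(w_tree)) return(list(block = integer(0), pos = integer(0),
                                   hap = matrix(0L, 0, 0)))
  in_rescue <- wins %in% cfg$rescue_windows
  out <- list(block = integer(0), pos = integer(0),
              hap = matrix(0L, 0, w_tree$n_tips))
  for (tree_case in list(list(tree = w_tree, sel = !in_rescue),
                         list(tree = w_tree_rescue, sel = in_rescue))) {
    if (is.null(tree_case$tree) || !any(tree_case$sel)) next
    idx <- which(tree_case$sel)
    wi <- w_internal_mutations(tree_case$tree, length(idx), block_length, mu,
                               used_by_block[idx])
    if (length(wi$pos) > 0) {
      out$block <- c(out$block, idx[wi$block + 1L] - 1L)
      out$pos <- c(out$pos, wi$pos)
      out$hap <- rbind(out$hap, wi$hap)
    }
  }
  out
}

sample_hap_map <- function(cfg, layout) {
  s <- cfg$samples
  nm <- layout$hap_names
  out <- list()
  for (i in seq_len(nrow(s))) {
    id <- s$id[i]
    cand <- list(c(paste0(id, "_W"), paste0(id, "_Z")),
                 c(paste0(id, "_Za"), paste0(id, "_Zb")),
                 c(paste0(id, "_a"), paste0(id, "_b")),
                 c(paste0(id, "_za"), paste0(id, "_zb")),
                 c(paste0(id, "_z"), paste0(id, "_z")))
    for (cc in cand) {
      if (all(cc %in% nm)) {
        out[[id]] <- match(cc, nm)
        break
      }
    }
    assert_that(!is.null(out[[id]]), "no haplotypes found for sample %s", id)
  }
  out
}

split_keys_of_tree <- function(w) {
  keys <- vapply(w$branches$tips, function(t)
    canonical_split_key(t, w$n_tips), character(1))
  sort(unique(keys[!is.na(keys)]))
}

# ---- coverage and expression ----------------------------------------------

sim_coverage_expression_impl <- function(cfg, gene_info, n_win, wl) {
  s <- cfg$samples
  plat_of_win <- rep(seq_along(cfg$plateau_windows), cfg$plateau_windows)
  shape <- 1 / cfg$depth_cv^2
  cov <- bind_rows(lapply(names(n_win), function(ch) {
    nw <- n_win[[ch]]
    d <- tidyr::expand_grid(window = seq_len(nw), sample = s$id)
    d$chrom <- ch
    d$start <- (d$window - 1L) * wl
    d$end <- d$window * wl
    sex <- s$sex[match(d$sample, s$id)]
    popn <- s$population[match(d$sample, s$id)]
    ratio <- rep(1, nrow(d))
    if (ch == "chrZ") ratio[sex == "female"] <- 0.5
    if (ch == "chrNeo" && cfg$fusion) {
      m <- cfg$mapping_rate[plat_of_win[d$window]]
      fused <- sex == "female" & popn == "Iberia"
      ratio[fused] <- (1 + m[fused]) / 2
    }
    d$depth <- rgamma(nrow(d), shape = shape,
                      rate = shape / (cfg$depth_mean * ratio))
    d[, c("chrom", "start", "end", "window", "sample", "depth")]
  }))
  expression <- NULL
  if (!is.null(gene_info) && nrow(gene_info) > 0) {
    n <- nrow(gene_info)
    total <- rnbinom(n, mu = cfg$expr_mean, size = cfg$expr_size)
    fold <- rlnorm(n, log(cfg$expr_fold), cfg$expr_sdlog)
    if (!cfg$fusion) fold <- rep(1, n)
    w_count <- rbinom(n, total, 1 / (1 + fold))
    expression <- tibble(gene_id = gene_info$gene_id,
                         plateau = gene_info$plateau,
                         z_count = total - w_count, w_count = w_count)
  }
  list(coverage = cov, expression = expression)
}

#' Simulate coverage tables and allele-specific expression counts
#'
#' Stand-alone access to the coverage/expression model: male neo-sex to
#' autosome depth ratio is 1, the female ratio is `(1 + m) / 2` for a
#' plateau with neo-W mapping rate `m`, and per-gene neo-Z : neo-W read
#' counts follow a log-normal fold distribution with configurable median.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A list with `coverage` (per-window per-sample depth) and
#'   `expression` (per-gene haplotype counts).
#' @export
simulate_coverage_expression <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  wl <- as.integer(cfg$window_length)
  n_win <- c(chrA1 = cfg$n_windows_autosome, chrZ = cfg$n_windows_z,
             chrNeo = sum(cfg$plateau_windows))
  plat_of_win <- rep(seq_along(cfg$plateau_windows), cfg$plateau_windows)
  gene_info <- NULL
  if (cfg$n_genes > 0) {
    win <- round(seq(1, sum(cfg$plateau_windows), length.out = cfg$n_genes))
    gene_info <- tibble(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                        window = win, plateau = plat_of_win[win],
                        start = NA_integer_, footprint = NA_integer_)
  }
  with_seed_if(seed, sim_coverage_expression_impl(cfg, gene_info, n_win, wl))
}

#' Simulate a windowed divergence landscape
#'
#' Windowed heterozygosity values for a three-plateau chromosome: the
#' per-window count of heterozygous sites is Poisson with mean
#' `level * callable sites per window`.
#'
#' @param cfg a [sim_config()].
#' @param levels per-plateau expected H; default the analytic expectation
#'   `2 mu (T_k + 2 Ne_anc_k)` from the configured demography.
#' @param seed optional integer seed.
#' @return Tibble (`window`, `plateau`, `h`) with attribute `boundaries`
#'   (true inter-window boundary indices: a change after window b).
#' @export
simulate_h_landscape <- function(cfg, levels = NULL, seed = NULL) {
  if (is.null(levels)) {
    levels <- 2 * cfg$mu * (cfg$plateau_t + 2 * cfg$ne_anc_plateau)
  }
  callable <- cfg$blocks_per_window * cfg$block_length
  n <- sum(cfg$plateau_windows)
  lev <- rep(levels, cfg$plateau_windows)
  with_seed_if(seed, {
    h <- rpois(n, lev * callable) / callable
    out <- tibble(window = seq_len(n),
                  plateau = rep(seq_along(levels), cfg$plateau_windows),
                  h = h)
    attr(out, "boundaries") <- head(cumsum(cfg$plateau_windows), -1)
    out
  })
}

#' Simulate neutral single-population blocks
#'
#' Independent coalescent genealogies with mutations for `n_hap` haplotypes
#' in one panmictic population: the basic neutral-null generator used for
#' spectrum and diversity expectations.
#'
#' @param n_hap number of haplotypes.
#' @param ne population size (diploid scale: a pair coalesces at rate
#'   `1 / (2 ne)`).
#' @param mu mutation rate per site per generation.
#' @param block_length sites per block.
#' @param n_blocks number of blocks.
#' @param seed optional integer seed.
#' @return A list: `block`, `pos`, `carriers` (mutations x haplotypes).
#' @export
simulate_neutral_blocks <- function(n_hap, ne, mu, block_length, n_blocks,
                                    seed = NULL) {
  with_seed_if(seed, {
    cpp_sim_blocks(n_blocks, block_length, mu, rep(0L, n_hap),
                   rep(0, n_hap), ne, numeric(0), integer(0), integer(0),
                   numeric(0))
  })
}

#' Simulate strict-divergence (DIV) two-population blocks
#'
#' Two populations of haploid sample sizes `n1_hap` and `n2_hap` split from
#' an ancestral population `t_split` generations ago, with no post-split
#' gene flow. Used for parameter-recovery experiments with
#' [moments_split_time()].
#'
#' @param n1_hap,n2_hap haplotypes sampled per population.
#' @param ne1,ne2,ne_anc population sizes.
#' @param t_split split time in generations.
#' @param mu mutation rate per site per generation.
#' @param block_length,n_blocks block geometry.
#' @param seed optional integer seed.
#' @return A list: `block`, `pos`, `carriers` (columns: population-1
#'   haplotypes then population-2 haplotypes), `n1_hap`, `n2_hap`.
#' @export
simulate_div_blocks <- function(n1_hap, n2_hap, ne1, ne2, ne_anc, t_split,
                                mu, block_length = 64, n_blocks = 1000,
                                seed = NULL) {
  with_seed_if(seed, {
    res <- cpp_sim_blocks(n_blocks, block_length, mu,
                          c(rep(0L, n1_hap), rep(1L, n2_hap)),
                          rep(0, n1_hap + n2_hap), c(ne1, ne2),
                          t_split, 1L, 0L, ne_anc)
    res$n1_hap <- n1_hap
    res$n2_hap <- n2_hap
    res
  })
}

# ---- writers ---------------------------------------------------------------

write_sim_dataset <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(out$variants, file.path(dir, "variants.vcf"))
  write_bed(out$mask, file.path(dir, "callable.bed"))
  if (!is.null(out$genes)) write_gff3(out$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(out$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(out$coverage, file.path(dir, "coverage.tsv"),
                   progress = FALSE)
  if (!is.null(out$expression)) {
    readr::write_tsv(out$expression, file.path(dir, "expression.tsv"),
                     progress = FALSE)
  }
  if (!is.null(out$w_calls)) {
    write_haploid_vcf(out$w_calls, file.path(dir, "neo_w_calls.vcf"))
    write_haploid_vcf(out$z_calls, file.path(dir, "neo_z_calls.vcf"))
  }
  fa <- character(0)
  for (ch in names(out$ref)) {
    fa <- c(fa, paste0(">", ch),
            substring(out$ref[[ch]], seq(1, nchar(out$ref[[ch]]), 80),
                      pmin(seq(1, nchar(out$ref[[ch]]), 80) + 79,
                           nchar(out$ref[[ch]]))))
  }
  writeLines(fa, file.path(dir, "reference.fa"))
  tr <- out$truth
  tr$hap <- NULL; tr$hap_names <- NULL
  tr$config$samples <- NULL
  write_json_stable(tr, file.path(dir, "truth.json"))
  invisible(dir)
}
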