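#' Simulation configuration
#'
#' Parameters of the block-wise coalescent generator emulating a Z-autosome
#' fusion system: an Iberian population carrying a non-recombining neo-W
#' whose divergence from the neo-Z is structured into three plateaus (rare
#' recombination-rescue events), plus Eastern/Western Maghreb populations
#' carrying the unfused homolog. Defaults follow the study conditions:
#' mutation rate 2.9e-9 per site per generation, a 1.5e6-generation
#' Iberia/Maghreb split, plateau split times 1.4e6 / 8.6e5 / 5.0e5
#' generations, derived diversities matching the populations' observed
#' 4D diversity, 64-bp non-recombining blocks, and 7 female + 3 male
#' Iberian, 4 Eastern and 1 Western Maghreb samples.
#'
#' @param ... overrides for any default field; see the method vignette for
#'   the meaning and provenance of each parameter.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    mu = 2.9e-9,
    generation_time = 1,
    ne_iberia = 6.47e5,        # 4*Ne*mu ~ 0.0075
    ne_maghreb_east = 1.724e6, # 4*Ne*mu ~ 0.020
    ne_maghreb_west = 1.12e6,  # 4*Ne*mu ~ 0.013
    ne_anc = 1.1e6,
    t_split = 1.5e6,
    t_maghreb = 7.5e5,
    ne_neo_z = 2.6e5,
    ne_neo_w = 2.1e4,
    plateau_t = c(1.4e6, 8.6e5, 5.0e5),
    ne_anc_plateau = c(1.3e6, 9.8e5, 5.7e5),
    plateau_windows = c(210L, 30L, 20L),
    neo_w_tmrca = 5e4,
    mapping_rate = c(0.8, 0.8, 1.0),
    me = 0,                    # reserved; strict-divergence history
    block_length = 64L,
    blocks_per_window = 100L,
    window_length = 51200L,
    n_windows_autosome = 60L,
    n_windows_z = 30L,
    fusion = TRUE,
    n_genes = 120L,
    gene_codons = 100L,
    lof_rate = 2.25e-7,
    depth_mean = 20,
    depth_cv = 0.05,
    expr_mean = 200,
    expr_size = 8,
    expr_fold = 1.5,
    expr_sdlog = 0.4,
    rescue_windows = integer(0),
    samples = default_samples())
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  assert_that(length(unknown) == 0, "unknown sim_config field(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_samples <- function() {
  tibble(
    id = c(paste0("IB_F", 1:7), paste0("IB_M", 1:3),
           "EM_F1", "EM_F2", "EM_M1", "EM_M2", "WM_F1"),
    sex = c(rep("female", 7), rep("male", 3),
            "female", "female", "male", "male", "female"),
    population = c(rep("Iberia", 10), rep("EasternMaghreb", 4),
                   "WesternMaghreb"))
}

validate_sim_config <- function(cfg) {
  pos <- c("mu", "ne_iberia", "ne_maghreb_east", "ne_maghreb_west", "ne_anc",
           "t_split", "t_maghreb", "ne_neo_z", "ne_neo_w", "neo_w_tmrca",
           "depth_mean", "expr_mean", "expr_fold")
  for (f in pos) assert_that(cfg[[f]] > 0, "%s must be positive", f)
  assert_that(all(cfg$plateau_t > 0) && !is.unsorted(rev(cfg$plateau_t)),
              "plateau_t must be positive and non-increasing")
  assert_that(length(cfg$plateau_t) == length(cfg$plateau_windows) &&
                length(cfg$plateau_t) == length(cfg$ne_anc_plateau) &&
                length(cfg$plateau_t) == length(cfg$mapping_rate),
              "per-plateau fields must have equal length")
  assert_that(cfg$window_length %% cfg$block_length == 0,
              "block_length must divide window_length")
  assert_that(cfg$blocks_per_window * (cfg$block_length + 1) <
                0.8 * cfg$window_length,
              "too many blocks per window for the window length")
  assert_that(all(cfg$mapping_rate >= 0 & cfg$mapping_rate <= 1),
              "mapping_rate must be in [0, 1]")
  assert_that(!cfg$fusion || cfg$neo_w_tmrca < min(cfg$plateau_t),
              "neo_w_tmrca must predate the youngest plateau split")
  assert_that(cfg$lof_rate >= 0, "lof_rate must be non-negative")
  invisible(cfg)
}

# ---- haplotype layout -------------------------------------------------------

# Iberian samples first in cfg$samples by convention
iberia_ids <- function(cfg) cfg$samples$id[cfg$samples$population == "Iberia"]

# tip configuration for the focal (fused) chromosome:
# pops 0 = Iberian neo-Z, 1 = EM, 2 = WM, 3 = neo-W stem
focal_layout <- function(cfg, w_mrca) {
  s <- cfg$samples
  ib_f <- s$id[s$population == "Iberia" & s$sex == "female"]
  ib_m <- s$id[s$population == "Iberia" & s$sex == "male"]
  em <- s$id[s$population == "EasternMaghreb"]
  wm <- s$id[s$population == "WesternMaghreb"]
  n_ibz <- length(ib_f) + 2 * length(ib_m)
  tip_pop <- c(rep(0L, n_ibz), rep(1L, 2 * length(em)),
               rep(2L, 2 * length(wm)), 3L)
  tip_time <- c(rep(0, length(tip_pop) - 1), w_mrca)
  hap_names <- c(paste0(ib_f, "_W"), paste0(ib_f, "_Z"),
                 paste0(rep(ib_m, each = 2), c("_Za", "_Zb")),
                 paste0(rep(c(em, wm), each = 2), c("_a", "_b")))
  # cpp tip index (1-based) -> columns of the expanded haplotype matrix
  n_w <- length(ib_f)
  expand <- c(as.list(n_w + seq_len(n_ibz)),
              as.list(n_w + n_ibz + seq_len(2 * (length(em) + length(wm)))),
              list(seq_len(n_w)))  # stem carries the whole neo-W clade
  list(tip_pop = tip_pop, tip_time = tip_time, hap_names = hap_names,
       expand = expand, n_hap = n_w + length(tip_pop) - 1,
       w_cols = seq_len(n_w), ib_f = ib_f, ib_m = ib_m, em = em, wm = wm)
}

# diploid layout for autosomes (and the focal chromosome without fusion)
autosome_layout <- function(cfg) {
  s <- cfg$samples
  hap_names <- paste0(rep(s$id, each = 2), c("_a", "_b"))
  popn <- c(Iberia = 0L, EasternMaghreb = 1L, WesternMaghreb = 2L)
  tip_pop <- rep(popn[s$population], each = 2)
  list(tip_pop = unname(tip_pop), tip_time = rep(0, length(tip_pop)),
       hap_names = hap_names, expand = as.list(seq_along(tip_pop)),
       n_hap = length(tip_pop))
}

# Z chromosome: females carry one haplotype, males two
z_layout <- function(cfg) {
  s <- cfg$samples
  nh <- ifelse(s$sex == "female", 1L, 2L)
  hap_names <- unlist(purrr::map2(s$id, nh, function(id, k) {
    if (k == 1) paste0(id, "_z") else paste0(id, c("_za", "_zb"))
  }))
  popn <- c(Iberia = 0L, EasternMaghreb = 1L, WesternMaghreb = 2L)
  tip_pop <- rep(popn[s$population], times = nh)
  list(tip_pop = unname(tip_pop), tip_time = rep(0, length(tip_pop)),
       hap_names = hap_names, expand = as.list(seq_along(tip_pop)),
       n_hap = length(tip_pop))
}

three_pop_events <- function(cfg, ne_scale = 1) {
  ev <- tibble(
    time = c(cfg$t_maghreb, cfg$t_split),
    from = c(2L, 1L), to = c(1L, 0L),
    ne = c(NA_real_, cfg$ne_anc * ne_scale))
  arrange(ev, .data$time)
}

# ---- neo-W genealogy --------------------------------------------------------

#' Simulate the neo-W clade genealogy
#'
#' Coalescent among the female-carried neo-W haplotypes under size
#' `ne_neo_w`, truncated at `neo_w_tmrca`: lineages still uncoalesced at the
#' cap are joined in a single polytomy (the sweep that fixed the last
#' recombinant neo-W bounds the clade's TMRCA).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A list: `parent`/`time` vectors (tips first), `tmrca`,
#'   `branches` (tibble with `mask` list-column of tip indices and `length`),
#'   `newick`.
#' @export
simulate_w_genealogy <- function(cfg, seed = NULL) {
  n_w <- sum(cfg$samples$population == "Iberia" & cfg$samples$sex == "female")
  with_seed_if(seed, {
    tr <- cpp_sim_tree(n_w, cfg$ne_neo_w, cfg$neo_w_tmrca)
    w_tree_from_cpp(tr)
  })
}

w_tree_from_cpp <- function(tr) {
  parent <- tr$parent + 1L  # 1-based; root has parent 0
  time <- tr$time
  n <- tr$n_tips
  n_nodes <- length(parent)
  tipsets <- vector("list", n_nodes)
  for (i in seq_len(n)) tipsets[[i]] <- i
  for (i in seq_len(n_nodes)) {
    p <- parent[i]
    if (p > 0) tipsets[[p]] <- sort(unique(c(tipsets[[p]], tipsets[[i]])))
  }
  # propagate in time order (children are created before parents)
  branches <- tibble(
    node = seq_len(n_nodes),
    length = ifelse(parent > 0, time[pmax(parent, 1)] - time, NA_real_))
  branches$tips <- tipsets
  branches <- branches[parent > 0, , drop = FALSE]
  list(parent = parent, time = time, n_tips = n,
       tmrca = max(time), branches = branches,
       newick = newick_from_parent(parent, time, n))
}

newick_from_parent <- function(parent, time, n_tips) {
  children <- split(seq_along(parent), parent)
  children[["0"]] <- NULL
  lab <- function(i) {
    if (i <= n_tips) return(sprintf("W%d", i))
    kids <- children[[as.character(i)]]
    paste0("(", paste(vapply(kids, function(k) {
      paste0(lab(k), ":", format(time[i] - time[k], scientific = FALSE))
    }, character(1)), collapse = ","), ")")
  }
  root <- which(parent == 0)
  paste0(lab(root), ";")
}

#' Simulate neo-sex genealogies and mutations for one plateau
#'
#' Per-block genealogies over the neo-W clade plus the Iberian neo-Z
#' haplotypes: the neo-W lineages coalesce among themselves by
#' `neo_w_tmrca`, their ancestral (stem) lineage joins the neo-Z population
#' at the plateau's split time, and the merged population takes the
#' plateau's ancestral size into the deep past. Mutations are dropped at
#' rate `mu` per site.
#'
#' @param cfg a [sim_config()].
#' @param plateau_index which plateau (1-based).
#' @param n_blocks number of independent blocks.
#' @param seed optional integer seed.
#' @return A list: `w_tree` (see [simulate_w_genealogy()]), `haplotypes`
#'   (mutations x haplotypes 0/1 matrix, neo-W tips first), `block`, `pos`,
#'   `hap_names`.
#' @export
simulate_neo_sex_genealogy <- function(cfg, plateau_index, n_blocks = 1,
                                       seed = NULL) {
  assert_that(plateau_index >= 1 && plateau_index <= length(cfg$plateau_t),
              "invalid plateau index")
  with_seed_if(seed, {
    w <- simulate_w_genealogy(cfg)
    s <- cfg$samples
    ib_f <- sum(s$population == "Iberia" & s$sex == "female")
    ib_m <- sum(s$population == "Iberia" & s$sex == "male")
    n_z <- ib_f + 2 * ib_m
    tip_pop <- c(rep(0L, n_z), 1L)
    tip_time <- c(rep(0, n_z), w$tmrca)
    res <- cpp_sim_blocks(
      n_blocks, cfg$block_length, cfg$mu, tip_pop, tip_time,
      c(cfg$ne_neo_z, cfg$ne_neo_w),
      cfg$plateau_t[plateau_index], 1L, 0L,
      cfg$ne_anc_plateau[plateau_index])
    # expand the stem column onto the neo-W clade; add within-clade mutations
    hap <- matrix(0L, length(res$block), ib_f + n_z)
    if (length(res$block) > 0) {
      hap[, ib_f + seq_len(n_z)] <- res$carriers[, seq_len(n_z), drop = FALSE]
      stem <- res$carriers[, n_z + 1] == 1
      hap[stem, seq_len(ib_f)] <- 1L
    }
    wi <- w_internal_mutations(w, n_blocks, cfg$block_length, cfg$mu,
                               split(res$pos, factor(res$block,
                                                    levels = 0:(n_blocks - 1))))
    if (nrow(wi$hap) > 0) {
      wz <- matrix(0L, nrow(wi$hap), n_z)
      hap <- rbind(hap, cbind(wi$hap, wz))
      res$block <- c(res$block, wi$block)
      res$pos <- c(res$pos, wi$pos)
    }
    hap_names <- c(paste0("W", seq_len(ib_f)), paste0("Z", seq_len(n_z)))
    ord <- order(res$block, res$pos)
    list(w_tree = w, haplotypes = hap[ord, , drop = FALSE],
         block = res$block[ord], pos = res$pos[ord], hap_names = hap_names)
  })
}

# mutations on the (chromosome-wide) neo-W clade genealogy, per block;
# used_by_block: list of positions already taken in each block
w_internal_mutations <- function(w, n_blocks, block_length, mu,
                                 used_by_block = NULL) {
  br <- w$branches
  n_w <- w$n_tips
  out_block <- integer(0); out_pos <- integer(0)
  out_hap <- matrix(0L, 0, n_w)
  for (j in seq_len(nrow(br))) {
    cnt <- rpois(n_blocks, mu * block_length * br$length[j])
    hit <- which(cnt > 0)
    if (length(hit) == 0) next
    tips <- br$tips[[j]]
    tips <- tips[tips <= n_w]
    if (length(tips) == 0 || length(tips) == n_w) next
    for (b in hit) {
      for (m in seq_len(cnt[b])) {
        used <- c(used_by_block[[b]], out_pos[out_block == (b - 1L)])
        free <- setdiff(0:(block_length - 1L), used)
        if (length(free) == 0) next
        p <- if (length(free) == 1) free else sample(free, 1)
        row <- integer(n_w); row[tips] <- 1L
        out_block <- c(out_block, b - 1L)
        out_pos <- c(out_pos, p)
        out_hap <- rbind(out_hap, row)
      }
    }
  }
  list(block = out_block, pos = out_pos, hap = out_hap)
}

# ---- gene models ------------------------------------------------------------

#' Generate synthetic gene models and reference CDS sequences
#'
#' Each gene has two CDS exons separated by a short intron; the reference
#' CDS starts with ATG, ends with TAA, and contains only sense codons.
#'
#' @param n number of genes.
#' @param chrom chromosome name.
#' @param starts genomic start (0-based) of each gene footprint.
#' @param codons codons per CDS (including start and stop).
#' @param intron_length intron length in bp.
#' @return A list: `genes` (gene-model tibble), `cds_seq` (named character,
#'   spliced CDS per gene), `footprint` (per-gene total span in bp),
#'   `strand` per gene.
#' @export
make_gene_models <- function(n, chrom, starts, codons = 100L,
                             intron_length = 100L) {
  assert_that(codons >= 4, "need at least 4 codons")
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[
                     Biostrings::GENETIC_CODE == "*"])
  cds_len <- 3L * codons
  exon1 <- (cds_len %/% 2L) - (cds_len %/% 2L) %% 3L  # exon boundary in frame
  exon2 <- cds_len - exon1
  strand <- rep(c("+", "-"), length.out = n)
  gid <- sprintf("g%03d", seq_len(n))
  cds_seq <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(sample(sense, codons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
  }, character(1))
  names(cds_seq) <- gid
  genes <- bind_rows(lapply(seq_len(n), function(i) {
    s0 <- starts[i]
    tibble(gene_id = gid[i], chrom = chrom, strand = strand[i],
           start = c(s0, s0 + exon1 + intron_length),
           end = c(s0 + exon1, s0 + exon1 + intron_length + exon2),
           phase = c(0L, 0L))
  }))
  list(genes = genes, cds_seq = cds_seq,
       footprint = cds_len + intron_length, strand = setNames(strand, gid))
}

# write gene CDS (in genomic orientation) into a reference character vector
splice_genes_into_ref <- function(refchars, genes, cds_seq) {
  for (gid in unique(genes$gene_id)) {
    d <- genes[genes$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    seq <- strsplit(cds_seq[[gid]], "")[[1]]
    if (d$strand[1] == "-") seq <- rev_comp_chars(rev(seq))
    off <- 0L
    for (i in seq_len(nrow(d))) {
      w <- d$end[i] - d$start[i]
      refchars[(d$start[i] + 1L):d$end[i]] <- seq[(off + 1L):(off + w)]
      off <- off + w
    }
  }
  refchars
}

# CDS layout: translation-order genomic positions and bases per gene
cds_layout <- function(ref, genes) {
  ref <- ref_as_character(ref)
  out <- list()
  for (gid in unique(genes$gene_id)) {
    d <- genes[genes$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(d)),
                          function(i) seq(d$start[i] + 1L, d$end[i])))
    seq <- extract_cds_chars(ref[[d$chrom[1]]], d)
    if (d$strand[1] == "-") {
      gpos <- rev(gpos)
      seq <- rev_comp_chars(rev(seq))
    }
    out[[gid]] <- list(gene_id = gid, chrom = d$chrom[1],
                       strand = d$strand[1], gpos = gpos, seq = seq)
  }
  out
}

# ---- loss-of-function injection --------------------------------------------

#' Inject fixed loss-of-function mutations onto the neo-W stem
#'
#' Each gene acquires a loss-of-function mutation (premature stop,
#' 1-bp frameshift, start-loss or stop-loss, drawn uniformly) with
#' probability `1 - exp(-lof_rate * age)`, where `age` is the plateau's
#' neo-W/neo-Z split time. The mutation is placed on the neo-W stem branch,
#' i.e. carried by every neo-W haplotype.
#'
#' @param genes gene-model tibble.
#' @param ref reference sequences (named character or DNAStringSet).
#' @param age per-gene plateau age in generations (recycled if length 1).
#' @param lof_rate per-gene per-generation loss-of-function fixation
#'   intensity.
#' @param seed optional integer seed.
#' @param used_positions optional tibble (`chrom`, `pos`) of positions
#'   already occupied by other variants.
#' @return A list: `variants` (tibble `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `category`) and `truth` (same, the injected ground truth).
#'   Genes with CDS < 6 bp are skipped with a warning.
#' @export
inject_lof <- function(genes, ref, age, lof_rate, seed = NULL,
                       used_positions = NULL) {
  ref <- ref_as_character(ref)
  gids <- unique(genes$gene_id)
  age <- rep_len(age, length(gids))
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  layouts <- cds_layout(ref, genes)
  used <- if (is.null(used_positions)) {
    character(0)
  } else {
    paste(used_positions$chrom, used_positions$pos)
  }
  with_seed_if(seed, {
    rows <- list()
    for (i in seq_along(gids)) {
      gid <- gids[i]
      lay <- layouts[[gid]]
      if (length(lay$seq) < 6) {
        warnf("gene %s: CDS shorter than 6 bp, skipped", gid)
        next
      }
      if (length(lay$seq) %% 3 != 0) next
      if (runif(1) >= 1 - exp(-lof_rate * age[i])) next
      cat_pick <- sample(c("premature_stop", "frameshift", "stop_loss",
                           "start_loss"), 1)
      v <- lof_variant(lay, cat_pick, ref, stops, used)
      if (is.null(v)) {  # no usable site for that category
        v <- lof_variant(lay, "frameshift", ref, stops, used)
      }
      if (is.null(v)) next
      used <- c(used, paste(v$chrom, v$pos))
      rows[[length(rows) + 1]] <- v
    }
    variants <- bind_rows(rows)
    if (nrow(variants) == 0) {
      variants <- tibble(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         gene_id = character(0), category = character(0))
    }
    list(variants = variants, truth = variants)
  })
}

# pick the genomic variant realizing one loss-of-function category
lof_variant <- function(lay, category, ref, stops, used) {
  n_cod <- length(lay$seq) / 3
  minus <- lay$strand == "-"
  to_genomic <- function(cds_i, base) {
    g <- lay$gpos[cds_i]
    list(pos = g, ref = if (minus) rev_comp_chars(lay$seq[cds_i]) else
      lay$seq[cds_i],
      alt = if (minus) rev_comp_chars(base) else base)
  }
  emit_snp <- function(cds_i, base) {
    v <- to_genomic(cds_i, base)
    if (paste(lay$chrom, v$pos) %in% used) return(NULL)
    tibble(chrom = lay$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
           gene_id = lay$gene_id, category = category)
  }
  bases <- c("A", "C", "G", "T")
  if (category == "premature_stop") {
    cands <- list()
    for (ci in 2:(n_cod - 1)) {
      cod <- lay$seq[(3 * ci - 2):(3 * ci)]
      for (p in 1:3) {
        for (b in setdiff(bases, cod[p])) {
          alt <- cod; alt[p] <- b
          if (paste(alt, collapse = "") %in% stops) {
            cands[[length(cands) + 1]] <- c(3 * (ci - 1) + p, b)
          }
        }
      }
    }
    if (length(cands) == 0) return(NULL)
    for (k in sample(seq_along(cands))) {
      v <- emit_snp(as.integer(cands[[k]][1]), cands[[k]][2])
      if (!is.null(v)) return(v)
    }
    return(NULL)
  }
  if (category == "start_loss") {
    p <- sample(1:3, 1)
    b <- sample(setdiff(bases, lay$seq[p]), 1)
    return(emit_snp(p, b))
  }
  if (category == "stop_loss") {
    idx <- (3 * n_cod - 2):(3 * n_cod)
    cands <- list()
    for (p in 1:3) {
      for (b in setdiff(bases, lay$seq[idx[p]])) {
        alt <- lay$seq[idx]; alt[p - 0] <- b
        alt[p] <- b
        if (!(paste(alt, collapse = "") %in% stops)) {
          cands[[length(cands) + 1]] <- c(idx[p], b)
        }
      }
    }
    if (length(cands) == 0) return(NULL)
    for (k in sample(seq_along(cands))) {
      v <- emit_snp(as.integer(cands[[k]][1]), cands[[k]][2])
      if (!is.null(v)) return(v)
    }
    return(NULL)
  }
  if (category == "frameshift") {
    # 1-bp indel strictly inside a CDS codon away from start/stop
    ok_idx <- setdiff(seq(4, 3 * n_cod - 3), integer(0))
    for (tries in 1:50) {
      ci <- sample(ok_idx, 1)
      g <- lay$gpos[ci]
      # the genomically-next base must also be CDS so the affected span
      # stays inside one segment (classifier excludes boundary-spanners)
      g2 <- g + 1L
      if (!(g2 %in% lay$gpos)) next
      if (paste(lay$chrom, g) %in% used) next
      refc <- ref_char_at(ref, lay$chrom, g)
      if (runif(1) < 0.5) {
        ref2 <- ref_char_at(ref, lay$chrom, g2)
        return(tibble(chrom = lay$chrom, pos = g, ref = paste0(refc, ref2),
                      alt = refc, gene_id = lay$gene_id,
                      category = category))
      }
      ins <- sample(bases, 1)
      return(tibble(chrom = lay$chrom, pos = g, ref = refc,
                    alt = paste0(refc, ins), gene_id = lay$gene_id,
                    category = category))
    }
    return(NULL)
  }
  NULL
}

ref_char_at <- function(ref, chrom, pos) {
  substr(ref[[chrom]], pos, pos)
}
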