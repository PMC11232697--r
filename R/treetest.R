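#' Canonical folded bipartition key
#'
#' The canonical form of an unordered bipartition is the smaller side; at a
#' size tie (`i = n/2`) the side excluding the first label is used. Keys are
#' comma-separated sorted tip indices.
#'
#' @param side integer tip indices on one side.
#' @param n total number of tips.
#' @param tie_idx tip index used to break size ties (default 1, the
#'   lexicographically-first label).
#' @return Character key, or `NA` for a monomorphic pattern.
#' @export
canonical_split_key <- function(side, n, tie_idx = 1L) {
  side <- sort(unique(side))
  k <- length(side)
  if (k == 0 || k == n) return(NA_character_)
  if (k > n - k || (2 * k == n && tie_idx %in% side)) {
    side <- setdiff(seq_len(n), side)
  }
  paste(side, collapse = ",")
}

split_from_key <- function(key) as.integer(strsplit(key, ",")[[1]])

#' Folded variant-type spectrum of a haplotype alignment
#'
#' Maps every segregating bi-allelic site to its canonical folded
#' bipartition and counts sites per type. Monomorphic sites are excluded;
#' sites with missing calls are dropped with a warning.
#'
#' @param hm a [haplotype_matrix()] (n >= 2 haplotypes).
#' @return A tibble of class `variant_spectrum`: `key`, `size`, `count`,
#'   `positions` (list of site positions); attributes `n`, `labels`,
#'   `total`.
#' @export
folded_spectrum <- function(hm) {
  n <- nrow(hm$mat)
  assert_that(n >= 2, "need at least two haplotypes")
  tie_idx <- order(hm$labels)[1]
  miss <- colSums(is.na(hm$mat)) > 0
  if (any(miss)) warnf("%d site(s) with missing calls dropped", sum(miss))
  m <- hm$mat[, !miss, drop = FALSE]
  pos <- hm$sites$pos[!miss]
  keys <- vapply(seq_len(ncol(m)), function(j)
    canonical_split_key(which(m[, j] == 1), n, tie_idx), character(1))
  seg <- !is.na(keys)
  keys <- keys[seg]; pos <- pos[seg]
  out <- tibble(key = keys, pos = pos) |>
    group_by(.data$key) |>
    summarise(count = n(), positions = list(sort(pos)), .groups = "drop")
  out$size <- lengths(lapply(out$key, split_from_key))
  out <- arrange(out[, c("key", "size", "count", "positions")],
                 dplyr::desc(.data$count), .data$key)
  attr(out, "n") <- n
  attr(out, "labels") <- hm$labels
  attr(out, "total") <- sum(out$count)
  class(out) <- c("variant_spectrum", class(out))
  out
}

#' Folded types generated by a single resolved tree
#'
#' An unrooted binary tree over `n` tips has `2n - 3` edges, each inducing
#' one folded bipartition; that is the number of distinct variant types a
#' single genealogy can generate.
#'
#' @param n number of tips (>= 3).
#' @return Integer `2n - 3`.
#' @export
count_tree_branch_types <- function(n) {
  assert_that(n >= 3, "need n >= 3")
  2L * as.integer(n) - 3L
}

#' All possible folded variant types
#'
#' The number of unordered bipartitions of `n` labelled haplotypes:
#' `2^(n-1) - 1`.
#'
#' @param n number of haplotypes (>= 2).
#' @return Integer count.
#' @export
count_possible_types <- function(n) {
  assert_that(n >= 2, "need n >= 2")
  as.integer(2^(n - 1) - 1)
}

#' Enumerate all canonical folded types
#'
#' @param n number of haplotypes (2..16).
#' @param tie_idx tip index excluded from balanced bipartitions (see
#'   [canonical_split_key()]).
#' @return Tibble with `key` and `size` for every folded bipartition.
#' @export
enumerate_folded_types <- function(n, tie_idx = 1L) {
  assert_that(n >= 2 && n <= 16, "enumeration supported for 2 <= n <= 16")
  out <- list()
  for (i in seq_len(floor(n / 2))) {
    sides <- utils::combn(n, i, simplify = FALSE)
    if (2 * i == n) sides <- sides[!vapply(sides, function(s)
      tie_idx %in% s, logical(1))]
    out[[i]] <- tibble(key = vapply(sides, paste, character(1),
                                    collapse = ","), size = i)
  }
  bind_rows(out)
}

#' Neutral-coalescent expectation for folded variant types
#'
#' Under the standard neutral coalescent all types in a size class are
#' equally frequent; a type with smaller side `i < n/2` has expected count
#' `theta (1/i + 1/(n-i)) / C(n,i)` and a balanced type (`i = n/2`)
#' `theta (2/n) / (C(n, n/2)/2)`. Unnormalized expectations sum to
#' `theta * sum_{i=1}^{n-1} 1/i` (Watterson's total).
#'
#' @param n number of haplotypes.
#' @param theta population mutation rate (total scale); ignored when
#'   `normalize = TRUE`.
#' @param normalize return proportions summing to 1?
#' @return Tibble with `key`, `size`, `expected` for every folded type.
#' @export
neutral_type_expectation <- function(n, theta = 1, normalize = FALSE) {
  types <- enumerate_folded_types(n)
  i <- types$size
  per_class <- ifelse(2 * i == n, theta * (2 / n), theta * (1 / i + 1 / (n - i)))
  n_types <- ifelse(2 * i == n, choose(n, i) / 2, choose(n, i))
  types$expected <- per_class / n_types
  if (normalize) types$expected <- types$expected / sum(types$expected)
  types
}

split_compatible <- function(a, b, n) {
  ia <- intersect(a, b)
  length(ia) == 0 || length(setdiff(a, b)) == 0 ||
    length(setdiff(b, a)) == 0 || length(union(a, b)) == n
}

#' Greedy perfect-phylogeny tree from a folded spectrum
#'
#' Types are ranked by descending count (ties by key) and accepted greedily
#' when pairwise compatible (splits A|B and C|D are compatible iff one of
#' the four side intersections is empty) -- the maximum-parsimony tree
#' implied by type frequencies under an infinite-sites model. The tree is
#' assembled from the accepted splits; remaining types are reported as
#' inconsistent together with their counts and site positions.
#'
#' @param spec a [folded_spectrum()].
#' @return A list of class `perfect_phylogeny`: `splits` (tibble with
#'   `accepted` flag), `newick`, `tree` (`ape::phylo`),
#'   `n_consistent`, `n_total`, `consistency` (fraction of variants
#'   compatible with the single tree), `inconsistent` tibble.
#' @export
perfect_phylogeny_tree <- function(spec) {
  assert_that(nrow(spec) > 0, "empty spectrum")
  n <- attr(spec, "n")
  labels <- attr(spec, "labels")
  spl <- arrange(as_tibble(spec), dplyr::desc(.data$count), .data$key)
  sides <- lapply(spl$key, split_from_key)
  accepted <- logical(nrow(spl))
  acc_sides <- list()
  for (i in seq_len(nrow(spl))) {
    ok <- all(vapply(acc_sides, split_compatible, logical(1),
                     b = sides[[i]], n = n))
    if (ok) {
      accepted[i] <- TRUE
      acc_sides[[length(acc_sides) + 1]] <- sides[[i]]
    }
  }
  spl$accepted <- accepted
  newick <- tree_from_splits(acc_sides, n, labels)
  tree <- ape::read.tree(text = newick)
  out <- list(splits = spl, newick = newick, tree = tree,
              n_consistent = sum(spl$count[accepted]),
              n_total = sum(spl$count),
              consistency = sum(spl$count[accepted]) / sum(spl$count),
              inconsistent = spl[!spl$accepted, , drop = FALSE])
  class(out) <- "perfect_phylogeny"
  out
}

#' @export
print.perfect_phylogeny <- function(x, ...) {
  cat(sprintf("<perfect_phylogeny> %d/%d variants (%.1f%%) consistent with a single tree\n",
              x$n_consistent, x$n_total, 100 * x$consistency))
  cat(sprintf("%d accepted split(s); %d inconsistent type(s)\n",
              sum(x$splits$accepted), nrow(x$inconsistent)))
  invisible(x)
}

#' @export
tidy.perfect_phylogeny <- function(x, ...) {
  dplyr::select(x$splits, -dplyr::any_of("positions"))
}

#' @export
glance.perfect_phylogeny <- function(x, ...) {
  tibble(n_consistent = x$n_consistent, n_total = x$n_total,
         consistency = x$consistency,
         n_splits = sum(x$splits$accepted))
}

# rooted laminar construction at tip 1, then serialized as unrooted newick
tree_from_splits <- function(sides, n, labels = NULL) {
  if (is.null(labels)) labels <- paste0("h", seq_len(n))
  clusters <- lapply(sides, function(s)
    if (1L %in% s) setdiff(seq_len(n), s) else s)
  clusters <- unique(clusters[lengths(clusters) > 1 &
                                lengths(clusters) < n - 1])
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]
  node_lab <- function(members, subclusters) {
    direct <- members
    parts <- character(0)
    remaining <- subclusters
    while (length(remaining) > 0) {
      top <- remaining[[1]]
      inner <- Filter(function(cc) all(cc %in% top),
                      remaining[-1])
      parts <- c(parts, node_lab(top, inner))
      direct <- setdiff(direct, top)
      remaining <- Filter(function(cc) !all(cc %in% top), remaining[-1])
    }
    parts <- c(parts, labels[direct])
    if (length(parts) == 1) parts else
      paste0("(", paste(parts, collapse = ","), ")")
  }
  all_members <- seq_len(n)
  paste0(node_lab(all_members, clusters), ";")
}

#' Polarize variants with an outgroup and estimate the TMRCA
#'
#' The derived allele at each site is the one not matching the outgroup;
#' sites where the derived allele is fixed are excluded. Types whose folded
#' bipartition is not an edge of the supplied tree are discarded; types
#' consistent with the tree but observed in the non-canonical orientation
#' (the complement of a tree split) are reassigned to the canonical side.
#' The TMRCA is the mean over individuals of the density of derived
#' mutations carried, divided by the mutation rate.
#'
#' @param hm a [haplotype_matrix()].
#' @param outgroup integer vector (one per site) giving the outgroup allele
#'   index (0/1); `NA` sites are dropped.
#' @param tree a [perfect_phylogeny_tree()] result.
#' @param mu mutation rate per site per generation.
#' @param callable_sites callable-site denominator.
#' @return A list of class `tmrca_estimate`: `tmrca`, `per_individual`
#'   tibble, `sites` tibble (kept/flipped/discarded), `polarized_spectrum`.
#' @export
polarize_and_tmrca <- function(hm, outgroup, tree, mu, callable_sites) {
  assert_that(mu > 0, "mu must be positive")
  assert_that(callable_sites > 0, "callable_sites must be positive")
  n <- nrow(hm$mat)
  tie_idx <- order(hm$labels)[1]
  accepted_keys <- tree$splits$key[tree$splits$accepted]
  ok_site <- !is.na(outgroup) & colSums(is.na(hm$mat)) == 0
  m <- hm$mat[, ok_site, drop = FALSE]
  og <- outgroup[ok_site]
  pos <- hm$sites$pos[ok_site]
  derived_count <- ifelse(og == 0, colSums(m == 1), colSums(m == 0))
  status <- character(ncol(m))
  carrier <- matrix(0L, n, ncol(m))
  for (j in seq_len(ncol(m))) {
    dset <- unname(if (og[j] == 0) which(m[, j] == 1) else
      which(m[, j] == 0))
    if (length(dset) == 0) { status[j] <- "monomorphic"; next }
    if (length(dset) == n) { status[j] <- "fixed_derived"; next }
    key <- canonical_split_key(dset, n, tie_idx)
    if (!(key %in% accepted_keys) &&
        !(length(dset) == 1 || length(dset) == n - 1)) {
      status[j] <- "discarded"; next
    }
    canon <- split_from_key(key)
    if (identical(sort(dset), sort(canon))) {
      status[j] <- "kept"
    } else {
      status[j] <- "flipped"
      dset <- canon
    }
    carrier[dset, j] <- 1L
  }
  keep <- status %in% c("kept", "flipped")
  per_ind <- tibble(
    haplotype = hm$labels,
    n_derived = rowSums(carrier[, keep, drop = FALSE]),
    rate = rowSums(carrier[, keep, drop = FALSE]) / callable_sites,
    tmrca_i = rowSums(carrier[, keep, drop = FALSE]) / callable_sites / mu)
  sites <- tibble(pos = pos, status = status,
                  derived_count = derived_count)
  pol_counts <- table(factor(colSums(carrier[, keep, drop = FALSE]),
                             levels = 1:(n - 1)))
  out <- list(tmrca = mean(per_ind$tmrca_i), per_individual = per_ind,
              sites = sites,
              polarized_spectrum = tibble(
                derived_size = 1:(n - 1),
                count = as.integer(pol_counts)),
              mu = mu, callable_sites = callable_sites)
  class(out) <- "tmrca_estimate"
  out
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("<tmrca_estimate> TMRCA = %.3g generations (mu = %g, %d callable sites)\n",
              x$tmrca, x$mu, as.integer(x$callable_sites)))
  invisible(x)
}

#' @export
glance.tmrca_estimate <- function(x, ...) {
  tibble(tmrca = x$tmrca, n_kept = sum(x$sites$status %in%
                                         c("kept", "flipped")),
         n_discarded = sum(x$sites$status == "discarded"),
         n_flipped = sum(x$sites$status == "flipped"))
}

#' Wald-Wolfowitz runs test for positional clustering
#'
#' Tests whether flagged sites (e.g. tree-inconsistent variants) cluster
#' physically along the chromosome: sites are ordered by position and the
#' number of runs of the binary flag is compared to its expectation under
#' random interleaving. A significantly low number of runs indicates
#' clustering.
#'
#' @param pos site positions.
#' @param flag logical flag per site.
#' @return One-row tibble: `n1`, `n2`, `runs`, `z`, `p_value`.
#' @export
runs_test_positions <- function(pos, flag) {
  o <- order(pos)
  x <- flag[o]
  n1 <- sum(x); n2 <- sum(!x)
  if (n1 == 0 || n2 == 0) {
    return(tibble(n1 = n1, n2 = n2, runs = NA_integer_, z = NA_real_,
                  p_value = NA_real_))
  }
  r <- 1L + sum(x[-1] != x[-length(x)])
  nn <- n1 + n2
  mu_r <- 2 * n1 * n2 / nn + 1
  var_r <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  z <- (r - mu_r) / sqrt(var_r)
  tibble(n1 = n1, n2 = n2, runs = r, z = z,
         p_value = 2 * pnorm(-abs(z)))
}
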