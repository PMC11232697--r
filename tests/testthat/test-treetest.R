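test_that("folded types use the canonical (smaller-side) bipartition", {
  hm <- toy_hm(rbind(c(0, 1), c(0, 0), c(1, 0), c(1, 0)))
  spec <- folded_spectrum(hm)
  # site 1 pattern 0011 -> side {3,4}; site 2 singleton on h1
  expect_setequal(spec$key, c("3,4", "1"))
  expect_equal(spec$count[spec$key == "3,4"], 1L)
  hm2 <- toy_hm(matrix(c(1, 0, 0, 0), 4, 6))
  spec2 <- folded_spectrum(hm2)
  expect_equal(nrow(spec2), 1)  # all sites are the same singleton type
  expect_equal(spec2$count, 6L)
})

test_that("spectra are invariant to haplotype relabeling up to renaming", {
  set.seed(8)
  m <- matrix(rbinom(6 * 60, 1, 0.4), 6, 60)
  s1 <- folded_spectrum(toy_hm(m))
  perm <- c(4, 6, 1, 3, 2, 5)
  s2 <- folded_spectrum(toy_hm(m[perm, ]))
  expect_equal(sort(s1$count), sort(s2$count))
  expect_equal(attr(s1, "total"), attr(s2, "total"))
})

test_that("branch-type counts match tree combinatorics", {
  expect_equal(count_tree_branch_types(7), 11L)
  expect_equal(count_tree_branch_types(3), 3L)
  expect_error(count_tree_branch_types(2), "n >= 3")
  expect_equal(count_possible_types(7), 63L)
  expect_equal(count_possible_types(2), 1L)
  expect_error(count_possible_types(1), "n >= 2")
  # n = 10: matches the edge count of random resolved unrooted trees
  set.seed(1)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(10))
    expect_equal(count_tree_branch_types(10), nrow(tr$edge))
  }
  # n = 9: exhaustive enumeration of folded subsets
  expect_equal(count_possible_types(9), nrow(enumerate_folded_types(9)))
  expect_equal(count_possible_types(8), nrow(enumerate_folded_types(8)))
})

test_that("spectra from single trees reconstruct the generating splits", {
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    labels <- sprintf("h%02d", 1:n)
    tr <- ape::unroot(ape::rtree(n, tip.label = sample(labels)))
    keys <- tree_split_keys(tr, labels)
    sites <- unlist(lapply(keys, function(k) {
      rep(k, sample(1:3, 1))
    }))
    m <- vapply(sites, function(k) {
      v <- integer(n); v[split_from_key(k)] <- 1L; v
    }, integer(n))
    hm <- toy_hm(m, labels = labels)
    tree <- perfect_phylogeny_tree(folded_spectrum(hm))
    expect_equal(tree$consistency, 1)
    expect_setequal(tree$splits$key[tree$splits$accepted], keys)
    # the reconstructed tree's splits equal the generator's
    got <- tree_split_keys(tree$tree, labels)
    expect_setequal(got, keys)
  }
})

test_that("greedy acceptance keeps the more frequent of two conflicting types", {
  m <- cbind(matrix(c(1, 1, 0, 0, 0), 5, 10),  # {1,2} x10
             matrix(c(0, 1, 1, 0, 0), 5, 1))   # {2,3} x1, incompatible
  spec <- folded_spectrum(toy_hm(m))
  tree <- perfect_phylogeny_tree(spec)
  expect_true(tree$splits$accepted[tree$splits$key == "1,2"])
  expect_false(tree$splits$accepted[tree$splits$key == "2,3"])
  expect_equal(tree$n_consistent, 10L)
  expect_equal(tree$n_total, 11L)
})

test_that("neutral type expectations have the exact Watterson total", {
  for (n in c(4, 7, 8)) {
    e <- neutral_type_expectation(n, theta = 3)
    expect_equal(sum(e$expected), 3 * sum(1 / seq_len(n - 1)))
    # all types within a size class share the same expectation
    for (s in unique(e$size)) {
      expect_equal(length(unique(e$expected[e$size == s])), 1)
    }
  }
  e2 <- neutral_type_expectation(2, normalize = TRUE)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$expected, 1)
})

test_that("polarization flips complement patterns and discards conflicts", {
  # tree generated by singletons plus the clade {1,2}
  m <- cbind(vapply(1:7, function(i) { v <- integer(7); v[i] <- 1L; v },
                    integer(7)),
             c(1, 1, 0, 0, 0, 0, 0),
             c(0, 1, 1, 1, 1, 1, 1),  # complement of {1}: mispolarized
             c(0, 1, 1, 0, 0, 0, 0))  # {2,3}: conflicts with {1,2}
  hm <- toy_hm(m)
  tree <- perfect_phylogeny_tree(folded_spectrum(hm))
  pol <- polarize_and_tmrca(hm, outgroup = rep(0L, ncol(m)), tree,
                            mu = MU, callable_sites = 1e6)
  st <- pol$sites$status
  expect_equal(sum(st == "flipped"), 1)
  expect_equal(sum(st == "discarded"), 1)
  # the flipped site now counts as a derived singleton on h1:
  # own singleton + the {1,2} clade + the flipped site
  expect_equal(pol$per_individual$n_derived[1], 3)
})

test_that("no derived variation gives a TMRCA of zero", {
  hm <- toy_hm(matrix(0L, 5, 4))
  spec_input <- toy_hm(rbind(diag(5)[, c(1, 2, 3, 4)]))
  tree <- perfect_phylogeny_tree(folded_spectrum(spec_input))
  pol <- polarize_and_tmrca(hm, rep(0L, 4), tree, MU, 1e5)
  expect_equal(pol$tmrca, 0)
})

test_that("a star genealogy's depth is recovered from derived density", {
  set.seed(20)
  G <- 5e4; L <- 1e6; n <- 7
  counts <- rpois(n, MU * G * L)
  m <- matrix(0L, n, sum(counts))
  j <- 0
  for (i in seq_len(n)) {
    if (counts[i] > 0) m[i, j + seq_len(counts[i])] <- 1L
    j <- j + counts[i]
  }
  hm <- toy_hm(m)
  tree <- perfect_phylogeny_tree(folded_spectrum(hm))
  pol <- polarize_and_tmrca(hm, rep(0L, ncol(m)), tree, MU, L)
  expect_lt(abs(pol$tmrca / G - 1), 0.1)
})

test_that("the runs test flags clustered but not interleaved patterns", {
  pos <- 1:60
  clustered <- c(rep(FALSE, 25), rep(TRUE, 10), rep(FALSE, 25))
  rt1 <- runs_test_positions(pos, clustered)
  expect_lt(rt1$p_value, 0.01)
  expect_lt(rt1$z, 0)
  set.seed(30)
  spread <- sample(clustered)
  rt2 <- runs_test_positions(pos, spread)
  expect_gt(rt2$p_value, 0.01)
  rt3 <- runs_test_positions(pos, rep(FALSE, 60))
  expect_true(is.na(rt3$p_value))
})
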