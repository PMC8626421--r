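# concordance_stats: quartet tabulation, branch supports, agreement tests,
# split support classification.

test_that("count_quartet_topologies tallies resolutions, unresolved and missing", {
  trees <- list(parse_newick("((A,B),(C,D));"),
                parse_newick("((A,B),(C,D));"),
                parse_newick("((A,C),(B,D));"))
  gts <- gene_tree_set(trees)
  expect_equal(count_quartet_topologies(gts, c("A", "B", "C", "D")),
               c(n1 = 2L, n2 = 1L, n3 = 0L, unresolved = 0L, missing = 0L))

  gts2 <- gene_tree_set(list(parse_newick("((A,B),C);"),
                             parse_newick("(A,(B,C));")),
                        taxa = c("A", "B", "C", "D"))
  expect_equal(count_quartet_topologies(gts2, c("A", "B", "C", "D")),
               c(n1 = 0L, n2 = 0L, n3 = 0L, unresolved = 0L, missing = 2L))
  expect_error(count_quartet_topologies(gts, c("A", "B", "C", "Z")),
               "outside")
})

test_that("all_quartet_frequencies enumerates C(n,4) subsets deterministically", {
  gts4 <- gene_tree_set(list(parse_newick("((A,B),(C,D));")))
  expect_equal(nrow(all_quartet_frequencies(gts4)), 1)

  set.seed(8)
  trees <- replicate(10, {
    tr <- ape::rtree(7, tip.label = sprintf("t%d", 1:7))
    parse_newick(ape::write.tree(tr))
  }, simplify = FALSE)
  gts7 <- gene_tree_set(trees)
  qt <- all_quartet_frequencies(gts7)
  expect_equal(nrow(qt), choose(7, 4))
  expect_identical(qt, all_quartet_frequencies(gts7))
  # full-taxa binary trees: no unresolved/missing, frequencies sum to 1
  expect_true(all(qt$unresolved == 0 & qt$missing == 0))
  expect_equal(qt$f1 + qt$f2 + qt$f3, rep(1, nrow(qt)))
  expect_equal(qt$n1 + qt$n2 + qt$n3 + qt$unresolved + qt$missing,
               rep(10L, nrow(qt)))
})

test_that("relabeling taxa by a permutation permutes the table consistently", {
  set.seed(9)
  trees <- replicate(8, {
    tr <- ape::rtree(6, tip.label = sprintf("t%d", 1:6))
    parse_newick(ape::write.tree(tr))
  }, simplify = FALSE)
  gts <- gene_tree_set(trees)
  qt <- all_quartet_frequencies(gts)

  perm <- c(t1 = "x4", t2 = "x2", t3 = "x6", t4 = "x1", t5 = "x3", t6 = "x5")
  trees2 <- lapply(trees, function(tr) {
    tr$tip.label <- unname(perm[tr$tip.label])
    tr
  })
  qt2 <- all_quartet_frequencies(gene_tree_set(trees2))
  for (r in seq_len(nrow(qt))) {
    orig <- unlist(qt[r, 1:4])
    img <- sort(unname(perm[orig]))
    r2 <- which(qt2$taxon_a == img[1] & qt2$taxon_b == img[2] &
                  qt2$taxon_c == img[3] & qt2$taxon_d == img[4])
    expect_length(r2, 1)
    expect_equal(sort(unlist(qt[r, c("n1", "n2", "n3")])),
                 sort(unlist(qt2[r2, c("n1", "n2", "n3")])),
                 ignore_attr = TRUE)
  }
})

test_that("branch support is 1 on a perfectly concordant set and ~1/3 with
           no signal", {
  spt <- parse_newick("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);", "coalescent")
  self <- gene_tree_set(rep(list(spt), 10))
  for (br in bipartitions(spt)) {
    bs <- branch_quartet_support(self, spt, br)
    expect_equal(bs$q1, 1)
    expect_equal(bs$q2 + bs$q3, 0)
  }

  spt0 <- parse_newick("(((A:1,B:1):1e-9,C:1):1e-9,D:1);", "coalescent")
  gts <- simulate_gene_trees(spt0, n_trees = 3000, seed = 4,
                             keep_trees = FALSE)
  bs <- branch_quartet_support(gts, spt0, c("A", "B"))
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(bs$q1 - 1 / 3), se3)
  expect_lt(abs(bs$q2 - 1 / 3), se3)
  expect_error(branch_quartet_support(gts, spt0, c("A", "C")),
               "not an internal edge")
})

test_that("coalescent length inverts quartet support with clipping and cap", {
  expect_equal(coalescent_length_from_support(1 / 3), 0)
  expect_equal(coalescent_length_from_support(0.7547), 1, tolerance = 1e-3)
  expect_equal(coalescent_length_from_support(0.2), 0) # below 1/3: clipped
  expect_equal(coalescent_length_from_support(1), 10)  # capped ceiling
  expect_equal(coalescent_length_from_support(1, ceiling = 4), 4)
  expect_error(coalescent_length_from_support(1.2), "\\[0, 1\\]")
  # inverse of the closed form on a grid
  t <- c(0.1, 0.5, 1, 2)
  expect_equal(coalescent_length_from_support(conc_prob(t)), t)
})

test_that("quartet-table regression matches closed-form least squares", {
  mk <- function(n1, n2, n3) {
    df <- data.frame(taxon_a = "A", taxon_b = "B", taxon_c = "C",
                     taxon_d = "D", n1 = n1, n2 = n2, n3 = n3,
                     unresolved = 0L, missing = 0L,
                     f1 = n1 / (n1 + n2 + n3), f2 = n2 / (n1 + n2 + n3),
                     f3 = n3 / (n1 + n2 + n3))
    structure(df, taxa = c("A", "B", "C", "D"),
              class = c("quartet_table", "data.frame"))
  }
  a <- mk(5, 3, 2)  # frequencies 0.5, 0.3, 0.2
  b <- mk(4, 4, 2)  # frequencies 0.4, 0.4, 0.2
  self <- correlate_quartet_tables(a, a)
  expect_equal(self$r_squared, 1)
  expect_equal(self$slope, 1)
  expect_equal(self$intercept, 0)

  fit <- correlate_quartet_tables(a, b)
  expect_equal(fit$r_squared, 4 / 7, tolerance = 1e-9)
  expect_equal(fit$r_squared, cor(c(.5, .3, .2), c(.4, .4, .2))^2)

  const <- mk(2, 2, 2)
  expect_error(correlate_quartet_tables(const, b), "variance")
})

test_that("minor-topology chi-square matches stats::chisq.test and handles
           degenerate tables per the stated conventions", {
  same <- minor_topology_chisq(c(10, 10), c(10, 10))
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p_value, 1)

  res <- minor_topology_chisq(c(30, 20), c(25, 25))
  oracle <- stats::chisq.test(rbind(c(30, 20), c(25, 25)), correct = FALSE)
  expect_equal(res$chi_sq, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, unname(oracle$p.value), tolerance = 1e-12)
  expect_equal(res$chi_sq, 1.0101, tolerance = 1e-3)
  expect_equal(res$df, 1L)

  expect_error(minor_topology_chisq(c(0, 0), c(5, 5)), "no classified")
  # zero column: computed normally (0/0 terms contribute nothing)
  zc <- minor_topology_chisq(c(10, 0), c(8, 0))
  expect_equal(zc$chi_sq, 0)
})

test_that("split support classification follows the contraction rule", {
  # split {A,B} present with high support
  t_hi <- parse_newick("(((A,B)98:1,C)90:1,(D,E)88:1);")
  # present with low support
  t_lo <- parse_newick("(((A,B)60:1,C)90:1,(D,E)88:1);")
  # absent; the only conflicting edge {A,C} has low support 60, so
  # contracting low-support branches makes the split compatible
  t_wr <- parse_newick("(((A,C)60:1,B)90:1,(D,E)88:1);")
  # absent; the conflicting edge has high support: strongly rejected
  t_sr <- parse_newick("(((A,C)95:1,B)90:1,(D,E)88:1);")
  gts <- gene_tree_set(list(t_hi, t_lo, t_wr, t_sr))
  res <- classify_split_support(gts, c("A", "B"), threshold = 75)
  expect_equal(res$categories,
               c("strongly_supported", "weakly_supported",
                 "weakly_rejected", "strongly_rejected"))
  expect_equal(res$n_categorized, 4)
  expect_equal(sum(res$proportions), 1)

  bare <- gene_tree_set(list(parse_newick("((A,B),(C,D));")))
  expect_error(classify_split_support(bare, c("A", "B")), "support")
  ok <- classify_split_support(bare, c("A", "B"), missing_support = "high")
  expect_equal(ok$categories, "strongly_supported")
})
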