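# msc_simulator: coalescent simulation within a species tree.

cu_tree <- function(txt) parse_newick(txt, unit_tag = "coalescent")

test_that("two species always yield the single possible topology", {
  spt <- cu_tree("(A:1,B:1);")
  gts <- simulate_gene_trees(spt, n_trees = 25, seed = 1)
  for (tr in gts$trees) {
    expect_setequal(tr$tip.label, c("A", "B"))
    expect_equal(tr$Nnode, 1)
  }
})

test_that("an effectively infinite internal branch gives no discordance", {
  spt <- cu_tree("(((A:1,B:1):50,C:2):1,D:3);")
  gts <- simulate_gene_trees(spt, n_trees = 200, seed = 2)
  tally <- count_quartet_topologies(gts, c("A", "B", "C", "D"))
  expect_equal(unname(tally["n1"]), 200) # A,B|C,D is resolution 1
})

test_that("gene trees are binary on the species taxa with n - 1 coalescences", {
  spt <- cu_tree("(((A:1,B:1):0.5,(C:1,D:1):0.2):0.4,E:2);")
  gts <- simulate_gene_trees(spt, n_trees = 50, seed = 3)
  for (tr in gts$trees) {
    expect_setequal(tr$tip.label, c("A", "B", "C", "D", "E"))
    expect_true(ape::is.binary(tr))
    expect_equal(tr$Nnode, 4)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("simulation is deterministic under a fixed seed and replicate i
           does not depend on n_trees", {
  spt <- cu_tree("((A:1,B:1):1,C:2);")
  g1 <- simulate_gene_trees(spt, sim_config(n_trees = 1, seed = 42))
  g2 <- simulate_gene_trees(spt, sim_config(n_trees = 1, seed = 42))
  expect_identical(write_newick(g1$trees[[1]]), write_newick(g2$trees[[1]]))

  g5 <- simulate_gene_trees(spt, sim_config(5, seed = 7))
  g9 <- simulate_gene_trees(spt, sim_config(9, seed = 7))
  expect_identical(g5$masks, g9$masks[1:5])
})

test_that("topology-only simulation matches the full one under the same seed", {
  spt <- cu_tree("(((A:1,B:1):0.5,C:1):0.7,D:2);")
  full <- simulate_gene_trees(spt, n_trees = 100, seed = 5)
  mask <- simulate_gene_trees(spt, n_trees = 100, seed = 5,
                              keep_trees = FALSE)
  expect_identical(full$masks, mask$masks)
  expect_error(write_gene_trees(mask, tempfile()), "topology-only")
})

test_that("3-species concordance tracks the closed form and a Monte-Carlo
           oracle within binomial error", {
  spt <- cu_tree("((A:1,B:1):1,C:2);")
  n <- 4000
  gts <- simulate_gene_trees(spt, n_trees = n, seed = 1, keep_trees = FALSE)
  ab <- vapply(seq_along(gts$masks), function(i)
    identical(induced_first_cherry(gts$masks[[i]], gts$taxa), c("A", "B")),
    logical(1))
  p_hat <- mean(ab)
  p <- conc_prob(1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 3 * se)
  expect_lt(abs(oracle_mc_concordance(1, 20000, 99) - p), 0.01)
})

test_that("quartet concordance is non-decreasing in branch length", {
  grid <- c(0.2, 0.5, 1, 2)
  freq <- vapply(grid, function(t) {
    spt <- cu_tree(sprintf("(((A:1,B:1):%g,C:2):1,D:3);", t))
    gts <- simulate_gene_trees(spt, n_trees = 2000, seed = 11,
                               keep_trees = FALSE)
    tal <- count_quartet_topologies(gts, c("A", "B", "C", "D"))
    tal[["n1"]] / sum(tal[c("n1", "n2", "n3")])
  }, numeric(1))
  expect_true(all(diff(freq) > 0))
})

test_that("multiple alleles per species are supported via the config hook", {
  spt <- cu_tree("(A:1,B:1);")
  gts <- simulate_gene_trees(spt, sim_config(5, seed = 2,
                                             alleles_per_species = 2))
  expect_setequal(gts$taxa, c("A_1", "A_2", "B_1", "B_2"))
  expect_equal(gts$trees[[1]]$Nnode, 3)
})

test_that("invalid simulation inputs error", {
  expect_error(sim_config(0), ">= 1")
  star <- parse_newick("(A:1,B:1,C:1);", "coalescent")
  expect_error(simulate_gene_trees(star, n_trees = 1, seed = 1),
               "rooted|binary")
  poly <- parse_newick("((A:1,B:1,C:1):1,D:1);", "coalescent")
  expect_error(simulate_gene_trees(poly, n_trees = 1, seed = 1), "binary")
  unrooted <- ape::unroot(ape::rtree(4))
  expect_error(simulate_gene_trees(unrooted, n_trees = 1, seed = 1),
               "rooted|binary")
})

test_that("coalescent_scale divides internals by theta and pins terminals to 1", {
  mu <- parse_newick("((A:0.2,B:0.3):0.05,C:0.4);", "mutation")
  cu <- coalescent_scale(mu, 0.001)
  expect_identical(unit_tag(cu), "coalescent")
  n <- length(cu$tip.label)
  internal <- cu$edge[, 2] > n
  expect_equal(cu$edge.length[internal], 50)
  expect_equal(cu$edge.length[!internal], rep(1, 3))

  # theta equal to each internal mutation length gives unit coalescent lengths
  cu2 <- coalescent_scale(mu, 0.05)
  expect_equal(cu2$edge.length[internal], 1)

  expect_error(coalescent_scale(mu, 0), "positive")
  expect_error(coalescent_scale(mu, -1), "positive")
})
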