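# Independent oracles used across the suite. None of these call into the
# package's split/quartet machinery.

# Closed-form MSC concordance for the quartet around a branch of length t
# coalescent units: each minor topology has probability (2/3) exp(-t) / 2.
conc_prob <- function(t) 1 - (2 / 3) * exp(-t)

# Induced quartet topology via ape pruning + phangorn RF distance.
oracle_quartet <- function(tree, quartet) {
  q <- sort(quartet)
  if (!all(q %in% tree$tip.label)) return("missing")
  sub <- ape::unroot(ape::keep.tip(tree, q))
  if (!ape::is.binary(sub)) return("unresolved")
  pairs <- list(c(2L, 3L, 4L), c(3L, 2L, 4L), c(4L, 2L, 3L))
  for (j in 1:3) {
    p <- pairs[[j]]
    ref <- ape::unroot(ape::read.tree(text = sprintf(
      "((%s,%s),(%s,%s));", q[1], q[p[1]], q[p[2]], q[p[3]])))
    if (phangorn::RF.dist(sub, ref) == 0)
      return(quartet_resolutions(q)[j])
  }
  stop("oracle failed to match any resolution")
}

# Pure Monte-Carlo MSC concordance for a single internal branch, written
# independently of the simulator: lineages entering a branch of length t
# either coalesce there (Exp(1) < t) or resolve uniformly afterwards.
oracle_mc_concordance <- function(t, n, seed) {
  set.seed(seed)
  coal <- stats::rexp(n) < t
  deep <- stats::runif(n) < 1 / 3
  mean(coal | deep)
}

# Random gene tree with supports on internal nodes, for split-support tests.
random_supported_tree <- function(taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  parse_newick(ape::write.tree(tr))
}

fixture_path <- function(...) file.path(tempdir(), ...)

popcount_oracle <- function(x) {
  vapply(x, function(v) sum(bitwAnd(bitwShiftR(v, 0:29), 1L)), integer(1))
}

# cherry (size-2 clade) of a 3-taxon gene tree, from its clade masks
induced_first_cherry <- function(masks, taxa) {
  two <- masks[popcount_oracle(masks) == 2][1]
  taxa[bitwAnd(bitwShiftR(two, seq_along(taxa) - 1L), 1L) == 1L]
}
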