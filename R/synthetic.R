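# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, standing in for the study-scale genome dataset.

#' Generate a matched (coalescent, mutation) species-tree pair
#'
#' Random binary topology by uniform coalescent joins; internal branch
#' lengths in coalescent units drawn uniformly on `cu_range`; terminal
#' coalescent branches set to 1. The mutation-unit twin has internal
#' lengths `mu_theta * coalescent length`, so [estimate_theta()] on the
#' pair recovers `mu_theta` exactly on every internal branch.
#'
#' @param n_taxa Number of taxa (>= 4); tips are labeled `s01, s02, ...`.
#' @param cu_range Length-2 range `(lo, hi)` for internal coalescent-unit
#'   lengths, `0 <= lo <= hi`.
#' @param mu_theta True theta applied to every branch.
#' @param seed Integer seed (same seed, same pair).
#' @return List: `coalescent` (`phylo`, `unit_tag = "coalescent"`),
#'   `mutation` (`phylo`, `unit_tag = "mutation"`), `theta` (echo of
#'   `mu_theta`).
#' @export
gen_species_tree <- function(n_taxa, cu_range = c(0.5, 2), mu_theta = 0.1,
                             seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 4L) stop("`n_taxa` must be >= 4")
  if (!is.numeric(cu_range) || length(cu_range) != 2L ||
      any(!is.finite(cu_range)) || cu_range[1] < 0 ||
      cu_range[1] > cu_range[2])
    stop("`cu_range` must be (lo, hi) with 0 <= lo <= hi")
  if (!is.numeric(mu_theta) || mu_theta <= 0) stop("`mu_theta` must be > 0")
  set.seed(as.integer(seed))
  tips <- sprintf("s%02d", seq_len(n_taxa))
  cu <- ape::rcoal(n_taxa, tip.label = tips)
  internal <- cu$edge[, 2L] > n_taxa
  cu$edge.length[internal] <- stats::runif(sum(internal),
                                           cu_range[1], cu_range[2])
  cu$edge.length[!internal] <- 1
  attr(cu, "unit_tag") <- "coalescent"
  mu <- cu
  mu$edge.length <- mu$edge.length * mu_theta
  attr(mu, "unit_tag") <- "mutation"
  list(coalescent = cu, mutation = mu, theta = mu_theta)
}

#' Generate copy-labeled gene trees for WGD scenarios
#'
#' `independent_wgd` emits `((A1,A2),(B1,B2))` backbones (each species
#' duplicated after the split); `shared_wgd` emits `((A1,B1),(A2,B2))`
#' (one duplication in the common ancestor). With probability `noise` a
#' tree is perturbed by one random nearest-neighbor interchange, which on
#' a four-tip tree moves to one of the two alternative quartet topologies
#' (chosen uniformly) - so full noise turns an independent backbone into a
#' shared-looking one with certainty, enumerable by brute force.
#'
#' @param scenario `"independent_wgd"` or `"shared_wgd"`.
#' @param n Number of trees (>= 1).
#' @param noise Per-tree NNI probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `trees` (list of `phylo`), `scenario`, `noise`, `n`,
#'   `seed` (ground truth echoed).
#' @export
gen_wgd_copy_trees <- function(scenario = c("independent_wgd", "shared_wgd"),
                               n, noise = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (!is.numeric(noise) || length(noise) != 1L || is.na(noise) ||
      noise < 0 || noise > 1)
    stop("`noise` must be in [0, 1]")
  set.seed(as.integer(seed))
  tips <- c("A1", "A2", "B1", "B2")
  topos <- c("((A1:1,A2:1):1,(B1:1,B2:1):1);",
             "((A1:1,B1:1):1,(A2:1,B2:1):1);",
             "((A1:1,B2:1):1,(A2:1,B1:1):1);")
  base_idx <- if (scenario == "independent_wgd") 1L else 2L
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- base_idx
    if (stats::runif(1) < noise) {
      # one NNI on the single internal edge: the two other resolutions
      idx <- sample(setdiff(1:3, base_idx), 1L)
    }
    trees[[i]] <- parse_newick(topos[idx])
  }
  list(trees = trees, scenario = scenario, noise = noise, n = n,
       seed = as.integer(seed))
}

#' Sample Ks values from a known Gaussian mixture
#'
#' I.i.d. draws from the mixture; negative draws are rejected and redrawn
#' (Ks cannot be negative).
#'
#' @param components Data frame or matrix with columns `weight`, `mean`,
#'   `sd` (weights must sum to 1, sds positive).
#' @param n Sample size (>= 1).
#' @param seed Integer seed.
#' @return List: `values` (numeric length `n`), `components` (ground
#'   truth), `n`, `seed`.
#' @export
gen_ks_mixture_sample <- function(components, n, seed = 1L) {
  cmp <- as.data.frame(components)
  if (!all(c("weight", "mean", "sd") %in% names(cmp)))
    stop("`components` needs columns weight, mean, sd")
  if (abs(sum(cmp$weight) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(cmp$weight <= 0)) stop("weights must be positive")
  if (any(cmp$sd <= 0)) stop("sds must be positive")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  set.seed(as.integer(seed))
  comp <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
  x <- stats::rnorm(n, cmp$mean[comp], cmp$sd[comp])
  while (any(x < 0)) {
    bad <- which(x < 0)
    x[bad] <- stats::rnorm(length(bad), cmp$mean[comp[bad]],
                           cmp$sd[comp[bad]])
  }
  list(values = x, components = cmp, n = n, seed = as.integer(seed))
}

#' Generate a full synthetic scenario
#'
#' One entry point over the generators, echoing all ground truth, as used
#' by the `synth` CLI subcommand.
#'
#' @param scenario One of `"msc"`, `"independent_wgd"`, `"shared_wgd"`,
#'   `"ks_mixture"`.
#' @param n Number of gene trees / trees / Ks draws.
#' @param seed Integer seed.
#' @param n_taxa,cu_range,mu_theta Passed to [gen_species_tree()] for
#'   `"msc"`.
#' @param noise NNI probability for the WGD scenarios.
#' @param components Mixture definition for `"ks_mixture"`.
#' @return A list with the generated data plus a `ground_truth` element
#'   echoing every parameter.
#' @export
generate_scenario <- function(scenario = c("msc", "independent_wgd",
                                           "shared_wgd", "ks_mixture"),
                              n = 1000L, seed = 1L,
                              n_taxa = 7L, cu_range = c(0.2, 1.2),
                              mu_theta = 0.1, noise = 0,
                              components = data.frame(
                                weight = c(0.6, 0.4),
                                mean = c(0.5, 1.07),
                                sd = c(0.15, 0.2))) {
  scenario <- match.arg(scenario)
  if (scenario == "msc") {
    pair <- gen_species_tree(n_taxa, cu_range, mu_theta, seed)
    gts <- simulate_gene_trees(pair$coalescent,
                               sim_config(n, seed = as.integer(seed) + 1L))
    list(species_trees = pair, gene_trees = gts,
         ground_truth = list(scenario = scenario, n = n, seed = seed,
                             n_taxa = n_taxa, cu_range = cu_range,
                             mu_theta = mu_theta))
  } else if (scenario == "ks_mixture") {
    smp <- gen_ks_mixture_sample(components, n, seed)
    list(ks = smp,
         ground_truth = list(scenario = scenario, n = n, seed = seed,
                             components = as.data.frame(components)))
  } else {
    gw <- gen_wgd_copy_trees(scenario, n, noise, seed)
    list(copy_trees = gw,
         ground_truth = list(scenario = scenario, n = n, seed = seed,
                             noise = noise))
  }
}

#' Proportion of gene trees matching a species-tree topology
#'
#' Compares unrooted split sets; used for the no-ILS baseline check (with
#' theta 0.001 essentially every simulated tree matches the species tree).
#'
#' @param gene_trees A [gene_tree_set()].
#' @param species_tree `phylo` on the same taxa.
#' @return Fraction of trees whose nontrivial splits equal the species
#'   tree's.
#' @export
prop_matching_topology <- function(gene_trees, species_tree) {
  stopifnot(inherits(gene_trees, "gene_tree_set"))
  taxa <- gene_trees$taxa
  if (!setequal(species_tree$tip.label, taxa))
    stop("species tree taxa must match the reference taxa")
  cl <- phylo_clades(species_tree, taxa)
  ref <- canonical_splits(cl$clades, cl$present)
  match1 <- vapply(seq_along(gene_trees$masks), function(i) {
    identical(canonical_splits(gene_trees$masks[[i]],
                               gene_trees$present[i]), ref)
  }, logical(1))
  mean(match1)
}
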