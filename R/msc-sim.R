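# Multispecies-coalescent gene-tree simulation within a species tree whose
# branch lengths are in coalescent units.
#
# Within a species-tree branch of duration t carrying k gene lineages,
# coalescences occur with exponential waiting times at rate k(k-1)/2, the
# coalescing pair drawn uniformly; surviving lineages pass to the parent
# branch, and the root branch has unbounded duration. With one allele per
# species, terminal branch durations cannot affect topology.

#' Simulation settings
#'
#' @param n_trees Number of gene trees to simulate (study default 20,000).
#' @param seed Integer seed; fixed seed gives byte-identical output. `NULL`
#'   draws one from the session RNG.
#' @param alleles_per_species Gene copies sampled per species (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trees = 20000L, seed = NULL,
                       alleles_per_species = 1L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be >= 1")
  alleles_per_species <- as.integer(alleles_per_species)
  if (is.na(alleles_per_species) || alleles_per_species < 1L)
    stop("`alleles_per_species` must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_trees = n_trees, seed = seed,
                 alleles_per_species = alleles_per_species),
            class = "sim_config")
}

# Deterministic per-replicate seed: changing n_trees never changes earlier
# replicates, the property stream-jumping would buy on a jumpable RNG.
replicate_seed <- function(seed, i) {
  base <- as.double(seed %% 20011L)
  as.integer((base * 100003 + as.double(i) * 7919) %% 2147483629)
}

prep_species_tree <- function(species_tree, alleles = 1L) {
  if (!inherits(species_tree, "phylo"))
    stop("`species_tree` must be a phylo object")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!ape::is.binary(species_tree)) stop("species tree must be binary")
  n <- length(species_tree$tip.label)
  if (n < 2L) stop("species tree needs at least 2 tips")
  check_taxa(species_tree$tip.label)
  nn <- n + species_tree$Nnode
  blen <- rep(NA_real_, nn)
  blen[species_tree$edge[, 2L]] <- species_tree$edge.length
  root <- setdiff(species_tree$edge[, 1L], species_tree$edge[, 2L])
  blen[root] <- Inf
  tip_na <- is.na(blen[seq_len(n)])
  blen[seq_len(n)][tip_na] <- 1 # terminal durations, inert with 1 allele
  if (anyNA(blen)) stop("species tree has internal branches without lengths")
  if (any(blen[is.finite(blen)] < 0)) stop("negative branch length")
  e <- ape::reorder.phylo(species_tree, "postorder")$edge
  node_order <- c(seq_len(n), unique(e[, 1L])) # children before parents
  children <- split(e[, 2L], factor(e[, 1L], levels = seq_len(nn)))
  if (alleles == 1L) {
    labels <- species_tree$tip.label
  } else {
    labels <- paste0(rep(species_tree$tip.label, each = alleles), "_",
                     rep(seq_len(alleles), n))
  }
  if (n * alleles > MAX_TAXA)
    stop("total sampled lineages exceed the ", MAX_TAXA, "-taxon limit")
  taxa <- sort(labels)
  list(n = n, nn = nn, root = root, blen = blen, order = node_order,
       children = children, alleles = alleles,
       tip_label = species_tree$tip.label, labels = labels, taxa = taxa)
}

# One replicate. Returns merge records: masks (clade bitmask over pre$taxa),
# child ids, child branch lengths. Provisional internal ids are L0 + k for
# the k-th merge, tips are 1..L0 in sorted-taxa order.
sim_core <- function(pre) {
  a <- pre$alleles
  L0 <- pre$n * a
  K <- L0 - 1L
  rec_mask <- integer(K); rec_c1 <- integer(K); rec_c2 <- integer(K)
  rec_l1 <- numeric(K); rec_l2 <- numeric(K)
  k_done <- 0L
  state <- vector("list", pre$nn)
  for (v in pre$order) {
    if (v <= pre$n) {
      idx <- match(if (a == 1L) pre$tip_label[v] else
                     paste0(pre$tip_label[v], "_", seq_len(a)),
                   pre$taxa)
      L <- list(mask = bitwShiftL(1L, idx - 1L), id = idx,
                pend = numeric(length(idx)))
    } else {
      ch <- pre$children[[v]]
      L <- list(mask = unlist(lapply(state[ch], `[[`, "mask")),
                id = unlist(lapply(state[ch], `[[`, "id")),
                pend = unlist(lapply(state[ch], `[[`, "pend")))
      state[ch] <- list(NULL)
    }
    dur <- pre$blen[v]
    k <- length(L$mask)
    while (k >= 2L) {
      w <- stats::rexp(1L, k * (k - 1) / 2)
      if (w > dur) break
      dur <- dur - w
      L$pend <- L$pend + w
      pr <- sample.int(k, 2L)
      i <- pr[1L]; j <- pr[2L]
      k_done <- k_done + 1L
      rec_mask[k_done] <- bitwOr(L$mask[i], L$mask[j])
      rec_c1[k_done] <- L$id[i]; rec_c2[k_done] <- L$id[j]
      rec_l1[k_done] <- L$pend[i]; rec_l2[k_done] <- L$pend[j]
      L$mask[i] <- rec_mask[k_done]
      L$id[i] <- L0 + k_done
      L$pend[i] <- 0
      L$mask <- L$mask[-j]; L$id <- L$id[-j]; L$pend <- L$pend[-j]
      k <- k - 1L
    }
    if (is.finite(dur)) L$pend <- L$pend + dur
    state[[v]] <- L
  }
  list(mask = rec_mask, c1 = rec_c1, c2 = rec_c2, l1 = rec_l1, l2 = rec_l2,
       L0 = L0)
}

# Assemble an ape phylo from merge records (root = last merge).
build_gene_phylo <- function(rec, taxa) {
  L0 <- rec$L0
  K <- L0 - 1L
  remap <- function(id) ifelse(id <= L0, id, 2L * L0 - (id - L0))
  parent <- remap(L0 + seq_len(K))
  edge <- rbind(cbind(parent, remap(rec$c1)), cbind(parent, remap(rec$c2)))
  tr <- structure(list(edge = edge,
                       edge.length = c(rec$l1, rec$l2),
                       tip.label = taxa,
                       Nnode = K),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "unit_tag") <- "coalescent"
  tr
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Uses the session RNG (call `set.seed()` for reproducibility); for batches
#' use [simulate_gene_trees()].
#'
#' @param species_tree Rooted binary `phylo` with internal branch lengths in
#'   coalescent units (terminal lengths are irrelevant with one allele).
#' @param alleles_per_species Gene copies sampled per species; with more
#'   than one, tips are labeled `species_i`.
#' @return A binary `phylo` gene tree on the sampled lineages, branch
#'   lengths in coalescent units.
#' @examples
#' set.seed(1)
#' simulate_gene_tree(parse_newick("((A:1,B:1):1,C:2);", "coalescent"))
#' @export
simulate_gene_tree <- function(species_tree, alleles_per_species = 1L) {
  pre <- prep_species_tree(species_tree, as.integer(alleles_per_species))
  build_gene_phylo(sim_core(pre), pre$taxa)
}

#' Simulate a set of gene trees under the multispecies coalescent
#'
#' @param species_tree Rooted binary `phylo`, internal branch lengths in
#'   coalescent units.
#' @param config A [sim_config()]; alternatively set `n_trees`/`seed`/
#'   `alleles_per_species` directly.
#' @param n_trees,seed,alleles_per_species Used when `config` is `NULL`.
#' @param keep_trees Keep the `phylo` objects (default). `FALSE` stores only
#'   clade bitmasks, which is all the quartet machinery needs and is
#'   substantially faster for large batches.
#' @return A [gene_tree_set()] of `n_trees` replicates; reproducible
#'   byte-for-byte under a fixed seed, and replicate `i` does not depend on
#'   `n_trees`.
#' @export
simulate_gene_trees <- function(species_tree, config = NULL,
                                n_trees = 20000L, seed = NULL,
                                alleles_per_species = 1L,
                                keep_trees = TRUE) {
  if (is.null(config))
    config <- sim_config(n_trees, seed, alleles_per_species)
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  if (is.null(config$seed))
    config$seed <- sample.int(.Machine$integer.max, 1L)
  pre <- prep_species_tree(species_tree, config$alleles_per_species)
  n <- config$n_trees
  trees <- if (keep_trees) vector("list", n) else NULL
  masks <- vector("list", n)
  fullm <- full_mask(length(pre$taxa))
  present <- rep(fullm, n)
  for (i in seq_len(n)) {
    set.seed(replicate_seed(config$seed, i))
    rec <- sim_core(pre)
    masks[[i]] <- rec$mask
    if (keep_trees) trees[[i]] <- build_gene_phylo(rec, pre$taxa)
  }
  out <- new_gene_tree_set(if (keep_trees) trees else
                             vector("list", n), pre$taxa, masks, present)
  attr(out, "config") <- config
  out
}

#' Rescale a mutation-unit species tree to coalescent units
#'
#' Internal coalescent length = mutation length / theta, the inverse of the
#' theta definition used throughout (theta = mutation units / coalescent
#' units, no factor of 2); terminal branches are set to 1. With a very small
#' theta (e.g. 0.001) this produces the no-ILS baseline: internal branches
#' become so long in coalescent units that deep coalescence vanishes.
#'
#' @param mutation_tree Rooted `phylo` with branch lengths in substitutions
#'   per site on every internal branch.
#' @param theta Positive scalar theta applied to every internal branch.
#' @return A `phylo` with `unit_tag = "coalescent"`.
#' @examples
#' coalescent_scale(parse_newick("((A:1,B:1)s:0.05,C:1);", "mutation"), 0.001)
#' @export
coalescent_scale <- function(mutation_tree, theta) {
  if (!inherits(mutation_tree, "phylo"))
    stop("`mutation_tree` must be a phylo object")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("`theta` must be a positive number")
  if (is.null(mutation_tree$edge.length))
    stop("mutation tree has no branch lengths")
  n <- length(mutation_tree$tip.label)
  tr <- mutation_tree
  internal <- tr$edge[, 2L] > n
  if (anyNA(tr$edge.length[internal]))
    stop("internal branch without length")
  tr$edge.length[internal] <- tr$edge.length[internal] / theta
  tr$edge.length[!internal] <- 1
  attr(tr, "unit_tag") <- "coalescent"
  tr
}
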