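# Per-branch theta estimation and the end-to-end ILS assessment:
# with-ILS simulation, no-ILS baseline, regression agreement, and
# minor-topology chi-square verdicts per focal branch.

# Unrooted internal-edge lengths keyed by canonical split mask. The two
# edges incident to the root induce the same bipartition; their lengths are
# summed, which is the unrooted length of that edge.
split_lengths <- function(tree, taxa) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  cl <- phylo_clades(tree, taxa)
  n <- length(tree$tip.label)
  out <- numeric(0)
  for (r in seq_len(nrow(tree$edge))) {
    child <- tree$edge[r, 2L]
    if (child <= n) next
    m <- canonical_mask(cl$all[child], cl$present)
    sz <- popcount(m)
    if (sz < 2L || sz > length(taxa) - 2L) next
    key <- as.character(m)
    out[key] <- if (key %in% names(out)) out[key] + tree$edge.length[r] else
      tree$edge.length[r]
  }
  out
}

#' Estimate theta per internal branch
#'
#' Theta for a branch is its length in mutation units (substitutions/site,
#' e.g. from a maximum-likelihood tree) divided by its length in coalescent
#' units (e.g. from a quartet-based species-tree method). High theta means a
#' large ancestral population and hence a high level of incomplete lineage
#' sorting. Branches are matched by bipartition, so the two trees may be
#' rooted differently; terminal branches carry no coalescent-unit
#' information and are excluded.
#'
#' @param mutation_tree `phylo` with mutation-unit branch lengths.
#' @param coalescent_tree `phylo` on the same taxa with coalescent-unit
#'   branch lengths.
#' @return A data frame of class `theta_estimate`: `split`,
#'   `mutation_length`, `coalescent_length`, `theta` (one row per shared
#'   internal branch; `theta = Inf` with a warning where the coalescent
#'   length is zero). Unmatched splits of either tree are reported in the
#'   `unmatched` attribute.
#' @examples
#' mu <- parse_newick("((A:1,B:1):0.05,(C:1,D:1):0.02);", "mutation")
#' cu <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.2);", "coalescent")
#' estimate_theta(mu, cu)
#' @export
estimate_theta <- function(mutation_tree, coalescent_tree) {
  if (!inherits(mutation_tree, "phylo") || !inherits(coalescent_tree, "phylo"))
    stop("both trees must be phylo objects")
  if (!setequal(mutation_tree$tip.label, coalescent_tree$tip.label))
    stop("trees are on different taxon sets")
  taxa <- check_taxa(mutation_tree$tip.label)
  mu <- split_lengths(mutation_tree, taxa)
  cu <- split_lengths(coalescent_tree, taxa)
  shared <- intersect(names(mu), names(cu))
  if (length(shared) == 0L) stop("no shared internal branch between the trees")
  unmatched <- list(mutation = setdiff(names(mu), shared),
                    coalescent = setdiff(names(cu), shared))
  if (length(unmatched$mutation) || length(unmatched$coalescent))
    message(length(unmatched$mutation) + length(unmatched$coalescent),
            " internal branch(es) present in only one tree; see attr 'unmatched'")
  m <- mu[shared]; k <- cu[shared]
  theta <- m / k
  if (any(k == 0)) {
    warning("zero coalescent length on ", sum(k == 0),
            " branch(es); theta reported as Inf")
    theta[k == 0] <- Inf
  }
  keys <- vapply(as.integer(shared), function(x)
    paste(mask_to_labels(x, taxa), collapse = ","), character(1))
  out <- data.frame(split = keys, mutation_length = unname(m),
                    coalescent_length = unname(k), theta = unname(theta),
                    stringsAsFactors = FALSE)
  structure(out, taxa = taxa,
            unmatched = lapply(unmatched, function(v)
              vapply(as.integer(v), function(x)
                paste(mask_to_labels(x, taxa), collapse = ","), character(1))),
            class = c("theta_estimate", "data.frame"))
}

#' Full ILS assessment of an empirical gene-tree set
#'
#' Reproduces the discordance-assessment procedure end to end:
#' \enumerate{
#'   \item simulate `config$n_trees` gene trees from the coalescent-unit
#'     species tree (the with-ILS expectation);
#'   \item rescale the mutation-unit tree with `theta_no_ils` (default
#'     0.001) via [coalescent_scale()] and simulate again (the no-ILS
#'     baseline);
#'   \item tabulate quartet frequencies for the empirical set and both
#'     simulations;
#'   \item regress each simulated table on the empirical one
#'     ([correlate_quartet_tables()]); comparable R-squared for the with-ILS
#'     simulation but not the baseline indicates discordance attributable
#'     to incomplete lineage sorting;
#'   \item per focal branch, chi-square the two minor-topology counts of
#'     the empirical set against the with-ILS simulation
#'     ([minor_topology_chisq()]); a non-significant test means ILS alone
#'     can explain the discordance around that branch. Raw p-values are
#'     reported with Benjamini-Hochberg adjusted companions.
#' }
#'
#' @param empirical A [gene_tree_set()].
#' @param mutation_tree Species tree with mutation-unit branch lengths.
#' @param coalescent_tree Species tree with coalescent-unit branch lengths.
#' @param config A [sim_config()] (a seed is required for reproducibility).
#' @param theta_no_ils Theta for the no-ILS baseline (default 0.001).
#' @param focal_branches List of splits (character vectors) for the
#'   chi-square tests; default: every internal branch of the coalescent
#'   tree that defines four groups.
#' @return A list of class `ils_report`: quartet tables (`empirical`,
#'   `with_ils`, `no_ils`), `r2_with_ils`, `r2_no_ils` (full regression
#'   summaries), `chisq` data frame, `theta` table, `branch_support`
#'   (with-ILS branch supports for the focal branches), and `config`.
#' @export
run_ils_assessment <- function(empirical, mutation_tree, coalescent_tree,
                               config = sim_config(),
                               theta_no_ils = 0.001,
                               focal_branches = NULL) {
  stopifnot(inherits(empirical, "gene_tree_set"))
  if (!setequal(coalescent_tree$tip.label, empirical$taxa))
    stop("coalescent tree taxa do not match the empirical reference taxa")
  if (!is.numeric(theta_no_ils) || theta_no_ils <= 0)
    stop("`theta_no_ils` must be positive")
  if (is.null(config$seed)) config <- sim_config(config$n_trees,
                                                 sample.int(1e6, 1L),
                                                 config$alleles_per_species)
  if (config$n_trees < 100L)
    warning("fewer than 100 simulated trees: quartet frequencies will be unstable")

  theta_tab <- estimate_theta(mutation_tree, coalescent_tree)

  sim_ils <- simulate_gene_trees(coalescent_tree, config, keep_trees = FALSE)
  no_ils_tree <- coalescent_scale(mutation_tree, theta_no_ils)
  cfg_no <- sim_config(config$n_trees, replicate_seed(config$seed, 104729L),
                       config$alleles_per_species)
  sim_no <- simulate_gene_trees(no_ils_tree, cfg_no, keep_trees = FALSE)

  qt_emp <- all_quartet_frequencies(empirical)
  qt_ils <- all_quartet_frequencies(sim_ils)
  qt_no <- all_quartet_frequencies(sim_no)

  r2_ils <- correlate_quartet_tables(qt_emp, qt_ils)
  r2_no <- correlate_quartet_tables(qt_emp, qt_no)

  taxa <- empirical$taxa
  if (is.null(focal_branches)) {
    focal_branches <- Filter(function(b) {
      cl <- phylo_clades(coalescent_tree, taxa)
      !inherits(tryCatch(branch_groups(coalescent_tree,
                                       canonical_mask(mask_from(b, taxa),
                                                      cl$present),
                                       taxa, cl),
                         error = function(e) e), "error")
    }, bipartitions(coalescent_tree))
  }
  chis <- lapply(focal_branches, function(br) {
    bs_emp <- branch_quartet_support(empirical, coalescent_tree, br)
    bs_sim <- branch_quartet_support(sim_ils, coalescent_tree, br)
    ct <- minor_topology_chisq(bs_emp$counts[c("alt13", "alt14")],
                               bs_sim$counts[c("alt13", "alt14")])
    list(split = paste(bs_emp$split, collapse = ","),
         chi_sq = ct$chi_sq, df = ct$df, p_value = ct$p_value,
         support = bs_emp)
  })
  chisq_df <- data.frame(
    split = vapply(chis, `[[`, character(1), "split"),
    chi_sq = vapply(chis, `[[`, numeric(1), "chi_sq"),
    df = vapply(chis, `[[`, integer(1), "df"),
    p_value = vapply(chis, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  chisq_df$p_adj_bh <- stats::p.adjust(chisq_df$p_value, method = "BH")

  structure(list(empirical = qt_emp, with_ils = qt_ils, no_ils = qt_no,
                 r2_with_ils = r2_ils, r2_no_ils = r2_no,
                 chisq = chisq_df, theta = theta_tab,
                 branch_support = lapply(chis, `[[`, "support"),
                 config = list(n_trees = config$n_trees, seed = config$seed,
                               theta_no_ils = theta_no_ils)),
            class = "ils_report")
}

#' @export
print.ils_report <- function(x, ...) {
  cat("ILS assessment (", x$config$n_trees, " simulated trees, seed ",
      x$config$seed, ")\n", sep = "")
  cat(sprintf("  R^2 with-ILS sim vs empirical: %.4f\n",
              x$r2_with_ils$r_squared))
  cat(sprintf("  R^2 no-ILS (theta = %g) vs empirical: %.4f\n",
              x$config$theta_no_ils, x$r2_no_ils$r_squared))
  cat("  theta range on shared branches: ",
      sprintf("%.3f - %.3f", min(x$theta$theta), max(x$theta$theta)), "\n")
  cat("  chi-square on minor topologies (", nrow(x$chisq), " focal branches):\n",
      sep = "")
  print(x$chisq, row.names = FALSE)
  invisible(x)
}

#' Write an ILS report to disk
#'
#' Emits deterministic TSVs (quartet tables, theta table, chi-square table)
#' plus a JSON summary, mirroring the CLI `ils-report` subcommand.
#'
#' @param report An `ils_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ils_report <- function(report, dir) {
  stopifnot(inherits(report, "ils_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(report$empirical, "quartets_empirical.tsv")
  wtsv(report$with_ils, "quartets_with_ils.tsv")
  wtsv(report$no_ils, "quartets_no_ils.tsv")
  wtsv(report$theta, "theta.tsv")
  wtsv(report$chisq, "chisq.tsv")
  summ <- list(config = report$config,
               r2_with_ils = report$r2_with_ils,
               r2_no_ils = report$r2_no_ils,
               theta = report$theta,
               chisq = report$chisq)
  jsonlite::write_json(summ, file.path(dir, "ils_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
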