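# Quartet-topology tabulation, branch quartet supports (q1,q2,q3),
# coalescent-unit estimation, regression agreement, minor-topology
# chi-square, and split support classification.

#' Tally the three resolutions of one quartet across gene trees
#'
#' @param gene_trees A [gene_tree_set()].
#' @param quartet Character vector of 4 distinct reference taxa.
#' @return Named integer vector `c(n1, n2, n3, unresolved, missing)` in the
#'   canonical resolution order of [quartet_resolutions()]; the components
#'   sum to the number of gene trees.
#' @export
count_quartet_topologies <- function(gene_trees, quartet) {
  stopifnot(inherits(gene_trees, "gene_tree_set"))
  q <- check_quartet(quartet)
  if (!all(q %in% gene_trees$taxa))
    stop("quartet taxa outside the reference set: ",
         paste(setdiff(q, gene_trees$taxa), collapse = ", "))
  geom <- quartet_geometry(matrix(q, nrow = 1L), gene_trees$taxa)
  tally <- integer(5L) # t1, t2, t3, unresolved, missing
  for (i in seq_along(gene_trees$masks)) {
    r <- resolve_quartets(geom, gene_trees$masks[[i]],
                          gene_trees$present[i])
    col <- if (r == -1L) 5L else if (r == 0L) 4L else r
    tally[col] <- tally[col] + 1L
  }
  names(tally) <- c("n1", "n2", "n3", "unresolved", "missing")
  tally
}

#' Quartet-topology frequencies for every four-taxon subset
#'
#' One row per `C(n, 4)` subset of the reference taxa, in lexicographic
#' order, with counts of the three canonical resolutions plus unresolved and
#' missing tallies. Resolved-only frequencies `f1..f3` use the denominator
#' `n1 + n2 + n3` (unresolved and missing trees carry no quartet signal).
#'
#' @param gene_trees A [gene_tree_set()].
#' @return A data frame of class `quartet_table` with columns
#'   `taxon_a..taxon_d`, `n1`, `n2`, `n3`, `unresolved`, `missing`,
#'   `f1`, `f2`, `f3`; attributes `taxa` and `n_trees`.
#' @export
all_quartet_frequencies <- function(gene_trees) {
  stopifnot(inherits(gene_trees, "gene_tree_set"))
  taxa <- gene_trees$taxa
  if (length(taxa) < 4L) stop("need at least 4 reference taxa")
  subsets <- t(utils::combn(taxa, 4L))
  geom <- quartet_geometry(subsets, taxa)
  nQ <- nrow(subsets)
  counts <- matrix(0L, nQ, 5L)
  for (i in seq_along(gene_trees$masks)) {
    r <- resolve_quartets(geom, gene_trees$masks[[i]],
                          gene_trees$present[i])
    col <- ifelse(r == -1L, 5L, ifelse(r == 0L, 4L, r))
    counts[cbind(seq_len(nQ), col)] <- counts[cbind(seq_len(nQ), col)] + 1L
  }
  res <- counts[, 1L] + counts[, 2L] + counts[, 3L]
  out <- data.frame(taxon_a = subsets[, 1L], taxon_b = subsets[, 2L],
                    taxon_c = subsets[, 3L], taxon_d = subsets[, 4L],
                    n1 = counts[, 1L], n2 = counts[, 2L], n3 = counts[, 3L],
                    unresolved = counts[, 4L], missing = counts[, 5L],
                    f1 = counts[, 1L] / res, f2 = counts[, 2L] / res,
                    f3 = counts[, 3L] / res,
                    stringsAsFactors = FALSE)
  structure(out, taxa = taxa, n_trees = length(gene_trees),
            class = c("quartet_table", "data.frame"))
}

# --- branch quartet support ----------------------------------------------

# The four taxon groups around an internal edge of a (rooted, binary)
# species tree, identified by its canonical split mask: the two child
# clades on one side and the two neighbor subtrees on the other.
branch_groups <- function(species_tree, split_mask, taxa, cl = NULL) {
  if (is.null(cl)) cl <- phylo_clades(species_tree, taxa)
  n <- length(species_tree$tip.label)
  e <- species_tree$edge
  parent <- integer(n + species_tree$Nnode)
  parent[e[, 2L]] <- e[, 1L]
  kids <- split(e[, 2L], factor(e[, 1L], levels = seq_len(length(parent))))
  full <- cl$present
  comp <- bitwAnd(bitwXor(split_mask, full), full)
  nodes <- (n + 1L):(n + species_tree$Nnode)
  hit <- nodes[cl$all[nodes] == split_mask | cl$all[nodes] == comp]
  hit <- setdiff(hit, cl$root)
  if (length(hit) == 0L)
    stop("split is not an internal edge of the species tree")
  v <- hit[1L]
  u <- parent[v]
  g12 <- cl$all[kids[[v]]]
  if (u == cl$root) {
    w <- setdiff(kids[[u]], v)
    if (w <= n) stop("split is trivial on this species tree")
    g34 <- cl$all[kids[[w]]]
  } else {
    sib <- setdiff(kids[[u]], v)
    g34 <- c(cl$all[sib], bitwAnd(bitwXor(cl$all[u], full), full))
  }
  if (any(c(g12, g34) == 0L)) stop("degenerate branch groups")
  list(g1 = g12[1L], g2 = g12[2L], g3 = g34[1L], g4 = g34[2L])
}

bits_of <- function(mask, taxa) mask_to_labels(mask, taxa)

#' Quartet support (q1, q2, q3) for an internal species-tree branch
#'
#' Around the branch, four taxon groups are defined (the two child clades
#' and the two neighbor subtrees); every quartet taking one taxon per group
#' is tallied across all gene trees and the resolved counts pooled with
#' equal weight per (tree, quartet) pair. `q1` is the pooled frequency of
#' the species-tree resolution; `q2 >= q3` are the two alternatives ranked
#' by pooled count. Per-gene-tree averaging is available via
#' `weighting = "per_tree"`, which averages each tree's resolved-quartet
#' frequencies before pooling.
#'
#' Under the multispecies coalescent, `q1` for a branch of length `t`
#' coalescent units has expectation `1 - (2/3) exp(-t)`.
#'
#' @param gene_trees A [gene_tree_set()].
#' @param species_tree Rooted binary `phylo` on the reference taxa.
#' @param branch A split: character vector naming one block of the
#'   bipartition (an element of [bipartitions()] of the species tree).
#' @param weighting `"pooled"` (default) or `"per_tree"`.
#' @return A list of class `branch_support`: `split`, `q1`, `q2`, `q3`,
#'   `counts` (pooled counts: species resolution, the two alternatives in
#'   the fixed g1-with-g3 / g1-with-g4 order), `est_cu` (coalescent-unit
#'   estimate from `q1`), `n_quartets`.
#' @export
branch_quartet_support <- function(gene_trees, species_tree, branch,
                                   weighting = c("pooled", "per_tree")) {
  stopifnot(inherits(gene_trees, "gene_tree_set"))
  weighting <- match.arg(weighting)
  taxa <- gene_trees$taxa
  if (!setequal(species_tree$tip.label, taxa))
    stop("species tree taxa must match the gene-tree reference taxa")
  cl <- phylo_clades(species_tree, taxa)
  smask <- canonical_mask(mask_from(branch, taxa), cl$present)
  gr <- branch_groups(species_tree, smask, taxa, cl)
  combos <- expand.grid(a = bits_of(gr$g1, taxa), b = bits_of(gr$g2, taxa),
                        c = bits_of(gr$g3, taxa), d = bits_of(gr$g4, taxa),
                        stringsAsFactors = FALSE)
  qm <- t(apply(as.matrix(combos), 1L, sort))
  geom <- quartet_geometry(qm, taxa)
  # For each quartet, which canonical index is the species resolution
  # (a with b), and which are the two cross pairings (a-c, a-d)?
  ab <- mask_from_pair(combos$a, combos$b, taxa)
  ac <- mask_from_pair(combos$a, combos$c, taxa)
  ad <- mask_from_pair(combos$a, combos$d, taxa)
  idx_of <- function(pair) {
    hit <- cbind(geom$p[, 1L] == pair | geom$pc[, 1L] == pair,
                 geom$p[, 2L] == pair | geom$pc[, 2L] == pair,
                 geom$p[, 3L] == pair | geom$pc[, 3L] == pair)
    max.col(hit, ties.method = "first")
  }
  map <- cbind(idx_of(ab), idx_of(ac), idx_of(ad)) # cols: species, alt13, alt14
  nQ <- nrow(qm)
  pooled <- c(species = 0, alt13 = 0, alt14 = 0)
  for (i in seq_along(gene_trees$masks)) {
    r <- resolve_quartets(geom, gene_trees$masks[[i]],
                          gene_trees$present[i])
    ok <- r > 0L
    if (!any(ok)) next
    hits <- c(sum(r[ok] == map[ok, 1L]), sum(r[ok] == map[ok, 2L]),
              sum(r[ok] == map[ok, 3L]))
    if (weighting == "per_tree") hits <- hits / sum(ok)
    pooled <- pooled + hits
  }
  tot <- sum(pooled)
  if (tot == 0) stop("no resolved quartets for this branch")
  q1 <- pooled[["species"]] / tot
  alts <- sort(c(pooled[["alt13"]], pooled[["alt14"]]) / tot,
               decreasing = TRUE)
  structure(list(split = mask_to_labels(smask, taxa),
                 q1 = q1, q2 = alts[1L], q3 = alts[2L],
                 counts = pooled,
                 est_cu = coalescent_length_from_support(q1),
                 n_quartets = nQ),
            class = "branch_support")
}

mask_from_pair <- function(a, b, taxa) {
  bitwOr(taxa_bits(a, taxa), taxa_bits(b, taxa))
}

#' @export
print.branch_support <- function(x, ...) {
  cat("branch:", paste(x$split, collapse = ","), "| rest\n")
  cat(sprintf("  q1 = %.4f  q2 = %.4f  q3 = %.4f  (est. %.3f coalescent units)\n",
              x$q1, x$q2, x$q3, x$est_cu))
  invisible(x)
}

#' Coalescent-unit branch length from quartet support
#'
#' Inverts the multispecies-coalescent expectation
#' `q1 = 1 - (2/3) exp(-t)`: `t = -log((3/2) (1 - q1))`, clipped to 0 when
#' `q1 <= 1/3` and capped at `ceiling` as `q1` approaches 1 (the estimator
#' diverges there; 10 units is far beyond any signal estimable from 20,000
#' trees).
#'
#' @param q1 Frequency (or vector of frequencies) in `[0, 1]`.
#' @param ceiling Cap for the estimate (default 10).
#' @return Estimated branch length(s) in coalescent units.
#' @examples
#' coalescent_length_from_support(c(1 / 3, 0.7547, 1))
#' @export
coalescent_length_from_support <- function(q1, ceiling = 10) {
  if (!is.numeric(q1) || any(!is.finite(q1)) || any(q1 < 0 | q1 > 1))
    stop("`q1` must be numeric in [0, 1]")
  t <- -log(1.5 * (1 - q1))
  pmin(pmax(t, 0), ceiling)
}

#' Regression agreement between two quartet-frequency tables
#'
#' Flattens each table's resolved-only frequencies (three per subset) and
#' fits ordinary least squares of `table_b`'s frequencies on `table_a`'s
#' via `stats::lm()`. Subsets with no resolved tree in either table are
#' dropped with a warning.
#'
#' @param table_a,table_b `quartet_table` objects over the same taxa (same
#'   subset ordering).
#' @return List: `r_squared`, `slope`, `intercept`, `p_value` (two-sided,
#'   slope), `n` (points used).
#' @export
correlate_quartet_tables <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "quartet_table"),
            inherits(table_b, "quartet_table"))
  if (!identical(attr(table_a, "taxa"), attr(table_b, "taxa")))
    stop("tables are over different taxon sets")
  x <- as.vector(t(as.matrix(table_a[, c("f1", "f2", "f3")])))
  y <- as.vector(t(as.matrix(table_b[, c("f1", "f2", "f3")])))
  drop <- is.na(x) | is.na(y)
  if (any(drop)) {
    warning(sum(drop) / 3, " subset(s) without resolved trees dropped")
    x <- x[!drop]; y <- y[!drop]
  }
  if (length(x) < 3L) stop("too few points for regression")
  if (stats::var(x) == 0) stop("zero variance in predictor frequencies")
  fit <- stats::lm(y ~ x)
  # a perfect fit (self-correlation) trips a harmless summary.lm warning
  sm <- suppressWarnings(summary(fit))
  list(r_squared = sm$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = unname(sm$coefficients[2L, 4L]),
       n = length(x))
}

#' Chi-square test on the two minor-topology counts
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' with rows = dataset (empirical, simulated) and columns = the two minor
#' quartet topologies around a focal branch. A zero column with non-zero
#' rows contributes 0 (the 0/0 convention); a zero row is an error.
#'
#' @param empirical,simulated Length-2 non-negative counts
#'   `(minor1, minor2)`, the same column identities in both.
#' @return List: `chi_sq`, `df`, `p_value`, `table`.
#' @examples
#' minor_topology_chisq(c(30, 20), c(25, 25))
#' @export
minor_topology_chisq <- function(empirical, simulated) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || any(x < 0))
      stop("`", nm, "` must be 2 non-negative counts")
    if (sum(x) == 0) stop("`", nm, "` has no classified trees")
    x
  }
  O <- rbind(empirical = chk(empirical, "empirical"),
             simulated = chk(simulated, "simulated"))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  term <- (O - E)^2 / E
  term[E == 0] <- 0
  chi <- sum(term)
  list(chi_sq = chi, df = 1L,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       table = O)
}

#' Classify per-gene-tree support for a split
#'
#' For each gene tree (restricted to the split's taxa that are present):
#' \describe{
#'   \item{strongly_supported}{the split is an edge of the tree with
#'     support at or above `threshold`}
#'   \item{weakly_supported}{an edge, but below `threshold`}
#'   \item{weakly_rejected}{absent, yet compatible with the tree once all
#'     edges below `threshold` are contracted}
#'   \item{strongly_rejected}{absent and in conflict with a
#'     high-support edge}
#' }
#' Trees on which the restricted split is trivial (fewer than two taxa on a
#' side) are uninformative and excluded from the proportions.
#'
#' @param gene_trees A [gene_tree_set()] whose trees carry support values.
#' @param split Character vector naming one block of the bipartition of the
#'   reference taxa.
#' @param threshold Support threshold in percent (default 75).
#' @param missing_support What to do with edges lacking a numeric support:
#'   `"error"` (default, if a tree has none at all) or `"high"` (treat as
#'   maximally supported).
#' @return List of class `split_support_summary`: `categories` (per tree;
#'   `NA` where uninformative), `proportions` (over categorized trees),
#'   `n_categorized`.
#' @export
classify_split_support <- function(gene_trees, split, threshold = 75,
                                   missing_support = c("error", "high")) {
  stopifnot(inherits(gene_trees, "gene_tree_set"))
  missing_support <- match.arg(missing_support)
  taxa <- gene_trees$taxa
  target <- mask_from(split, taxa)
  if (popcount(target) < 2L || popcount(target) > length(taxa) - 2L)
    stop("split is trivial on the reference taxa")
  trees <- gts_trees(gene_trees)
  lv <- c("strongly_supported", "weakly_supported",
          "weakly_rejected", "strongly_rejected")
  out <- rep(NA_character_, length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    cl <- phylo_clades(tr, taxa)
    present <- cl$present
    tp <- bitwAnd(target, present)
    cp <- bitwAnd(bitwXor(tp, present), present)
    if (popcount(tp) < 2L || popcount(cp) < 2L) next
    sup <- tree_support(tr)
    if (all(is.na(sup)) && missing_support == "error")
      stop("tree ", i, " carries no numeric support values; ",
           "set missing_support = \"high\" to treat edges as supported")
    sup[is.na(sup)] <- 100 # isolated unlabeled edges count as supported
    n <- length(tr$tip.label)
    nodes <- seq_along(cl$clades)
    is_root <- (n + nodes) == cl$root
    masks <- cl$clades[!is_root]
    esup <- sup[!is_root]
    sz <- popcount(masks)
    keep <- sz >= 2L & sz <= popcount(present) - 2L
    masks <- masks[keep]; esup <- esup[keep]
    hit <- masks == tp | masks == cp
    if (any(hit)) {
      out[i] <- if (max(esup[hit]) >= threshold) lv[1L] else lv[2L]
    } else {
      high <- masks[esup >= threshold]
      compat <- TRUE
      for (s in high) {
        sc <- bitwAnd(bitwXor(s, present), present)
        if (bitwAnd(tp, s) != 0L && bitwAnd(tp, sc) != 0L &&
            bitwAnd(cp, s) != 0L && bitwAnd(cp, sc) != 0L) {
          compat <- FALSE
          break
        }
      }
      out[i] <- if (compat) lv[3L] else lv[4L]
    }
  }
  cats <- factor(out, levels = lv)
  nc <- sum(!is.na(cats))
  structure(list(categories = out,
                 proportions = if (nc > 0) table(cats) / nc else table(cats),
                 n_categorized = nc),
            class = "split_support_summary")
}
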