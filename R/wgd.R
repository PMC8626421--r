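# Polyploidy evidence: shared-vs-independent WGD/WGT classification of
# copy-labeled collinear gene trees, Ks block medians and Gaussian-mixture
# peak fitting, and LTR insertion-time dating.

copy_tips <- function(tree, species) {
  hits <- grep(paste0("^", species, "[0-9]+$"), tree$tip.label, value = TRUE)
  hits[order(hits)]
}

#' Classify a copy-labeled collinear gene tree
#'
#' Tips carry species-plus-copy labels (`A1`, `A2`, `B1`, `B2`, ...). With
#' two copies per species the unrooted quartet on the four copies decides
#' the verdict: copies of the same species sister
#' (`((A1,A2),(B1,B2))`) means each species duplicated after their
#' divergence (`independent`); either cross-species pairing places one
#' duplication in the common ancestor (`shared`); an unresolved quartet is
#' `other`. With three copies each (a whole-genome triplication) the
#' verdict is `independent` iff each species' copies form a clade on the
#' induced six-tip subtree; a resolved subtree violating that is `shared`,
#' an unresolved one `other`. Copies of other species in the tree are
#' ignored. The verdict is invariant to rooting and to swapping the two
#' species.
#'
#' @param tree A `phylo` whose tips include the copies of both species.
#' @param species_a,species_b Species label prefixes.
#' @return `"independent"`, `"shared"` or `"other"`.
#' @examples
#' classify_copy_tree(parse_newick("((A1,A2),(B1,B2));"), "A", "B")
#' classify_copy_tree(parse_newick("((A1,B1),(A2,B2));"), "A", "B")
#' @export
classify_copy_tree <- function(tree, species_a, species_b) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  ca <- copy_tips(tree, species_a)
  cb <- copy_tips(tree, species_b)
  if (length(ca) < 2L)
    stop("missing copies for species ", species_a,
         " (found: ", paste(ca, collapse = ", "), ")")
  if (length(cb) < 2L)
    stop("missing copies for species ", species_b,
         " (found: ", paste(cb, collapse = ", "), ")")
  if (length(ca) != length(cb))
    stop("unequal copy counts: ", length(ca), " vs ", length(cb))
  keep <- c(ca, cb)
  taxa <- check_taxa(tree$tip.label)
  cl <- phylo_clades(tree, taxa)
  km <- mask_from(keep, taxa)
  am <- mask_from(ca, taxa)
  # restricted splits of the tree on the copy tips
  sub <- bitwAnd(cl$clades, km)
  sz <- popcount(sub)
  nontriv <- sub[sz >= 2L & sz <= length(keep) - 2L]
  nontriv <- unique(canonical_mask(nontriv, km))
  species_split <- canonical_mask(am, km)
  if (species_split %in% nontriv) return("independent")
  if (length(ca) == 2L) {
    # three possible quartet splits; any other nontrivial split is cross
    if (length(nontriv) > 0L) return("shared")
    return("other")
  }
  # WGT (3+3): not independent; shared only if the subtree is fully
  # resolved (3 internal edges on 6 tips), otherwise undecidable
  if (length(nontriv) == 3L) "shared" else "other"
}

#' Proportion of collinear gene trees supporting an independent WGD
#'
#' @param trees List of copy-labeled `phylo` trees (or a
#'   [gene_tree_set()]).
#' @param species_a,species_b Species label prefixes.
#' @return List: `proportion` = independent / (independent + shared),
#'   `counts` (named: independent, shared, other).
#' @export
independent_wgd_proportion <- function(trees, species_a, species_b) {
  if (inherits(trees, "gene_tree_set")) trees <- gts_trees(trees)
  if (!is.list(trees) || length(trees) == 0L)
    stop("`trees` must be a non-empty list")
  v <- vapply(trees, classify_copy_tree, character(1),
              species_a = species_a, species_b = species_b)
  counts <- c(independent = sum(v == "independent"),
              shared = sum(v == "shared"),
              other = sum(v == "other"))
  cls <- counts[["independent"]] + counts[["shared"]]
  if (cls == 0L) stop("no classifiable trees (all verdicts 'other')")
  list(proportion = counts[["independent"]] / cls, counts = counts)
}

#' Per-block median Ks
#'
#' Whole-genome duplications leave collinear blocks of paralogs; the median
#' Ks of each block is a robust per-block age signal used for peak fitting.
#' Medians use the midpoint rule for even counts.
#'
#' @param blocks Either a data frame with columns `block_id` and `ks`, or a
#'   named list of numeric Ks vectors.
#' @return Named numeric vector of block medians.
#' @export
block_median_ks <- function(blocks) {
  if (is.data.frame(blocks)) {
    if (!all(c("block_id", "ks") %in% names(blocks)))
      stop("data frame must have columns `block_id` and `ks`")
    blocks <- split(blocks$ks, blocks$block_id)
  }
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("`blocks` must be a non-empty list or data frame")
  vapply(seq_along(blocks), function(i) {
    v <- blocks[[i]]
    if (length(v) == 0L || all(is.na(v)))
      stop("block ", names(blocks)[i], " is empty")
    if (any(v < 0, na.rm = TRUE)) stop("negative Ks in block ", names(blocks)[i])
    stats::median(v, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE) -> med
  names(med) <- names(blocks)
  med
}

#' Fit a Gaussian mixture to Ks values by expectation-maximization
#'
#' Values are truncated to `(0, max_ks]` before fitting. Components are
#' initialized from evenly spaced sample quantiles, iterated to a relative
#' log-likelihood tolerance of `tol`, and returned sorted by mean, so the
#' fit is deterministic. The peak of the distribution is the mean of the
#' heaviest component ([ks_peak()]).
#'
#' @param values Numeric Ks values (synonymous substitutions per
#'   synonymous site).
#' @param k Number of components (>= 1); at least `10 * k` values must
#'   survive truncation.
#' @param max_ks Truncation ceiling (default 5; saturation makes larger Ks
#'   uninformative).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return A list of class `ks_mixture_fit`: `weights`, `means`, `sds`,
#'   `loglik`, `loglik_trace`, `converged`, `n_iter`, `bic`, `k`, `n`.
#' @export
fit_ks_mixture <- function(values, k, max_ks = 5, tol = 1e-6,
                           max_iter = 500L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stop("`k` must be a positive integer")
  k <- as.integer(k)
  if (!is.numeric(values)) stop("`values` must be numeric")
  x <- values[is.finite(values) & values > 0 & values <= max_ks]
  n <- length(x)
  if (n < 10L * k)
    stop("insufficient data: ", n, " values after truncation, need ",
         10L * k)
  w <- rep(1 / k, k)
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k))
  sd0 <- stats::sd(x)
  if (sd0 == 0) stop("Ks values are constant; nothing to fit")
  sg <- rep(max(sd0 / k, 1e-3), k)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (1 + abs(ll_old))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (matrix(x, n, k) -
                                 matrix(mu, n, k, byrow = TRUE))^2) / nk)
    sg[sg < 1e-4] <- 1e-4 # guard against component collapse
  }
  ord <- order(mu)
  fit <- list(weights = w[ord], means = mu[ord], sds = sg[ord],
              loglik = trace[length(trace)], loglik_trace = trace,
              converged = converged, n_iter = it,
              bic = -2 * trace[length(trace)] + (3 * k - 1) * log(n),
              k = k, n = n)
  class(fit) <- "ks_mixture_fit"
  fit
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit to", x$n, "Ks values (k =", x$k, ")\n")
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  cat(sprintf("  logLik %.2f, BIC %.2f, %s in %d iterations\n",
              x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  Ks peak (heaviest component): %.3f\n", ks_peak(x)))
  invisible(x)
}

#' Ks peak of a fitted mixture
#'
#' @param fit A `ks_mixture_fit`.
#' @return Mean of the component with the largest weight.
#' @export
ks_peak <- function(fit) {
  stopifnot(inherits(fit, "ks_mixture_fit"))
  fit$means[which.max(fit$weights)]
}

#' Date an LTR retrotransposon insertion with a molecular clock
#'
#' The two long terminal repeats of a retrotransposon are identical at
#' insertion and diverge afterwards, so `T = K / (2 r)` with `K` the
#' divergence between them and `r` the mutation rate of repeat sequences.
#'
#' @param K Divergence per site between the two LTRs (>= 0; vectorized).
#' @param r Mutation rate per site per year (default `3.8e-9`, twice the
#'   `1.9e-9` synonymous coding rate, reflecting the faster evolution of
#'   repeats).
#' @return Insertion time in years.
#' @examples
#' ltr_insertion_time(0.0076) # 1 Myr at the default rate
#' @export
ltr_insertion_time <- function(K, r = 3.8e-9) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K < 0))
    stop("`K` must be non-negative divergence per site")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a positive mutation rate")
  K / (2 * r)
}

#' Synonymous-rate constants
#'
#' Default molecular-clock rates: `coding` for synonymous sites of
#' single-copy genes, `repeat_seq` (2x) for repeat sequences.
#'
#' @return Named numeric vector (per site per year).
#' @export
clock_rates <- function() c(coding = 1.9e-9, repeat_seq = 3.8e-9)
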