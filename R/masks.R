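# Internal bitmask machinery for splits and quartets.
#
# Every taxon set is a fixed, sorted character vector; a set of taxa is an
# integer with bit i-1 set iff taxa[i] is in the set. This caps the package
# at 30 taxa (31-bit signed integers), which comfortably covers the
# genome-scale datasets this toolkit targets; larger sets error early.

MAX_TAXA <- 30L

check_taxa <- function(taxa) {
  if (!is.character(taxa) || length(taxa) < 1L)
    stop("taxon set must be a non-empty character vector")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (any(!nzchar(taxa))) stop("empty taxon labels are not allowed")
  if (length(taxa) > MAX_TAXA)
    stop("at most ", MAX_TAXA, " taxa are supported (got ", length(taxa), ")")
  sort(taxa)
}

taxa_bits <- function(labels, taxa) {
  i <- match(labels, taxa)
  if (anyNA(i))
    stop("unknown taxa: ", paste(labels[is.na(i)], collapse = ", "))
  bitwShiftL(1L, i - 1L)
}

mask_from <- function(labels, taxa) {
  if (length(labels) == 0L) return(0L)
  Reduce(bitwOr, taxa_bits(labels, taxa), 0L)
}

mask_to_labels <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

full_mask <- function(n) bitwShiftL(1L, n) - 1L

popcount <- function(x) {
  x <- as.integer(x)
  r <- integer(length(x))
  while (any(x != 0L)) {
    r <- r + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  r
}

# Canonical orientation of a split mask relative to the taxa actually present
# (scalar `present`): keep the side containing the lowest-numbered present taxon.
canonical_mask <- function(mask, present) {
  low <- bitwAnd(present, -present) # lowest set bit of `present`
  flip <- bitwAnd(mask, low) == 0L
  mask[flip] <- bitwAnd(bitwXor(mask[flip], present), present)
  mask
}

# Nontrivial canonical splits (sizes 2..n-2 of the present set), deduplicated.
canonical_splits <- function(masks, present) {
  m <- canonical_mask(bitwAnd(masks, present), present)
  np <- popcount(present)
  sz <- popcount(m)
  sort(unique(m[sz >= 2L & sz <= np - 2L]))
}

split_key <- function(mask, taxa) {
  vapply(mask, function(m) paste(mask_to_labels(m, taxa), collapse = ","),
         character(1))
}

# Clade masks of a phylo object over a reference taxon ordering.
# Returns list(all = mask per node, clades = masks of internal nodes,
#              present = mask of tips present, root = root node id).
phylo_clades <- function(tree, taxa) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  m <- integer(nn)
  m[seq_len(n)] <- taxa_bits(tree$tip.label, taxa)
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e)))
    m[e[i, 1L]] <- bitwOr(m[e[i, 1L]], m[e[i, 2L]])
  root <- e[nrow(e), 1L]
  list(all = m, clades = m[(n + 1L):nn], present = m[root], root = root)
}

# --- quartet resolution machinery ---------------------------------------
#
# A quartet over sorted taxa (a < b < c < d) has three canonical resolutions:
#   1: ab|cd   2: ac|bd   3: ad|bc
# (ordered by the sister pair containing the alphabetically smallest taxon).
# A clade mask s resolves quartet q as topology k iff s restricted to q
# equals the k-th pair mask or its complement within q.

quartet_geometry <- function(quartets, taxa) {
  # quartets: 4-column character matrix, each row sorted
  bits <- matrix(taxa_bits(as.vector(quartets), taxa), ncol = 4L)
  q <- bits[, 1L] + bits[, 2L] + bits[, 3L] + bits[, 4L]
  p1 <- bitwOr(bits[, 1L], bits[, 2L])
  p2 <- bitwOr(bits[, 1L], bits[, 3L])
  p3 <- bitwOr(bits[, 1L], bits[, 4L])
  list(q = as.integer(q), p = cbind(p1, p2, p3),
       pc = cbind(bitwXor(q, p1), bitwXor(q, p2), bitwXor(q, p3)))
}

# Resolve all quartets in `geom` against one tree's clade masks.
# Returns integer vector: 1/2/3 resolution, 0 unresolved, -1 missing taxa.
resolve_quartets <- function(geom, clade_masks, present) {
  res <- integer(length(geom$q))
  for (s in clade_masks) {
    x <- bitwAnd(s, geom$q)
    res[x == geom$p[, 1L] | x == geom$pc[, 1L]] <- 1L
    res[x == geom$p[, 2L] | x == geom$pc[, 2L]] <- 2L
    res[x == geom$p[, 3L] | x == geom$pc[, 3L]] <- 3L
  }
  res[bitwAnd(present, geom$q) != geom$q] <- -1L
  res
}
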