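# Tree data model: newick I/O, unit tags, splits, induced quartets.

UNIT_TAGS <- c("coalescent", "mutation", "none")

#' Parse a newick string into a phylogenetic tree
#'
#' Trees are represented as [ape::phylo] objects carrying two extras: a
#' `unit_tag` attribute recording what the branch lengths mean
#' (`"coalescent"`, `"mutation"` or `"none"`), and numeric internal-node
#' labels interpreted as support values. Support values in `(0, 1]` (e.g.
#' ASTRAL local posteriors) are rescaled to the `[0, 100]` bootstrap scale on
#' read, so that percentage thresholds apply uniformly. Non-numeric internal
#' labels are kept verbatim but ignored by all support-aware operations.
#'
#' @param text A single newick statement terminated by `";"`.
#' @param unit_tag Branch-length unit: `"coalescent"`, `"mutation"` or
#'   `"none"` (default).
#' @return A `phylo` object with attribute `unit_tag`.
#' @examples
#' tr <- parse_newick("((A,B)95:0.1,(C,D)88:0.2);")
#' tree_support(tr)
#' @export
parse_newick <- function(text, unit_tag = "none") {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single character string")
  unit_tag <- match.arg(unit_tag, UNIT_TAGS)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  if (!grepl(";\\s*$", text)) stop("newick string must end with ';'")
  parens <- strsplit(gsub("[^()]", "", text), "", fixed = FALSE)[[1]]
  depth <- 0L
  for (ch in parens) {
    depth <- depth + if (ch == "(") 1L else -1L
    if (depth < 0L) stop("unbalanced parentheses: unmatched ')'")
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unmatched '('")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("failed to parse newick string: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label))) stop("empty tip label")
  if (!is.null(tr$edge.length)) {
    el <- tr$edge.length
    if (any(!is.na(el) & !is.finite(el)))
      stop("non-finite branch length")
    if (any(el < 0, na.rm = TRUE))
      stop("negative branch length: ", format(min(el, na.rm = TRUE)))
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    resc <- !is.na(sup) & sup > 0 & sup <= 1
    sup[resc] <- sup[resc] * 100
    if (any(!is.na(sup) & (sup < 0 | sup > 100)))
      stop("support values must lie in [0, 100] (or (0, 1], rescaled)")
    keep <- !is.na(sup)
    tr$node.label[keep] <- formatC(sup[keep], format = "g", digits = 15)
  }
  attr(tr, "unit_tag") <- unit_tag
  tr
}

#' Serialize a tree to newick
#'
#' Inverse of [parse_newick()]: topology, branch lengths (to ~1e-9) and
#' support labels round-trip.
#'
#' @param tree A `phylo` object.
#' @return A newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (length(tree$tip.label) < 1L) stop("empty tree")
  ape::write.tree(tree, digits = 12)
}

#' Branch-length unit tag of a tree
#'
#' @param tree A `phylo` object.
#' @return `"coalescent"`, `"mutation"` or `"none"`.
#' @export
unit_tag <- function(tree) {
  u <- attr(tree, "unit_tag")
  if (is.null(u)) "none" else u
}

#' @rdname unit_tag
#' @param value New unit tag.
#' @export
`unit_tag<-` <- function(tree, value) {
  attr(tree, "unit_tag") <- match.arg(value, UNIT_TAGS)
  tree
}

#' Numeric support values per internal node
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (NA where no numeric label).
#' @export
tree_support <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' One split per internal edge; trivial splits (one taxon versus the rest)
#' are excluded, and the two root edges of a rooted tree (which induce the
#' same bipartition) are reported once. Each split is returned as the block
#' containing the alphabetically smallest taxon.
#'
#' @param tree A `phylo` object.
#' @return A list of character vectors (one block per split), with attribute
#'   `taxa` giving the full taxon set. Fewer than 4 tips gives an empty list.
#' @examples
#' bipartitions(parse_newick("((((A,B),C),D),E);"))
#' @export
bipartitions <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  taxa <- check_taxa(tree$tip.label)
  if (length(taxa) < 4L)
    return(structure(list(), taxa = taxa))
  cl <- phylo_clades(tree, taxa)
  masks <- canonical_splits(cl$clades, cl$present)
  structure(lapply(masks, mask_to_labels, taxa = taxa), taxa = taxa)
}

#' Canonical resolutions of a four-taxon set
#'
#' @param quartet Character vector of 4 distinct taxon labels.
#' @return Character vector of the three resolutions in canonical order
#'   (sister pair containing the smallest taxon: `ab|cd`, `ac|bd`, `ad|bc`),
#'   formatted as `"X,Y|Z,W"` with sorted blocks.
#' @export
quartet_resolutions <- function(quartet) {
  q <- check_quartet(quartet)
  fmt <- function(p, o) paste0(paste(p, collapse = ","), "|",
                               paste(o, collapse = ","))
  c(fmt(q[c(1, 2)], q[c(3, 4)]),
    fmt(q[c(1, 3)], q[c(2, 4)]),
    fmt(q[c(1, 4)], q[c(2, 3)]))
}

check_quartet <- function(quartet) {
  if (!is.character(quartet) || length(quartet) != 4L)
    stop("`quartet` must be a character vector of 4 taxon labels")
  if (anyDuplicated(quartet))
    stop("duplicate taxa in quartet: ",
         paste(unique(quartet[duplicated(quartet)]), collapse = ", "))
  sort(quartet)
}

#' Quartet topology induced by a tree
#'
#' Restricts the (unrooted) tree to four taxa and reports the induced
#' resolution. Rooting does not affect the result.
#'
#' @param tree A `phylo` object.
#' @param quartet Character vector of 4 distinct taxon labels.
#' @return One of the three strings from [quartet_resolutions()],
#'   `"unresolved"` (the restriction is a star) or `"missing"` (a taxon is
#'   absent from the tree).
#' @examples
#' induced_quartet_topology(parse_newick("((A,B),((C,D),E));"),
#'                          c("A", "C", "D", "E"))
#' @export
induced_quartet_topology <- function(tree, quartet) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  q <- check_quartet(quartet)
  taxa <- check_taxa(unique(c(tree$tip.label, q)))
  cl <- phylo_clades(tree, taxa)
  geom <- quartet_geometry(matrix(q, nrow = 1L), taxa)
  r <- resolve_quartets(geom, cl$clades, cl$present)
  if (r == -1L) return("missing")
  if (r == 0L) return("unresolved")
  quartet_resolutions(q)[r]
}

#' Collection of gene trees over a common reference taxon set
#'
#' The container every concordance statistic consumes. Trees may cover
#' subsets of the reference taxa. Internally each tree is reduced to its
#' clade bitmasks once, so repeated quartet tabulations are cheap; the
#' `phylo` objects themselves are kept unless the set was built
#' topology-only (see [simulate_gene_trees()]).
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param taxa Reference taxon set; defaults to the union of tip labels.
#' @return An object of class `gene_tree_set`.
#' @export
gene_tree_set <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!is.list(trees) || length(trees) == 0L)
    stop("`trees` must be a non-empty list of phylo objects")
  ok <- vapply(trees, inherits, logical(1), what = "phylo")
  if (!all(ok)) stop("element ", which(!ok)[1], " is not a phylo object")
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  taxa <- check_taxa(taxa)
  for (i in seq_along(trees)) {
    extra <- setdiff(trees[[i]]$tip.label, taxa)
    if (length(extra))
      stop("tree ", i, " has tips outside the reference taxa: ",
           paste(extra, collapse = ", "))
  }
  masks <- vector("list", length(trees))
  present <- integer(length(trees))
  for (i in seq_along(trees)) {
    cl <- phylo_clades(trees[[i]], taxa)
    masks[[i]] <- cl$clades
    present[i] <- cl$present
  }
  new_gene_tree_set(trees, taxa, masks, present)
}

new_gene_tree_set <- function(trees, taxa, masks, present) {
  structure(list(trees = trees, taxa = taxa, masks = masks,
                 present = present),
            class = "gene_tree_set")
}

#' @export
length.gene_tree_set <- function(x) length(x$masks)

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("gene_tree_set:", length(x), "trees over",
      length(x$taxa), "reference taxa\n")
  cat("  taxa:", paste(utils::head(x$taxa, 8), collapse = ", "),
      if (length(x$taxa) > 8) "..." else "", "\n")
  if (is.null(x$trees[[1]]))
    cat("  (topology-only: clade masks kept, phylo objects dropped)\n")
  invisible(x)
}

gts_trees <- function(gts) {
  if (is.null(gts$trees) || is.null(gts$trees[[1]]))
    stop("this gene_tree_set is topology-only; rebuild with keep_trees = TRUE")
  gts$trees
}

#' Read gene trees from a newick file
#'
#' One tree per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param taxa Optional reference taxon set (default: union of tips).
#' @param unit_tag Unit tag applied to every tree.
#' @return A [gene_tree_set()].
#' @export
read_gene_trees <- function(path, taxa = NULL, unit_tag = "none") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no trees in ", path)
  gene_tree_set(lapply(lines, parse_newick, unit_tag = unit_tag), taxa = taxa)
}

#' Write gene trees to a newick file (one per line)
#'
#' @param gts A [gene_tree_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_trees <- function(gts, path) {
  stopifnot(inherits(gts, "gene_tree_set"))
  writeLines(vapply(gts_trees(gts), write_newick, character(1)), path)
  invisible(path)
}
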