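#' Quartet topologies
#'
#' An unrooted binary tree on four leaves `(a, b, c, d)` displays exactly one
#' of the three quartet topologies `ab|cd`, `ac|bd` or `ad|bc`, named after
#' the two cherries separated by the internal edge.  Throughout the package a
#' quartet topology relative to an *ordered* 4-tuple of labels is encoded as
#' an integer: 1 = `ab|cd`, 2 = `ac|bd`, 3 = `ad|bc`.  The fixed order
#' 1 < 2 < 3 is also the tie-breaking order used everywhere.
#'
#' @param index integer in 1:3.
#' @param labels character vector of four leaf labels, in order.
#' @return `quartet_split()` returns the split as a string, e.g. `"a,b|c,d"`.
#' @examples
#' quartet_split(2, c("a", "b", "c", "d"))
#' @export
quartet_split <- function(index, labels) {
  stopifnot(length(labels) == 4L, index %in% 1:3)
  other <- switch(index, c(3L, 4L), c(2L, 4L), c(2L, 3L))
  pair <- c(1L, setdiff(2:4, other))
  paste0(paste(labels[pair], collapse = ","), "|",
         paste(labels[other], collapse = ","))
}

## Given a tip-tip distance matrix D (topological, unit edge lengths) and an
## ordered 4-vector of tip indices, return 1/2/3 for ab|cd / ac|bd / ad|bc.
## The smallest of the three pairwise path-length sums identifies the split;
## in a binary tree it is unique.
.quartet_index_dist <- function(D, idx) {
  s1 <- D[idx[1L], idx[2L]] + D[idx[3L], idx[4L]]
  s2 <- D[idx[1L], idx[3L]] + D[idx[2L], idx[4L]]
  s3 <- D[idx[1L], idx[4L]] + D[idx[2L], idx[3L]]
  which.min(c(s1, s2, s3))
}

## Topological (unit branch length) tip-tip distances of a phylo.
.topo_dist <- function(phy) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  stats::cophenetic(phy)
}

#' Displayed quartet topology of four leaves
#'
#' Restricts a tree to four leaves and reports the quartet topology the
#' unrooted restriction displays.  The result is invariant under re-rooting.
#'
#' @param tree a `phylo`, [locus_tree] or [gene_tree] object.
#' @param leaves character vector of four distinct leaf labels, in order
#'   `(a, b, c, d)`.
#' @param as_index return the integer encoding (1 = `ab|cd`, 2 = `ac|bd`,
#'   3 = `ad|bc` relative to the order of `leaves`) instead of the split
#'   string.
#' @return split string (or integer when `as_index = TRUE`).
#' @examples
#' tr <- ape::read.tree(text = "(((a:1,c:1):1,b:2):1,d:3);")
#' quartet_topology(tr, c("a", "b", "c", "d"))
#' @export
quartet_topology <- function(tree, leaves, as_index = FALSE) {
  phy <- as_phylo(tree)
  if (length(leaves) != 4L || anyDuplicated(leaves))
    stop("`leaves` must be four distinct labels")
  if (!all(leaves %in% phy$tip.label))
    stop("leaves not found in tree: ",
         paste(setdiff(leaves, phy$tip.label), collapse = ", "))
  D <- .topo_dist(phy)
  k <- .quartet_index_dist(D, match(leaves, rownames(D)))
  if (as_index) k else quartet_split(k, leaves)
}

#' @export
#' @rdname quartet_topology
#' @param x object to coerce to `phylo`.
as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (inherits(x, c("locus_tree", "gene_tree"))) return(x$phylo)
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to phylo")
}
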