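## Tree containers and Newick/NHX input-output.
##
## Trees are ape `phylo` objects.  Two thin S3 wrappers add the model
## semantics: `locus_tree` (phylo + duplication-points + leaf -> species map)
## and `gene_tree` (phylo + leaf -> species and leaf -> locus maps).  The
## planted root edge is `phy$root.edge`; an open-ended planted edge (the
## final coalescence is unbounded above the root) is flagged with the
## attribute `open_root`.

#' Node heights of an ultrametric tree
#'
#' Heights are measured in coalescent units above the leaf level: leaves sit
#' at time 0 and time increases rootward.
#'
#' @param tree a `phylo`, [locus_tree] or [gene_tree].
#' @param tol tolerance for the ultrametricity check.
#' @return numeric vector indexed by ape node id (tips `1:n`, then internal
#'   nodes); tips are exactly 0.
#' @export
node_heights <- function(tree, tol = 1e-6) {
  phy <- as_phylo(tree)
  depth <- ape::node.depth.edgelength(phy)
  ntip <- ape::Ntip(phy)
  top <- max(depth[seq_len(ntip)])
  if (diff(range(depth[seq_len(ntip)])) > tol * max(top, 1))
    stop("tree is not ultrametric: leaves are not aligned in time")
  h <- top - depth
  h[seq_len(ntip)] <- 0
  h
}

.species_from_label <- function(labels) {
  setNames(sub("_[0-9]+$", "", labels), labels)
}

#' Locus tree
#'
#' A locus tree records the duplication/loss history of a gene family inside
#' a species tree.  Duplication-points mark the start of a novel (daughter)
#' locus: each sits on the edge above `node` at absolute height `height`,
#' and all gene lineages originating below it must coalesce below that
#' height under the bounded coalescent.  A duplication-point on the planted
#' root edge is recorded with `node` equal to the root node id.
#'
#' @param phy ultrametric rooted binary `phylo`; `phy$root.edge` is the
#'   planted root edge (defaults to 0).
#' @param dup_points data frame with columns `node` (ape node id of the
#'   lower end of the edge) and `height` (absolute height of the point), or
#'   `NULL` for none.
#' @param species named character vector mapping each tip label to its
#'   species; by default the label up to a trailing `_<copy>` suffix.
#' @param open_root logical; if `TRUE` the planted root edge is open-ended
#'   (no upper limit on the final coalescence).
#' @return object of class `locus_tree`.
#' @export
locus_tree <- function(phy, dup_points = NULL, species = NULL,
                       open_root = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) stop("leaf labels must be unique")
  if (is.null(phy$root.edge)) phy$root.edge <- 0
  if (is.null(species)) species <- .species_from_label(phy$tip.label)
  if (!all(phy$tip.label %in% names(species)))
    stop("`species` must cover every tip label")
  species <- species[phy$tip.label]
  if (is.null(dup_points)) {
    dup_points <- tibble::new_tibble(
      list(node = integer(), height = numeric()), nrow = 0L)
  } else {
    dup_points <- tibble::new_tibble(
      list(node = as.integer(dup_points$node),
           height = as.numeric(dup_points$height)),
      nrow = length(dup_points$node))
  }
  h <- node_heights(phy)
  root <- ape::Ntip(phy) + 1L
  parent_of <- .parent_vector(phy)
  for (i in seq_len(nrow(dup_points))) {
    v <- dup_points$node[i]
    hi <- dup_points$height[i]
    lo <- h[v]
    up <- if (v == root) {
      if (open_root) Inf else h[root] + phy$root.edge
    } else h[parent_of[v]]
    if (hi < lo - 1e-8 || hi > up + 1e-8)
      stop("duplication-point height ", hi,
           " outside its edge interval [", lo, ", ", up, "]")
  }
  structure(list(phylo = phy, dup_points = dup_points, species = species,
                 open_root = open_root),
            class = "locus_tree")
}

#' Gene tree
#'
#' @param phy ultrametric rooted binary `phylo` with leaves labelled
#'   `<species>_<copy>`.
#' @param species named character vector tip label -> species.
#' @param locus named character vector tip label -> extant locus-tree leaf.
#' @return object of class `gene_tree`.
#' @export
gene_tree <- function(phy, species = NULL, locus = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(species)) species <- .species_from_label(phy$tip.label)
  if (is.null(locus)) locus <- setNames(phy$tip.label, phy$tip.label)
  structure(list(phylo = phy, species = species[phy$tip.label],
                 locus = locus[phy$tip.label]),
            class = "gene_tree")
}

#' @export
print.locus_tree <- function(x, ...) {
  cat("<locus_tree> ", ape::Ntip(x$phylo), " leaves, ",
      nrow(x$dup_points), " duplication-point(s), ",
      length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree> ", ape::Ntip(x$phylo), " leaves, ",
      length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

.parent_vector <- function(phy) {
  p <- integer(ape::Ntip(phy) + phy$Nnode)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

.children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}

.assert_binary <- function(phy) {
  kids <- tabulate(phy$edge[, 1L], nbins = ape::Ntip(phy) + phy$Nnode)
  internal <- kids[kids > 0L]
  if (any(internal != 2L))
    stop("tree is not binary: found a node with ",
         max(internal), " children")
  invisible(TRUE)
}

## ---------------------------------------------------------------- Newick IO

.NHX_RE <- ":([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\[&&NHX:DUPTIME=([0-9_.eE+-]+)\\]"

#' Read a Newick or NHX-annotated tree
#'
#' The `"nhx"` dialect carries duplication-points as edge comments of the
#' form `[&&NHX:DUPTIME=<height>]` placed after the branch length of the
#' edge the point sits on (several heights on one edge are joined with
#' `_`).  Heights are absolute (leaves at time 0).  A trailing `:<len>`
#' before the final `;` is the planted root edge.
#'
#' @param text Newick string (one tree).
#' @param file path to a file containing one Newick string (used when
#'   `text` is `NULL`).
#' @param dialect `"plain"` for an undecorated `phylo`, `"nhx"` for a
#'   [locus_tree].
#' @param open_root passed to [locus_tree()] for the `"nhx"` dialect.
#' @return `phylo` or `locus_tree`.
#' @examples
#' read_newick("((a:1,b:1):1[&&NHX:DUPTIME=1.5],(c:1,d:1):1):0;",
#'             dialect = "nhx")
#' @export
read_newick <- function(text = NULL, file = NULL,
                        dialect = c("plain", "nhx"), open_root = TRUE) {
  dialect <- match.arg(dialect)
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (dialect == "plain") {
    phy <- .parse_one(text)
    .assert_binary(phy)
    return(phy)
  }
  marked <- gsub(.NHX_RE, "__DUPTIME_\\2:\\1", text)
  if (grepl("\\[", marked))
    stop("unparsed comment in NHX input near: ",
         sub(".*?(\\[[^]]*\\]).*", "\\1", marked))
  phy <- .parse_one(marked)
  .assert_binary(phy)
  labs <- c(phy$tip.label,
            if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label)
  dup_node <- integer(); dup_h <- numeric()
  for (v in which(grepl("__DUPTIME_", labs))) {
    raw <- sub("^.*__DUPTIME_", "", labs[v])
    hts <- as.numeric(strsplit(raw, "_", fixed = TRUE)[[1L]])
    dup_node <- c(dup_node, rep(v, length(hts)))
    dup_h <- c(dup_h, hts)
    labs[v] <- sub("__DUPTIME_.*$", "", labs[v])
  }
  phy$tip.label <- labs[seq_len(ape::Ntip(phy))]
  phy$node.label <- NULL
  locus_tree(phy,
             dup_points = data.frame(node = dup_node, height = dup_h),
             open_root = open_root)
}

.parse_one <- function(text) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick: ape could not parse the string")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree")
  if (is.null(phy$root.edge)) phy$root.edge <- 0
  phy
}

#' Write a tree in canonical Newick/NHX form
#'
#' The canonical form orders the children of every node by the smallest leaf
#' label below them and prints branch lengths with 10 significant digits, so
#' that parse -> write round-trips bit-exactly.  [locus_tree] objects are
#' written with `[&&NHX:DUPTIME=...]` edge comments.
#'
#' @param tree `phylo`, [locus_tree] or [gene_tree].
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  phy <- as_phylo(tree)
  dup <- if (inherits(tree, "locus_tree")) tree$dup_points else NULL
  kids <- .children_list(phy)
  ntip <- ape::Ntip(phy)
  has_len <- !is.null(phy$edge.length)
  fmt <- function(x) formatC(x, digits = digits, format = "g", width = 1)
  ann <- function(v) {
    if (is.null(dup)) return("")
    hts <- sort(dup$height[dup$node == v])
    if (!length(hts)) return("")
    sprintf("[&&NHX:DUPTIME=%s]", paste(fmt(hts), collapse = "_"))
  }
  minlab <- character(ntip + phy$Nnode)
  build <- function(v) {
    if (v <= ntip) {
      minlab[v] <<- phy$tip.label[v]
      return(phy$tip.label[v])
    }
    parts <- vapply(kids[[v]], build, "")
    ord <- order(minlab[kids[[v]]])
    minlab[v] <<- min(minlab[kids[[v]]])
    lenstr <- if (has_len) {
      lens <- vapply(kids[[v]][ord], function(u) {
        e <- which(phy$edge[, 2L] == u)
        phy$edge.length[e]
      }, 0)
      paste0(":", fmt(lens))
    } else ""
    inner <- paste0(parts[ord], lenstr,
                    vapply(kids[[v]][ord], ann, ""), collapse = ",")
    paste0("(", inner, ")")
  }
  root <- ntip + 1L
  s <- build(root)
  re <- if (is.null(phy$root.edge)) 0 else phy$root.edge
  s <- paste0(s, if (has_len) paste0(":", fmt(re)), ann(root), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

## ------------------------------------------------------------- restriction

#' Restrict a tree to a subset of leaves
#'
#' Suppressed degree-2 nodes have their edge lengths summed, so leaf-to-root
#' path lengths (and node heights) are preserved.  For a [locus_tree],
#' duplication-points are re-attached to the merged edge spanning their
#' height above the retained leaves they constrain; when several land on one
#' edge only the lowest is kept, since it implies the others.  The planted
#' root edge is extended so the tree still reaches the original top height.
#'
#' @param tree `phylo` or [locus_tree].
#' @param leaves character vector of at least two leaf labels to keep.
#' @return object of the same class as `tree`.
#' @export
restrict_tree <- function(tree, leaves) {
  UseMethod("restrict_tree")
}

#' @export
restrict_tree.phylo <- function(tree, leaves) {
  .check_leaves(tree, leaves)
  re_top <- node_heights(tree)[ape::Ntip(tree) + 1L] +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  phy <- ape::keep.tip(tree, leaves)
  phy$root.edge <- re_top - node_heights(phy)[ape::Ntip(phy) + 1L]
  phy
}

#' @export
restrict_tree.locus_tree <- function(tree, leaves) {
  phy0 <- tree$phylo
  .check_leaves(phy0, leaves)
  h0 <- node_heights(phy0)
  root0 <- ape::Ntip(phy0) + 1L
  top0 <- h0[root0] + phy0$root.edge
  phy <- ape::keep.tip(phy0, leaves)
  h1 <- node_heights(phy)
  root1 <- ape::Ntip(phy) + 1L
  phy$root.edge <- top0 - h1[root1]
  ## map duplication-points: constrained retained leaves -> position
  kids0 <- .children_list(phy0)
  below0 <- .tips_below(phy0, kids0)
  parent1 <- .parent_vector(phy)
  dup <- tree$dup_points
  out_node <- integer(); out_h <- numeric()
  for (i in seq_len(nrow(dup))) {
    kept <- intersect(below0[[dup$node[i]]], leaves)
    if (!length(kept)) next
    hgt <- dup$height[i]
    v <- if (length(kept) == 1L) match(kept, phy$tip.label)
         else ape::getMRCA(phy, kept)
    ## climb until the edge above v spans hgt
    while (v != root1 && h1[parent1[v]] < hgt - 1e-9) v <- parent1[v]
    out_node <- c(out_node, v); out_h <- c(out_h, hgt)
  }
  dup1 <- tibble::tibble(node = out_node, height = out_h)
  if (nrow(dup1)) {
    dup1 <- dup1 |>
      dplyr::group_by(.data$node) |>
      dplyr::slice_min(.data$height, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  locus_tree(phy, dup_points = dup1,
             species = tree$species[leaves], open_root = tree$open_root)
}

.check_leaves <- function(phy, leaves) {
  if (length(leaves) < 2L) stop("need at least two leaves to restrict to")
  bad <- setdiff(leaves, phy$tip.label)
  if (length(bad)) stop("unknown leaf label(s): ", paste(bad, collapse = ", "))
}

## list: node id -> tip labels below (tips map to themselves)
.tips_below <- function(phy, kids = .children_list(phy)) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  out <- vector("list", n)
  rec <- function(v) {
    if (v <= ntip) {
      out[[v]] <<- phy$tip.label[v]
    } else {
      for (u in kids[[v]]) rec(u)
      out[[v]] <<- unlist(out[kids[[v]]], use.names = FALSE)
    }
  }
  rec(ntip + 1L)
  out
}
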