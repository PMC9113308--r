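## Independent oracle implementations used to cross-check the package.
## These deliberately use different algorithms from the package internals:
## quartets are read off cherries of the unrooted restriction (not distance
## sums), and tallies/scores are brute-force loops.

## quartet index of four leaves via cherry detection on the unrooted
## restriction; 1 = l1 l2 | l3 l4, 2 = l1 l3 | l2 l4, 3 = l1 l4 | l2 l3
oracle_quartet <- function(phy, leaves) {
  ut <- ape::unroot(ape::keep.tip(phy, leaves))
  par <- integer(4L)
  for (i in 1:4) {
    tip <- match(leaves[i], ut$tip.label)
    par[i] <- ut$edge[ut$edge[, 2L] == tip, 1L]
  }
  for (i in 1:3) for (j in (i + 1):4) {
    if (par[i] == par[j]) {
      pr <- sort(c(i, j))
      if (all(pr == c(1L, 2L)) || all(pr == c(3L, 4L))) return(1L)
      if (all(pr == c(1L, 3L)) || all(pr == c(2L, 4L))) return(2L)
      return(3L)
    }
  }
  stop("no cherry found in unrooted 4-leaf tree")
}

## brute-force ASTRAL-multi tally: loop over every copy combination
oracle_multi_tally <- function(g, species4) {
  copies <- lapply(species4, function(sp) names(g$species)[g$species == sp])
  n <- c(0L, 0L, 0L)
  if (any(lengths(copies) == 0L)) return(n)
  for (a in copies[[1]]) for (b in copies[[2]])
    for (cc in copies[[3]]) for (d in copies[[4]]) {
      k <- oracle_quartet(g$phylo, c(a, b, cc, d))
      n[k] <- n[k] + 1L
    }
  n
}

## brute-force quartet-score of a candidate topology against a tally table
oracle_tree_score <- function(phy, tallies) {
  tot <- 0
  for (r in seq_len(nrow(tallies))) {
    s4 <- c(tallies$s1[r], tallies$s2[r], tallies$s3[r], tallies$s4[r])
    k <- oracle_quartet(phy, s4)
    tot <- tot + c(tallies$n1[r], tallies$n2[r], tallies$n3[r])[k]
  }
  tot
}

## random ultrametric tree with a planted root edge
random_ultrametric <- function(n, root_edge = 0.5) {
  phy <- ape::rcoal(n)
  phy$root.edge <- root_edge
  phy
}

## random locus tree: random ultrametric tree plus duplication-points drawn
## uniformly inside random edge intervals
random_locus_tree <- function(n, n_dups = 2, root_edge = 1) {
  phy <- random_ultrametric(n, root_edge)
  h <- node_heights(phy)
  root <- n + 1L
  nodes <- sample(setdiff(seq_len(n + phy$Nnode), root), n_dups)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  dup <- data.frame(
    node = nodes,
    height = vapply(nodes, function(v)
      stats::runif(1, h[v], h[parent[v]]), 0))
  locus_tree(phy, dup_points = dup)
}

## random multi-copy gene tree on species A..D with given copy counts
random_multicopy_gene_tree <- function(copies = c(A = 2, B = 1, C = 3, D = 1)) {
  labs <- unlist(lapply(names(copies), function(sp)
    paste0(sp, "_", seq_len(copies[[sp]]))))
  phy <- ape::rcoal(length(labs), tip.label = sample(labs))
  gene_tree(phy)
}

balanced_species <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):1;")
}

caterpillar_species <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3):1;")
}
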