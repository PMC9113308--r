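## Quartet extraction from multi-copy gene trees and exact small-scale
## species-tree estimation by quartet score.
##
## A multi-copy gene tree can carry several leaves per species and hence
## suggest conflicting quartets for a species 4-tuple.  ASTRAL-one draws a
## single random copy per species (once per gene tree) and reads off one
## quartet; ASTRAL-multi enumerates every copy combination and counts all
## the displayed quartets.

.species_copies <- function(g, species4) {
  stopifnot(inherits(g, "gene_tree"), length(species4) == 4L)
  lapply(species4, function(sp) names(g$species)[g$species == sp])
}

#' ASTRAL-one quartet sample from one gene tree
#'
#' Samples one gene copy per species uniformly at random and returns the
#' quartet topology displayed by the four sampled leaves, as an index
#' relative to the order of `species4` (1 = `s1 s2 | s3 s4`, 2 =
#' `s1 s3 | s2 s4`, 3 = `s1 s4 | s2 s3`).  Returns `NA` when the tree has
#' no copy of some species.
#'
#' @param g a [gene_tree].
#' @param species4 four distinct species labels, in order.
#' @param seed optional integer seed.
#' @return integer in 1:3, or `NA_integer_`.
#' @export
astral_one_sample <- function(g, species4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copies <- .species_copies(g, species4)
  if (any(lengths(copies) == 0L)) return(NA_integer_)
  picked <- vapply(copies, function(cp) cp[sample.int(length(cp), 1L)], "")
  quartet_topology(g, picked, as_index = TRUE)
}

#' ASTRAL-multi quartet tally from one gene tree
#'
#' Counts, over every combination of one copy per species, the quartet
#' topology displayed by the four chosen leaves.  The counts sum to the
#' product of the per-species copy numbers.
#'
#' @inheritParams astral_one_sample
#' @return tibble with one row: `n_ab_cd`, `n_ac_bd`, `n_ad_bc` (indices
#'   relative to the order of `species4`) and `n_combinations`.
#' @export
astral_multi_tally <- function(g, species4) {
  copies <- .species_copies(g, species4)
  if (any(lengths(copies) == 0L))
    return(tibble::new_tibble(list(n_ab_cd = 0L, n_ac_bd = 0L,
                                   n_ad_bc = 0L, n_combinations = 0L),
                              nrow = 1L))
  D <- .topo_dist(g$phylo)
  pos <- lapply(copies, function(cp) match(cp, rownames(D)))
  combo <- expand.grid(a = pos[[1L]], b = pos[[2L]], c = pos[[3L]],
                       d = pos[[4L]], KEEP.OUT.ATTRS = FALSE)
  s <- cbind(D[cbind(combo$a, combo$b)] + D[cbind(combo$c, combo$d)],
             D[cbind(combo$a, combo$c)] + D[cbind(combo$b, combo$d)],
             D[cbind(combo$a, combo$d)] + D[cbind(combo$b, combo$c)])
  k <- max.col(-s, ties.method = "first")
  n <- tabulate(k, nbins = 3L)
  tibble::new_tibble(list(n_ab_cd = n[1L], n_ac_bd = n[2L], n_ad_bc = n[3L],
                          n_combinations = nrow(combo)), nrow = 1L)
}

#' Aggregate quartet tallies over a collection of gene trees
#'
#' Gene trees missing one of the four species contribute nothing (the
#' analysis is conditioned on all four genes being present).
#'
#' @param genes list of [gene_tree] objects.
#' @param species4 four distinct species labels, in order.
#' @param mode `"one"` (one random copy per species per tree) or `"multi"`
#'   (all copy combinations).
#' @param seed optional integer seed (used by `"one"`).
#' @return tibble with one row: the three counts, `n_trees_used` and
#'   `mode`.
#' @export
tally_gene_trees <- function(genes, species4, mode = c("one", "multi"),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- c(0L, 0L, 0L); used <- 0L
  for (g in genes) {
    if (mode == "one") {
      k <- astral_one_sample(g, species4)
      if (!is.na(k)) { n[k] <- n[k] + 1L; used <- used + 1L }
    } else {
      tl <- astral_multi_tally(g, species4)
      if (tl$n_combinations > 0L) {
        n <- n + c(tl$n_ab_cd, tl$n_ac_bd, tl$n_ad_bc)
        used <- used + 1L
      }
    }
  }
  tibble::tibble(n_ab_cd = n[1L], n_ac_bd = n[2L], n_ad_bc = n[3L],
                 n_trees_used = used, mode = mode)
}

#' Dominant quartet of a tally
#'
#' @param tally a tibble row from [astral_multi_tally()] /
#'   [tally_gene_trees()], or a numeric vector of three counts in the fixed
#'   topology order.
#' @return integer in 1:3 (argmax count; ties broken towards the smaller
#'   index, i.e. the fixed order `ab|cd < ac|bd < ad|bc`).
#' @export
dominant_quartet <- function(tally) {
  n <- if (is.data.frame(tally))
    c(tally$n_ab_cd[1L], tally$n_ac_bd[1L], tally$n_ad_bc[1L])
  else as.numeric(tally[1:3])
  if (sum(n) <= 0) stop("empty tally: no quartets observed")
  which.max(n)
}

#' Exact species-tree estimation by quartet score
#'
#' Exhaustively scores every unrooted binary topology on the taxa of
#' `tallies` by the total count of quartets it displays, and returns the
#' argmax.  Intended as a transparent stand-in for a constrained
#' quartet-score search at desk scale (`n <= 8`).
#'
#' @param tallies tibble with columns `s1..s4` (a species 4-tuple, sorted)
#'   and `n1, n2, n3` (quartet counts relative to the sorted tuple), one
#'   row per 4-subset; see [tally_all_quartets()].
#' @return the best unrooted topology as a `phylo`; ties are reported via
#'   attribute `"ties"` (canonical Newick strings) and broken towards the
#'   lexicographically smallest string.  The score is attribute `"score"`.
#' @export
infer_species_tree <- function(tallies) {
  taxa <- sort(unique(c(tallies$s1, tallies$s2, tallies$s3, tallies$s4)))
  if (length(taxa) > 8L)
    stop("refusing exhaustive search over more than 8 taxa")
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  cand <- phangorn::allTrees(length(taxa), rooted = FALSE,
                             tip.label = taxa)
  score_one <- function(phy) {
    D <- .topo_dist(phy)
    tot <- 0
    for (r in seq_len(nrow(tallies))) {
      idx <- match(c(tallies$s1[r], tallies$s2[r],
                     tallies$s3[r], tallies$s4[r]), rownames(D))
      k <- .quartet_index_dist(D, idx)
      tot <- tot + c(tallies$n1[r], tallies$n2[r], tallies$n3[r])[k]
    }
    tot
  }
  scores <- vapply(cand, score_one, 0)
  best <- which(scores == max(scores))
  strs <- vapply(cand[best], function(p) {
    p$root.edge <- 0
    write_newick(p)
  }, "")
  pick <- best[order(strs)[1L]]
  out <- cand[[pick]]
  attr(out, "score") <- max(scores)
  attr(out, "ties") <- sort(strs)
  out
}

#' Tally quartets for every species 4-subset
#'
#' In `"one"` mode a single random copy per species is drawn *once per gene
#' tree* and reused for every 4-tuple of that tree (set
#' `resample_per_subset = TRUE` to draw independently for each 4-tuple, for
#' sensitivity checks).  Gene trees missing a species of a 4-tuple are
#' skipped for that tuple.
#'
#' @param genes list of [gene_tree] objects.
#' @param taxa species labels to consider; defaults to all species seen.
#' @param resample_per_subset draw a fresh copy per 4-tuple in `"one"` mode.
#' @inheritParams tally_gene_trees
#' @return tibble with columns `s1..s4` (sorted 4-tuple), `n1, n2, n3`
#'   (counts relative to the sorted tuple) and `n_trees_used`.
#' @export
tally_all_quartets <- function(genes, taxa = NULL,
                               mode = c("one", "multi"), seed = NULL,
                               resample_per_subset = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(genes, function(g) g$species))))
  taxa <- sort(taxa)
  subsets <- combn(taxa, 4L)
  ns <- ncol(subsets)
  n <- matrix(0L, nrow = ns, ncol = 3L)
  used <- integer(ns)
  for (g in genes) {
    picked <- NULL
    if (mode == "one" && !resample_per_subset) {
      picked <- vapply(taxa, function(sp) {
        cp <- names(g$species)[g$species == sp]
        if (!length(cp)) NA_character_ else cp[sample.int(length(cp), 1L)]
      }, "")
      D <- .topo_dist(g$phylo)
    }
    for (i in seq_len(ns)) {
      s4 <- subsets[, i]
      if (mode == "multi") {
        tl <- astral_multi_tally(g, s4)
        if (tl$n_combinations > 0L) {
          n[i, ] <- n[i, ] + c(tl$n_ab_cd, tl$n_ac_bd, tl$n_ad_bc)
          used[i] <- used[i] + 1L
        }
      } else if (resample_per_subset) {
        k <- astral_one_sample(g, s4)
        if (!is.na(k)) { n[i, k] <- n[i, k] + 1L; used[i] <- used[i] + 1L }
      } else {
        leaves <- picked[s4]
        if (anyNA(leaves)) next
        k <- .quartet_index_dist(D, match(leaves, rownames(D)))
        n[i, k] <- n[i, k] + 1L
        used[i] <- used[i] + 1L
      }
    }
  }
  tibble::tibble(s1 = subsets[1L, ], s2 = subsets[2L, ],
                 s3 = subsets[3L, ], s4 = subsets[4L, ],
                 n1 = n[, 1L], n2 = n[, 2L], n3 = n[, 3L],
                 n_trees_used = used)
}
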