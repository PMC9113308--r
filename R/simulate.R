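## The DLCoal generative process.
##
## Stage one (`sim_locus_tree`): a birth-death duplication/loss process runs
## top-down along the species tree, starting with one lineage at the top of
## the planted root edge; a duplication splits a lineage into a mother (same
## locus) and a daughter (novel locus, marked by a duplication-point at the
## duplication height); a loss terminates the lineage.  Extinct subtrees are
## pruned, unary nodes suppressed with lengths summed, and duplication-points
## migrate onto the merged edges.
##
## Stage two (`sim_gene_tree`): the bounded multispecies coalescent runs
## bottom-up along the locus tree, one gene lineage per extant leaf, rate 1
## per lineage pair within an edge.  Every duplication-point is an exact
## constraint: all lineages below it must have coalesced to one when it is
## reached.  Constraints are enforced by per-daughter-locus rejection, which
## is exact conditional sampling because daughter subtrees are independent
## given their entry lineage counts.

#' Simulate a locus tree by gene duplication and loss
#'
#' @param species ultrametric rooted binary `phylo` (branch lengths in
#'   coalescent units); its `root.edge` is used unless `root_edge` is given.
#' @param lam duplication (birth) rate per coalescent unit.
#' @param mu loss (death) rate per coalescent unit.
#' @param root_edge length of the species-tree root edge on which the
#'   process starts.
#' @param seed optional integer seed.
#' @return an object of class `locus_history`: a list with elements
#'   `locus` (a [locus_tree], or `NULL` when fewer than two copies
#'   survive), `leaves` (extant copy labels `<species>_<copy>`),
#'   `root_lineage` (named integer: extant leaf -> index of the root
#'   lineage it descends from), `l` (number of locus lineages crossing the
#'   root speciation) and `events` (tibble of duplication/loss events with
#'   heights and species-tree edges).
#' @examples
#' sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):1;")
#' sim_locus_tree(sp, lam = 0.3, mu = 0.3, seed = 1)
#' @export
sim_locus_tree <- function(species, lam, mu, root_edge = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- as_phylo(species)
  .assert_binary(phy)
  if (lam < 0 || mu < 0 || !is.finite(lam) || !is.finite(mu))
    stop("rates must be finite and non-negative")
  if (is.null(root_edge)) root_edge <- phy$root.edge %||% 0
  if (!is.finite(root_edge) || root_edge < 0)
    stop("`root_edge` must be finite and non-negative")
  h <- node_heights(phy)
  kids <- .children_list(phy)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  start_h <- h[root] + root_edge
  rate <- lam + mu
  env <- new.env(parent = emptyenv())
  env$copy <- setNames(integer(ntip), phy$tip.label)
  env$rl <- 0L
  env$ev_type <- character(); env$ev_h <- numeric(); env$ev_sp <- integer()

  note <- function(type, hh, sp) {
    env$ev_type <- c(env$ev_type, type)
    env$ev_h <- c(env$ev_h, hh)
    env$ev_sp <- c(env$ev_sp, sp)
  }

  ## one locus lineage moving down the species edge that ends at `sp_node`
  sim_lin <- function(sp_node, h_cur, rl_idx) {
    w <- if (rate > 0) rexp(1L, rate) else Inf
    if (h_cur - w > h[sp_node]) {
      h_ev <- h_cur - w
      if (runif(1L) < mu / rate) {
        note("loss", h_ev, sp_node)
        return(NULL)
      }
      note("dup", h_ev, sp_node)
      k1 <- sim_lin(sp_node, h_ev, rl_idx)
      k2 <- sim_lin(sp_node, h_ev, rl_idx)
      return(list(type = "dup", height = h_ev, kids = list(k1, k2),
                  daughter = sample.int(2L, 1L)))
    }
    ## reached the bottom of the current species edge
    if (sp_node <= ntip) {
      env$copy[sp_node] <- env$copy[sp_node] + 1L
      return(list(type = "leaf",
                  label = paste0(phy$tip.label[sp_node], "_",
                                 env$copy[sp_node]),
                  rl = rl_idx))
    }
    if (sp_node == root && is.na(rl_idx)) {
      env$rl <- env$rl + 1L
      rl_idx <- env$rl
    }
    list(type = "spec", height = h[sp_node],
         kids = list(sim_lin(kids[[sp_node]][1L], h[sp_node], rl_idx),
                     sim_lin(kids[[sp_node]][2L], h[sp_node], rl_idx)))
  }

  top <- sim_lin(root, start_h, NA_integer_)

  ## prune extinct subtrees; suppress unary nodes; duplication-points stay
  ## with the daughter side
  prune <- function(node) {
    if (is.null(node)) return(NULL)
    if (node$type == "leaf")
      return(list(height = 0, kids = NULL, dup_above = numeric(0),
                  label = node$label, rl = node$rl))
    a <- prune(node$kids[[1L]])
    b <- prune(node$kids[[2L]])
    if (node$type == "dup") {
      d <- if (node$daughter == 1L) a else b
      m <- if (node$daughter == 1L) b else a
      if (!is.null(d)) d$dup_above <- c(d$dup_above, node$height)
      if (is.null(d)) return(m)
      if (is.null(m)) return(d)
      return(list(height = node$height, kids = list(m, d),
                  dup_above = numeric(0)))
    }
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(height = node$height, kids = list(a, b), dup_above = numeric(0))
  }
  top <- prune(top)

  events <- tibble::new_tibble(
    list(type = env$ev_type, height = env$ev_h, species_node = env$ev_sp),
    nrow = length(env$ev_type))
  out <- list(locus = NULL, leaves = character(), root_lineage = integer(),
              l = env$rl, events = events)
  class(out) <- "locus_history"
  if (is.null(top)) return(out)
  if (is.null(top$kids)) {                       # single surviving copy
    out$leaves <- top$label
    out$root_lineage <- setNames(top$rl, top$label)
    return(out)
  }
  out$locus <- .nested_to_locus(top, start_h)
  lv <- attr(out$locus, "rl")
  attr(out$locus, "rl") <- NULL
  out$leaves <- names(lv)
  out$root_lineage <- lv
  out
}

## Convert the pruned nested history into a locus_tree (pre-order edge
## construction, so the edge matrix is cladewise).
.nested_to_locus <- function(top, start_h) {
  nl <- 0L
  cnt <- function(nd) {
    if (is.null(nd$kids)) nl <<- nl + 1L
    else { cnt(nd$kids[[1L]]); cnt(nd$kids[[2L]]) }
  }
  cnt(top)
  nn <- nl - 1L
  edge <- matrix(0L, nl + nn - 1L, 2L)
  elen <- numeric(nl + nn - 1L)
  tipl <- character(nl)
  rl <- integer(nl)
  dup_node <- integer(); dup_h <- numeric()
  tip_i <- 0L; node_i <- nl + 1L; e_i <- 0L
  rec <- function(nd) {
    if (is.null(nd$kids)) {
      tip_i <<- tip_i + 1L
      id <- tip_i
      tipl[id] <<- nd$label
      rl[id] <<- nd$rl
    } else {
      id <- node_i
      node_i <<- node_i + 1L
      for (k in nd$kids) {
        e_row <- e_i <<- e_i + 1L
        cid <- rec(k)
        edge[e_row, ] <<- c(id, cid)
        elen[e_row] <<- nd$height - (if (is.null(k$kids)) 0 else k$height)
      }
    }
    if (length(nd$dup_above)) {
      dup_node <<- c(dup_node, rep(id, length(nd$dup_above)))
      dup_h <<- c(dup_h, nd$dup_above)
    }
    id
  }
  rec(top)
  phy <- structure(list(edge = edge, edge.length = elen, tip.label = tipl,
                        Nnode = nn, root.edge = start_h - top$height),
                   class = "phylo", order = "cladewise")
  lt <- locus_tree(phy,
                   dup_points = if (length(dup_node))
                     data.frame(node = dup_node, height = dup_h) else NULL)
  attr(lt, "rl") <- setNames(rl, tipl)
  lt
}

#' @export
print.locus_history <- function(x, ...) {
  cat("<locus_history> ", length(x$leaves), " extant copies, l = ", x$l,
      " root lineage(s), ", sum(x$events$type == "dup"), " duplication(s), ",
      sum(x$events$type == "loss"), " loss(es)\n", sep = "")
  invisible(x)
}

## ----------------------------------------------------- bounded coalescent

## Precompile a locus tree into flat vectors for the sampler.
.bmsc_compile <- function(lt, max_retries = 1e6) {
  phy <- lt$phylo
  ntip <- ape::Ntip(phy)
  n_all <- ntip + phy$Nnode
  h <- node_heights(phy)
  parent <- .parent_vector(phy)
  kids <- .children_list(phy)
  bound <- rep(Inf, n_all)
  for (i in seq_len(nrow(lt$dup_points))) {
    v <- lt$dup_points$node[i]
    bound[v] <- min(bound[v], lt$dup_points$height[i])
  }
  ## a tip, or any node whose top edge carries a bound, delivers exactly one
  ## lineage at the top of its edge with probability one
  det_one <- seq_len(n_all) <= ntip | is.finite(bound)
  list(ntip = ntip, root = ntip + 1L, h = h, parent = parent, kids = kids,
       bound = bound, det_one = det_one, root_edge = phy$root.edge %||% 0,
       labels = phy$tip.label, max_retries = max_retries)
}

## Draw one bounded-coalescent history.  Returns the merge log: a list of
## c(child1, child2, new_id, height).  Lineage ids 1..ntip are the tips; new
## ids are allocated from a counter (gaps from rejected draws are remapped
## at assembly time).
.bmsc_bump <- function(pre, env) {
  env$tries <- env$tries + 1L
  if (env$tries > pre$max_retries)
    stop("bounded-coalescent rejection retry limit exceeded (",
         pre$max_retries, "); a duplication bound is pathologically ",
         "tight for this locus tree")
}

## Waiting times (relative to the segment start) of a Kingman death chain
## from n lineages, conditioned to reach one lineage within time s.  Each
## step draws from a truncated exponential and thins by the ratio
## g_{k-1,1}(r - w) / g_{k-1,1}(r), which is at most one since the chance
## of full coalescence grows with the time left.
.rcond_death_times <- function(n, s, pre, env) {
  times <- numeric(n - 1L)
  hrel <- 0
  for (k in n:2) {
    rate <- k * (k - 1) / 2
    r <- s - hrel
    if (k == 2L) {
      w <- -log1p(runif(1L) * expm1(-r))
    } else {
      gk <- coal_prob(k - 1L, 1L, r)
      repeat {
        .bmsc_bump(pre, env)
        w <- -log1p(runif(1L) * expm1(-rate * r)) / rate
        if (runif(1L) <= coal_prob(k - 1L, 1L, r - w) / gk) break
      }
    }
    hrel <- hrel + w
    times[n - k + 1L] <- hrel
  }
  times
}

.bmsc_sample <- function(pre, env) {
  record <- function(lg, lins, pair, height) {
    env$next_id <- env$next_id + 1L
    lg[[length(lg) + 1L]] <- c(lins[pair[1L]], lins[pair[2L]],
                               env$next_id, height)
    lg
  }
  clade <- function(v) {
    hb <- pre$bound[v]
    htop <- if (v == pre$root) pre$h[v] + pre$root_edge else
      pre$h[pre$parent[v]]
    if (v <= pre$ntip) return(list(lins = v, log = list()))
    ch <- pre$kids[[v]]
    det <- pre$det_one[ch]
    ## children delivering a deterministic single lineage are sampled once:
    ## acceptance of the bound on this edge cannot depend on their internals
    fixed <- lapply(ch[det], clade)

    if (is.finite(hb)) {
      ## bounded edge: all entering lineages must reach one by `hb`.
      ## Accept the lower configuration with probability
      ## g_{n,1}(s) / g_{2,1}(s) (a valid envelope since n >= 2), then draw
      ## the coalescence path conditioned on full coalescence within s.
      s <- hb - pre$h[v]
      g2 <- coal_prob(2L, 1L, s)
      repeat {
        varp <- lapply(ch[!det], clade)
        parts <- c(fixed, varp)
        lins <- unlist(lapply(parts, `[[`, "lins"), use.names = FALSE)
        n <- length(lins)
        if (n == 2L || (g2 > 0 &&
                        runif(1L) <= coal_prob(n, 1L, s) / g2)) break
        .bmsc_bump(pre, env)
      }
      lg <- do.call(c, lapply(parts, `[[`, "log"))
      times <- .rcond_death_times(n, s, pre, env)
      for (tau in times) {
        pair <- if (length(lins) == 2L) 1:2 else
          sample.int(length(lins), 2L)
        lg <- record(lg, lins, pair, pre$h[v] + tau)
        lins <- c(lins[-pair], env$next_id)
      }
      return(list(lins = lins, log = lg))
    }

    ## unbounded edge: free Kingman coalescence up to the edge top
    varp <- lapply(ch[!det], clade)
    parts <- c(fixed, varp)
    lins <- unlist(lapply(parts, `[[`, "lins"), use.names = FALSE)
    lg <- do.call(c, lapply(parts, `[[`, "log"))
    hcur <- pre$h[v]
    n <- length(lins)
    while (n > 1L) {
      w <- rexp(1L, n * (n - 1L) / 2)
      if (hcur + w > htop) break
      hcur <- hcur + w
      pair <- sample.int(n, 2L)
      lg <- record(lg, lins, pair, hcur)
      lins <- c(lins[-pair], env$next_id)
      n <- n - 1L
    }
    list(lins = lins, log = lg)
  }
  res <- clade(pre$root)
  ## above the planted root edge: unbounded coalescence to a single lineage
  lins <- res$lins; lg <- res$log
  hcur <- pre$h[pre$root] + pre$root_edge
  n <- length(lins)
  while (n > 1L) {
    hcur <- hcur + rexp(1L, n * (n - 1L) / 2)
    pair <- sample.int(n, 2L)
    env$next_id <- env$next_id + 1L
    lg[[length(lg) + 1L]] <- c(lins[pair[1L]], lins[pair[2L]],
                               env$next_id, hcur)
    lins <- c(lins[-pair], env$next_id)
    n <- n - 1L
  }
  lg
}

#' Simulate a gene tree on a locus tree (bounded multispecies coalescent)
#'
#' One gene lineage starts in every extant locus-tree leaf; within an edge
#' any pair of co-existing lineages coalesces at rate 1.  Every
#' duplication-point bound is satisfied exactly by per-daughter-locus
#' rejection.  Above the planted root edge the remaining lineages coalesce
#' on an unbounded stem, so the gene tree is always fully resolved.
#'
#' @param lt a [locus_tree] or a `locus_history` (its `locus` element is
#'   used; it must have at least two leaves).
#' @param seed optional integer seed.
#' @param max_retries cap on rejection retries before erroring out.
#' @return a [gene_tree]; its leaves carry the locus-tree leaf labels.
#' @export
sim_gene_tree <- function(lt, seed = NULL, max_retries = 1e6) {
  if (inherits(lt, "locus_history")) lt <- lt$locus
  stopifnot(inherits(lt, "locus_tree"))
  if (!is.null(seed)) set.seed(seed)
  pre <- .bmsc_compile(lt, max_retries)
  env <- new.env(parent = emptyenv())
  env$tries <- 0L; env$next_id <- pre$ntip
  lg <- .bmsc_sample(pre, env)
  phy <- .merges_to_phylo(lg, pre$ntip, pre$labels)
  gene_tree(phy, species = lt$species,
            locus = setNames(pre$labels, pre$labels))
}

.merges_to_phylo <- function(lg, ntip, labels) {
  m <- do.call(rbind, lg)                       # c1, c2, id, height
  stopifnot(nrow(m) == ntip - 1L)
  ord <- order(m[, 4L], decreasing = TRUE)      # root first
  m <- m[ord, , drop = FALSE]
  newid <- setNames(ntip + seq_len(nrow(m)), m[, 3L])
  hmap <- c(rep(0, ntip), m[, 4L])              # by new id
  remap <- function(v) ifelse(v <= ntip, v, unname(newid[as.character(v)]))
  edge <- matrix(0L, nrow = 2L * nrow(m), ncol = 2L)
  elen <- numeric(2L * nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- ntip + i
    ch <- c(remap(m[i, 1L]), remap(m[i, 2L]))
    edge[2L * i - 1L, ] <- c(p, ch[1L])
    edge[2L * i, ] <- c(p, ch[2L])
    elen[2L * i - 1L] <- hmap[p] - hmap[ch[1L]]
    elen[2L * i] <- hmap[p] - hmap[ch[2L]]
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = nrow(m),
                        root.edge = 0),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

## Fast path for four-leaf locus trees: returns only the quartet index
## (1/2/3 relative to the tip order of the locus tree's tip.label sorted as
## given in `leaf_order`).  The split of a four-leaf gene tree is the pair
## formed by any tip-tip merge.
.bmsc_topology_once <- function(pre, env, leaf_pos) {
  lg <- .bmsc_sample(pre, env)
  for (r in lg) {
    if (r[1L] <= pre$ntip && r[2L] <= pre$ntip) {
      i <- leaf_pos[r[1L]]; j <- leaf_pos[r[2L]]
      pair <- sort(c(i, j))
      if (pair[1L] == 1L)
        return(c(`2` = 1L, `3` = 2L, `4` = 3L)[[as.character(pair[2L])]])
      return(switch(paste0(pair[1L], pair[2L]),
                    "34" = 1L, "24" = 2L, "23" = 3L))
    }
  }
  stop("internal error: no tip-tip merge found in a four-leaf gene tree")
}

#' Check duplication bounds on a gene tree
#'
#' Verifies that, for every duplication-point of the locus tree, the gene
#' lineages of all leaves below the point have their most recent common
#' ancestor strictly below the duplication height.
#'
#' @param g a [gene_tree] whose leaves match the locus tree's leaves.
#' @param lt the [locus_tree] (or `locus_history`) it was generated on.
#' @param tol numerical tolerance.
#' @return list with `ok` (logical) and `violations` (tibble with one row
#'   per violated bound: `node`, `height`, `mrca_height`).
#' @export
validate_bounds <- function(g, lt, tol = 1e-9) {
  if (inherits(lt, "locus_history")) lt <- lt$locus
  stopifnot(inherits(g, "gene_tree"), inherits(lt, "locus_tree"))
  gphy <- g$phylo
  if (!setequal(gphy$tip.label, lt$phylo$tip.label))
    stop("gene tree and locus tree have different leaf sets")
  below <- .tips_below(lt$phylo)
  hg <- node_heights(gphy)
  bad <- tibble::tibble(node = integer(), height = numeric(),
                        mrca_height = numeric())
  for (i in seq_len(nrow(lt$dup_points))) {
    v <- lt$dup_points$node[i]
    hgt <- lt$dup_points$height[i]
    constrained <- below[[v]]
    if (length(constrained) < 2L) next                  # vacuous
    mrca <- ape::getMRCA(gphy, constrained)
    if (hg[mrca] > hgt + tol)
      bad <- dplyr::bind_rows(bad, tibble::tibble(
        node = v, height = hgt, mrca_height = hg[mrca]))
  }
  list(ok = nrow(bad) == 0L, violations = bad)
}

#' Root-lineage scenario of four sampled genes
#'
#' Partitions four sampled genes `(a, b, c, d)` by the root lineage (index
#' in `1..l`) each descends from, e.g. `(ab,cd)` when
#' `i_a = i_b != i_c = i_d`.
#'
#' @param lh a `locus_history` from [sim_locus_tree()].
#' @param genes character vector of four extant locus-leaf labels, in the
#'   role order `(a, b, c, d)`.
#' @return object of class `scenario_label`: list with `partition` (e.g.
#'   `"(ab,cd)"`), `indices` (named integer vector) and `l`.
#' @export
classify_scenario <- function(lh, genes) {
  stopifnot(inherits(lh, "locus_history"), length(genes) == 4L)
  missing <- setdiff(genes, names(lh$root_lineage))
  if (length(missing))
    stop("gene(s) absent from the locus history: ",
         paste(missing, collapse = ", "))
  idx <- unname(lh$root_lineage[genes])
  letters4 <- c("a", "b", "c", "d")
  groups <- split(letters4, match(idx, unique(idx)))
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  partition <- paste0("(", paste(vapply(groups, paste0, "", collapse = ""),
                                 collapse = ","), ")")
  structure(list(partition = partition,
                 indices = setNames(idx, letters4), l = lh$l),
            class = "scenario_label")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat("<scenario_label> ", x$partition, "  indices: ",
      paste(x$indices, collapse = " "), "  l = ", x$l, "\n", sep = "")
  invisible(x)
}
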