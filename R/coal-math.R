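## Exact coalescent probability kernels.
##
## `coal_prob()` is the Tavare lineage-count law g_{i,j}(x): the probability
## that i lineages entering an edge have coalesced down to j lineages after
## x coalescent units.  On top of it sit the bounded pair-coalescence law,
## a dynamic program for "all lineages coalesced before a bound", and the
## closed-form quartet-topology distributions for four-leaf locus trees
## under every duplication placement.

#' Tavare lineage-count probability \eqn{g_{i,j}(x)}
#'
#' Probability that `i` gene lineages entering an edge coalesce down to
#' exactly `j` lineages within `x` coalescent units, under the Kingman
#' coalescent (rate 1 per lineage pair):
#' \deqn{g_{i,j}(x)=\sum_{k=j}^{i} e^{-k(k-1)x/2}\,
#'   \frac{(2k-1)(-1)^{k-j}}{j!\,(k-j)!\,(j+k-1)}
#'   \prod_{m=0}^{k-1}\frac{(j+m)(i-m)}{i+m}.}
#'
#' @param i number of entering lineages (>= 1).
#' @param j number of remaining lineages, `1 <= j <= i`.
#' @param x elapsed time in coalescent units (vectorised, `>= 0`).
#' @return numeric vector of probabilities, one per element of `x`.
#' @examples
#' coal_prob(2, 1, 1)          # 1 - exp(-1)
#' sum(sapply(1:5, coal_prob, i = 5, x = 0.7))  # == 1
#' @export
coal_prob <- function(i, j, x) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != 1L || length(j) != 1L || j < 1L || j > i)
    stop("need scalar i, j with 1 <= j <= i")
  if (any(x < 0)) stop("`x` must be non-negative")
  out <- numeric(length(x))
  for (k in j:i) {
    m <- seq_len(k) - 1L                      # 0 .. k-1
    lprod <- sum(log(j + m) + log(i - m) - log(i + m))
    coef <- (2 * k - 1) * (-1)^(k - j) /
      (factorial(j) * factorial(k - j) * (j + k - 1)) * exp(lprod)
    decay <- if (k < 2L) rep(1, length(x)) else exp(-k * (k - 1) / 2 * x)
    out <- out + coef * decay
  }
  pmin(pmax(out, 0), 1)
}

#' Pair coalescence under a duplication bound
#'
#' Probability that two lineages have coalesced within time `x` given that
#' they must coalesce before a duplication-point: the unbounded law
#' \eqn{1-e^{-x}} renormalised by the prior probability of coalescing before
#' the bound, \eqn{(1-e^{-x})/p_{prior}}.
#'
#' @param x elapsed time in coalescent units; must not exceed the time to
#'   the bound (i.e. `1 - exp(-x) <= p_prior`, up to `tol`).
#' @param p_prior probability, under unbounded coalescence, that the pair
#'   coalesces before the bound; `p_prior = 1` recovers the unbounded law.
#' @param tol numerical tolerance for the domain check.
#' @return probability in `[0, 1]`.
#' @export
bounded_pair_prob <- function(x, p_prior, tol = 1e-9) {
  if (any(x < 0)) stop("`x` must be non-negative")
  if (any(p_prior <= 0))
    stop("conditioning on a zero-probability bound event")
  if (any(p_prior > 1 + tol)) stop("`p_prior` must be a probability")
  raw <- -expm1(-x)
  if (any(raw > p_prior + tol))
    stop("`x` exceeds the time to the bound: 1 - exp(-x) > p_prior")
  pmin(pmax(raw / p_prior, 0), 1)
}

#' Probability that all lineages coalesce before a bound
#'
#' Dynamic program over the edges of a locus tree: one gene lineage enters
#' at every leaf, lineage-count distributions are propagated along each edge
#' with [coal_prob()], summed at internal nodes, and finished along the stem
#' from the root to `bound_height`.  This is the exact denominator of the
#' root-edge duplication cases ("all of a, b, c, d coalesced before the
#' duplication").
#'
#' @param tree `phylo` or [locus_tree]; duplication-points on `tree` are
#'   ignored — only the branching schedule matters.
#' @param bound_height absolute height of the bound; must be at least the
#'   root height.
#' @return probability that a single lineage remains at `bound_height`.
#' @export
prob_all_coalesced <- function(tree, bound_height) {
  phy <- as_phylo(tree)
  .assert_binary(phy)
  h <- node_heights(phy)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  if (bound_height < h[root] - 1e-9)
    stop("`bound_height` is below the root of the schedule")
  kids <- .children_list(phy)
  dist_at <- function(v) {                 # named prob vector over counts
    if (v <= ntip) return(c(`1` = 1))
    parts <- lapply(kids[[v]], function(u) {
      p <- dist_at(u)
      .edge_transform(p, h[v] - h[u])
    })
    Reduce(.count_convolve, parts)
  }
  p <- dist_at(root)
  p <- .edge_transform(p, bound_height - h[root])
  unname(p["1"]) %||% 0
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.edge_transform <- function(p, len) {
  ns <- as.integer(names(p))
  out <- numeric(max(ns))
  for (ii in seq_along(ns)) {
    n <- ns[ii]
    for (j in seq_len(n)) out[j] <- out[j] + p[ii] * coal_prob(n, j, len)
  }
  setNames(out, seq_along(out))[out > 0 | seq_along(out) == 1L]
}

.count_convolve <- function(p, q) {
  np <- as.integer(names(p)); nq <- as.integer(names(q))
  out <- numeric(max(np) + max(nq))
  for (a in seq_along(np)) for (b in seq_along(nq))
    out[np[a] + nq[b]] <- out[np[a] + nq[b]] + p[a] * q[b]
  setNames(out, seq_along(out))[out > 0]
}

## --------------------------------------------------------------- case maths

#' Parameters of a four-leaf locus-tree case
#'
#' Describes the restriction of a locus tree to four genes from four
#' distinct species, displaying quartet `ab|cd`, in the coordinates used by
#' the closed forms: for the balanced shape `((a,b),(c,d))`, `x` and `y` are
#' the lengths of the two internal edges; for the caterpillar
#' `(((a,b),c),d)`, `x` is the cherry edge and `y` the edge from the
#' `abc`-ancestor to the root.  For a duplication on the planted root edge,
#' `t` is the time from the root vertex of the quartet up to the
#' duplication-point; for a caterpillar duplication on `Y`, `t` is the time
#' from the `abc`-ancestor up to the point.  `z` is the point's absolute
#' height (informational; the closed forms use `t`).
#'
#' @param shape `"balanced"` or `"caterpillar"`.
#' @param dup_case one of `"none"`, `"dup_on_X"`, `"dup_on_Y"`,
#'   `"dup_on_root_edge"`, `"dup_at_root_vertex"`.
#' @param x,y internal edge lengths (coalescent units, > 0).
#' @param t time from the relevant subtree top to the duplication-point.
#' @param z absolute height of the duplication-point (optional).
#' @return object of class `case_params`.
#' @export
case_params <- function(shape = c("balanced", "caterpillar"),
                        dup_case = c("none", "dup_on_X", "dup_on_Y",
                                     "dup_on_root_edge",
                                     "dup_at_root_vertex"),
                        x, y = NULL, t = NULL, z = NULL) {
  shape <- match.arg(shape)
  dup_case <- match.arg(dup_case)
  if (shape == "caterpillar" && dup_case == "dup_at_root_vertex")
    stop("a caterpillar duplication-point at the root vertex is a Y-edge ",
         "duplication with t = y; use dup_on_Y")
  if (x <= 0) stop("`x` must be positive")
  if (shape == "balanced" && (is.null(y) || y <= 0))
    stop("balanced cases need `y` > 0")
  if (dup_case %in% c("dup_on_root_edge") && (is.null(t) || t <= 0))
    stop("root-edge duplication cases need `t` > 0")
  if (shape == "caterpillar" && dup_case == "dup_on_Y") {
    if (is.null(t) || t <= 0)
      stop("caterpillar Y-edge duplication needs `t` > 0")
    if (!is.null(y) && t > y + 1e-9)
      stop("`t` exceeds the Y edge length")
  }
  if (shape == "caterpillar" && dup_case == "dup_on_root_edge" &&
      (is.null(y) || y <= 0))
    stop("caterpillar root-edge duplication needs `y` > 0")
  structure(list(shape = shape, dup_case = dup_case,
                 x = x, y = y, t = t, z = z),
            class = "case_params")
}

#' @export
print.case_params <- function(x, ...) {
  cat("<case_params> ", x$shape, ", ", x$dup_case,
      ": x = ", x$x,
      if (!is.null(x$y)) paste0(", y = ", x$y),
      if (!is.null(x$t)) paste0(", t = ", x$t), "\n", sep = "")
  invisible(x)
}

## schedule trees used for the DP denominators (pendant lengths are
## irrelevant: a single lineage does not change along a pendant edge)
.case_schedule <- function(params) {
  with(params, switch(
    paste(shape, dup_case),
    "balanced dup_on_root_edge" = {
      hr <- 1 + max(x, y)
      s <- sprintf("((a:%.12g,b:%.12g):%.12g,(c:%.12g,d:%.12g):%.12g):1;",
                   hr - x, hr - x, x, hr - y, hr - y, y)
      read_newick(s)
    },
    "caterpillar dup_on_Y" = {
      s <- sprintf("((a:1,b:1):%.12g,c:%.12g):1;", x, 1 + x)
      read_newick(s)
    },
    "caterpillar dup_on_root_edge" = {
      s <- sprintf("(((a:1,b:1):%.12g,c:%.12g):%.12g,d:%.12g):1;",
                   x, 1 + x, y, 1 + x + y)
      read_newick(s)
    },
    stop("no DP schedule for this case")))
}

#' Closed-form quartet-topology distribution of a four-leaf locus tree
#'
#' Given the case parameters of a four-leaf locus tree displaying `ab|cd`,
#' returns the exact probabilities that the gene tree produced by the
#' bounded multispecies coalescent displays `ab|cd` (`p_match`), `ac|bd`
#' (`p_alt1`) and `ad|bc` (`p_alt2`).  The two alternatives are equal by
#' symmetry in every case.
#'
#' The cases: with no duplication the unbounded law
#' \eqn{p_{match} = 1 - \frac{2}{3}e^{-s}} applies with `s = x + y`
#' (balanced) or `s = x` (caterpillar).  A duplication on an internal edge
#' below the root (`dup_on_X`, balanced `dup_on_Y`, or a duplication at the
#' root vertex) forces the matching topology, `p_match = 1`.  A caterpillar
#' duplication on `Y` gives
#' \eqn{p_{alt} = \frac{1}{3}e^{-x} g_{3,1}(t) / D} with
#' \eqn{D = \sum_j g_{2,j}(x)\,g_{j+1,1}(t)} the probability that a, b, c
#' coalesced before the duplication.  A duplication on the root edge gives,
#' for the balanced shape,
#' \eqn{p_{alt} = \frac{1}{3}e^{-(x+y)} g_{4,1}(t) / D} and for the
#' caterpillar
#' \eqn{p_{alt} = \frac{1}{3}e^{-x}\,(g_{3,2}(y)g_{3,1}(t) +
#' g_{3,1}(y)g_{2,1}(t) + g_{3,3}(y)g_{4,1}(t)) / D}, where `D` is the
#' probability that all four lineages coalesced before the duplication,
#' computed by the lineage-count dynamic program ([prob_all_coalesced()]).
#'
#' @param params a [case_params] object (e.g. from
#'   [classify_locus_case()]).
#' @return named numeric vector `c(p_match, p_alt1, p_alt2)` summing to 1.
#' @examples
#' quartet_probs(case_params("balanced", "none", x = 0.5, y = 0.5))
#' @export
quartet_probs <- function(params) {
  stopifnot(inherits(params, "case_params"))
  p_alt <- with(params, switch(
    paste(shape, dup_case),
    "balanced none" = exp(-(x + y)) / 3,
    "caterpillar none" = exp(-x) / 3,
    "balanced dup_on_X" = ,
    "balanced dup_on_Y" = ,
    "balanced dup_at_root_vertex" = ,
    "caterpillar dup_on_X" = 0,
    "balanced dup_on_root_edge" = {
      sched <- .case_schedule(params)
      D <- prob_all_coalesced(sched, node_heights(sched)[5L] + t)
      exp(-(x + y)) * coal_prob(4, 1, t) / (3 * D)
    },
    "caterpillar dup_on_Y" = {
      sched <- .case_schedule(params)
      D <- prob_all_coalesced(sched, node_heights(sched)[4L] + t)
      exp(-x) * coal_prob(3, 1, t) / (3 * D)
    },
    "caterpillar dup_on_root_edge" = {
      sched <- .case_schedule(params)
      D <- prob_all_coalesced(sched, node_heights(sched)[5L] + t)
      num <- coal_prob(3, 2, y) * coal_prob(3, 1, t) +
        coal_prob(3, 1, y) * coal_prob(2, 1, t) +
        coal_prob(3, 3, y) * coal_prob(4, 1, t)
      exp(-x) * num / (3 * D)
    },
    stop("unsupported case: ", shape, " / ", dup_case)))
  if (p_alt < -1e-12 || p_alt > 1 / 3 + 1e-12)
    stop("internal error: alternative-quartet probability ", p_alt,
         " outside [0, 1/3]")
  p_alt <- min(max(p_alt, 0), 1 / 3)
  c(p_match = 1 - 2 * p_alt, p_alt1 = p_alt, p_alt2 = p_alt)
}

#' Classify the duplication case of a four-leaf locus tree
#'
#' Identifies the shape (balanced or caterpillar), the governing duplication
#' placement and the case coordinates of a locus tree restricted to four
#' genes from four distinct species.  Duplication-points on external
#' (pendant) edges do not affect the coalescence of the four lineages and
#' are ignored.  When several placements co-occur the lower one governs: a
#' duplication on an internal edge below the root forces the matching
#' topology outright, so it dominates any duplication above it; a
#' caterpillar `Y`-edge duplication dominates a root-edge duplication.
#'
#' @param lt a [locus_tree] with exactly four leaves from four distinct
#'   species.
#' @return a [case_params] object; additionally carries the displayed
#'   quartet as attribute `"quartet"` (ordered leaf labels, cherry pair
#'   first).
#' @export
classify_locus_case <- function(lt) {
  stopifnot(inherits(lt, "locus_tree"))
  phy <- lt$phylo
  if (ape::Ntip(phy) != 4L) stop("locus tree must have exactly 4 leaves")
  if (length(unique(lt$species)) != 4L)
    stop("the four leaves must come from four distinct species")
  h <- node_heights(phy)
  root <- 5L
  kids <- .children_list(phy)
  below <- .tips_below(phy, kids)
  ch <- kids[[root]]
  internal_ch <- ch[ch > 4L]
  tol <- 1e-9

  if (length(internal_ch) == 2L) {             # balanced ((a,b),(c,d))
    shape <- "balanced"
    xn <- internal_ch[1L]; yn <- internal_ch[2L]
    ## X = cherry holding the smallest label, for a deterministic frame
    if (min(below[[yn]]) < min(below[[xn]])) { tmp <- xn; xn <- yn; yn <- tmp }
    x <- h[root] - h[xn]; y <- h[root] - h[yn]
    quart <- c(sort(below[[xn]]), sort(below[[yn]]))
    internal_nodes <- c(xn, yn)
    sub_top <- h[root]
  } else if (length(internal_ch) == 1L) {      # caterpillar (((a,b),c),d)
    shape <- "caterpillar"
    abc <- internal_ch
    d_tip <- ch[ch <= 4L]
    ab <- kids[[abc]][kids[[abc]] > 4L]
    if (length(ab) != 1L) stop("unexpected four-leaf topology")
    c_tip <- kids[[abc]][kids[[abc]] <= 4L]
    x <- h[abc] - h[ab]; y <- h[root] - h[abc]
    quart <- c(sort(below[[ab]]), phy$tip.label[c_tip], phy$tip.label[d_tip])
    internal_nodes <- c(X = ab, Y = abc)
    sub_top <- h[abc]
  } else stop("unexpected four-leaf topology")

  dup <- lt$dup_points
  pick <- function(nodes) {
    rows <- dup[dup$node %in% nodes, , drop = FALSE]
    if (!nrow(rows)) NULL else rows[which.min(rows$height), , drop = FALSE]
  }
  t <- NULL; z <- NULL
  if (shape == "balanced") {
    on_int <- pick(internal_nodes)
    on_root <- pick(root)
    if (!is.null(on_int)) {
      dup_case <- if (on_int$height >= h[root] - tol)
        "dup_at_root_vertex" else "dup_on_X"
      z <- on_int$height
    } else if (!is.null(on_root)) {
      dup_case <- "dup_on_root_edge"
      z <- on_root$height; t <- z - h[root]
      if (t <= tol)
        stop("root-edge duplication-point at the root vertex is degenerate")
    } else dup_case <- "none"
  } else {
    on_x <- pick(internal_nodes[["X"]])
    on_y <- pick(internal_nodes[["Y"]])
    on_root <- pick(root)
    if (!is.null(on_x)) {
      dup_case <- "dup_on_X"; z <- on_x$height
    } else if (!is.null(on_y)) {
      dup_case <- "dup_on_Y"
      z <- on_y$height; t <- z - sub_top
      if (t <= tol)
        stop("Y-edge duplication-point at the abc-ancestor is degenerate: ",
             "it would require a, b and c to coalesce in zero time")
    } else if (!is.null(on_root)) {
      dup_case <- "dup_on_root_edge"
      z <- on_root$height; t <- z - h[root]
      if (t <= tol)
        stop("root-edge duplication-point at the root vertex is degenerate")
    } else dup_case <- "none"
  }
  out <- case_params(shape, dup_case, x = x, y = y, t = t, z = z)
  attr(out, "quartet") <- quart
  out
}
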