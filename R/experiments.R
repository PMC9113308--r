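## Monte-Carlo oracles and theorem-verification harness.
##
## These routines re-derive, by simulation, the quantities the closed forms
## and consistency arguments predict: quartet frequencies on fixed four-leaf
## locus trees, scenario-stratified quartet behaviour under the full DLCoal
## process, and the convergence of the dominant quartet to the species
## quartet as the number of gene families grows.

## deterministic substream seed for family/cell `i`, stage `stage`
.derive_seed <- function(master, i, stage = 0L) {
  as.integer((as.double(master) * 48271 + i * 7919 + stage * 104729) %%
               2147483563) + 1L
}

#' Monte-Carlo quartet frequencies on a fixed four-leaf locus tree
#'
#' Simulates the bounded multispecies coalescent on `lt` repeatedly and
#' reports the frequency of each quartet topology, with binomial standard
#' errors.  `"match"` is the topology displayed by the locus tree itself.
#'
#' @param lt a four-leaf [locus_tree].
#' @param n_reps number of replicates (>= 100 for the SE to be meaningful).
#' @param seed integer seed.
#' @return tibble with columns `topology` (`match`, `alt1`, `alt2`),
#'   `split`, `freq`, `se`, `n_reps`.
#' @export
mc_quartet_probs <- function(lt, n_reps = 1e4, seed = 1L) {
  stopifnot(inherits(lt, "locus_tree"))
  if (ape::Ntip(lt$phylo) != 4L) stop("locus tree must have 4 leaves")
  if (n_reps < 100) stop("`n_reps` < 100 gives meaningless standard errors")
  set.seed(seed)
  tips <- sort(lt$phylo$tip.label)
  disp <- quartet_topology(lt, tips, as_index = TRUE)
  ## role order (a, b, c, d): arrangement of sorted tips whose split 1 is
  ## the displayed quartet
  role <- switch(disp, tips, tips[c(1L, 3L, 2L, 4L)], tips[c(1L, 4L, 2L, 3L)])
  pre <- .bmsc_compile(lt)
  leaf_pos <- match(lt$phylo$tip.label, role)
  env <- new.env(parent = emptyenv())
  counts <- c(0L, 0L, 0L)
  for (r in seq_len(n_reps)) {
    env$tries <- 0L; env$next_id <- pre$ntip
    k <- .bmsc_topology_once(pre, env, leaf_pos)
    counts[k] <- counts[k] + 1L
  }
  freq <- counts / n_reps
  tibble::tibble(
    topology = c("match", "alt1", "alt2"),
    split = vapply(1:3, quartet_split, "", labels = role),
    freq = freq,
    se = sqrt(freq * (1 - freq) / n_reps),
    n_reps = n_reps)
}

#' Build the four-leaf locus tree realising a closed-form case
#'
#' Species are `A, B, C, D` with one gene each (`A_1`, ...).  Pendant edges
#' are chosen so the tree is ultrametric; the duplication-point is placed
#' mid-edge for internal-edge cases, at height `t` above the relevant
#' subtree top for `dup_on_Y` / `dup_on_root_edge`, and at the root height
#' for `dup_at_root_vertex`.
#'
#' @param params a [case_params].
#' @param dup_frac relative position of an internal-edge duplication-point
#'   along its edge (0 = bottom, 1 = top); default mid-edge.
#' @return a [locus_tree] displaying `A_1 B_1 | C_1 D_1`.
#' @export
case_locus_tree <- function(params, dup_frac = 0.5) {
  stopifnot(inherits(params, "case_params"))
  with(params, {
    if (shape == "balanced") {
      hr <- 1 + max(x, y)
      re <- max(t %||% 0 + 1, 1)
      txt <- sprintf(
        "((A_1:%.12g,B_1:%.12g):%.12g,(C_1:%.12g,D_1:%.12g):%.12g):%.12g;",
        hr - x, hr - x, x, hr - y, hr - y, y, re)
      phy <- read_newick(txt)
      ab <- ape::getMRCA(phy, c("A_1", "B_1"))
      dup <- switch(dup_case,
        none = NULL,
        dup_on_X = data.frame(node = ab, height = hr - x + dup_frac * x),
        dup_on_Y = data.frame(node = ape::getMRCA(phy, c("C_1", "D_1")),
                              height = hr - y + dup_frac * y),
        dup_at_root_vertex = data.frame(node = ab, height = hr),
        dup_on_root_edge = data.frame(node = 5L, height = hr + t))
      locus_tree(phy, dup_points = dup)
    } else {
      hr <- 1 + x + (y %||% 1)
      yy <- y %||% 1
      re <- max(t %||% 0 + 1, 1)
      txt <- sprintf(
        "(((A_1:1,B_1:1):%.12g,C_1:%.12g):%.12g,D_1:%.12g):%.12g;",
        x, 1 + x, yy, hr, re)
      phy <- read_newick(txt)
      ab <- ape::getMRCA(phy, c("A_1", "B_1"))
      abc <- ape::getMRCA(phy, c("A_1", "B_1", "C_1"))
      dup <- switch(dup_case,
        none = NULL,
        dup_on_X = data.frame(node = ab, height = 1 + dup_frac * x),
        dup_on_Y = data.frame(node = abc, height = 1 + x + t),
        dup_on_root_edge = data.frame(node = 5L, height = hr + t))
      locus_tree(phy, dup_points = dup)
    }
  })
}

#' Default verification grid for the closed-form cases
#'
#' One representative parameter cell per duplication case and shape,
#' spanning weak and strong incomplete lineage sorting at desk-scale
#' runtime.
#'
#' @return tibble with columns `shape`, `dup_case`, `x`, `y`, `t`.
#' @export
default_case_grid <- function() {
  tibble::tribble(
    ~shape,        ~dup_case,           ~x,  ~y,  ~t,
    "balanced",    "none",              0.2, 1.0, NA,
    "balanced",    "dup_on_X",          1.0, 1.0, NA,
    "balanced",    "dup_at_root_vertex", 1.0, 1.0, NA,
    "balanced",    "dup_on_root_edge",  0.5, 0.5, 1.0,
    "balanced",    "dup_on_root_edge",  1.0, 0.2, 0.3,
    "caterpillar", "none",              1.0, 1.0, NA,
    "caterpillar", "dup_on_X",          1.0, 1.0, NA,
    "caterpillar", "dup_on_Y",          1.0, 1.0, 0.5,
    "caterpillar", "dup_on_Y",          0.2, 1.0, 1.0,
    "caterpillar", "dup_on_root_edge",  1.0, 0.5, 0.5,
    "caterpillar", "dup_on_root_edge",  0.2, 1.0, 1.0)
}

#' Closed forms versus Monte-Carlo oracle
#'
#' For every cell of the grid, evaluates the closed-form quartet
#' distribution and an independent Monte-Carlo estimate on the realised
#' locus tree, and reports per-topology z-scores
#' `(closed form - MC frequency) / SE`.  Also checks, on the closed forms,
#' that the matching probability is non-decreasing in `x` at fixed `y`, `t`
#' and duplication placement (strictly increasing except under an X-edge
#' duplication, where it is constantly 1).
#'
#' @param grid tibble as [default_case_grid()].
#' @param n_reps Monte-Carlo replicates per cell.
#' @param seed master seed; each cell uses a derived substream.
#' @return object of class `closed_form_report`: list with `cells` (one
#'   row per cell: closed forms, MC frequencies, `z_match`, `z_alt1`,
#'   `z_alt2`, `z_max`) and `monotonicity` (one row per case family:
#'   `increasing` flag).
#' @export
check_closed_forms <- function(grid = default_case_grid(), n_reps = 1e5,
                               seed = 20210528) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    params <- case_params(gr$shape, gr$dup_case, x = gr$x, y = gr$y,
                          t = if (is.na(gr$t)) NULL else gr$t)
    cf <- quartet_probs(params)
    lt <- case_locus_tree(params)
    mc <- mc_quartet_probs(lt, n_reps = n_reps,
                           seed = .derive_seed(seed, i))
    z <- (cf - mc$freq) / ifelse(mc$se > 0, mc$se, 1)
    z[mc$se == 0 & abs(cf - mc$freq) > 0] <- Inf
    rows[[i]] <- tibble::tibble(
      shape = gr$shape, dup_case = gr$dup_case,
      x = gr$x, y = gr$y, t = gr$t, n_reps = n_reps,
      p_match = cf[["p_match"]], p_alt = cf[["p_alt1"]],
      mc_match = mc$freq[1L], mc_alt1 = mc$freq[2L], mc_alt2 = mc$freq[3L],
      z_match = z[[1L]], z_alt1 = z[[2L]], z_alt2 = z[[3L]],
      z_max = max(abs(z)))
  }
  cells <- dplyr::bind_rows(rows)
  ## closed-form monotonicity in x (fixed y, t, placement)
  xs <- c(0.2, 0.5, 1, 2, 3)
  mono <- dplyr::bind_rows(lapply(
    list(list("balanced", "none", 1, NULL),
         list("balanced", "dup_on_root_edge", 1, 0.5),
         list("caterpillar", "none", 1, NULL),
         list("caterpillar", "dup_on_X", 1, NULL),
         list("caterpillar", "dup_on_Y", 1, 0.5),
         list("caterpillar", "dup_on_root_edge", 1, 0.5)),
    function(cs) {
      pm <- vapply(xs, function(xx)
        quartet_probs(case_params(cs[[1]], cs[[2]], x = xx, y = cs[[3]],
                                  t = cs[[4]]))[["p_match"]], 0)
      tibble::tibble(shape = cs[[1]], dup_case = cs[[2]],
                     increasing = all(diff(pm) >= -1e-12),
                     strictly = all(diff(pm) > 1e-12),
                     constant_one = all(abs(pm - 1) < 1e-12))
    }))
  structure(list(cells = cells, monotonicity = mono),
            class = "closed_form_report")
}

#' @export
print.closed_form_report <- function(x, ...) {
  worst <- max(x$cells$z_max)
  ok <- worst <= 4 && all(x$monotonicity$increasing)
  cat("<closed_form_report> ", nrow(x$cells), " cells, max |z| = ",
      signif(worst, 3), if (ok) " [PASS]" else " [FLAG]", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.closed_form_report <- function(x, ...) x$cells

## -------------------------------------------------- full-process harness

#' Simulate one usable gene family
#'
#' Draws locus and gene trees from the DLCoal process until a family
#' containing at least one copy of every species in `need` is obtained
#' (families with missing species are discarded, matching the conditioning
#' of the consistency analysis).
#'
#' @param species ultrametric species tree (`phylo` with `root.edge`).
#' @param lam,mu duplication and loss rates.
#' @param need species that must be present; defaults to all tips.
#' @param seed optional integer seed.
#' @param max_attempts cap on discarded families.
#' @return list with `lh` (locus_history), `gt` ([gene_tree]) and
#'   `attempts`.
#' @export
sim_usable_family <- function(species, lam, mu, need = NULL, seed = NULL,
                              max_attempts = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  phy <- as_phylo(species)
  if (is.null(need)) need <- phy$tip.label
  for (attempt in seq_len(max_attempts)) {
    lh <- sim_locus_tree(phy, lam, mu)
    if (is.null(lh$locus)) next
    if (!all(need %in% lh$locus$species)) next
    gt <- sim_gene_tree(lh)
    return(list(lh = lh, gt = gt, attempts = attempt))
  }
  stop("no usable family in ", max_attempts, " attempts")
}

#' Scenario-stratified quartet behaviour under DLCoal
#'
#' Simulates gene families on a four-taxon species tree, samples one gene
#' per species uniformly, classifies each family's root-lineage scenario,
#' and stratifies quartet outcomes.  Reports (i) per-partition counts with
#' the frequency comparison `(ab,cd)` vs `(ac,bd)`, (ii) the cross-clade
#' pair-index agreement frequency against its exact value `1/l`, and (iii)
#' per-stratum quartet frequencies (strata with fewer than `min_stratum`
#' families are marked inconclusive rather than dropped).
#'
#' @param species ultrametric four-taxon species tree displaying
#'   `s1 s2 | s3 s4` for its sorted tip labels.
#' @param lam,mu duplication and loss rates.
#' @param n_families number of usable families.
#' @param seed master seed.
#' @param min_stratum minimal stratum size for a conclusive frequency.
#' @return object of class `scenario_report`: list of tibbles `records`,
#'   `partitions`, `pair_index`, `strata`, plus `discard_rate`.
#' @export
scenario_check <- function(species, lam, mu, n_families = 2000,
                           seed = 1L, min_stratum = 50L) {
  phy <- as_phylo(species)
  stopifnot(ape::Ntip(phy) == 4L)
  sp4 <- sort(phy$tip.label)
  disp <- quartet_topology(phy, sp4, as_index = TRUE)
  role <- switch(disp, sp4, sp4[c(1L, 3L, 2L, 4L)], sp4[c(1L, 4L, 2L, 3L)])
  rec <- vector("list", n_families)
  attempts <- 0L
  for (i in seq_len(n_families)) {
    fam <- sim_usable_family(phy, lam, mu, seed = .derive_seed(seed, i))
    attempts <- attempts + fam$attempts
    genes <- vapply(role, function(sp) {
      cp <- fam$lh$leaves[startsWith(fam$lh$leaves, paste0(sp, "_"))]
      cp[sample.int(length(cp), 1L)]
    }, "")
    sc <- classify_scenario(fam$lh, genes)
    k <- quartet_topology(fam$gt, genes, as_index = TRUE)
    rec[[i]] <- tibble::tibble(
      family = i, partition = sc$partition, l = sc$l,
      i_a = sc$indices[["a"]], i_c = sc$indices[["c"]],
      quartet = k)
  }
  records <- dplyr::bind_rows(rec)
  partitions <- records |>
    dplyr::count(.data$partition, name = "n_families") |>
    dplyr::arrange(dplyr::desc(.data$n_families))
  pair_index <- records |>
    dplyr::group_by(l = .data$l) |>
    dplyr::summarise(n = dplyr::n(),
                     freq_ia_eq_ic = mean(.data$i_a == .data$i_c),
                     expected = 1 / .data$l[1L],
                     se = sqrt(.data$expected * (1 - .data$expected) /
                                 dplyr::n()),
                     .groups = "drop")
  strata <- records |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(n = dplyr::n(),
                     freq_match = mean(.data$quartet == 1L),
                     freq_alt1 = mean(.data$quartet == 2L),
                     freq_alt2 = mean(.data$quartet == 3L),
                     conclusive = dplyr::n() >= min_stratum,
                     .groups = "drop")
  structure(list(records = records, partitions = partitions,
                 pair_index = pair_index, strata = strata,
                 discard_rate = 1 - n_families / attempts,
                 role = role),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", nrow(x$records), " families, discard rate ",
      signif(x$discard_rate, 3), "\n", sep = "")
  print(x$strata)
  invisible(x)
}

#' Convergence of quartet-based estimation to the species tree
#'
#' For each dataset replicate, simulates gene families on a four-taxon
#' species tree and asks, at increasing family counts `m`, whether the
#' dominant quartet (ASTRAL-one sampling, ASTRAL-multi tallying, or both)
#' equals the species-tree quartet.  Families are accumulated, so curves
#' within a replicate are nested.
#'
#' @param species ultrametric four-taxon species tree.
#' @param lam,mu duplication and loss rates.
#' @param gene_counts increasing vector of family counts at which to
#'   evaluate.
#' @param n_datasets number of independent dataset replicates.
#' @param mode `"one"`, `"multi"` or `"both"`.
#' @param seed master seed.
#' @return object of class `convergence_report`: list with `runs` (one row
#'   per replicate, mode and `m`: `correct` 0/1) and `curve` (fraction
#'   correct per mode and `m`).
#' @export
convergence_experiment <- function(species, lam = 0.3, mu = 0.3,
                                   gene_counts = c(50, 200, 1000),
                                   n_datasets = 10, mode = "both",
                                   seed = 1L) {
  phy <- as_phylo(species)
  stopifnot(ape::Ntip(phy) == 4L)
  if (is.unsorted(gene_counts)) stop("`gene_counts` must be increasing")
  modes <- if (mode == "both") c("one", "multi") else mode
  sp4 <- sort(phy$tip.label)
  true_idx <- quartet_topology(phy, sp4, as_index = TRUE)
  m_max <- max(gene_counts)
  runs <- list()
  for (r in seq_len(n_datasets)) {
    set.seed(.derive_seed(seed, r, stage = 9L))
    tally <- list(one = c(0, 0, 0), multi = c(0, 0, 0))
    ci <- 1L
    for (m in seq_len(m_max)) {
      fam <- sim_usable_family(phy, lam, mu)
      if ("one" %in% modes) {
        k <- astral_one_sample(fam$gt, sp4)
        tally$one[k] <- tally$one[k] + 1
      }
      if ("multi" %in% modes) {
        tl <- astral_multi_tally(fam$gt, sp4)
        tally$multi <- tally$multi +
          c(tl$n_ab_cd, tl$n_ac_bd, tl$n_ad_bc)
      }
      if (m == gene_counts[ci]) {
        for (md in modes)
          runs[[length(runs) + 1L]] <- tibble::tibble(
            dataset = r, mode = md, m = m,
            correct = as.integer(dominant_quartet(tally[[md]]) == true_idx))
        ci <- ci + 1L
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  curve <- runs |>
    dplyr::group_by(.data$mode, .data$m) |>
    dplyr::summarise(fraction_correct = mean(.data$correct),
                     n_datasets = dplyr::n(), .groups = "drop")
  structure(list(runs = runs, curve = curve), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  print(x$curve)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.convergence_report <- function(x, ...) x$curve
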