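test_that("with no duplications or losses the locus tree is the species tree", {
  sp <- balanced_species()
  lh <- sim_locus_tree(sp, lam = 0, mu = 0, seed = 1)
  expect_equal(lh$l, 1L)
  expect_equal(nrow(lh$locus$dup_points), 0L)
  expect_setequal(lh$leaves, c("A_1", "B_1", "C_1", "D_1"))
  ## same topology and branch lengths as the species tree
  relab <- lh$locus$phylo
  relab$tip.label <- sub("_1$", "", relab$tip.label)
  expect_identical(write_newick(relab), write_newick(sp))
  expect_true(all(lh$root_lineage == 1L))
})

test_that("root-lineage counts follow the pure-birth expectation", {
  ## with mu = 0 the number of lineages crossing the root speciation after
  ## a root edge of length T is geometric with mean exp(lam * T)
  sp <- balanced_species()
  lam <- 0.5
  set.seed(99)
  ls <- replicate(3000, sim_locus_tree(sp, lam, 0)$l)
  expect_equal(mean(ls), exp(lam * 1),
               tolerance = 4 * stats::sd(ls) / sqrt(length(ls)) /
                 exp(lam * 1))
})

test_that("simulation is reproducible under a fixed seed", {
  sp <- caterpillar_species()
  a <- sim_locus_tree(sp, 0.4, 0.2, seed = 123)
  b <- sim_locus_tree(sp, 0.4, 0.2, seed = 123)
  expect_identical(write_newick(a$locus), write_newick(b$locus))
  expect_identical(a$root_lineage, b$root_lineage)
  ga <- sim_gene_tree(a, seed = 5)
  gb <- sim_gene_tree(b, seed = 5)
  expect_identical(write_newick(ga$phylo), write_newick(gb$phylo))
})

test_that("every duplication node carries its daughter duplication-point", {
  set.seed(17)
  n_dup_nodes <- 0L
  for (i in 1:150) {
    lh <- sim_locus_tree(balanced_species(), 0.5, 0.1)
    if (is.null(lh$locus)) next
    lt <- lh$locus
    ## each duplication-point must sit at the top of its edge or inside it
    h <- node_heights(lt$phylo)
    for (j in seq_len(nrow(lt$dup_points))) {
      v <- lt$dup_points$node[j]
      expect_gte(lt$dup_points$height[j], h[v] - 1e-9)
    }
    n_dup_nodes <- n_dup_nodes + nrow(lt$dup_points)
  }
  expect_gt(n_dup_nodes, 50L)   # the rate grid actually produced dups
})

test_that("generated gene trees always satisfy the coalescence bounds", {
  set.seed(31)
  checked <- 0L
  for (rate in c(0.1, 0.3, 0.5)) {
    for (i in 1:80) {
      lh <- sim_locus_tree(balanced_species(), rate, rate)
      if (is.null(lh$locus)) next
      gt <- sim_gene_tree(lh)
      v <- validate_bounds(gt, lh)
      expect_true(v$ok)
      ## gene trees are ultrametric and fully resolved
      expect_silent(node_heights(gt$phylo))
      expect_equal(ape::Ntip(gt$phylo), length(lh$leaves))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 150L)
})

test_that("validate_bounds flags a constructed violation", {
  txt <- "((a:1,b:1):1[&&NHX:DUPTIME=1.2],(c:1,d:1):1):1;"
  lt <- read_newick(txt, dialect = "nhx")
  ## gene tree in which a and b only meet above the duplication height
  bad <- gene_tree(read_newick("((a:1.6,c:1.6):1,(b:1.8,d:1.8):0.8):0;"),
                   species = setNames(c("A", "B", "C", "D"),
                                      c("a", "b", "c", "d")))
  v <- validate_bounds(bad, lt)
  expect_false(v$ok)
  expect_equal(nrow(v$violations), 1L)
  expect_equal(v$violations$height, 1.2)
  ## vacuous when there are no duplication-points
  lt0 <- read_newick("((a:1,b:1):1,(c:1,d:1):1):1;", dialect = "nhx")
  expect_true(validate_bounds(bad, lt0)$ok)
  expect_error(validate_bounds(bad, restrict_tree(lt, c("a", "b", "c"))),
               "different leaf sets")
})

test_that("root-lineage scenarios are classified by index partition", {
  fake <- structure(list(
    root_lineage = setNames(c(1L, 1L, 2L, 2L, 3L),
                            c("A_1", "B_1", "C_1", "D_1", "D_2")),
    leaves = c("A_1", "B_1", "C_1", "D_1", "D_2"), l = 3L),
    class = "locus_history")
  expect_identical(
    classify_scenario(fake, c("A_1", "B_1", "C_1", "D_1"))$partition,
    "(ab,cd)")
  fake$root_lineage[] <- c(1L, 2L, 1L, 2L, 3L)
  expect_identical(
    classify_scenario(fake, c("A_1", "B_1", "C_1", "D_1"))$partition,
    "(ac,bd)")
  fake$root_lineage[] <- c(1L, 2L, 3L, 4L, 4L)
  sc <- classify_scenario(fake, c("A_1", "B_1", "C_1", "D_1"))
  expect_identical(sc$partition, "(a,b,c,d)")
  expect_identical(sc$l, 3L)
  fake$root_lineage[] <- 1L
  expect_identical(
    classify_scenario(fake, c("A_1", "B_1", "C_1", "D_1"))$partition,
    "(abcd)")
  expect_error(classify_scenario(fake, c("A_1", "B_1", "C_1", "Z_9")),
               "absent")
})

test_that("an X-edge duplication forces the matching quartet in simulation", {
  lt <- case_locus_tree(case_params("balanced", "dup_on_X", x = 1, y = 1))
  set.seed(2)
  for (i in 1:200) {
    gt <- sim_gene_tree(lt)
    expect_identical(
      quartet_topology(gt, c("A_1", "B_1", "C_1", "D_1"), as_index = TRUE),
      1L)
  }
})

test_that("degenerate locus histories are handled", {
  sp <- balanced_species()
  set.seed(4)
  seen_small <- FALSE
  for (i in 1:200) {
    lh <- sim_locus_tree(sp, 0.05, 3)
    if (length(lh$leaves) < 2) {
      seen_small <- TRUE
      expect_null(lh$locus)
    }
  }
  expect_true(seen_small)
})
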