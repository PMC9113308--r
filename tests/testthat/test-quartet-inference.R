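test_that("single-copy trees give deterministic ASTRAL-one samples", {
  g <- gene_tree(read_newick("((A_1:1,B_1:1):1,(C_1:1,D_1:1):1):0;"))
  for (s in 1:5)
    expect_identical(astral_one_sample(g, c("A", "B", "C", "D"), seed = s), 1L)
  ## a missing species yields no sample
  expect_true(is.na(astral_one_sample(g, c("A", "B", "C", "E"))))
})

test_that("ASTRAL-one is constant when every combination agrees", {
  ## both A copies sit in the cherry with B: every pick displays AB|CD
  g <- gene_tree(read_newick(
    "(((A_1:1,A_2:1):1,B_1:2):1,(C_1:2,D_1:2):1):0;"))
  ks <- vapply(1:25, function(s)
    astral_one_sample(g, c("A", "B", "C", "D"), seed = s), 0L)
  expect_true(all(ks == 1L))
})

test_that("ASTRAL-one sampling frequencies match exact enumeration", {
  set.seed(21)
  g <- random_multicopy_gene_tree(c(A = 2, B = 1, C = 2, D = 2))
  sp4 <- c("A", "B", "C", "D")
  ## exact distribution: uniform over all copy combinations
  n <- oracle_multi_tally(g, sp4)
  p_exact <- n / sum(n)
  draws <- vapply(seq_len(4000), function(i) astral_one_sample(g, sp4), 0L)
  obs <- tabulate(draws, 3L)
  keep <- p_exact > 0
  chi <- stats::chisq.test(obs[keep], p = p_exact[keep])
  expect_gt(chi$p.value, 1e-4)
})

test_that("ASTRAL-multi tallies agree with brute-force enumeration", {
  set.seed(8)
  for (i in 1:100) {
    copies <- c(A = sample(1:3, 1), B = sample(1:3, 1),
                C = sample(1:3, 1), D = sample(1:2, 1))
    g <- random_multicopy_gene_tree(copies)
    tl <- astral_multi_tally(g, c("A", "B", "C", "D"))
    expect_identical(c(tl$n_ab_cd, tl$n_ac_bd, tl$n_ad_bc),
                     oracle_multi_tally(g, c("A", "B", "C", "D")))
    expect_identical(tl$n_combinations, as.integer(prod(copies)))
  }
})

test_that("ASTRAL-multi is equivariant under copy relabelling", {
  set.seed(9)
  g <- random_multicopy_gene_tree(c(A = 3, B = 2, C = 1, D = 2))
  tl <- astral_multi_tally(g, c("A", "B", "C", "D"))
  ## swap the labels of A_1 and A_3
  phy2 <- g$phylo
  sw <- phy2$tip.label
  sw[sw == "A_1"] <- "tmp"; sw[sw == "A_3"] <- "A_1"; sw[sw == "tmp"] <- "A_3"
  phy2$tip.label <- sw
  tl2 <- astral_multi_tally(gene_tree(phy2), c("A", "B", "C", "D"))
  expect_identical(tl[1:3], tl2[1:3])
})

test_that("dominant quartet uses the fixed tie-breaking order", {
  expect_identical(dominant_quartet(c(10, 3, 3)), 1L)
  expect_identical(dominant_quartet(c(5, 5, 2)), 1L)
  expect_identical(dominant_quartet(c(2, 5, 5)), 2L)
  expect_identical(dominant_quartet(c(0, 0, 1)), 3L)
  expect_error(dominant_quartet(c(0, 0, 0)), "empty tally")
})

test_that("exact search recovers the generating topology from clean tallies", {
  true <- ape::read.tree(text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1):0;")
  subsets <- combn(sort(true$tip.label), 4L)
  tl <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(i) {
    s4 <- subsets[, i]
    k <- quartet_topology(true, s4, as_index = TRUE)
    n <- c(0L, 0L, 0L); n[k] <- 100L
    data.frame(s1 = s4[1], s2 = s4[2], s3 = s4[3], s4 = s4[4],
               n1 = n[1], n2 = n[2], n3 = n[3])
  }))
  est <- infer_species_tree(tl)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
  expect_length(attr(est, "ties"), 1L)
})

test_that("exact search agrees with an independent brute-force scorer", {
  set.seed(14)
  taxa <- c("A", "B", "C", "D", "E")
  subsets <- combn(taxa, 4L)
  for (rep in 1:10) {
    tl <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(i) {
      s4 <- subsets[, i]
      n <- sample(0:30, 3)
      data.frame(s1 = s4[1], s2 = s4[2], s3 = s4[3], s4 = s4[4],
                 n1 = n[1], n2 = n[2], n3 = n[3])
    }))
    est <- infer_species_tree(tl)
    cand <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
    sc <- vapply(cand, oracle_tree_score, 0, tallies = tl)
    expect_equal(attr(est, "score"), max(sc))
    ## the returned tree attains the oracle maximum
    expect_equal(oracle_tree_score(est, tl), max(sc))
  }
  expect_error(infer_species_tree(
    data.frame(s1 = "A", s2 = "B", s3 = "C", s4 = "D",
               n1 = 1, n2 = 0, n3 = 0)[0, ]), "at least 4 taxa")
})

test_that("four-taxon inference reduces to the dominant quartet", {
  tl <- data.frame(s1 = "A", s2 = "B", s3 = "C", s4 = "D",
                   n1 = 3, n2 = 9, n3 = 1)
  est <- infer_species_tree(tl)
  expect_identical(quartet_topology(est, c("A", "B", "C", "D"),
                                    as_index = TRUE), 2L)
})

test_that("per-root-lineage copy counts are positively associated", {
  ## A_1 = number of a-copies descending from root lineage 1, B_1 likewise;
  ## shared duplication history below the root makes them positively
  ## correlated: mean(A1 B1) >= mean(A1) mean(B1) up to sampling error
  sp <- balanced_species()
  set.seed(61)
  a1 <- c(); b1 <- c(); ls <- c()
  for (i in 1:2500) {
    lh <- sim_locus_tree(sp, 0.3, 0.3)
    if (!length(lh$leaves)) next
    sp_of <- sub("_[0-9]+$", "", names(lh$root_lineage))
    a1 <- c(a1, sum(sp_of == "A" & lh$root_lineage == 1L))
    b1 <- c(b1, sum(sp_of == "B" & lh$root_lineage == 1L))
    ls <- c(ls, lh$l)
  }
  for (l in 1:2) {
    a <- a1[ls == l]; b <- b1[ls == l]
    n <- length(a)
    expect_gt(n, 200)
    gap <- mean(a * b) - mean(a) * mean(b)
    se <- stats::sd((a - mean(a)) * (b - mean(b))) / sqrt(n)
    expect_gt(gap, -4 * se)
  }
})

test_that("tally_all_quartets reuses one draw per tree in one mode", {
  set.seed(3)
  genes <- replicate(30, random_multicopy_gene_tree(
    c(A = 2, B = 2, C = 1, D = 1, E = 1)), simplify = FALSE)
  tl <- tally_all_quartets(genes, mode = "one", seed = 1)
  expect_equal(nrow(tl), choose(5, 4))
  expect_true(all(tl$n1 + tl$n2 + tl$n3 == tl$n_trees_used))
  expect_identical(tally_all_quartets(genes, mode = "one", seed = 1), tl)
  tm <- tally_all_quartets(genes, mode = "multi")
  expect_true(all(tm$n_trees_used == 30L))
})
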