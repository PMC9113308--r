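test_that("lineage-count probabilities match closed forms", {
  xs <- c(0.5, 1, 2)
  expect_equal(coal_prob(1, 1, xs), rep(1, 3))
  expect_equal(coal_prob(2, 1, xs), 1 - exp(-xs))
  expect_equal(coal_prob(3, 1, xs),
               1 - 1.5 * exp(-xs) + 0.5 * exp(-3 * xs), tolerance = 1e-12)
  for (i in 2:6)
    expect_equal(coal_prob(i, i, xs), exp(-choose(i, 2) * xs),
                 tolerance = 1e-12)
  expect_error(coal_prob(2, 3, 1), "1 <= j <= i")
  expect_error(coal_prob(2, 1, -1), "non-negative")
})

test_that("lineage-count law agrees with a Monte-Carlo Kingman simulator", {
  ## time for 3 lineages to reach 1 is Exp(3) + Exp(1)
  set.seed(1)
  n <- 4e4
  tt <- rexp(n, 3) + rexp(n, 1)
  for (x in c(0.5, 1, 2)) {
    p_hat <- mean(tt < x)
    se <- sqrt(p_hat * (1 - p_hat) / n)
    expect_lt(abs(coal_prob(3, 1, x) - p_hat), 4 * se)
  }
})

test_that("lineage-count law is a proper stochastic semigroup", {
  for (i in 1:10) for (x in c(0.01, 0.1, 1, 10)) {
    expect_equal(sum(vapply(1:i, coal_prob, 0, i = i, x = x)), 1,
                 tolerance = 1e-10)
  }
  ## semigroup property g(i,j,x+y) = sum_k g(i,k,x) g(k,j,y)
  for (i in c(3, 5, 8)) for (j in 1:2) {
    x <- 0.4; y <- 0.9
    lhs <- coal_prob(i, j, x + y)
    rhs <- sum(vapply(j:i, function(k)
      coal_prob(i, k, x) * coal_prob(k, j, y), 0))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  ## identity at zero, absorption at infinity
  for (i in 2:6) {
    expect_equal(coal_prob(i, i, 0), 1)
    for (j in seq_len(i - 1)) expect_equal(coal_prob(i, j, 0), 0)
    expect_equal(coal_prob(i, 1, 60), 1, tolerance = 1e-10)
  }
  ## full coalescence gets harder with more lineages (rejection envelope)
  for (s in c(0.01, 0.1, 0.5, 2)) {
    p <- vapply(2:8, coal_prob, 0, j = 1, x = s)
    expect_true(all(diff(p) < 0))
  }
})

test_that("bounded pair coalescence renormalises the unbounded law", {
  expect_equal(bounded_pair_prob(0, 0.5), 0)
  expect_equal(bounded_pair_prob(1.3, 1), 1 - exp(-1.3))
  x <- 0.8
  expect_equal(bounded_pair_prob(x, 1 - exp(-x)), 1)
  expect_error(bounded_pair_prob(1, 0), "zero-probability")
  expect_error(bounded_pair_prob(2, 1 - exp(-1)), "exceeds the time")
})

test_that("the all-coalesced DP matches direct enumeration", {
  ## two lineages on a stem
  two <- read_newick("(a:1,b:1):2;")
  expect_equal(prob_all_coalesced(two, 1 + 1.3), coal_prob(2, 1, 1.3),
               tolerance = 1e-12)
  ## balanced quartet: explicit double sum over surviving lineage counts
  x <- 0.7; y <- 0.4; t <- 0.9
  bal <- read_newick(sprintf(
    "((a:%g,b:%g):%g,(c:%g,d:%g):%g):3;", 1, 1, x, 1 + x - y, 1 + x - y, y))
  direct <- 0
  for (j in 1:2) for (k in 1:2)
    direct <- direct + coal_prob(2, j, x) * coal_prob(2, k, y) *
      coal_prob(j + k, 1, t)
  expect_equal(prob_all_coalesced(bal, 1 + x + t), direct,
               tolerance = 1e-12)
  ## caterpillar: nested sum
  cat4 <- read_newick(sprintf(
    "(((a:1,b:1):%g,c:%g):%g,d:%g):3;", x, 1 + x, y, 1 + x + y))
  direct2 <- 0
  for (j in 1:2) for (k in 1:(j + 1))
    direct2 <- direct2 + coal_prob(2, j, x) * coal_prob(j + 1, k, y) *
      coal_prob(k + 1, 1, t)
  expect_equal(prob_all_coalesced(cat4, 1 + x + y + t), direct2,
               tolerance = 1e-12)
  expect_error(prob_all_coalesced(bal, 0.5), "below the root")
})

test_that("closed-form quartet distributions reproduce the printed cases", {
  ## unbounded: p_match = 1 - (2/3) exp(-(x+y)) (balanced), exp(-x) (cat)
  p <- quartet_probs(case_params("balanced", "none", x = 0.6, y = 0.4))
  expect_equal(unname(p),
               c(1 - 2 / 3 * exp(-1), exp(-1) / 3, exp(-1) / 3),
               tolerance = 1e-12)
  p2 <- quartet_probs(case_params("caterpillar", "none", x = 1))
  expect_equal(unname(p2),
               c(1 - 2 / 3 * exp(-1), exp(-1) / 3, exp(-1) / 3),
               tolerance = 1e-12)
  ## internal-edge duplication forces the matching topology
  for (pp in list(case_params("balanced", "dup_on_X", x = 1, y = 1),
                  case_params("balanced", "dup_on_Y", x = 1, y = 1),
                  case_params("balanced", "dup_at_root_vertex", x = 1, y = 1),
                  case_params("caterpillar", "dup_on_X", x = 1, y = 1)))
    expect_equal(unname(quartet_probs(pp)), c(1, 0, 0))
})

test_that("quartet distributions are proper and symmetric in the alternatives", {
  grid <- default_case_grid()
  for (i in seq_len(nrow(grid))) {
    p <- quartet_probs(case_params(grid$shape[i], grid$dup_case[i],
                                   x = grid$x[i], y = grid$y[i],
                                   t = if (is.na(grid$t[i])) NULL
                                       else grid$t[i]))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_identical(p[["p_alt1"]], p[["p_alt2"]])
    expect_gte(p[["p_match"]], 1 / 3)
    ## matching topology strictly dominates each alternative
    expect_gt(p[["p_match"]], p[["p_alt1"]])
  }
})

test_that("matching probability is monotone in the cherry edge length", {
  xs <- c(0.1, 0.3, 1, 2, 4)
  for (cs in list(list("balanced", "none", 1, NULL),
                  list("caterpillar", "none", 1, NULL),
                  list("balanced", "dup_on_root_edge", 1, 0.7),
                  list("caterpillar", "dup_on_Y", 5, 0.7),
                  list("caterpillar", "dup_on_root_edge", 1, 0.7))) {
    pm <- vapply(xs, function(xx)
      quartet_probs(case_params(cs[[1]], cs[[2]], x = xx, y = cs[[3]],
                                t = cs[[4]]))[["p_match"]], 0)
    expect_true(all(diff(pm) > 0))
  }
  ## with an X-edge duplication the probability is constantly one
  pm1 <- vapply(xs, function(xx)
    quartet_probs(case_params("caterpillar", "dup_on_X", x = xx,
                              y = 1))[["p_match"]], 0)
  expect_identical(pm1, rep(1, length(xs)))
})

test_that("locus-tree case classification recovers shape, case and coordinates", {
  for (shape in c("balanced", "caterpillar")) {
    for (dc in c("none", "dup_on_X", "dup_on_root_edge")) {
      p0 <- case_params(shape, dc, x = 0.8, y = 0.5,
                        t = if (dc == "dup_on_root_edge") 0.6 else NULL)
      cl <- classify_locus_case(case_locus_tree(p0))
      expect_identical(cl$shape, shape)
      expect_identical(cl$dup_case, dc)
      expect_equal(cl$x, 0.8, tolerance = 1e-9)
      expect_equal(cl$y, 0.5, tolerance = 1e-9)
      if (dc == "dup_on_root_edge") expect_equal(cl$t, 0.6, tolerance = 1e-9)
    }
  }
  cl <- classify_locus_case(case_locus_tree(
    case_params("caterpillar", "dup_on_Y", x = 1, y = 1, t = 0.4)))
  expect_identical(cl$dup_case, "dup_on_Y")
  expect_equal(cl$t, 0.4, tolerance = 1e-9)
  cl <- classify_locus_case(case_locus_tree(
    case_params("balanced", "dup_at_root_vertex", x = 1, y = 1)))
  expect_identical(cl$dup_case, "dup_at_root_vertex")
})

test_that("an internal-edge duplication dominates a root-edge duplication", {
  p0 <- case_params("balanced", "dup_on_X", x = 1, y = 1)
  lt <- case_locus_tree(p0)
  ## add a second duplication-point on the planted root edge
  lt2 <- locus_tree(lt$phylo,
                    dup_points = rbind(as.data.frame(lt$dup_points),
                                       data.frame(node = 5L, height = 2.5)))
  cl <- classify_locus_case(lt2)
  expect_identical(cl$dup_case, "dup_on_X")
  expect_equal(unname(quartet_probs(cl)), c(1, 0, 0))

  ## external-edge duplications are ignored
  lt3 <- case_locus_tree(case_params("balanced", "none", x = 1, y = 1))
  tipA <- match("A_1", lt3$phylo$tip.label)
  lt4 <- locus_tree(lt3$phylo, dup_points = data.frame(node = tipA,
                                                       height = 0.4))
  expect_identical(classify_locus_case(lt4)$dup_case, "none")

  ## four distinct species are required
  phy <- read_newick("((A_1:1,A_2:1):1,(C_1:1,D_1:1):1):1;")
  expect_error(classify_locus_case(locus_tree(phy)), "distinct species")
})
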