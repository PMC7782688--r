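test_that("IBS distances count mismatching alleles", {
  g <- cbind(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
             c = c(1L, 0L, 1L, 0L))
  gm <- make_gm(g, is_x = TRUE, sex = rep("male", 3))
  D <- ibs_distance(gm)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)

  g2 <- cbind(a = c(rep(0L, 7), 1L, 1L, 1L), b = rep(0L, 10))
  D2 <- ibs_distance(make_gm(g2, is_x = TRUE, sex = c("male", "male")))
  expect_equal(D2[1, 2], 0.3)

  g3 <- cbind(a = c(1L, NA), b = c(NA, 1L))
  expect_error(ibs_distance(make_gm(g3, is_x = TRUE, sex = c("male", "male"))),
               "no co-called")
})

test_that("NJ recovers three-taxon branch lengths and additive trees", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  tip_edges <- which(tr$edge[, 2] <= 3)
  pend <- setNames(tr$edge.length[tip_edges],
                   tr$tip.label[tr$edge[tip_edges, 2]])
  expect_equal(unname(pend[c("A", "B", "C")]), c(1, 1, 3))

  # random additive matrices from known trees are reconstructed exactly
  set.seed(8)
  for (rep in 1:5) {
    ref <- ape::rtree(8, br = runif)
    Dm <- cophenetic(ref)
    rec <- nj_tree(Dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), ape::unroot(rec))), 0)
  }

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bootstrap consensus supports true population splits", {
  set.seed(15)
  ns <- 200
  pa <- runif(ns, 0, 1); pb <- pmin(1, pa + (rbinom(ns, 1, .3) * 0.9))
  ga <- matrix(rbinom(ns * 6, 1, pa), ns, 6)
  gb <- matrix(rbinom(ns * 6, 1, pb), ns, 6)
  gm <- make_gm(cbind(ga, gb), is_x = TRUE, sex = rep("male", 12),
                pop = rep(c("a", "b"), each = 6))
  bc <- bootstrap_consensus(gm, B = 50)
  sup <- flatwing_bipartition_support(bc$trees, gm$samples$id[1:6])
  expect_gte(sup, 95)

  # B = 1: single tree, trivial support
  b1 <- bootstrap_consensus(gm, B = 1)
  expect_equal(length(b1$trees), 1L)

  # pure-noise genotypes give weak supports
  gn <- matrix(rbinom(ns * 12, 1, 0.5), ns, 12)
  gmn <- make_gm(gn, is_x = TRUE, sex = rep("male", 12),
                 pop = rep(c("a", "b"), each = 6))
  bcn <- bootstrap_consensus(gmn, B = 50)
  supn <- flatwing_bipartition_support(bcn$trees, gmn$samples$id[1:6])
  expect_lt(supn, 50)
})

test_that("the morph clustering test reads monophyly and mixing", {
  tr <- ape::read.tree(
    text = "((fwK:1,fwO:1,fwH:1):1,(nwK:1,nwO:1,nwH:1):1);")
  morph <- setNames(c(rep("flatwing", 3), rep("normal", 3)), tr$tip.label)
  res <- flatwing_clustering_test(tr, morph, support = 100)
  expect_true(res$monophyletic)
  expect_equal(res$mixing_score, 1)
  expect_equal(res$verdict, "introgression-consistent")

  # population-wise clades, each containing both morphs
  tr2 <- ape::read.tree(
    text = "((fwK:1,nwK:1):1,((fwO:1,nwO:1):1,(fwH:1,nwH:1):1):1);")
  res2 <- flatwing_clustering_test(tr2, morph)
  expect_false(res2$monophyletic)
  expect_gte(res2$mixing_score, 3)
  expect_equal(res2$verdict, "parallel-consistent")

  # Fitch mixing score is invariant to rooting
  tr3 <- ape::root(tr2, outgroup = "nwH", resolve.root = TRUE)
  res3 <- flatwing_clustering_test(tr3, morph)
  expect_equal(res3$mixing_score, res2$mixing_score)

  # monophyly without support stays inconclusive for the verdict
  low <- flatwing_clustering_test(tr, morph, support = 40)
  expect_equal(low$verdict, "parallel-consistent")
  expect_error(flatwing_clustering_test(tr, morph[1:2][0]), "flatwing tips")
})

test_that("randomization contrasts detect shifted regions and stay calibrated", {
  set.seed(25)
  n <- 120
  win <- data.frame(scaffold = "sX", start = seq(1, by = 2500, length = n))
  win$end <- win$start + 9999
  win$d <- rnorm(n, 0.01, 0.002)
  win$dxy <- rnorm(n, 0.02, 0.002)
  mask <- rep(FALSE, n); mask[41:60] <- TRUE

  # null: region like the background
  r0 <- region_divergence_contrast(win, mask, n_randomizations = 400,
                                   seed = 1)
  expect_gt(r0$d$p_perm, 0.05)

  # forced extreme: all in-region d shifted +10 sigma
  win2 <- win; win2$d[mask] <- win2$d[mask] + 0.02
  r1 <- region_divergence_contrast(win2, mask, n_randomizations = 1000,
                                   mode = "windows", seed = 2)
  expect_equal(r1$d$p_perm, 1 / 1001, tolerance = 1e-9)
  r1b <- region_divergence_contrast(win2, mask, n_randomizations = 400,
                                    seed = 3)
  expect_lt(r1b$d$p_perm, 0.05)
  # permutation p and the t-test agree in direction
  expect_lt(r1$d$p_t, 0.05)
  expect_gt(r1$dxy$p_perm, 0.05)     # dxy untouched

  expect_error(region_divergence_contrast(win, rep(TRUE, n), 10), "all windows")
  expect_error(region_divergence_contrast(win, c(TRUE, rep(FALSE, n - 1)), 10),
               "at least 10")
})
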