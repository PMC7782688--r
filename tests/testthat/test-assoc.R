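test_that("Fisher p-values match hypergeometric enumeration", {
  # 10 hemizygous cases all ALT vs 10 controls all REF
  p1 <- fisher_site(0, 10, 10, 0)
  expect_equal(p1, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(p1, oracle_fisher2(0, 10, 10, 0), tolerance = 1e-9)
  # 20 v 20 alleles fully separated
  p2 <- fisher_site(0, 20, 20, 0)
  expect_equal(p2, 2 / choose(40, 20), tolerance = 1e-6)
  # identical allele frequencies
  expect_equal(fisher_site(5, 5, 5, 5), 1)
  expect_warning(pe <- fisher_site(0, 0, 10, 10), "empty margin")
  expect_equal(pe, 1)
  expect_error(fisher_site(-1, 2, 3, 4), "non-negative")

  # invariance to swapping case/control and ref/alt simultaneously
  set.seed(6)
  for (rep in 1:10) {
    tb <- rpois(4, 6)
    expect_equal(fisher_site(tb[1], tb[2], tb[3], tb[4]),
                 fisher_site(tb[3], tb[4], tb[1], tb[2]), tolerance = 1e-12)
    expect_equal(fisher_site(tb[1], tb[2], tb[3], tb[4]),
                 fisher_site(tb[2], tb[1], tb[4], tb[3]), tolerance = 1e-12)
  }
})

test_that("the GWAS skips monomorphic sites and adjusts within-run", {
  # one polymorphic site among monomorphic ones; males hemizygous on X
  g <- rbind(rep(0L, 8),
             c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L),
             rep(1L, 8))
  gm <- make_gm(g, is_x = TRUE, sex = rep("male", 8),
                morph = rep(c("flatwing", "normal"), each = 4))
  tab <- gwas(gm, case_idx = 1:4, ctrl_idx = 5:8)
  expect_equal(nrow(tab), 1L)               # monomorphic sites not tested
  expect_equal(attr(tab, "n_tests"), 1L)
  expect_equal(tab$p_adj, tab$p)            # single test: no adjustment
  expect_equal(tab$case_alt, 4L)            # one allele per hemizygous male
  expect_error(gwas(gm, 1L, 5:8), "at least 2")
})

test_that("shuffled morph labels produce no significant associations", {
  set.seed(12)
  ns <- 150
  g <- matrix(rbinom(ns * 20, 1, runif(ns, .2, .8)), ns, 20)
  gm <- make_gm(g, is_x = TRUE, sex = rep("male", 20))
  hits <- vapply(1:60, function(r) {
    idx <- sample(20)
    sum(gwas(gm, idx[1:10], idx[11:20])$significant)
  }, 0)
  expect_gte(mean(hits == 0), 0.95)
})

test_that("the strictest-criterion harmonisation uses the reference cutoff", {
  mk <- function(p, n_tests) {
    t <- data.frame(scaffold = "sX", pos = seq_along(p), case_ref = 0,
                    case_alt = 10, ctrl_ref = 10, ctrl_alt = 0, p = p,
                    p_adj = pmin(1, p * n_tests),
                    significant = p * n_tests < 0.05, population = "x")
    attr(t, "n_tests") <- n_tests
    t
  }
  tabs <- list(ref = mk(c(1e-9, 1e-6), 1e6),
               other = mk(c(1e-7, 1e-9), 1e6))
  harm <- strictest_criterion(tabs, "ref")
  expect_equal(harm$cutoff, 5e-8)
  expect_equal(nrow(harm$sets$ref), 1L)       # 1e-6 fails the 5e-8 cutoff
  expect_equal(harm$sets$other$pos, 2L)       # 1e-7 dropped under the cutoff

  # reference = each population itself reduces to per-population Bonferroni
  solo <- strictest_criterion(tabs["ref"], "ref")
  expect_equal(solo$sets$ref$pos, which(tabs$ref$p * 1e6 <= 0.05))
  empty <- tabs$ref[0, ]
  attr(empty, "n_tests") <- 10
  expect_error(strictest_criterion(list(ref = empty), "ref"), "empty")
})

test_that("Venn overlaps distinguish SNP-level from scaffold-level sharing", {
  A <- data.frame(scaffold = "s18404", pos = c(1, 2))
  B <- data.frame(scaffold = "s18404", pos = c(3, 4))
  C <- data.frame(scaffold = "s18404", pos = 5)
  ov <- assoc_overlap(list(k = A, o = B, h = C))
  expect_equal(ov$shared_all_snps, 0)
  expect_equal(ov$shared_all_scaffolds, 1)

  same <- assoc_overlap(list(k = A, o = A, h = A))
  expect_equal(same$shared_all_snps, 2)
  expect_equal(sum(same$snp[1:6]), 0)

  none <- assoc_overlap(list(k = A[0, ], o = A[0, ], h = A[0, ]))
  expect_true(all(none$snp == 0) && all(none$scaffold == 0))
})

test_that("the planted causal site is the strongest association", {
  ds <- simulate_demography(make_scenario("parallel"), seed = 4)
  gm <- qc_chain(ds$genotypes)$gm
  tab <- morph_gwas(gm, "kauai", control_pool = c("oahu", "hilo"),
                    scaffolds = "scaffold_X1")
  top <- tab[which.min(tab$p), ]
  causal_pos <- ds$truth$causal$pos[ds$truth$causal$deme == "kauai"]
  # minimum-p site is the causal site or a perfectly linked core site
  expect_lte(abs(top$pos - causal_pos), ds$config$hitch_floor)
  expect_true(tab$significant[tab$pos == causal_pos])
})
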