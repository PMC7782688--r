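test_that("window grids stay inside scaffolds", {
  w <- window_iter(c(s1 = 15000))
  expect_equal(w$start, c(1, 2501, 5001))
  expect_equal(w$end, c(10000, 12500, 15000))
  expect_equal(nrow(window_iter(c(s1 = 9999))), 0L)
  expect_equal(nrow(window_iter(c(s1 = 10000))), 1L)
  expect_error(window_iter(c(s1 = 1e5), step = 0), "positive")
  expect_error(window_iter(c(s1 = 1e5), size = 100, step = 200), "exceed")
})

test_that("pi matches direct pairwise counting", {
  # 2 haplotypes differing at 1 site in a 10 kb window
  expect_equal(window_pi(n_ref = 1, n_alt = 1, window_bp = 1e4), 1e-4)
  # identical haplotypes
  expect_equal(window_pi(n_ref = c(2, 2), n_alt = c(0, 0), window_bp = 10), 0)
  # 4 haplotypes, one site with 2/2 split, 10 bp window
  expect_equal(window_pi(2, 2, 10), (2 * 2 * 2 / 12) / 10)

  # oracle equivalence on random haplotype sets
  set.seed(5)
  for (rep in 1:20) {
    nh <- sample(2:8, 1)
    ns <- sample(5:50, 1)
    haps <- matrix(rbinom(nh * ns, 1, runif(1, .1, .9)), ns, nh)
    cc <- hap_counts(haps)
    expect_equal(window_pi(cc$n_ref, cc$n_alt, 100),
                 oracle_pi(haps, 100), tolerance = 1e-12)
  }
})

test_that("Tajima's D agrees with direct evaluation of the 1989 constants", {
  expect_true(is.na(tajimas_d(4, n_ref = c(4, 4), n_alt = c(0, 0))))
  # n = 4, two singleton sites: hand evaluation gives ~ -0.71
  d <- tajimas_d(4, n_ref = c(3, 3), n_alt = c(1, 1))
  expect_equal(d, -0.71, tolerance = 0.01)
  # large near-neutral sample: |D| is modest for a balanced frequency profile
  set.seed(9)
  nh <- 20
  haps <- matrix(0L, 40, nh)
  for (i in 1:40) haps[i, sample(nh, sample(1:(nh - 1), 1))] <- 1L
  cc <- hap_counts(haps)
  expect_lt(abs(tajimas_d(nh, cc$n_ref, cc$n_alt)), 2.5)
})

test_that("Fst estimators behave at the extremes and under relabeling", {
  # fixed difference, large samples: ~ 1
  expect_gt(wc_fst(100, 0, 0, 100), 0.98)
  expect_gt(wc_fst(100, 0, 0, 100, method = "hudson"), 0.98)

  # two samples from one panmictic pool: mean over many sites ~ 0
  set.seed(17)
  p <- runif(500, 0.1, 0.9)
  a_alt <- rbinom(500, 20, p); b_alt <- rbinom(500, 20, p)
  f0 <- wc_fst(20 - a_alt, a_alt, 20 - b_alt, b_alt)
  expect_lt(abs(f0), 0.03)

  # invariance to swapping ref/alt at all sites
  a_alt2 <- rbinom(500, 20, p + 0.05 * rnorm(500) > 0.5)
  f1 <- wc_fst(20 - a_alt, a_alt, 20 - b_alt, b_alt)
  f2 <- wc_fst(a_alt, 20 - a_alt, b_alt, 20 - b_alt)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("dxy and net divergence follow their definitions", {
  expect_equal(net_divergence(0.02, 0.01, 0.01), 0.01)
  # one fixed difference in 10 kb, no polymorphism
  expect_equal(window_dxy(5, 0, 0, 5, 1e4), 1e-4)
  dd <- net_divergence(window_dxy(5, 0, 0, 5, 1e4), 0, 0)
  expect_equal(dd, 1e-4)

  set.seed(23)
  for (rep in 1:10) {
    ns <- sample(5:50, 1)
    hx <- matrix(rbinom(4 * ns, 1, .4), ns, 4)
    hy <- matrix(rbinom(6 * ns, 1, .6), ns, 6)
    cx <- hap_counts(hx); cy <- hap_counts(hy)
    dxy <- window_dxy(cx$n_ref, cx$n_alt, cy$n_ref, cy$n_alt, 100)
    expect_equal(dxy, oracle_dxy(hx, hy, 100), tolerance = 1e-12)
    dx <- window_pi(cx$n_ref, cx$n_alt, 100)
    dy <- window_pi(cy$n_ref, cy$n_alt, 100)
    d <- net_divergence(dxy, dx, dy)
    expect_lte(d, dxy + 1e-12)
    # identical populations: d = 0
    dself <- net_divergence(
      window_dxy(cx$n_ref, cx$n_alt, cx$n_ref, cx$n_alt, 100),
      dx, dx)
    expect_lt(abs(dself), dx / 3 + 1e-9)
  }
})

test_that("pi log-ratio flags total diversity loss instead of dropping it", {
  expect_equal(pi_log_ratio(0.01, 0.01), 0)
  expect_equal(pi_log_ratio(0.01, 0.001), 1)
  expect_equal(pi_log_ratio(0.01, 0), Inf)
  expect_true(is.na(pi_log_ratio(0, 0.01)))
})

test_that("r-squared matches hand enumeration and pruning removes later sites", {
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # haplotypes AB, AB, ab, aB  (A=1, B=1)
  h1 <- c(1, 1, 0, 0); h2 <- c(1, 1, 0, 1)
  expect_equal(ld_r2(h1, h2), 1 / 3, tolerance = 1e-12)
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1))))

  set.seed(3)
  base <- rbinom(30, 1, 0.5)                    # 30 haplotypes
  haps <- rbind(base,                           # site 1
                base,                           # site 2 duplicates site 1
                matrix(rbinom(4 * 30, 1, 0.5), 4, 30))  # independent sites
  kept <- ld_prune(haps, threshold = 0.3)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)                     # later member of the pair goes
  # monomorphic sites are retained but never drive a removal
  haps2 <- rbind(haps[1, , drop = FALSE], 1L, haps[-1, , drop = FALSE])
  kept2 <- ld_prune(haps2, threshold = 0.3)
  expect_true(2 %in% kept2)
})

test_that("window tables recover a planted low-diversity window", {
  set.seed(41)
  ns <- 300
  pos <- sort(sample(1:30000, ns))
  sel <- matrix(rbinom(ns * 10, 1, 0.5), ns, 10)
  uns <- matrix(rbinom(ns * 10, 1, 0.5), ns, 10)
  # wipe diversity of the selected group in [10001, 20000]
  wipe <- pos >= 10001 & pos <= 20000
  sel[wipe, ] <- 0L
  gm <- make_gm(cbind(uns, sel), pos = pos,
                pop = rep(c("u", "s"), each = 10), is_x = TRUE)
  w <- window_stats(gm, list(u = 1:10, s = 11:20), contrast = c("u", "s"),
                    scaffold_lengths = c(s1 = 30000))
  inw <- w$start >= 10001 & w$end <= 20000
  expect_true(all(w$pi_s[inw] == 0))
  expect_true(all(!is.finite(w$pi_log_ratio[inw])))
  expect_gt(mean(w$fst[inw], na.rm = TRUE),
            mean(w$fst[!inw], na.rm = TRUE))
})
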