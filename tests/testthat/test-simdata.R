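test_that("scenario presets encode the study system", {
  expect_error(make_scenario("bogus"), "valid names")

  ng <- make_scenario("no_geneflow")
  expect_true(all(ng$migration == 0))
  expect_equal(ng$causal$deme, "kauai")

  nt <- make_scenario("neutral")
  expect_equal(nrow(nt$causal), 0L)

  par <- make_scenario("parallel")
  # colonisation dates in years converted at 4 generations per year
  expect_equal(unname(par$split_gens), c(3200L, 2280L, 1600L))
  expect_equal(length(unique(par$causal$pos)), 3L)
  expect_true(all(par$causal$deme == par$causal$origin_deme))

  intro <- make_scenario("introgression")
  expect_equal(length(unique(intro$causal$pos)), 1L)
  expect_true(all(intro$causal$origin_deme == "kauai"))
})

test_that("configuration invariants are enforced", {
  expect_error(make_scenario("neutral",
                             split_gens = c(oahu = 100L, hilo = 200L,
                                            kauai = 50L)),
               "strictly decreasing")
  bad_m <- matrix(0.6, 3, 3,
                  dimnames = list(c("kauai", "oahu", "hilo"),
                                  c("kauai", "oahu", "hilo")))
  expect_error(make_scenario("neutral", migration = bad_m), "row sums")
  expect_error(make_scenario("neutral", deme_size = 1L), ">= 2")
  expect_error(make_scenario("neutral",
                             genome = make_scenario("neutral")$genome[0, ]),
               "at least one scaffold")
})

test_that("sweep trajectories absorb at the boundaries", {
  up <- simulate_sweep_trajectory(seed = 1, N = 200, w_normal = 0.5, p0 = 1,
                                  n_generations = 20)
  expect_true(all(up$p_f == 1) && all(up$p_m == 1))
  dn <- simulate_sweep_trajectory(seed = 1, N = 200, w_normal = 0.5, p0 = 0,
                                  n_generations = 20)
  expect_true(all(dn$p_f == 0) && all(dn$p_m == 0))

  # once lost, stays lost (no recurrent mutation)
  tr <- simulate_sweep_trajectory(seed = 42, N = 50, w_normal = 1, p0 = 0.02,
                                  n_generations = 400)
  hit0 <- which(tr$p_f == 0 & tr$p_m == 0)
  if (length(hit0)) {
    expect_true(all(tr$p_f[hit0[1]:nrow(tr)] == 0))
  }
  expect_true(all(tr$p_f >= 0 & tr$p_f <= 1 & tr$p_m >= 0 & tr$p_m <= 1))
})

test_that("neutral trajectories have zero expected frequency change", {
  set.seed(7)
  n_rep <- 1200
  dp <- vapply(seq_len(n_rep), function(i) {
    tr <- simulate_sweep_trajectory(seed = 10000 + i, N = 100, w_normal = 1,
                                    p0 = 0.3, n_generations = 1)
    tr$p_f[2] + tr$p_m[2] - tr$p_f[1] - tr$p_m[1]
  }, 0)
  sgn <- dp[dp != 0]
  bt <- binom.test(sum(sgn > 0), length(sgn), 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("selection drives the sweep at the deterministic rate", {
  det <- deterministic_sweep(n_generations = 30, w_normal = 0.1, p0 = 0.005)
  cross <- which(det$male_pheno_freq >= 0.95)[1] - 1L
  expect_lte(cross, 12L)   # >95% silent males within a dozen generations
  # stochastic runs at N = 1000 track the deterministic recursion
  ph30 <- vapply(1:30, function(s) {
    tr <- simulate_sweep_trajectory(seed = s, N = 1000, w_normal = 0.1,
                                    p0 = 0.005, n_generations = 30)
    tr$male_pheno_freq[31]
  }, 0)
  kept <- ph30[ph30 > 0]
  expect_gte(median(kept), 0.95)
})

test_that("frequency-dependent male fitness holds a balanced polymorphism", {
  fin <- vapply(1:10, function(s) {
    tr <- simulate_sweep_trajectory(seed = s, N = 2000, w_normal = 1,
                                    p0 = 0.05, freq_dependent = TRUE,
                                    p_eq = 0.45, fd_strength = 1,
                                    n_generations = 150)
    mean(tr$male_pheno_freq[100:151])
  }, 0)
  expect_gt(mean(fin), 0.25)
  expect_lt(mean(fin), 0.65)
})

test_that("simulated datasets satisfy the X-dosage and ploidy invariants", {
  cfg <- small_scenario("neutral",
                        sample_females = list(kauai = 3L, oahu = 0L,
                                              hilo = 0L, australia = 0L,
                                              outgroup = 0L))
  ds <- simulate_demography(cfg, seed = 5)
  gm <- ds$genotypes
  pl <- ploidy_matrix(gm)
  expect_true(all(gm$geno <= pl, na.rm = TRUE))
  # X allele counts = 2 female copies + 1 male copy, exactly
  kj <- which(gm$samples$pop == "kauai")
  nf <- sum(gm$samples$sex[kj] == "female")
  nm <- sum(gm$samples$sex[kj] == "male")
  ac <- allele_counts(gm, kj)
  expect_true(all(ac$n_obs[gm$sites$is_x] == 2 * nf + nm))
  expect_true(all(ac$n_obs[!gm$sites$is_x] == 2 * (nf + nm)))
})

test_that("realised migrant influx matches the configured rates", {
  cfg <- small_scenario("neutral", migration_start_gen = 400L)
  m <- cfg$migration
  m["kauai", "oahu"] <- m["oahu", "kauai"] <- 0.01
  cfg$migration <- m
  ds <- simulate_demography(cfg, seed = 3)
  infl <- ds$truth$migrant_influx
  expect_equal(nrow(infl), 400L)
  obs <- mean(infl[, "kauai"])
  se <- sd(infl[, "kauai"]) / sqrt(nrow(infl))
  expect_lt(abs(obs - 0.01), 3 * se + 1e-6)
})

test_that("differentiation in simulated data reflects divergence time", {
  ds <- simulate_demography(small_scenario("neutral"), seed = 13)
  gm <- ds$genotypes
  s <- gm$samples
  # two half-samples of the same deme are a panmictic split: Fst ~ 0
  ka <- which(s$pop == "kauai")
  w0 <- window_stats(gm, list(a = ka[1:10], b = ka[11:20]),
                     contrast = c("a", "b"))
  expect_lt(abs(mean(w0$fst, na.rm = TRUE)), 0.05)
  # deeper splits give more differentiation: kauai-hilo < kauai-australia
  pops <- list(kauai = which(s$pop == "kauai"),
               hilo = which(s$pop == "hilo"),
               australia = which(s$pop == "australia"))
  wkh <- window_stats(gm, pops[c("kauai", "hilo")],
                      contrast = c("kauai", "hilo"))
  wka <- window_stats(gm, pops[c("kauai", "australia")],
                      contrast = c("kauai", "australia"))
  expect_gt(mean(wka$fst, na.rm = TRUE), mean(wkh$fst, na.rm = TRUE))
})

test_that("identical config and seed give identical output", {
  cfg <- small_scenario("no_geneflow",
                        causal = data.frame(
                          deme = "kauai", scaffold = "scaffold_X1",
                          pos = 100000L, origin_gen = 40L, w_normal = 0.1,
                          freq_dependent = FALSE, p0 = 0.01,
                          target = "fixed", origin_deme = "kauai",
                          stringsAsFactors = FALSE))
  d1 <- simulate_demography(cfg, seed = 9)
  d2 <- simulate_demography(cfg, seed = 9)
  expect_identical(d1$genotypes$geno, d2$genotypes$geno)
  f1 <- file.path(tempdir(), "a.vcf"); f2 <- file.path(tempdir(), "b.vcf")
  write_vcf_gm(d1$genotypes, f1)
  write_vcf_gm(d2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("introgressed causal haplotypes trace to the origin deme", {
  cfg <- make_scenario("introgression")
  cfg$genome <- data.frame(scaffold = c("scaffold_A1", "scaffold_X1"),
                           length_bp = c(4e5, 3e6), is_x = c(FALSE, TRUE),
                           n_anc = c(800L, 3000L), stringsAsFactors = FALSE)
  cfg$deme_size <- 400L
  cfg$australia_size <- 400L
  cfg$mutation_influx <- 0.05
  ds <- simulate_demography(cfg, seed = 21)
  hap <- ds$truth$sweep_haplotypes
  expect_length(hap, 1L)
  expect_equal(hap[[1]]$origin, "kauai")
  # every carrier, in every deme, matches the donor haplotype at the
  # selection-maintained core around the causal site
  gm <- ds$genotypes
  core <- abs(hap[[1]]$positions - hap[[1]]$pos) <= cfg$hitch_floor
  core_pos <- hap[[1]]$positions[core]
  core_allele <- hap[[1]]$alleles[core]
  row_of <- match(paste0("scaffold_X1:", core_pos),
                  paste0(gm$sites$scaffold, ":", gm$sites$pos))
  keep <- !is.na(row_of)
  carriers <- which(gm$samples$morph == "flatwing")
  expect_true(length(carriers) >= 20)
  for (ci in carriers) {
    expect_equal(unname(gm$geno[row_of[keep], ci]), core_allele[keep])
  }
})

test_that("truth tables round-trip through TSV", {
  cfg <- small_scenario("no_geneflow",
                        causal = data.frame(
                          deme = "kauai", scaffold = "scaffold_X1",
                          pos = 100000L, origin_gen = 40L, w_normal = 0.1,
                          freq_dependent = FALSE, p0 = 0.01,
                          target = "fixed", origin_deme = "kauai",
                          stringsAsFactors = FALSE))
  ds <- simulate_demography(cfg, seed = 2)
  dir <- file.path(tempdir(), "truth_rt")
  write_truth(ds, dir)
  back <- read_truth(dir)
  expect_equal(back$causal$pos, ds$truth$causal$pos)
  expect_equal(back$causal$final_freq, ds$truth$causal$final_freq,
               tolerance = 1e-12)
  expect_equal(back$samples$morph, ds$samples$morph)
  expect_equal(back$trajectories$kauai$p_f,
               ds$truth$trajectories$kauai$p_f, tolerance = 1e-12)

  # neutral preset: causal truth table is empty
  ds0 <- simulate_demography(small_scenario("neutral"), seed = 2)
  dir0 <- file.path(tempdir(), "truth_rt0")
  write_truth(ds0, dir0)
  expect_equal(nrow(read_truth(dir0)$causal), 0L)
})

test_that("zero scaffolds is rejected", {
  cfg <- small_scenario("neutral")
  cfg$genome <- cfg$genome[0, ]
  expect_error(simulate_demography(cfg, seed = 1), "scaffold")
})
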