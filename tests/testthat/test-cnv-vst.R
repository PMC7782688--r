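test_that("CNV calls merge by overlap closure with support filtering", {
  calls <- data.frame(
    individual = c("i1", "i2", "i3"),
    scaffold = "sX",
    start = c(100L, 150L, 280L),
    end = c(200L, 300L, 400L),
    copy_number = c(2, 2.5, 3))
  cn <- merge_cnvrs(calls, individuals = c("i1", "i2", "i3", "i4"))
  expect_length(cn, 1L)
  expect_equal(cn[[1]]$start, 100L)
  expect_equal(cn[[1]]$end, 400L)
  expect_equal(cn[[1]]$support, 3L)
  expect_equal(unname(cn[[1]]$copy_number["i4"]), 1)  # baseline for no call

  # fewer than three supporting individuals: filtered
  expect_length(merge_cnvrs(calls[1:2, ]), 0L)

  # disjoint calls stay separate candidate regions (then support-filtered)
  dj <- data.frame(individual = c("i1", "i2"), scaffold = "sX",
                   start = c(100L, 300L), end = c(200L, 400L),
                   copy_number = 2)
  expect_length(merge_cnvrs(dj, min_support = 1L), 2L)

  # input order does not matter
  sh <- calls[c(3, 1, 2), ]
  cn2 <- merge_cnvrs(sh, individuals = c("i1", "i2", "i3", "i4"))
  expect_equal(cn2[[1]]$start, cn[[1]]$start)
  expect_equal(sort(cn2[[1]]$copy_number), sort(cn[[1]]$copy_number))

  bad <- calls; bad$end[1] <- 50L
  expect_error(merge_cnvrs(bad), "malformed")
})

test_that("VST matches hand-computed variance partitions", {
  # A = [2,2,2], B = [4,4,4]: VT = 1.2, VS = 0, VST = 1
  expect_equal(vst(c(2, 2, 2), c(4, 4, 4)), 1)
  expect_equal(var(c(2, 2, 2, 4, 4, 4)), 1.2)

  # identical large groups: ~ 0
  set.seed(44)
  x <- rnorm(200, 2, 0.5)
  expect_lt(abs(vst(x, x)), 0.01)

  # symmetry and shift invariance
  a <- c(1, 2, 2, 3); b <- c(2, 4, 4, 5)
  expect_equal(vst(a, b), vst(b, a))
  expect_equal(vst(a, b), vst(a + 7, b + 7), tolerance = 1e-12)

  # no variation at all: defined as 0
  expect_equal(vst(c(1, 1), c(1, 1)), 0)
  expect_error(vst(1, c(1, 2)), ">= 2")

  # bounded above by 1 whenever means differ
  set.seed(45)
  for (r in 1:10) {
    a <- rnorm(6, 1); b <- rnorm(6, 3)
    expect_lte(vst(a, b), 1)
  }
})

test_that("differentiated CNVRs need both the VST percentile and the t-test", {
  set.seed(46)
  inds <- paste0("i", 1:12)
  groups <- setNames(rep(c("flatwing", "normal"), each = 6), inds)
  mk_region <- function(start, cn) {
    list(scaffold = "sX", start = start, end = start + 999L, support = 4L,
         copy_number = setNames(cn, inds))
  }
  # background regions are exactly morph-balanced: each flatwing individual
  # is mirrored by a normal individual with the same copy number, so no
  # background region can pass the t-test
  neutral <- lapply(seq_len(99), function(i) {
    half <- rnorm(6, 2, 0.3)
    mk_region(i * 2000L, c(half, half))
  })
  planted <- mk_region(500000L, c(rnorm(6, 1, 0.05), rnorm(6, 3, 0.05)))
  res <- differentiated_cnvrs(c(neutral, list(planted)), groups)
  expect_equal(sum(res$differentiated), 1L)
  expect_equal(res$start[res$differentiated], 500000L)

  # identical copy numbers everywhere: nothing flagged
  flat <- lapply(seq_len(25), function(i) mk_region(i * 2000L, rep(2, 12)))
  res2 <- differentiated_cnvrs(flat, groups)
  expect_equal(sum(res2$differentiated), 0L)

  # high VST but an untestable/weak t-test (n = 2 per group) is not flagged
  inds2 <- paste0("j", 1:4)
  groups2 <- setNames(rep(c("flatwing", "normal"), each = 2), inds2)
  small <- lapply(seq_len(24), function(i) {
    list(scaffold = "sX", start = i * 1000L, end = i * 1000L + 99L,
         support = 3L, copy_number = setNames(rnorm(4, 2, 0.2), inds2))
  })
  extreme <- list(scaffold = "sX", start = 90000L, end = 90099L, support = 3L,
                  copy_number = setNames(c(1, 1, 3, 3), inds2))
  res3 <- suppressWarnings(differentiated_cnvrs(c(small, list(extreme)),
                                                groups2))
  ex_row <- res3$start == 90000L
  expect_equal(res3$vst[ex_row], 1)
  expect_false(res3$differentiated[ex_row])   # zero within-group variance:
                                              # the t-test cannot reject
})
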