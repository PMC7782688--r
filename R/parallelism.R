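#' Identity-by-state distance matrix
#'
#' Pairwise distance = fraction of co-called alleles that mismatch,
#' comparing alt-allele fractions call by call with pairwise deletion of
#' unknowns (PLINK-style 1 - IBS).  For haploid calls this is the exact
#' mismatch fraction; for diploid calls dosage differences count
#' proportionally.
#'
#' @param gm A [geno_matrix()].
#' @param sites_idx Optional site subset (e.g. flatwing-associated SNPs).
#' @param samples_idx Optional sample subset.
#' @return A symmetric `dist`-compatible matrix with individual ids.
#' @export
ibs_distance <- function(gm, sites_idx = NULL, samples_idx = NULL) {
  if (is.null(sites_idx)) sites_idx <- seq_len(nrow(gm$sites))
  if (is.null(samples_idx)) samples_idx <- seq_len(nrow(gm$samples))
  if (length(samples_idx) < 2L) stop("need at least 2 individuals")
  # direct matrix indexing: sites_idx may repeat (bootstrap resampling)
  f <- (gm$geno / ploidy_matrix(gm))[sites_idx, samples_idx, drop = FALSE]
  ids <- gm$samples$id[samples_idx]
  n <- ncol(f)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  obs <- !is.na(f)
  f0 <- f; f0[!obs] <- 0
  # pairwise mean |f_i - f_j| over co-observed sites, via E|a-b| expansion
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- obs[, i] & obs[, j]
      if (!any(ok)) {
        stop("individuals ", ids[i], " and ", ids[j],
             " share no co-called sites")
      }
      D[i, j] <- D[j, i] <- mean(abs(f[ok, i] - f[ok, j]))
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths are clamped
#' to zero with a warning.
#'
#' @param D Symmetric distance matrix with at least 3 taxa.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)))) stop("distance matrix must be symmetric")
  if (nrow(as.matrix(D)) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap majority-rule consensus NJ tree
#'
#' Resamples sites with replacement `B` times, rebuilds the IBS distance
#' and NJ tree each time, and returns the majority-rule consensus with
#' bootstrap support percentages on internal nodes.
#'
#' @param gm A [geno_matrix()].
#' @param sites_idx Site subset to resample from (default all).
#' @param B Number of bootstrap replicates (B = 1 gives a single tree with
#'   all supports 100).
#' @param samples_idx Optional sample subset.
#' @return list: `tree` (consensus `phylo`), `support` (per internal node,
#'   percentage), `trees` (the bootstrap sample).
#' @export
bootstrap_consensus <- function(gm, sites_idx = NULL, B = 1000L,
                                samples_idx = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(sites_idx)) sites_idx <- seq_len(nrow(gm$sites))
  if (length(sites_idx) < 10L) {
    warning("fewer than 10 sites in the bootstrap subset")
  }
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    res <- sample(sites_idx, length(sites_idx), replace = TRUE)
    trees[[b]] <- suppressWarnings(nj_tree(
      ibs_distance(gm, sites_idx = res, samples_idx = samples_idx)))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  supp <- ape::prop.clades(cons, trees, rooted = FALSE) / B * 100
  list(tree = cons, support = supp, trees = trees)
}

#' Morph clustering test on a tree
#'
#' Tests the adaptive-introgression expectation that flatwing individuals
#' from all populations form one clade: reports (i) whether the flatwing
#' tips are monophyletic (as a bipartition of the unrooted tree), (ii) a
#' mixing score = minimum number of morph state changes on the tree (Fitch
#' parsimony on the binary morph character, invariant to rooting), and
#' (iii) the verdict `"introgression-consistent"` iff flatwing monophyly
#' holds with bootstrap support at least `min_support`.
#'
#' @param tree An `ape::phylo` whose tip labels identify individuals.
#' @param morph Named character vector (by tip label) with values
#'   `"flatwing"` / `"normal"`.
#' @param support Bootstrap support (0-100) of the flatwing bipartition if
#'   known, or `NA` to judge on topology alone.
#' @param min_support Support threshold for the verdict (default 70).
#' @return list: `monophyletic`, `mixing_score`, `support`, `verdict`.
#' @export
flatwing_clustering_test <- function(tree, morph, support = NA_real_,
                                     min_support = 70) {
  fw <- names(morph)[morph == "flatwing"]
  if (length(fw) < 2L) stop("need at least 2 flatwing tips")
  mono <- ape::is.monophyletic(tree, fw)
  states <- morph[tree$tip.label]
  dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                 dimnames = list(tree$tip.label, NULL)),
                          type = "USER", levels = c("flatwing", "normal"))
  score <- phangorn::fitch(tree, dat)
  ok_support <- is.na(support) || support >= min_support
  verdict <- if (mono && ok_support) "introgression-consistent"
             else "parallel-consistent"
  list(monophyletic = mono, mixing_score = score,
       support = support, verdict = verdict)
}

#' Bootstrap support of the flatwing bipartition
#'
#' Fraction (as a percentage) of bootstrap trees in which the flatwing tips
#' are monophyletic.
#'
#' @param trees `multiPhylo` bootstrap sample.
#' @param fw_tips Tip labels of flatwing individuals.
#' @export
flatwing_bipartition_support <- function(trees, fw_tips) {
  mean(vapply(trees, function(t) ape::is.monophyletic(t, fw_tips), TRUE)) * 100
}

#' Net-divergence contrast between a region and the genomic background
#'
#' Compares the mean of a window statistic (net divergence `d`, and
#' separately `dxy`) inside a region mask against the rest of the windows.
#' Significance comes from a randomization null: `n_randomizations` random
#' reassignments of the in-region label preserving its count, with the
#' one-sided empirical p-value `(1 + #null >= observed) / (n + 1)`.  Because
#' overlapping sliding windows are autocorrelated, the default permutation
#' mode `"blocks"` permutes contiguous runs (by random circular rotation of
#' the mask within each scaffold), which preserves the run structure;
#' `mode = "windows"` gives the naive label permutation.  The two-sided
#' Welch t-test is also reported.
#'
#' @param windows A [window_stats()] table with columns `d` and `dxy`.
#' @param region_mask Logical vector: window inside the flatwing-associated
#'   region?
#' @param n_randomizations Number of randomizations (default 1000).
#' @param mode `"blocks"` (default) or `"windows"`.
#' @param seed Optional RNG seed.
#' @return list with per-statistic (`d`, `dxy`) observed mean difference
#'   (inside - outside), empirical `p_perm`, and t-test `p_t`.
#' @export
region_divergence_contrast <- function(windows, region_mask,
                                       n_randomizations = 1000L,
                                       mode = c("blocks", "windows"),
                                       seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(region_mask) == nrow(windows))
  if (all(region_mask)) stop("region covers all windows")
  if (sum(region_mask) < 10L || sum(!region_mask) < 10L) {
    stop("need at least 10 windows inside and outside the region")
  }
  scaff <- windows$scaffold
  rotate_mask <- function() {
    out <- logical(length(region_mask))
    for (s in unique(scaff)) {
      i <- which(scaff == s)
      k <- sample.int(length(i), 1L)
      out[i] <- region_mask[i][((seq_along(i) - 1L + k) %% length(i)) + 1L]
    }
    out
  }
  one <- function(stat) {
    x <- windows[[stat]]
    ok <- is.finite(x)
    obs <- mean(x[region_mask & ok]) - mean(x[!region_mask & ok])
    null <- vapply(seq_len(n_randomizations), function(r) {
      m <- if (mode == "blocks") rotate_mask() else
        sample(region_mask)
      mean(x[m & ok]) - mean(x[!m & ok])
    }, 0)
    p_perm <- (1 + sum(null >= obs)) / (n_randomizations + 1)
    tt <- stats::t.test(x[region_mask & ok], x[!region_mask & ok])
    list(observed_diff = obs, p_perm = p_perm, p_t = tt$p.value)
  }
  list(d = one("d"), dxy = one("dxy"),
       n_in = sum(region_mask), n_out = sum(!region_mask),
       n_randomizations = n_randomizations, mode = mode)
}
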