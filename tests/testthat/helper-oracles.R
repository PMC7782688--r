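# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately avoid the package's own computation paths.

# mean pairwise Hamming distance per site across haplotypes (columns),
# divided by window length: the textbook definition of pi
oracle_pi <- function(haps, window_bp) {
  n <- ncol(haps)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(haps[, i] != haps[, j])
    }
  }
  tot / choose(n, 2) / window_bp
}

# mean pairwise difference between two haplotype sets, per site
oracle_dxy <- function(hx, hy, window_bp) {
  tot <- 0
  for (i in seq_len(ncol(hx))) {
    for (j in seq_len(ncol(hy))) {
      tot <- tot + sum(hx[, i] != hy[, j])
    }
  }
  tot / (ncol(hx) * ncol(hy)) / window_bp
}

# literal ABBA/BABA pattern counting on single haploid genomes (0/1 alleles)
oracle_pattern_d <- function(g1, g2, g3, g4) {
  abba <- sum(g1 == 0 & g2 == 1 & g3 == 1 & g4 == 0)
  baba <- sum(g1 == 1 & g2 == 0 & g3 == 1 & g4 == 0)
  (abba - baba) / (abba + baba)
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) no more probable than observed
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b          # row 1 margin (e.g. case alleles)
  n <- c + d
  k <- a + c          # column margin (e.g. ref alleles)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, 0)
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# allele counts from a haplotype matrix (sites x haplotypes)
hap_counts <- function(haps) {
  list(n_ref = rowSums(haps == 0), n_alt = rowSums(haps == 1))
}

# minimal geno_matrix around a dosage matrix
make_gm <- function(geno, pos = seq_len(nrow(geno)), scaffold = "s1",
                    is_x = FALSE, sex = rep("male", ncol(geno)),
                    pop = rep("pop1", ncol(geno)),
                    morph = rep("normal", ncol(geno)),
                    qual = rep(60, nrow(geno)), mean_depth = 30) {
  geno_matrix(
    sites = data.frame(scaffold = scaffold, pos = pos, is_x = is_x,
                       qual = qual, stringsAsFactors = FALSE),
    geno = geno,
    samples = data.frame(id = if (is.null(colnames(geno)))
                           paste0("ind", seq_len(ncol(geno))) else
                           colnames(geno),
                         pop = pop,
                         sex = sex, morph = morph, mean_depth = mean_depth,
                         stringsAsFactors = FALSE))
}

# tiny, fast simulation configuration for structural tests
small_scenario <- function(name, causal = make_scenario("neutral")$causal,
                           ...) {
  make_scenario(
    name,
    deme_size = 1000L,
    australia_size = 1000L,
    genome = data.frame(scaffold = c("scaffold_A1", "scaffold_X1"),
                        length_bp = c(4e5, 2e5), is_x = c(FALSE, TRUE),
                        n_anc = c(1200L, 600L), stringsAsFactors = FALSE),
    mutation_influx = 0.05,
    hitch_halfwidth = 50000L,
    causal = causal,
    ...)
}
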