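#' ABBA/BABA site weights from derived-allele frequencies
#'
#' Frequency-weighted site patterns for the four-taxon test
#' (((P1,P2),P3),Outgroup):
#' `abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`.
#' Single-genome 0/1 inputs reduce to literal pattern counts.  Outgroup
#' polymorphism down-weights a site through `(1-p4)` rather than excluding
#' it.
#'
#' @param p1,p2,p3,p4 Derived-allele frequency vectors in \[0,1\]
#'   (`p4` = outgroup).
#' @return data.frame with columns `abba`, `baba`.
#' @export
site_weights <- function(p1, p2, p3, p4) {
  ps <- cbind(p1, p2, p3, p4)
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  data.frame(abba = (1 - p1) * p2 * p3 * (1 - p4),
             baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Patterson's D from site weights
#'
#' `D = (sum abba - sum baba) / (sum abba + sum baba)`.  Positive D is an
#' excess of shared derived alleles between P2 and P3 (ABBA excess);
#' D = 0 is the no-gene-flow null.
#'
#' @param w data.frame from [site_weights()] (columns `abba`, `baba`).
#' @return D, or `NA` if the denominator is zero (flagged undefined).
#' @export
d_statistic <- function(w) {
  num <- sum(w$abba, na.rm = TRUE) - sum(w$baba, na.rm = TRUE)
  den <- sum(w$abba, na.rm = TRUE) + sum(w$baba, na.rm = TRUE)
  if (den == 0) return(NA_real_)
  num / den
}

#' Genome-wide D with weighted block jackknife
#'
#' Splits sites into contiguous genomic blocks of `block_size_bp`, computes
#' the genome-wide D, and estimates its standard error by the weighted
#' delete-one-block jackknife (Busing et al. 1999), with block weights equal
#' to their informative-site mass (abba+baba).  `Z = D / SE`, with a
#' two-sided normal p-value.
#'
#' @param w Site weights ([site_weights()] output).
#' @param scaffold,pos Site coordinates parallel to `w`.
#' @param block_size_bp Block size in bp (default 1e6).
#' @return list of class `d_result`: `D`, `se`, `Z`, `p`, `n_blocks`,
#'   `blocks` (per-block data.frame with abba, baba, weight, D_minus
#'   delete-one values and per-block D).
#' @export
block_jackknife <- function(w, scaffold, pos, block_size_bp = 1e6) {
  block <- paste0(scaffold, ":", floor((pos - 1) / block_size_bp))
  ab <- tapply(w$abba, block, sum)
  ba <- tapply(w$baba, block, sum)
  tot <- ab + ba
  keep <- !is.na(tot) & tot > 0
  ab <- ab[keep]; ba <- ba[keep]; tot <- tot[keep]
  g <- length(tot)
  if (g < 10L) {
    stop("need at least 10 non-empty blocks; use a smaller block size")
  }
  AB <- sum(ab); BA <- sum(ba)
  D <- (AB - BA) / (AB + BA)
  n <- sum(tot)
  D_minus <- ((AB - ab) - (BA - ba)) / ((AB - ab) + (BA - ba))
  D_block <- (ab - ba) / tot

  if (all(abs(D_minus - D) < .Machine$double.eps^0.5)) {
    se <- 0; Z <- ifelse(D == 0, 0, Inf)
  } else {
    h <- n / tot
    # Busing et al. (1999) delete-m_j jackknife variance
    theta_J <- g * D - sum((1 - tot / n) * D_minus)
    tau <- h * D - (h - 1) * D_minus
    se <- sqrt(sum((tau - theta_J)^2 / (h - 1)) / g)
    Z <- D / se
  }
  res <- list(D = D, se = se, Z = Z,
              p = 2 * stats::pnorm(-abs(Z)),
              n_blocks = g, n_sites_weight = n,
              blocks = data.frame(abba = as.vector(ab), baba = as.vector(ba),
                                  weight = as.vector(tot),
                                  D_block = as.vector(D_block),
                                  D_minus = as.vector(D_minus)))
  class(res) <- "d_result"
  res
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.4f  SE = %.4f  Z = %.2f  p = %.3g  (%d blocks)\n",
              x$D, x$se, x$Z, x$p, x$n_blocks))
  invisible(x)
}

#' D statistic for a genotype matrix and taxon assignment
#'
#' Convenience wrapper: computes derived-allele frequencies per population
#' (derived = the allele that is the minor allele in the outgroup, i.e.
#' polarised against the outgroup major allele), builds site weights, and
#' runs the block jackknife.
#'
#' @param gm A [geno_matrix()].
#' @param p1,p2,p3,outgroup Population labels in `gm$samples$pop`.
#' @param scaffolds Optional scaffold subset (e.g. the X scaffold).
#' @param block_size_bp Jackknife block size.
#' @return A `d_result`.
#' @export
dstat_test <- function(gm, p1, p2, p3, outgroup, scaffolds = NULL,
                       block_size_bp = 1e6) {
  if (!is.null(scaffolds)) {
    gm <- subset_gm(gm, sites_idx = which(gm$sites$scaffold %in% scaffolds))
  }
  fr <- function(pop) allele_counts(gm, which(gm$samples$pop == pop))$p
  f1 <- fr(p1); f2 <- fr(p2); f3 <- fr(p3); f4 <- fr(outgroup)
  # polarise on the outgroup major allele
  flip <- !is.na(f4) & f4 > 0.5
  f1[flip] <- 1 - f1[flip]; f2[flip] <- 1 - f2[flip]
  f3[flip] <- 1 - f3[flip]; f4[flip] <- 1 - f4[flip]
  use <- !is.na(f1) & !is.na(f2) & !is.na(f3) & !is.na(f4)
  w <- site_weights(f1[use], f2[use], f3[use], f4[use])
  block_jackknife(w, gm$sites$scaffold[use], gm$sites$pos[use], block_size_bp)
}

#' Contrast the magnitude of D between two scenario groups
#'
#' Welch two-sided t-test on per-block |D| values, as used to compare
#' within-archipelago gene-flow scenarios against distant-population control
#' scenarios.  When every value is identical across both groups the test is
#' degenerate and p = 1 is returned.
#'
#' @param d_blocks_a,d_blocks_b Numeric vectors of per-block D values for
#'   the two scenario groups.
#' @return list with `t`, `df`, `p`, group means of |D|.
#' @export
compare_dstat_groups <- function(d_blocks_a, d_blocks_b) {
  a <- abs(d_blocks_a[!is.na(d_blocks_a)])
  b <- abs(d_blocks_b[!is.na(d_blocks_b)])
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (length(unique(c(a, b))) == 1L) {
    return(list(t = 0, df = NA_real_, p = 1,
                mean_abs_a = mean(a), mean_abs_b = mean(b)))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_abs_a = mean(a), mean_abs_b = mean(b))
}
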