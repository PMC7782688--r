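#' Sliding-window grid over scaffolds
#'
#' Windows of `size` bp advancing by `step` bp, starting at position 1.
#' Windows overstepping a scaffold boundary are dropped, so every window is
#' fully contained.  Coordinates are 1-based inclusive.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param size Window size in bp (default 10000).
#' @param step Step in bp (default 2500); must be positive and at most `size`.
#' @return data.frame with `scaffold`, `start`, `end`.
#' @export
#' @examples
#' window_iter(c(s1 = 15000))          # 3 windows
window_iter <- function(scaffold_lengths, size = 10000L, step = 2500L) {
  if (step <= 0L) stop("step must be positive")
  if (step > size) stop("step must not exceed window size")
  out <- lapply(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    if (L < size) return(NULL)
    starts <- seq(1L, L - size + 1L, by = step)
    data.frame(scaffold = s, start = starts, end = starts + size - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

## per-site sum of pairwise differences: 2 * n_ref * n_alt / (n * (n-1))
.site_pair_diff <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  ifelse(n >= 2, 2 * n_ref * n_alt / (n * (n - 1)), 0)
}

#' Nucleotide diversity of one population over a window
#'
#' Mean pairwise difference per site: the per-site pairwise-difference
#' probabilities `2 n_ref n_alt / (n (n-1))` summed over sites and divided
#' by the full window length in bp (the VCFtools convention; monomorphic and
#' unobserved sites contribute zero to the numerator).
#'
#' @param n_ref,n_alt Observed reference/alternate allele counts per site.
#' @param window_bp Window length in bp.
#' @return Per-site pi, or `NA` if no site has two or more observed alleles
#'   (undefined, not zero).
#' @export
window_pi <- function(n_ref, n_alt, window_bp) {
  if (!length(n_ref) || all(n_ref + n_alt < 2)) {
    if (!length(n_ref)) return(0)      # no segregating sites: pi is 0
    return(NA_real_)
  }
  sum(.site_pair_diff(n_ref, n_alt)) / window_bp
}

#' Watterson's theta over a window
#'
#' `S / a1` for `S` segregating sites and `a1` the (n-1)-th harmonic number,
#' divided by the window length (per-site scale).
#'
#' @param n_alleles Number of sampled alleles (per window; sites with fewer
#'   observed alleles still count toward S if polymorphic).
#' @param S Number of segregating sites in the window.
#' @param window_bp Window length in bp.
#' @export
watterson_theta <- function(n_alleles, S, window_bp) {
  if (n_alleles < 2L) return(NA_real_)
  a1 <- sum(1 / seq_len(n_alleles - 1L))
  (S / a1) / window_bp
}

#' Tajima's D for a window
#'
#' Standard normalised difference between the mean pairwise difference `k`
#' and `S/a1`, with the 1989 constants:
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S-1))`.  `k` is per window, not per
#' site.  Undefined (NA) when there are no segregating sites.
#'
#' @param n Number of sampled alleles.
#' @param n_ref,n_alt Per-site observed allele counts over the window's
#'   segregating sites.
#' @return The D statistic, or `NA` when S = 0.
#' @export
tajimas_d <- function(n, n_ref, n_alt) {
  seg <- n_ref > 0 & n_alt > 0
  S <- sum(seg)
  if (S == 0L || n < 2L) return(NA_real_)
  k <- sum(.site_pair_diff(n_ref[seg], n_alt[seg]))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den == 0) return(NA_real_)
  (k - S / a1) / den
}

#' Weir-Cockerham Fst between two populations over a window
#'
#' Ratio-of-sums weighted estimator from per-site variance components,
#' computed on observed allele counts with the heterozygosity term at zero
#' (appropriate for haploid male X data and for allele-count summaries).
#' Negative estimates are reported as-is.  The Hudson estimator
#' (Bhatia et al. form) is available as an option.
#'
#' @param n1_ref,n1_alt,n2_ref,n2_alt Per-site observed allele counts in the
#'   two populations.
#' @param method `"wc"` (default) or `"hudson"`.
#' @return The window Fst estimate (`NA` when no usable site).
#' @export
wc_fst <- function(n1_ref, n1_alt, n2_ref, n2_alt, method = c("wc", "hudson")) {
  method <- match.arg(method)
  n1 <- n1_ref + n1_alt
  n2 <- n2_ref + n2_alt
  use <- n1 >= 2 & n2 >= 2 & (n1_alt + n2_alt) > 0 & (n1_ref + n2_ref) > 0
  if (!any(use)) return(NA_real_)
  p1 <- n1_alt[use] / n1[use]
  p2 <- n2_alt[use] / n2[use]
  n1 <- n1[use]; n2 <- n2[use]
  if (method == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    keep <- den > 0
    if (!any(keep)) return(NA_real_)
    return(sum(num[keep]) / sum(den[keep]))
  }
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  den <- sum(a + b)
  if (den == 0) return(NA_real_)
  sum(a) / den
}

#' Absolute divergence dxy between two populations over a window
#'
#' Mean per-site difference over inter-population allele pairs,
#' `p1 (1 - p2) + p2 (1 - p1)` summed over sites and divided by the window
#' length.
#'
#' @inheritParams wc_fst
#' @param window_bp Window length in bp.
#' @export
window_dxy <- function(n1_ref, n1_alt, n2_ref, n2_alt, window_bp) {
  n1 <- n1_ref + n1_alt
  n2 <- n2_ref + n2_alt
  use <- n1 >= 1 & n2 >= 1
  if (!any(use)) return(NA_real_)
  p1 <- n1_alt[use] / n1[use]
  p2 <- n2_alt[use] / n2[use]
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / window_bp
}

#' Net nucleotide divergence
#'
#' `d = dxy - (dx + dy) / 2`, with `dx`, `dy` the within-population
#' per-site pairwise differences over the same sites.
#'
#' @param dxy,dx,dy Component values (same units).
#' @export
net_divergence <- function(dxy, dx, dy) dxy - (dx + dy) / 2

#' Log10 ratio of unselected to selected nucleotide diversity
#'
#' Positive values indicate diversity loss in the selected group.  A window
#' where the selected group has lost all diversity (`pi_selected = 0`) is
#' flagged `+Inf` so it still enters top-percentile scans; a window with
#' `pi_unselected = 0` is undefined (`NA`, dropped downstream).
#'
#' @param pi_unselected,pi_selected Window diversities of the two groups.
#' @export
pi_log_ratio <- function(pi_unselected, pi_selected) {
  out <- rep(NA_real_, length(pi_unselected))
  ok <- !is.na(pi_unselected) & !is.na(pi_selected) & pi_unselected > 0
  out[ok & pi_selected > 0] <-
    log10(pi_unselected[ok & pi_selected > 0] /
            pi_selected[ok & pi_selected > 0])
  out[ok & pi_selected == 0] <- Inf
  out
}

#' Sliding-window statistics table
#'
#' Computes, per window: number of segregating sites, per-population pi,
#' Watterson's theta and Tajima's D, and for a designated population pair
#' the Weir-Cockerham Fst, dxy, dx, dy, net divergence d and pi log-ratio
#' (`pops[1]` is taken as unselected/reference, `pops[2]` as selected when
#' forming the ratio).
#'
#' @param gm A [geno_matrix()].
#' @param pops Named list mapping population labels to sample indices (or a
#'   character vector of `gm$samples$pop` values).
#' @param contrast Character vector of two population labels for the
#'   pairwise columns, or `NULL` for diversity-only output.
#' @param scaffold_lengths Named lengths for the window grid (defaults to
#'   max observed position per scaffold).
#' @param size,step Window geometry in bp.
#' @return A data.frame, one row per window.
#' @export
window_stats <- function(gm, pops, contrast = NULL, scaffold_lengths = NULL,
                         size = 10000L, step = 2500L) {
  if (is.character(pops)) {
    pops <- stats::setNames(
      lapply(pops, function(p) which(gm$samples$pop == p)), pops)
  }
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- vapply(
      split(gm$sites$pos, gm$sites$scaffold), max, 0)
  }
  win <- window_iter(scaffold_lengths, size = size, step = step)
  if (nrow(win) == 0L) return(win)

  counts <- lapply(pops, function(idx) allele_counts(gm, idx))

  res <- lapply(seq_len(nrow(win)), function(i) {
    in_w <- which(gm$sites$scaffold == win$scaffold[i] &
                    gm$sites$pos >= win$start[i] & gm$sites$pos <= win$end[i])
    row <- list(scaffold = win$scaffold[i], start = win$start[i],
                end = win$end[i], n_sites = length(in_w))
    for (pn in names(pops)) {
      cc <- counts[[pn]][in_w, , drop = FALSE]
      nmax <- if (length(in_w)) max(cc$n_obs) else 0L
      row[[paste0("pi_", pn)]] <- window_pi(cc$n_ref, cc$n_alt, size)
      row[[paste0("theta_w_", pn)]] <-
        watterson_theta(nmax, sum(cc$n_ref > 0 & cc$n_alt > 0), size)
      row[[paste0("tajima_d_", pn)]] <- tajimas_d(nmax, cc$n_ref, cc$n_alt)
    }
    if (!is.null(contrast)) {
      c1 <- counts[[contrast[1]]][in_w, , drop = FALSE]
      c2 <- counts[[contrast[2]]][in_w, , drop = FALSE]
      fst <- wc_fst(c1$n_ref, c1$n_alt, c2$n_ref, c2$n_alt)
      dxy <- window_dxy(c1$n_ref, c1$n_alt, c2$n_ref, c2$n_alt, size)
      dx <- window_pi(c1$n_ref, c1$n_alt, size)
      dy <- window_pi(c2$n_ref, c2$n_alt, size)
      dx0 <- ifelse(is.na(dx), 0, dx)
      dy0 <- ifelse(is.na(dy), 0, dy)
      row$fst <- fst
      row$dxy <- dxy
      row$dx <- dx0
      row$dy <- dy0
      row$d <- net_divergence(dxy, dx0, dy0)
      row$pi_log_ratio <- pi_log_ratio(dx0, dy0)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
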