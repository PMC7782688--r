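#' Pairwise linkage disequilibrium r-squared between two sites
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))` computed on
#' haplotypes (haploid male X data or phased chromosomes), using only
#' haplotype pairs observed at both sites.
#'
#' @param h1,h2 0/1 allele vectors of equal length (NA = unknown).
#' @return r-squared in \[0, 1\], or `NA` if either site is monomorphic
#'   among the co-observed haplotypes.
#' @export
ld_r2 <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  if (!any(ok)) return(NA_real_)
  a <- h1[ok]; b <- h2[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(a == 1 & b == 1)
  D <- pab - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Greedy sliding-window LD pruning
#'
#' Scans sites left to right; within a sliding window of `win_sites`
#' consecutive retained sites, the later member of any pair with
#' `r2 > threshold` is removed.  Monomorphic sites are excluded from the
#' pruning decisions (they have undefined r2) but are retained.
#'
#' @param haps Haplotype matrix, sites x haplotypes (0/1/NA), sites in
#'   genomic order.
#' @param threshold r-squared above which the later site is dropped.
#' @param win_sites Size of the site window (default 50).
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(haps, threshold = 0.3, win_sites = 50L) {
  ns <- nrow(haps)
  keep <- rep(TRUE, ns)
  poly <- apply(haps, 1L, function(h) {
    h <- h[!is.na(h)]
    length(unique(h)) > 1L
  })
  kept_poly <- integer(0)
  for (i in seq_len(ns)) {
    if (!poly[i]) next
    recent <- utils::tail(kept_poly, win_sites)
    drop <- FALSE
    for (j in rev(recent)) {
      r2 <- ld_r2(haps[j, ], haps[i, ])
      if (!is.na(r2) && r2 > threshold) { drop <- TRUE; break }
    }
    if (drop) keep[i] <- FALSE else kept_poly <- c(kept_poly, i)
  }
  which(keep)
}
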