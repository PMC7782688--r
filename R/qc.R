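#' Filter sites on Phred-scaled site quality
#'
#' Removes sites whose quality is below `min_qual` (default 30); a site at
#' exactly the threshold is retained.  Site order is preserved.
#'
#' @param gm A [geno_matrix()].
#' @param min_qual Minimum retained quality score.
#' @return Filtered `geno_matrix` (possibly with zero sites).
#' @export
filter_site_quality <- function(gm, min_qual = 30) {
  if (all(is.na(gm$sites$qual))) stop("site quality scores are not present")
  keep <- which(!is.na(gm$sites$qual) & gm$sites$qual >= min_qual)
  subset_gm(gm, sites_idx = keep)
}

#' Mask calls with abnormal read depth
#'
#' Sets to unknown any call whose total depth is lower than one-third or
#' higher than three times the individual's mean sequencing depth.  For
#' sites on X-linked scaffolds the criteria are halved: bounds become
#' mean/6 and 1.5 x mean.  Boundary depths (exactly at a bound) are kept —
#' the rule is strict.
#'
#' @param gm A [geno_matrix()] with `dp` and `samples$mean_depth` present.
#' @return The matrix with offending calls set to `NA`.
#' @export
mask_abnormal_depth <- function(gm) {
  if (is.null(gm$dp)) stop("per-call depths (DP) are not present")
  md <- gm$samples$mean_depth
  if (is.null(md) || anyNA(md)) {
    bad <- if (is.null(md)) gm$samples$id else gm$samples$id[is.na(md)]
    stop("mean sequencing depth missing for individual(s): ",
         paste(bad, collapse = ", "))
  }
  lo <- matrix(rep(md / 3, each = nrow(gm$sites)), nrow = nrow(gm$sites))
  hi <- matrix(rep(md * 3, each = nrow(gm$sites)), nrow = nrow(gm$sites))
  xi <- gm$sites$is_x
  lo[xi, ] <- lo[xi, ] / 2
  hi[xi, ] <- hi[xi, ] / 2
  bad <- !is.na(gm$dp) & (gm$dp < lo | gm$dp > hi)
  gm$geno[bad] <- NA_integer_
  gm
}

#' Resolve male X heterozygous calls to haploid calls
#'
#' Males are hemizygous (XX/XO sex determination), so an apparently
#' heterozygous male call at an X site must be a genotyping artefact.  The
#' call is fixed to the allele whose read depth is strictly greater than
#' three times the other's; if neither allele has that supermajority the
#' genotype becomes unknown.  Homozygous diploid-coded calls collapse to the
#' single allele.  The operation is idempotent.
#'
#' @param gm A [geno_matrix()]; allele depths (`ad_ref`, `ad_alt`) are
#'   required to resolve heterozygous calls (without them such calls become
#'   unknown).
#' @return The matrix with male X calls haploid (dosage 0/1 or `NA`).
#' @export
fix_x_hemizygotes <- function(gm) {
  male <- gm$samples$sex == "male"
  xi <- gm$sites$is_x
  if (!any(xi) || !any(male)) return(gm)
  sub <- gm$geno[xi, male, drop = FALSE]
  if (!is.null(gm$ad_ref)) {
    a <- gm$ad_ref[xi, male, drop = FALSE]
    b <- gm$ad_alt[xi, male, drop = FALSE]
    if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
      stop("negative allele depths")
    }
  } else {
    a <- b <- matrix(NA_integer_, nrow(sub), ncol(sub))
  }
  # which male X calls were literally heterozygous (diploid-coded artefact);
  # a haploid dosage of 1 with no het flag is a clean ALT call
  het <- if (!is.null(gm$het)) {
    gm$het[xi, male, drop = FALSE] & !is.na(sub)
  } else {
    matrix(FALSE, nrow(sub), ncol(sub))
  }
  # homozygous diploid-coded calls collapse to the single allele
  sub[!is.na(sub) & sub == 2L] <- 1L
  sub[het] <- NA_integer_
  fix_ref <- het & !is.na(a) & !is.na(b) & a > 3 * b
  fix_alt <- het & !is.na(a) & !is.na(b) & b > 3 * a
  sub[fix_ref] <- 0L
  sub[fix_alt] <- 1L
  gm$geno[xi, male] <- sub
  if (!is.null(gm$het)) gm$het[xi, male] <- FALSE
  gm
}

#' Drop sites with excessive missingness
#'
#' Removes sites with unknown genotypes in more than `max_fraction` of all
#' individuals (default 25%); a site at exactly the threshold is kept.
#'
#' @param gm A [geno_matrix()].
#' @param max_fraction Maximum tolerated unknown fraction.
#' @return Filtered `geno_matrix`.
#' @export
filter_missingness <- function(gm, max_fraction = 0.25) {
  frac <- rowMeans(is.na(gm$geno))
  subset_gm(gm, sites_idx = which(frac <= max_fraction))
}

#' Full QC chain
#'
#' Applies, in order: site-quality filtering, abnormal-depth masking, male-X
#' hemizygote fixing, and missingness filtering, and reports how many sites
#' each rule removed (masking removes calls, not sites, and is reported as
#' masked-call count).
#'
#' @param gm A [geno_matrix()].
#' @param min_qual,max_missing Thresholds passed through.
#' @return list with `gm` (the cleaned matrix) and `report` (data.frame of
#'   rule, sites_in, removed).
#' @export
qc_chain <- function(gm, min_qual = 30, max_missing = 0.25) {
  rep <- list()
  n0 <- nrow(gm$sites)
  gm1 <- filter_site_quality(gm, min_qual)
  rep[[1]] <- data.frame(rule = "site_quality", sites_in = n0,
                         removed = n0 - nrow(gm1$sites))
  calls0 <- sum(!is.na(gm1$geno))
  gm2 <- if (!is.null(gm1$dp)) mask_abnormal_depth(gm1) else gm1
  rep[[2]] <- data.frame(rule = "abnormal_depth_calls", sites_in = nrow(gm1$sites),
                         removed = calls0 - sum(!is.na(gm2$geno)))
  gm3 <- fix_x_hemizygotes(gm2)
  rep[[3]] <- data.frame(rule = "x_hemizygote_unknowns", sites_in = nrow(gm2$sites),
                         removed = sum(!is.na(gm2$geno)) - sum(!is.na(gm3$geno)))
  n3 <- nrow(gm3$sites)
  gm4 <- filter_missingness(gm3, max_missing)
  rep[[4]] <- data.frame(rule = "missingness", sites_in = n3,
                         removed = n3 - nrow(gm4$sites))
  list(gm = gm4, report = do.call(rbind, rep))
}
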