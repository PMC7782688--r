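#' Empirical nearest-rank percentile cutoff
#'
#' The q-quantile by the nearest-rank rule: the value at rank
#' `ceiling(q * n)` of the sorted finite values.  `+Inf` flags (fully swept
#' windows) sort above every finite value and therefore always exceed a
#' finite cutoff.
#'
#' @param values Numeric vector (NA dropped; +Inf kept out of the rank but
#'   always counted as above the cutoff by callers).
#' @param q Quantile in (0, 1), default 0.95.
#' @return The cutoff value.
#' @export
empirical_cutoff <- function(values, q = 0.95) {
  v <- sort(values[is.finite(values)])
  if (length(v) < 20L) stop("need at least 20 finite values for a percentile")
  v[ceiling(q * length(v))]
}

#' Call candidate selective-sweep regions
#'
#' Windows strictly above both the `q` empirical percentile of Fst and the
#' `q` percentile of the pi log-ratio are flagged; flagged windows on the
#' same scaffold that overlap or are book-ended (end + 1 = start) are merged
#' into single regions by min-start/max-end.  Ties at a threshold are
#' excluded (strict inequality).
#'
#' @param windows A [window_stats()] table with `fst` and `pi_log_ratio`.
#' @param q Percentile (default 0.95, i.e. "top 5%").
#' @param per_scaffold Compute the cutoffs per scaffold instead of globally.
#' @return data.frame of regions: scaffold, start, end, n_windows,
#'   mean_fst, mean_pi_log_ratio; attributes `fst_cutoff`, `ratio_cutoff`.
#' @export
call_sweeps <- function(windows, q = 0.95, per_scaffold = FALSE) {
  flag_of <- function(w) {
    fc <- empirical_cutoff(w$fst, q)
    rc <- empirical_cutoff(w$pi_log_ratio, q)
    flag <- !is.na(w$fst) & !is.na(w$pi_log_ratio) &
      w$fst > fc & w$pi_log_ratio > rc
    list(flag = flag, fc = fc, rc = rc)
  }
  if (per_scaffold) {
    flag <- logical(nrow(windows))
    fc <- rc <- NULL
    for (s in unique(windows$scaffold)) {
      i <- windows$scaffold == s
      f <- flag_of(windows[i, ])
      flag[i] <- f$flag
    }
  } else {
    f <- flag_of(windows)
    flag <- f$flag; fc <- f$fc; rc <- f$rc
  }
  flagged <- windows[flag, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_fst = numeric(), mean_pi_log_ratio = numeric())
  } else {
    out <- do.call(rbind, lapply(split(flagged, flagged$scaffold), function(fw) {
      ir <- IRanges::reduce(IRanges::IRanges(fw$start, fw$end),
                            min.gapwidth = 1L)
      hits <- IRanges::findOverlaps(IRanges::IRanges(fw$start, fw$end), ir)
      data.frame(
        scaffold = fw$scaffold[1L],
        start = IRanges::start(ir),
        end = IRanges::end(ir),
        n_windows = as.vector(table(S4Vectors::subjectHits(hits))),
        mean_fst = as.vector(tapply(fw$fst, S4Vectors::subjectHits(hits), mean)),
        mean_pi_log_ratio = as.vector(tapply(fw$pi_log_ratio,
                                             S4Vectors::subjectHits(hits),
                                             function(x) {
                                               f <- x[is.finite(x)]
                                               # fully swept members: all +Inf
                                               if (!length(f)) Inf else mean(f)
                                             })),
        stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out <- out[order(match(out$scaffold, unique(windows$scaffold)), out$start), ]
  }
  if (!per_scaffold) {
    attr(out, "fst_cutoff") <- fc
    attr(out, "ratio_cutoff") <- rc
  }
  out
}

#' Annotate sweep regions with contained SNPs
#'
#' Inclusive-interval containment of SNP positions (1-based) in regions.
#'
#' @param regions A [call_sweeps()] table.
#' @param snps data.frame with `scaffold`, `pos` (e.g. significant
#'   association SNPs).
#' @return `regions` with `n_snps` and a comma-separated `snp_keys` column.
#' @export
annotate_regions <- function(regions, snps) {
  regions$n_snps <- 0L
  regions$snp_keys <- ""
  if (nrow(regions) == 0L || nrow(snps) == 0L) return(regions)
  for (i in seq_len(nrow(regions))) {
    hit <- snps$scaffold == regions$scaffold[i] &
      snps$pos >= regions$start[i] & snps$pos <= regions$end[i]
    regions$n_snps[i] <- sum(hit)
    regions$snp_keys[i] <- paste(paste0(snps$scaffold[hit], ":", snps$pos[hit]),
                                 collapse = ",")
  }
  regions
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions data.frame with scaffold, start, end (1-based inclusive).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$scaffold, regions$start - 1L, regions$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
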