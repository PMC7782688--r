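#' Merge per-individual CNV calls into copy-number-variable regions (CNVRs)
#'
#' Overlapping CNV calls from different individuals are merged by transitive
#' overlap closure per scaffold; each region's boundaries are the minimum
#' start and maximum end of its member calls.  Regions supported by fewer
#' than `min_support` distinct individuals are filtered.  Individuals
#' without a call in a region are assigned the baseline copy number 1
#' (single-X male normalisation).
#'
#' @param calls data.frame: `individual`, `scaffold`, `start`, `end`
#'   (1-based inclusive), `copy_number`.
#' @param individuals Character vector of all individuals (defaults to those
#'   present in `calls`); needed so baseline copy numbers cover everyone.
#' @param min_support Minimum distinct supporting individuals (default 3).
#' @return list of CNVRs; each element has `scaffold`, `start`, `end`,
#'   `support`, and `copy_number` (named vector over all individuals).
#' @export
merge_cnvrs <- function(calls, individuals = NULL, min_support = 3L) {
  if (any(calls$end < calls$start)) stop("malformed interval (end < start)")
  if (is.null(individuals)) individuals <- sort(unique(calls$individual))
  out <- list()
  for (s in unique(calls$scaffold)) {
    cs <- calls[calls$scaffold == s, , drop = FALSE]
    ir <- IRanges::IRanges(cs$start, cs$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)   # strict overlap closure
    hits <- IRanges::findOverlaps(ir, merged)
    for (r in seq_along(merged)) {
      member <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == r]
      sup <- unique(cs$individual[member])
      if (length(sup) < min_support) next
      cn <- stats::setNames(rep(1, length(individuals)), individuals)
      # an individual with several member calls contributes their mean
      agg <- tapply(cs$copy_number[member], cs$individual[member], mean)
      cn[names(agg)] <- agg
      out[[length(out) + 1L]] <- list(
        scaffold = s,
        start = min(cs$start[member]), end = max(cs$end[member]),
        support = length(sup), copy_number = cn)
    }
  }
  out
}

#' VST copy-number differentiation between two groups
#'
#' `VST = (VT - VS) / VT`, where `VT` is the total variance in copy number
#' across both groups and `VS` the average of the within-group variances
#' weighted by sample size.  Sample (n-1) variances are used throughout.
#' `VT = 0` (no variation at all) is defined as VST = 0.
#'
#' @param a,b Numeric copy-number vectors for the two groups (each length
#'   >= 2).
#' @return The VST value (at most 1; 1 exactly when within-group variance
#'   is zero and the groups differ).
#' @export
vst <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  vt <- stats::var(c(a, b))
  if (vt == 0) return(0)
  vs <- (length(a) * stats::var(a) + length(b) * stats::var(b)) /
    (length(a) + length(b))
  (vt - vs) / vt
}

#' Flag morph-differentiated CNVRs
#'
#' A CNVR is flagged when its VST is strictly above the `q` nearest-rank
#' percentile of all CNVR VSTs AND a two-sample t-test on the copy numbers
#' gives p < `alpha`.
#'
#' @param cnvrs list from [merge_cnvrs()].
#' @param groups Named character vector (by individual id) with two group
#'   labels (e.g. morphs).
#' @param q Percentile for the VST criterion (default 0.95).
#' @param alpha t-test significance level (default 0.05).
#' @return data.frame: scaffold, start, end, support, vst, p_t,
#'   differentiated.
#' @export
differentiated_cnvrs <- function(cnvrs, groups, q = 0.95, alpha = 0.05) {
  if (length(cnvrs) == 0L) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), support = integer(), vst = numeric(),
                      p_t = numeric(), differentiated = logical()))
  }
  gl <- unique(groups)
  stopifnot(length(gl) == 2L)
  stat <- lapply(cnvrs, function(r) {
    cn <- r$copy_number[names(groups)]
    a <- cn[groups == gl[1]]
    b <- cn[groups == gl[2]]
    v <- vst(a, b)
    p <- if (stats::var(c(a, b)) == 0) 1 else
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    c(v = v, p = p)
  })
  v <- vapply(stat, `[[`, 0, "v")
  p <- vapply(stat, `[[`, 0, "p")
  if (length(v) < 20L) {
    warning("fewer than 20 CNVRs; the VST percentile is unstable")
    cut <- sort(v)[ceiling(q * length(v))]
  } else {
    cut <- empirical_cutoff(v, q)
  }
  data.frame(
    scaffold = vapply(cnvrs, `[[`, "", "scaffold"),
    start = vapply(cnvrs, function(r) as.integer(r$start), 0L),
    end = vapply(cnvrs, function(r) as.integer(r$end), 0L),
    support = vapply(cnvrs, function(r) as.integer(r$support), 0L),
    vst = v, p_t = p,
    differentiated = v > cut & p < alpha,
    stringsAsFactors = FALSE)
}
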