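#' Two-sided Fisher exact p-value for one site
#'
#' Case/control allele-count association.  Hemizygous male X genotypes
#' contribute one allele; diploid calls two.  An empty margin (no observed
#' alleles in a group, or a monomorphic table) gives p = 1 with a warning.
#'
#' @param case_ref,case_alt,ctrl_ref,ctrl_alt Allele counts of the 2x2 table.
#' @return Two-sided Fisher exact p-value.
#' @export
fisher_site <- function(case_ref, case_alt, ctrl_ref, ctrl_alt) {
  tab <- matrix(c(case_ref, case_alt, ctrl_ref, ctrl_alt), 2L, 2L)
  if (any(tab < 0)) stop("allele counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Case/control genome-wide association scan
#'
#' Per-site two-sided Fisher exact test on allele counts between flatwing
#' (case) and normal-wing (control) males, Bonferroni adjustment across the
#' sites actually tested in this run, and a significance flag at adjusted
#' p < 0.05.  Monomorphic sites (among the observed case+control alleles)
#' are skipped and do not count toward the number of tests.
#'
#' @param gm A [geno_matrix()].
#' @param case_idx,ctrl_idx Sample indices of cases and controls.
#' @param population Label stored in the output.
#' @param scaffolds Optional scaffold subset to test (e.g. X scaffolds only).
#' @return data.frame of class `assoc_table`: scaffold, pos, the 2x2 counts,
#'   `p`, `p_adj`, `significant`, `population`; attribute `n_tests`.
#' @export
gwas <- function(gm, case_idx, ctrl_idx, population = "pop",
                 scaffolds = NULL) {
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("need at least 2 cases and 2 controls")
  }
  sites_idx <- if (is.null(scaffolds)) seq_len(nrow(gm$sites)) else
    which(gm$sites$scaffold %in% scaffolds)
  sub <- subset_gm(gm, sites_idx = sites_idx)
  ca <- allele_counts(sub, case_idx)
  co <- allele_counts(sub, ctrl_idx)
  tot_alt <- ca$n_alt + co$n_alt
  tot_ref <- ca$n_ref + co$n_ref
  testable <- tot_alt > 0 & tot_ref > 0 & ca$n_obs > 0 & co$n_obs > 0
  idx <- which(testable)
  p <- vapply(idx, function(i) {
    stats::fisher.test(matrix(c(ca$n_ref[i], ca$n_alt[i],
                                co$n_ref[i], co$n_alt[i]), 2L, 2L))$p.value
  }, 0)
  n_tests <- length(idx)
  out <- data.frame(scaffold = sub$sites$scaffold[idx],
                    pos = sub$sites$pos[idx],
                    case_ref = ca$n_ref[idx], case_alt = ca$n_alt[idx],
                    ctrl_ref = co$n_ref[idx], ctrl_alt = co$n_alt[idx],
                    p = p,
                    p_adj = pmin(1, p * n_tests),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < 0.05
  out$population <- population
  attr(out, "n_tests") <- n_tests
  class(out) <- c("assoc_table", class(out))
  out
}

#' Convenience morph GWAS for one population
#'
#' Runs [gwas()] with flatwing males of `population` as cases.  Controls are
#' the population's normal-wing males, optionally extended to a pooled
#' control set from other populations (`control_pool`) for designs where the
#' within-population control morph is scarce.
#'
#' @param gm A [geno_matrix()] whose samples carry `pop`, `sex`, `morph`.
#' @param population Population label of the cases.
#' @param control_pool Optional character vector of population labels whose
#'   normal-wing males are added to the controls.
#' @param scaffolds Optional scaffold subset.
#' @return An `assoc_table`.
#' @export
morph_gwas <- function(gm, population, control_pool = NULL, scaffolds = NULL) {
  s <- gm$samples
  case_idx <- which(s$pop == population & s$morph == "flatwing" & s$sex == "male")
  ctrl_pops <- unique(c(population, control_pool))
  ctrl_idx <- which(s$pop %in% ctrl_pops & s$morph == "normal" & s$sex == "male")
  gwas(gm, case_idx, ctrl_idx, population = population, scaffolds = scaffolds)
}

#' Harmonise significant sets by the strictest (reference) criterion
#'
#' The reference run's Bonferroni-corrected raw-p cutoff,
#' `0.05 / n_tests_reference`, is applied to the raw p-values of every
#' population's table, so all populations are judged by the most
#' conservative uniform threshold.
#'
#' @param tables Named list of `assoc_table`s (one per population).
#' @param reference_pop Name of the reference population in `tables`.
#' @return list with `cutoff` and `sets`: named list of data.frames of
#'   retained sites per population.
#' @export
strictest_criterion <- function(tables, reference_pop) {
  ref <- tables[[reference_pop]]
  if (is.null(ref) || nrow(ref) == 0L) stop("reference table is empty")
  cutoff <- 0.05 / attr(ref, "n_tests")
  sets <- lapply(tables, function(t) t[t$p <= cutoff, , drop = FALSE])
  list(cutoff = cutoff, sets = sets)
}

#' Three-set overlap (Venn) counts at SNP and scaffold level
#'
#' Exact counts for all 7 regions of the three-set Venn diagram, at the SNP
#' granularity (scaffold:pos keys) and at the scaffold granularity.
#'
#' @param sets Named list of three data.frames with `scaffold` and `pos`.
#' @return list with `snp` and `scaffold`: named counts
#'   (`A_only, B_only, C_only, AB, AC, BC, ABC` with A/B/C replaced by the
#'   set names), plus `shared_all` convenience counts.
#' @export
assoc_overlap <- function(sets) {
  stopifnot(length(sets) == 3L)
  nm <- names(sets)
  venn <- function(keys) {
    inA <- keys$all %in% keys$k[[1]]
    inB <- keys$all %in% keys$k[[2]]
    inC <- keys$all %in% keys$k[[3]]
    cnt <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
             sum(!inA & !inB & inC), sum(inA & inB & !inC),
             sum(inA & !inB & inC), sum(!inA & inB & inC),
             sum(inA & inB & inC))
    names(cnt) <- c(paste0(nm, "_only"),
                    paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
    cnt
  }
  snp_keys <- lapply(sets, function(s) {
    if (nrow(s) == 0L) character(0) else paste0(s$scaffold, ":", s$pos)
  })
  scf_keys <- lapply(sets, function(s) unique(s$scaffold))
  snp <- venn(list(all = unique(unlist(snp_keys)), k = snp_keys))
  scf <- venn(list(all = unique(unlist(scf_keys)), k = scf_keys))
  list(snp = snp, scaffold = scf,
       shared_all_snps = unname(snp[length(snp)]),
       shared_all_scaffolds = unname(scf[length(scf)]))
}
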