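#' Genotype matrix container
#'
#' The substrate for all statistics in the package: biallelic sites by
#' individuals, with per-site metadata (scaffold, 1-based position,
#' X/autosome flag, site quality), per-individual metadata (id, population,
#' sex, morph, mean sequencing depth), and optional per-call depth fields
#' (DP and allele depths).  Genotypes are stored as alternate-allele dosages:
#' 0..2 at diploid calls, 0..1 at hemizygous male X calls, `NA` for unknown.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based,
#'   strictly increasing within scaffold), `is_x`, and optionally `qual`.
#' @param geno integer matrix, sites x individuals, of alt-allele dosages.
#' @param samples data.frame with columns `id`, `pop`, `sex` and optionally
#'   `morph`, `mean_depth`.
#' @param dp,ad_ref,ad_alt optional matrices of per-call total / reference /
#'   alternate read depths, same shape as `geno`.
#' @param het optional logical matrix flagging calls that were literally
#'   heterozygous in the source VCF (needed to recognise diploid-coded male X
#'   artefacts, where a dosage of 1 is otherwise ambiguous).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, geno, samples, dp = NULL, ad_ref = NULL,
                        ad_alt = NULL, het = NULL) {
  stopifnot(is.data.frame(sites), is.data.frame(samples),
            nrow(geno) == nrow(sites), ncol(geno) == nrow(samples))
  if (is.null(sites$qual)) sites$qual <- NA_real_
  for (scf in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == scf]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within scaffold ", scf)
    }
  }
  colnames(geno) <- samples$id
  structure(list(sites = sites, geno = geno, samples = samples,
                 dp = dp, ad_ref = ad_ref, ad_alt = ad_alt, het = het),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$sites), "sites x", nrow(x$samples),
      "individuals on", length(unique(x$sites$scaffold)), "scaffold(s)\n")
  cat("  X sites:", sum(x$sites$is_x), "; populations:",
      paste(unique(x$samples$pop), collapse = ", "), "\n")
  invisible(x)
}

#' Per-call ploidy of a genotype matrix
#'
#' 1 for male calls at X sites (XX/XO hemizygosity), 2 elsewhere.
#'
#' @param gm A [geno_matrix()].
#' @return Integer matrix, sites x individuals.
#' @export
ploidy_matrix <- function(gm) {
  pl <- matrix(2L, nrow(gm$sites), nrow(gm$samples))
  if (any(gm$sites$is_x)) {
    male <- gm$samples$sex == "male"
    pl[gm$sites$is_x, male] <- 1L
  }
  pl
}

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param sites_idx,samples_idx integer/logical indices; `NULL` keeps all.
#' @return The subsetted `geno_matrix`.
#' @export
subset_gm <- function(gm, sites_idx = NULL, samples_idx = NULL) {
  if (is.null(sites_idx)) sites_idx <- seq_len(nrow(gm$sites))
  if (is.null(samples_idx)) samples_idx <- seq_len(nrow(gm$samples))
  sub <- function(m) if (is.null(m)) NULL else m[sites_idx, samples_idx, drop = FALSE]
  geno_matrix(gm$sites[sites_idx, , drop = FALSE],
              sub(gm$geno),
              gm$samples[samples_idx, , drop = FALSE],
              dp = sub(gm$dp), ad_ref = sub(gm$ad_ref), ad_alt = sub(gm$ad_alt),
              het = sub(gm$het))
}

#' Observed allele counts per site
#'
#' Counts observed reference and alternate alleles across a set of
#' individuals, respecting ploidy and skipping unknown calls
#' (pairwise deletion).
#'
#' @param gm A [geno_matrix()].
#' @param samples_idx individuals to count over (default all).
#' @return data.frame with `n_ref`, `n_alt`, `n_obs` and alt frequency `p`
#'   (`NaN` where nothing observed).
#' @export
allele_counts <- function(gm, samples_idx = NULL) {
  if (is.null(samples_idx)) samples_idx <- seq_len(nrow(gm$samples))
  g <- gm$geno[, samples_idx, drop = FALSE]
  pl <- ploidy_matrix(gm)[, samples_idx, drop = FALSE]
  pl[is.na(g)] <- 0L
  g0 <- g; g0[is.na(g0)] <- 0L
  n_alt <- rowSums(g0)
  n_obs <- rowSums(pl)
  data.frame(n_ref = n_obs - n_alt, n_alt = n_alt, n_obs = n_obs,
             p = ifelse(n_obs > 0, n_alt / n_obs, NaN))
}

## ---------------------------------------------------------------------------
## VCF and TSV interchange

#' Write a genotype matrix as VCF v4.2
#'
#' X scaffolds are flagged in the contig header lines; male X calls are
#' written haploid.  Output is gzip-compressed when the path ends in `.gz`,
#' plain text otherwise.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of scaffold lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_gm <- function(gm, path, contig_lengths = NULL) {
  n_site <- nrow(gm$sites)
  n_ind <- nrow(gm$samples)
  pl <- ploidy_matrix(gm)

  gt <- matrix("", n_site, n_ind)
  dip <- pl == 2L
  g <- gm$geno
  gt[dip & !is.na(g) & g == 0L] <- "0/0"
  gt[dip & !is.na(g) & g == 1L] <- "0/1"
  gt[dip & !is.na(g) & g == 2L] <- "1/1"
  gt[!dip & !is.na(g) & g == 0L] <- "0"
  gt[!dip & !is.na(g) & g == 1L] <- "1"
  gt[dip & is.na(g)] <- "./."
  gt[!dip & is.na(g)] <- "."

  has_depth <- !is.null(gm$dp) && !is.null(gm$ad_ref)
  if (has_depth) {
    body <- paste(gt, paste0(gm$ad_ref, ",", gm$ad_alt), gm$dp, sep = ":")
    body[is.na(g)] <- paste0(gt[is.na(g)], ":.,.:.")
    fmt <- "GT:AD:DP"
  } else {
    body <- gt
    fmt <- "GT"
  }
  body <- matrix(body, n_site, n_ind)

  scfs <- unique(gm$sites$scaffold)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(scfs, function(s)
      max(gm$sites$pos[gm$sites$scaffold == s]), 0)
  }
  is_x_scf <- vapply(scfs, function(s)
    any(gm$sites$is_x[gm$sites$scaffold == s]), TRUE)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=flatwingr",
    paste0("##contig=<ID=", scfs, ",length=", contig_lengths[scfs],
           ",chromosome=", ifelse(is_x_scf, "X", "autosome"), ">"),
    '##INFO=<ID=XL,Number=0,Type=Flag,Description="Site on an X-linked scaffold">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_depth) c(
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  )
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$samples$id), collapse = "\t")
  lines <- c(meta, header,
             paste(gm$sites$scaffold, gm$sites$pos, ".", "A", "T",
                   ifelse(is.na(gm$sites$qual), ".", gm$sites$qual), "PASS",
                   ifelse(gm$sites$is_x, "XL", "."), fmt,
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read a VCF plus sample metadata into a genotype matrix
#'
#' Uses vcfR for parsing.  X scaffolds are identified from the `XL` INFO
#' flag or contig header metadata written by [write_vcf_gm()], or can be
#' supplied explicitly.  Haploid GT fields become dosage 0/1; unrecognised
#' or missing GT becomes `NA`.
#'
#' @param vcf_path VCF file (plain or gzipped).
#' @param meta Sample metadata data.frame (`id`, `pop`, `sex`, ...) or a path
#'   to a TSV with those columns; `NULL` derives a minimal one (all male,
#'   one population).
#' @param x_scaffolds Optional character vector naming X scaffolds.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(vcf_path, meta = NULL, x_scaffolds = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  scf <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- fix[, "INFO"]
  if (is.null(x_scaffolds)) {
    x_scaffolds <- unique(scf[grepl("(^|;)XL($|;)", info)])
    if (!length(x_scaffolds)) {
      m <- regmatches(v@meta, regexec("##contig=<ID=([^,>]+).*chromosome=X",
                                      v@meta))
      x_scaffolds <- vapply(Filter(function(x) length(x) == 2, m),
                            `[`, "", 2L)
    }
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  dos[gt == "0"] <- 0L
  dos[gt == "1"] <- 1L
  het <- matrix(gt %in% c("0/1", "1/0", "0|1", "1|0"), nrow(gt), ncol(gt))

  dp <- ad_ref <- ad_alt <- NULL
  fmt_has <- function(el) any(grepl(paste0("(^|:)", el, "($|:)"),
                                    v@gt[, "FORMAT"]))
  if (fmt_has("AD")) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- suppressWarnings(matrix(as.integer(sub(",.*", "", ad)),
                                      nrow(ad), ncol(ad)))
    ad_alt <- suppressWarnings(matrix(as.integer(sub(".*,", "", ad)),
                                      nrow(ad), ncol(ad)))
  }
  if (fmt_has("DP")) {
    dp <- suppressWarnings(matrix(as.integer(vcfR::extract.gt(v, element = "DP")),
                                  nrow(gt), ncol(gt)))
  }

  ids <- colnames(gt)
  if (is.character(meta) && length(meta) == 1L) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  }
  if (is.null(meta)) {
    meta <- data.frame(id = ids, pop = "pop1", sex = "male",
                       stringsAsFactors = FALSE)
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  if (anyNA(meta$id)) stop("sample metadata is missing ids present in the VCF")

  geno_matrix(
    sites = data.frame(scaffold = scf, pos = pos,
                       is_x = scf %in% x_scaffolds, qual = qual,
                       stringsAsFactors = FALSE),
    geno = dos, samples = meta, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    het = het)
}

#' Write the ground-truth tables of a simulated dataset
#'
#' Serialises the truth of a [simulate_demography()] run as plain TSV files
#' alongside the VCF: `truth_causal.tsv` (causal loci and realised final
#' frequencies), `truth_trajectory_<deme>.tsv` (per-generation allele and
#' phenotype frequencies), `truth_samples.tsv` (per-individual deme, sex,
#' morph, source, migrant ancestry) and `truth_migration.tsv` (realised
#' per-generation migrant influx per deme).  The round trip through
#' [read_truth()] is lossless up to numeric formatting.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create truth directory ", dir)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(dataset$truth$causal, "truth_causal.tsv")
  wt(dataset$samples, "truth_samples.tsv")
  for (d in names(dataset$truth$trajectories)) {
    wt(dataset$truth$trajectories[[d]], paste0("truth_trajectory_", d, ".tsv"))
  }
  if (!is.null(dataset$truth$migrant_influx)) {
    wt(as.data.frame(dataset$truth$migrant_influx), "truth_migration.tsv")
  }
  invisible(dir)
}

#' Read back truth tables written by [write_truth()]
#'
#' @param dir Directory containing the truth TSVs.
#' @return list with `causal`, `samples`, `trajectories`, `migrant_influx`.
#' @export
read_truth <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f)) utils::read.delim(f, stringsAsFactors = FALSE) else NULL
  }
  tr_files <- list.files(dir, pattern = "^truth_trajectory_.*\\.tsv$")
  traj <- lapply(tr_files, function(f) utils::read.delim(file.path(dir, f)))
  names(traj) <- sub("^truth_trajectory_(.*)\\.tsv$", "\\1", tr_files)
  list(causal = rd("truth_causal.tsv"), samples = rd("truth_samples.tsv"),
       trajectories = traj, migrant_influx = rd("truth_migration.tsv"))
}

#' Write sample metadata TSV (id, deme/population, sex, morph)
#'
#' @param dataset A `sim_dataset` or a [geno_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(dataset, path) {
  df <- if (inherits(dataset, "sim_dataset")) {
    data.frame(id = dataset$samples$id, pop = dataset$samples$deme,
               sex = dataset$samples$sex, morph = dataset$samples$morph,
               mean_depth = dataset$genotypes$samples$mean_depth,
               stringsAsFactors = FALSE)
  } else dataset$samples
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
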