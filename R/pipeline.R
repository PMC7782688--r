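#' Default end-to-end run configuration
#'
#' Assembles the stage parameters for [run_pipeline()]: the simulation
#' scenario, window geometry, jackknife block size, association and
#' tree-building settings, permutation counts and output location.  Every
#' parameter can be overridden by name.
#'
#' @param scenario Scenario preset name (see [make_scenario()]).
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param ... Named overrides of any config field.
#' @return A `run_config` list.
#' @export
default_run_config <- function(scenario = "parallel", seed = 1L,
                               out_dir = NULL, ...) {
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    out_dir = out_dir,
    scenario_overrides = list(),
    stages = c(simulate = TRUE, qc = TRUE, dstat = TRUE, winstats = TRUE,
               assoc = TRUE, trees = TRUE, contrast = TRUE, sweep = TRUE),
    vcf_path = NULL,
    meta_path = NULL,
    window_size = 10000L,
    window_step = 2500L,
    min_qual = 30,
    max_missing = 0.25,
    dstat_block_bp = 5e4,
    gwas_reference = "oahu",
    tree_flank_bp = 25000L,
    bootstrap_B = 200L,
    n_permutations = 1000L,
    sweep_q = 0.95,
    contrast_flank_bp = 75000L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown run-config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration without running it
#'
#' Lists unmet preconditions: unknown scenario, disabled simulation without
#' input paths, inconsistent window geometry, missing stage inputs.
#'
#' @param config A `run_config`.
#' @return Character vector of problems (length 0 = valid).
#' @export
validate_config <- function(config) {
  probs <- character(0)
  if (!config$scenario %in% c("parallel", "introgression", "no_geneflow",
                              "neutral")) {
    probs <- c(probs, paste0("unknown scenario '", config$scenario, "'"))
  }
  if (!config$stages[["simulate"]] &&
      (is.null(config$vcf_path) || is.null(config$meta_path))) {
    probs <- c(probs,
               "simulation disabled but no vcf_path/meta_path supplied")
  }
  if (config$window_step > config$window_size) {
    probs <- c(probs, "window step exceeds window size")
  }
  if (config$window_step <= 0) probs <- c(probs, "window step must be positive")
  if (config$stages[["contrast"]] && !config$stages[["winstats"]]) {
    probs <- c(probs, "contrast stage needs the winstats stage")
  }
  if (config$stages[["sweep"]] && !config$stages[["winstats"]]) {
    probs <- c(probs, "sweep stage needs the winstats stage")
  }
  probs
}

#' Run the full inference chain on a simulated scenario
#'
#' Orchestrates simulate -> qc -> gene-flow D -> window statistics ->
#' per-island association -> trees/clustering -> net-divergence contrast ->
#' sweep scan, and returns a machine-readable summary with the headline
#' verdict fields: `gene_flow_detected`, `shared_snps`, `shared_scaffolds`,
#' `flatwing_monophyletic`, `d_contrast_p`, `sweep_regions_n`.  Identical
#' config + seed give identical output.  When `out_dir` is set, stage
#' outputs (VCF, truth, tables, summary JSON) are written there.
#'
#' @param config A `run_config` from [default_run_config()].
#' @return list with `verdict`, `stages` (per-stage results) and `truth`.
#' @export
run_pipeline <- function(config) {
  probs <- validate_config(config)
  if (length(probs)) stop("invalid config: ", paste(probs, collapse = "; "))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  save_tsv <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  ## -- simulate ------------------------------------------------------------
  ds <- NULL
  if (config$stages[["simulate"]]) {
    scfg <- do.call(make_scenario,
                    c(list(config$scenario), config$scenario_overrides))
    ds <- simulate_demography(scfg, seed = config$seed)
    if (!is.null(out_dir)) {
      write_vcf_gm(ds$genotypes, file.path(out_dir, "simulated.vcf"),
                   contig_lengths = stats::setNames(scfg$genome$length_bp,
                                                    scfg$genome$scaffold))
      write_sample_meta(ds, file.path(out_dir, "samples.tsv"))
      write_truth(ds, file.path(out_dir, "truth"))
    }
    gm <- ds$genotypes
  } else {
    gm <- read_genotypes(config$vcf_path, config$meta_path)
  }
  stages$simulate <- list(n_sites = nrow(gm$sites),
                          n_samples = nrow(gm$samples))

  ## -- qc ------------------------------------------------------------------
  if (config$stages[["qc"]]) {
    qc <- qc_chain(gm, min_qual = config$min_qual,
                   max_missing = config$max_missing)
    gm <- qc$gm
    stages$qc <- qc$report
    save_tsv(qc$report, "qc_report.tsv")
  }
  x_scaffolds <- unique(gm$sites$scaffold[gm$sites$is_x])
  pops <- gm$samples$pop
  has_morphs <- any(gm$samples$morph == "flatwing")

  ## -- gene flow (ABBA-BABA) ----------------------------------------------
  if (config$stages[["dstat"]]) {
    set.seed(config$seed + 11L)
    d_haw <- dstat_test(gm, "kauai", "hilo", "oahu", "outgroup",
                        block_size_bp = config$dstat_block_bp)
    d_ctrl <- if ("australia" %in% pops) {
      dstat_test(gm, "kauai", "hilo", "australia", "outgroup",
                 block_size_bp = config$dstat_block_bp)
    } else NULL
    cmp <- if (!is.null(d_ctrl)) {
      compare_dstat_groups(d_haw$blocks$D_block, d_ctrl$blocks$D_block)
    } else NULL
    stages$dstat <- list(hawaii = d_haw, control = d_ctrl, contrast = cmp)
    gene_flow_detected <- is.finite(d_haw$Z) && abs(d_haw$Z) >= 3
  } else gene_flow_detected <- NA

  ## -- window statistics ---------------------------------------------------
  win_sweep <- win_x <- NULL
  if (config$stages[["winstats"]]) {
    scf_len <- .scaffold_lengths(ds, gm)
    s <- gm$samples
    popsets <- list(australia = which(s$pop == "australia"))
    for (d in c("kauai", "oahu", "hilo")) {
      popsets[[paste0(d, "_fw")]] <- which(s$pop == d & s$morph == "flatwing")
      popsets[[paste0(d, "_nw")]] <- which(s$pop == d & s$morph == "normal")
    }
    popsets <- popsets[vapply(popsets, length, 0L) >= 2L]
    if (has_morphs && "kauai_fw" %in% names(popsets) &&
        "australia" %in% names(popsets)) {
      win_sweep <- window_stats(gm, popsets[c("australia", "kauai_fw")],
                                contrast = c("australia", "kauai_fw"),
                                scaffold_lengths = scf_len,
                                size = config$window_size,
                                step = config$window_step)
      save_tsv(win_sweep, "windows_sweepscan.tsv")
    }
    if (has_morphs && all(c("kauai_fw", "oahu_fw") %in% names(popsets))) {
      win_x <- window_stats(gm, popsets[c("kauai_fw", "oahu_fw")],
                            contrast = c("kauai_fw", "oahu_fw"),
                            scaffold_lengths = scf_len[x_scaffolds],
                            size = config$window_size,
                            step = config$window_step)
      save_tsv(win_x, "windows_x_flatwing.tsv")
    }
    stages$winstats <- list(sweep_grid = win_sweep, x_grid = win_x)
  }

  ## -- association ---------------------------------------------------------
  shared_snps <- shared_scaffolds <- NA_integer_
  sig_snps <- NULL
  if (config$stages[["assoc"]] && has_morphs) {
    set.seed(config$seed + 13L)
    tabs <- list()
    for (d in c("kauai", "oahu", "hilo")) {
      s <- gm$samples
      n_case <- sum(s$pop == d & s$morph == "flatwing" & s$sex == "male")
      n_ctrl <- sum(s$pop == d & s$morph == "normal" & s$sex == "male")
      if (n_case < 2L) next
      pool <- if (d == "kauai") c("oahu", "hilo") else NULL
      tabs[[d]] <- morph_gwas(gm, d, control_pool = pool,
                              scaffolds = x_scaffolds)
    }
    stages$assoc <- tabs
    if (length(tabs) == 3L) {
      harm <- strictest_criterion(tabs, config$gwas_reference)
      sig <- lapply(harm$sets, function(t) t[, c("scaffold", "pos")])
      ov <- assoc_overlap(sig)
      shared_snps <- ov$shared_all_snps
      shared_scaffolds <- ov$shared_all_scaffolds
      sig_snps <- unique(do.call(rbind, sig))
      stages$assoc_harmonised <- harm
      stages$assoc_overlap <- ov
      save_tsv(do.call(rbind, lapply(names(harm$sets), function(n) {
        x <- harm$sets[[n]]; x$population <- n; x
      })), "assoc_significant.tsv")
    }
  }

  ## -- trees / morph clustering --------------------------------------------
  flatwing_monophyletic <- NA
  if (config$stages[["trees"]] && has_morphs && !is.null(sig_snps) &&
      nrow(sig_snps) > 0L) {
    set.seed(config$seed + 17L)
    near <- rep(FALSE, nrow(gm$sites))
    for (k in seq_len(nrow(sig_snps))) {
      near <- near | (gm$sites$scaffold == sig_snps$scaffold[k] &
                        abs(gm$sites$pos - sig_snps$pos[k]) <= config$tree_flank_bp)
    }
    tip_idx <- which(gm$samples$pop %in% c("kauai", "oahu", "hilo", "australia"))
    bc <- bootstrap_consensus(gm, sites_idx = which(near),
                              B = config$bootstrap_B, samples_idx = tip_idx)
    morph <- stats::setNames(gm$samples$morph[tip_idx],
                             gm$samples$id[tip_idx])
    fw_tips <- names(morph)[morph == "flatwing"]
    supp <- flatwing_bipartition_support(bc$trees, fw_tips)
    main_tree <- suppressWarnings(nj_tree(
      ibs_distance(gm, sites_idx = which(near), samples_idx = tip_idx)))
    ct <- flatwing_clustering_test(main_tree, morph, support = supp)
    stages$trees <- list(consensus = bc$tree, support = supp, test = ct,
                         n_sites = sum(near))
    flatwing_monophyletic <- ct$monophyletic && supp >= 70
    if (!is.null(out_dir)) {
      ape::write.tree(main_tree, file.path(out_dir, "flatwing_region_nj.nwk"))
    }
  }

  ## -- net-divergence contrast ---------------------------------------------
  d_contrast_p <- NA_real_
  if (config$stages[["contrast"]] && !is.null(win_x) && !is.null(sig_snps) &&
      nrow(sig_snps) > 0L) {
    mask <- rep(FALSE, nrow(win_x))
    for (k in seq_len(nrow(sig_snps))) {
      mask <- mask | (win_x$scaffold == sig_snps$scaffold[k] &
                        win_x$end >= sig_snps$pos[k] - config$contrast_flank_bp &
                        win_x$start <= sig_snps$pos[k] + config$contrast_flank_bp)
    }
    if (sum(mask) >= 10L && sum(!mask) >= 10L) {
      ctr <- region_divergence_contrast(win_x, mask,
                                        n_randomizations = config$n_permutations,
                                        seed = config$seed + 19L)
      stages$contrast <- ctr
      d_contrast_p <- ctr$d$p_perm
    }
  }

  ## -- sweep scan ----------------------------------------------------------
  sweep_regions_n <- NA_integer_
  if (config$stages[["sweep"]] && !is.null(win_sweep)) {
    regions <- call_sweeps(win_sweep, q = config$sweep_q)
    if (!is.null(sig_snps) && nrow(regions)) {
      regions <- annotate_regions(regions, sig_snps)
    }
    stages$sweep <- regions
    sweep_regions_n <- nrow(regions)
    if (!is.null(out_dir) && nrow(regions)) {
      save_tsv(regions, "sweep_regions.tsv")
      write_bed(regions, file.path(out_dir, "sweep_regions.bed"))
    }
  }

  verdict <- list(
    scenario = config$scenario,
    gene_flow_detected = gene_flow_detected,
    shared_snps = shared_snps,
    shared_scaffolds = shared_scaffolds,
    flatwing_monophyletic = flatwing_monophyletic,
    d_contrast_p = d_contrast_p,
    sweep_regions_n = sweep_regions_n
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(verdict, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(verdict = verdict, stages = stages,
       truth = if (!is.null(ds)) ds$truth else NULL)
}

.scaffold_lengths <- function(ds, gm) {
  if (!is.null(ds)) {
    stats::setNames(ds$config$genome$length_bp, ds$config$genome$scaffold)
  } else {
    vapply(split(gm$sites$pos, gm$sites$scaffold), max, 0)
  }
}
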