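#!/usr/bin/env Rscript
# The introgression-vs-parallel instruments: IBS neighbour-joining trees on
# flatwing-associated regions with bootstrap consensus and the morph
# clustering test, plus the net-divergence (d) randomization contrast
# between flatwing-associated windows and the X background.
# Needs: analysis/01_simulate_scenarios.R

suppressMessages(library(flatwingr))

dir.create("results/trees", recursive = TRUE, showWarnings = FALSE)

for (sc in c("parallel", "introgression")) {
  gm <- read_genotypes(file.path("results/sim", sc, "genotypes.vcf"),
                       file.path("results/sim", sc, "samples.tsv"))
  gm <- qc_chain(gm)$gm
  tabs <- list(
    kauai = morph_gwas(gm, "kauai", control_pool = c("oahu", "hilo"),
                       scaffolds = "scaffold_X1"),
    oahu = morph_gwas(gm, "oahu", scaffolds = "scaffold_X1"),
    hilo = morph_gwas(gm, "hilo", scaffolds = "scaffold_X1"))
  sig <- do.call(rbind, lapply(strictest_criterion(tabs, "oahu")$sets,
                               `[`, c("scaffold", "pos")))

  near <- rep(FALSE, nrow(gm$sites))
  for (k in seq_len(nrow(sig))) {
    near <- near | (gm$sites$scaffold == sig$scaffold[k] &
                      abs(gm$sites$pos - sig$pos[k]) <= 25000)
  }
  tips <- which(gm$samples$pop %in% c("kauai", "oahu", "hilo", "australia"))
  bc <- bootstrap_consensus(gm, which(near), B = 200, samples_idx = tips)
  morph <- setNames(gm$samples$morph[tips], gm$samples$id[tips])
  supp <- flatwing_bipartition_support(bc$trees,
                                       names(morph)[morph == "flatwing"])
  tree <- suppressWarnings(nj_tree(ibs_distance(gm, which(near), tips)))
  verdict <- flatwing_clustering_test(tree, morph, support = supp)
  ape::write.tree(tree, file.path("results/trees", paste0(sc, "_nj.nwk")))

  # d between wild flatwing Kauai and Oahu, flatwing regions vs X background
  s <- gm$samples
  w <- window_stats(gm, list(
    kauai_fw = which(s$pop == "kauai" & s$morph == "flatwing"),
    oahu_fw = which(s$pop == "oahu" & s$morph == "flatwing")),
    contrast = c("kauai_fw", "oahu_fw"),
    scaffold_lengths = c(scaffold_X1 = 3e6))
  mask <- rep(FALSE, nrow(w))
  for (k in seq_len(nrow(sig))) {
    mask <- mask | (w$scaffold == sig$scaffold[k] &
                      w$end >= sig$pos[k] - 75000 &
                      w$start <= sig$pos[k] + 75000)
  }
  ctr <- region_divergence_contrast(w, mask, n_randomizations = 1000,
                                    seed = 1)
  message(sprintf(
    "%-13s flatwing monophyletic %s (support %.0f, mixing score %d) | d contrast: diff %+0.2e perm p %.4f (dxy p %.3f)",
    sc, verdict$monophyletic, supp, verdict$mixing_score,
    ctr$d$observed_diff, ctr$d$p_perm, ctr$dxy$p_perm))
}
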