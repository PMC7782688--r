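#!/usr/bin/env Rscript
# Joint empirical-percentile selective-sweep scan: windows in the top 5% of
# both Fst and the pi log-ratio (Kauai flatwing vs unselected Australia),
# merged into candidate regions and annotated with flatwing-associated SNPs.
# Needs: analysis/04_window_diversity.R and analysis/05_association_mapping.R

suppressMessages(library(flatwingr))

w <- read.delim("results/windows/selection_grid.tsv")
sig <- read.delim("results/assoc/parallel_significant.tsv")

regions <- call_sweeps(w, q = 0.95)
regions <- annotate_regions(regions, sig)
dir.create("results/sweeps", recursive = TRUE, showWarnings = FALSE)
write.table(regions, "results/sweeps/sweep_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_bed(regions, "results/sweeps/sweep_regions.bed")

message(sprintf(
  "%d candidate sweep regions (Fst cutoff %.3f, ratio cutoff %.3f), %.2f%% of the genome",
  nrow(regions), attr(regions, "fst_cutoff"), attr(regions, "ratio_cutoff"),
  100 * sum(regions$end - regions$start + 1) / 9e6))
message(sprintf("%d flatwing-associated SNPs fall inside sweep regions",
                sum(regions$n_snps)))
print(regions[order(-regions$n_windows), ][1:5,
      c("scaffold", "start", "end", "n_windows", "mean_fst", "n_snps")])
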