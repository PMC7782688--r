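#!/usr/bin/env Rscript
# Apply the variant QC chain (site quality >= 30, per-individual abnormal
# depth masking with halved X criteria, male-X hemizygote fixing, <= 25%
# missingness) to the simulated parallel-scenario VCF and report what each
# rule removed.  Needs: analysis/01_simulate_scenarios.R

suppressMessages(library(flatwingr))

gm <- read_genotypes("results/sim/parallel/genotypes.vcf",
                     "results/sim/parallel/samples.tsv")
res <- qc_chain(gm)
print(res$report)
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.table(res$report, "results/qc/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf_gm(res$gm, "results/qc/parallel_qc.vcf")
message(sprintf("retained %d of %d sites (%.2f%%)",
                nrow(res$gm$sites), nrow(gm$sites),
                100 * nrow(res$gm$sites) / nrow(gm$sites)))
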