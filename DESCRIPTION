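Package: flatwingr
Title: Population-Genomic Inference of Parallel Adaptation Under Gene Flow in Island Crickets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of an island-structured cricket
    metapopulation with an X-linked, male-limited adaptive morph ('flatwing'),
    together with the inference chain used to distinguish parallel mutational
    origins from adaptive introgression: VCF genotype quality control with
    XX/XO hemizygote handling, sliding-window diversity and differentiation
    statistics (pi, Watterson's theta, Tajima's D, Weir-Cockerham Fst, dxy and
    net divergence), ABBA-BABA D statistics with block jackknife, per-island
    case/control association with Bonferroni harmonisation, identity-by-state
    neighbour-joining trees with bootstrap consensus and a morph-clustering
    test, net-divergence randomization contrasts, joint pi-ratio/Fst
    selective-sweep scans, and VST copy-number differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    vcfR,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
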