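---
title: "Models and methods: parallel adaptation under gene flow in island crickets"
author: "flatwingr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Hawaiian field crickets (*Teleogryllus oceanicus*) on Kauai, Oahu and the
Big Island have repeatedly evolved silent "flatwing" males: an X-linked,
male-limited wing mutation that erases the sound-producing structures and
thereby protects males from an acoustically orienting parasitoid fly. The
population-genomic question is whether the same causal allele spread from
island to island (adaptive introgression) or whether each island acquired
its own mutation (parallel evolution) — and whether the answer holds up in
the presence of substantial ongoing inter-island gene flow.

`flatwingr` implements both halves of the investigation at desk scale:

1. a forward Wright–Fisher simulator of the island system that can plant
   either history (one causal origin carried by migrants, or three
   independent origins) with full ground truth, and
2. the inference chain that distinguishes the two: genotype QC, ABBA–BABA
   *D* statistics with block jackknife, per-island case/control association
   with a harmonised significance criterion, identity-by-state
   neighbour-joining trees with a morph-clustering test, net-divergence
   randomization contrasts, sliding-window diversity statistics, a joint
   Fst × π-log-ratio selective-sweep scan, and V~ST~ copy-number
   differentiation.

Every stage of the chain is exercisable against simulated data whose truth
is known, so the package's tests check the *inferential* behaviour of the
pipeline, not only the arithmetic of its estimators.

## The sweep model

The flatwing locus is X-linked and male-limited. With XX females and XO
males, sons receive their single X from their mother, daughters one X from
each parent. Selection is viability selection on males only: a singing
(non-carrier) male survives to adulthood with relative fitness
$w_{normal}$, a silent carrier with fitness 1. Writing $p_f$ and $p_m$ for
the carrier-allele frequency in female and male gametes,

$$\phi = \frac{p_m}{p_m + (1-p_m)\,w_{normal}}, \qquad
  p_f' = \tfrac12\,(p_f + \phi), \qquad p_m' = p_f ,$$

with binomial Wright–Fisher sampling at $N_f = N_m = N/2$ around each step;
$\phi$ is also the observable flatwing fraction among adult males.
`simulate_sweep_trajectory()` implements the stochastic recursion and
`deterministic_sweep()` its infinite-population limit, which serves as an
oracle in the tests. With $w_{normal} = 0.1$ and $p_0 = 0.005$ the
deterministic recursion carries the male phenotype past 95% within about
ten generations, matching the field observation that silent males rose from
0% to over 95% of the Kauai population within 20–30 generations, and
essentially all established stochastic trajectories at $N = 1000$ are fixed
well before generation 60 (the Kauai population is now fixed for the
morph). $w_{normal} = 0.1$ is a deliberately strong but field-plausible
value: parasitoid attack on singing males is close to lethal where the fly
is dense.

The Oahu-like deme holds the morph at an intermediate frequency. We model
this as negatively frequency-dependent carrier-male fitness,
$w_{flat} = \exp\{s\,(p_{eq} - \phi_{t-1})\}$ with $p_{eq} = 0.45$ and
$s = 1$, a protected polymorphism whose equilibrium matches the ~45%
flatwing frequency persistently observed on Oahu. The Hilo-like deme
carries the morph at low frequency; we give it weak selection
($w_{normal} = 0.9$) and a later origin, and condition on the allele
segregating at sampling.

## The demographic backbone

Scenario presets encode the reconstructed colonisation history, converted
from years at 4 generations/year (generation time 0.25 yr): an Oahu-like
deme founded 3200 generations ago (800 years), Hilo splitting from Oahu
2280 generations ago (570 years), Kauai from the Hilo lineage 1600
generations ago (400 years), founder bottlenecks after each split, and
recent migration among all three islands beginning 1500 generations ago
(~370 years, within the reconstructed 300–400-year window) and continuing
to the present. A distant conspecific deme (Australia-like; split 4000
generations, never exchanging migrants with the islands) provides the
unselected control population, and an outgroup taxon carrying fixed derived
differences provides polarisation for the ABBA–BABA test.

Neutral variation is a frequency-level forward Wright–Fisher simulation
under infinite sites: ancestral standing variation drawn from the neutral
site-frequency spectrum (density $\propto 1/p$), drift by binomial
resampling of deme allele frequencies at the deme's allele count (2N at
autosomes, 1.5N at X sites), a Poisson influx of new mutations on island
lineages, and stochastic island-model migrant replacement. The realised
per-generation migrant fraction and deme ancestry proportions are recorded
as ground truth. Deep migration-free branch segments are advanced with
drift-equivalent time compression (a segment of $g$ generations at allele
count $M$ is stepped $g/k$ times at count $M/k$, preserving the frequency
diffusion; $k = 8$ by default); all generations with migration active are
simulated individually.

Free parameters not fixed by the study system were chosen once, as
plausible desk-scale values, and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| island deme size $N$ | 3000 | recent splits must leave abundant shared polymorphism (incomplete lineage sorting) for the D statistic; $T/2N \le 0.5$ per branch |
| Australia-like deme | $N = 8000$, split 4000 gen | an older, larger, unselected reference population |
| migration rates | Kauai↔Oahu $2\times10^{-3}$, other pairs $2\times10^{-5}$ | all pairs exchange migrants ("extensive gene flow"), with pair-specific magnitudes (the reconstruction's per-pair rates differ); the asymmetry across pairs is what the ABBA–BABA test detects |
| bottleneck | ×0.5 for 100 gen after founding | founder effects without degenerate fixation of whole windows |
| genome | 6 Mb autosome (24k sites) + 3 Mb X (5k sites) | enough windows for empirical percentiles; X density low enough that per-island Bonferroni correction leaves the causal association detectable with 10 vs 10 males |
| hitchhiking tract | mean 2 Mb/side, 50 kb core | at ~60 generations post-origin the expected recombination breakpoint distance is of megabase order; the core emulates the selection-maintained haplotype in complete LD with the causal site |
| read depth | Poisson, mean 30× (halved on male X) | matches a ~25–30× resequencing design |

Sampling mirrors the field design: 10 flatwing + 10 normal-wing males per
island, 7 Australian males, 3 outgroup males, with lab-stock conditioning
where a morph is absent in the wild (Kauai normal-wing, Hilo flatwing are
drawn conditioned on carrier state, labelled `lab` in the metadata).

### What the generator does and does not emulate

Sites are exchangeable and unlinked except for the causal tract: linked
selection is emulated by copying a locus-specific sweep haplotype into
carriers over a contiguous exponential-length tract, not by simulating
recombination genome-wide. Consequences: window autocorrelation of the
neutral background is weaker than in real data (the randomization contrast
offers a block-permutation mode for the overlapping-window grid);
haplotype-based sweep statistics (iHS-type) are out of scope; and the
per-block variance of D reflects site sampling rather than linkage blocks.
There is no sequencing error, no alignment artefact, and depth fields are
honest — the QC chain therefore removes almost nothing from simulated data
(< 1% of sites), which the tests assert; the QC rules are exercised against
hand-constructed corrupted inputs instead.

## The inference chain

**QC (`qc_chain`)** applies, in order: site quality ≥ 30 (strict `< 30`
removal); masking of calls with depth below 1/3× or above 3× the
individual's mean (bounds halved on X scaffolds: mean/6 and 1.5× mean);
male-X heterozygote resolution by allele-depth supermajority (fix to the
allele with strictly more than 3× the other's depth, otherwise unknown);
and removal of sites with unknown calls in strictly more than 25% of
individuals. Boundary cases are retained; all inequalities are read
strictly. Downstream statistics use pairwise deletion of unknown calls.

**Window statistics (`window_stats`)** use a 10 kb / 2.5 kb sliding grid,
dropping windows that overstep scaffold ends. π and d~xy~ are divided by
the full window length in bp (the convention of the standard VCF tooling),
not by callable sites. Tajima's D uses the 1989 constants with the window's
maximum observed allele count; Weir–Cockerham Fst is the ratio-of-sums
weighted estimator computed from allele counts with the heterozygosity term
at zero (appropriate for hemizygous male X data), with the Hudson
estimator as a cross-check option; negative estimates are reported as-is.
Net divergence is $d = d_{xy} - (d_x + d_y)/2$. The π log-ratio
$\log_{10}(\pi_{unselected}/\pi_{selected})$ flags totally swept windows
($\pi_{selected} = 0$) as $+\infty$ so they are never excluded from
top-percentile scans, and drops windows with $\pi_{unselected} = 0$ as
undefined.

**ABBA–BABA (`dstat_test`)** uses frequency weighting
$abba = (1-p_1)p_2p_3(1-p_4)$, $baba = p_1(1-p_2)p_3(1-p_4)$ with the
derived allele polarised against the outgroup major allele; outgroup
polymorphism down-weights rather than excludes sites. The standard error is
the weighted delete-one-block jackknife (Busing et al. 1999) over
contiguous blocks with block weights equal to their informative mass. The
pipeline's gene-flow verdict is $|Z| \ge 3$ for the island trio
(((Kauai, Hilo), Oahu), outgroup). The Welch contrast between island and
control trios' per-block |D| is implemented and reported, but at desk
scale, with unlinked sites, per-block |D| is inflated for the
information-poor control trio, so it does not drive the verdict.

**Association (`morph_gwas`)** is a per-site two-sided Fisher exact test
on allele counts (one allele per hemizygous male), Bonferroni-adjusted
within the run; monomorphic sites are skipped and do not count as tests.
The Kauai design pools normal-wing controls from the lab stock and the
other islands, as in the field study. Cross-island harmonisation
(`strictest_criterion`) applies the reference (Oahu) run's Bonferroni raw-p
cutoff, $0.05/n_{tests}^{ref}$, to every population — the only reading of a
"most conservative criterion" that is monotone and robust to different
control-set sizes. Benjamini–Hochberg adjustment can be obtained by
applying `p.adjust` to the table's raw p column; the package asserts
nothing about it.

**Trees and clustering (`bootstrap_consensus`,
`flatwing_clustering_test`)** build identity-by-state distances
(pairwise-deletion mismatch fractions), neighbour-joining trees, and
majority-rule bootstrap consensus over site resampling. The
introgression-vs-parallel verdict is operationalised as: flatwing tips
monophyletic *and* that bipartition supported in ≥ 70% of bootstrap
replicates; the Fitch parsimony count of morph state changes is reported as
a rooting-invariant mixing score. The 70% threshold is this package's
operationalisation of a judgement the original analysis made by visual
inspection of the trees.

**Net-divergence contrast (`region_divergence_contrast`)** compares mean
$d$ (and separately $d_{xy}$) between flatwing-associated windows and the
rest of the X, with a one-sided randomization p-value
$(1 + \#\{null \ge obs\})/(n+1)$ over 1000 label reassignments. Because
2.5 kb-step windows overlap, the default null permutes contiguous runs (a
random circular rotation of the mask per scaffold) rather than individual
windows, which would be anti-conservative; the naive window permutation and
the Welch t-test are also available/reported. Under parallel origins the
flatwing regions show elevated $d$ (each island swept a different
haplotype, crushing within-island diversity) with unremarkable $d_{xy}$;
under introgression neither is elevated — the discriminating pattern.

**Sweep scan (`call_sweeps`)** flags windows strictly above the
nearest-rank 95th percentile of both Fst and the π log-ratio (ties at the
threshold excluded — deterministic and conservative), merges overlapping or
book-ended flagged windows per scaffold, and annotates regions with
contained association SNPs by inclusive-interval containment. Percentiles
are genome-wide by default with a per-scaffold option.

**Copy number (`merge_cnvrs`, `vst`)** merges per-individual CNV calls by
strict overlap closure into CNVRs (boundaries = min start/max end),
discards regions supported by fewer than three individuals, assigns
baseline copy number 1 (single-X male normalisation) to individuals without
a call, and flags morph-differentiated CNVRs by VST strictly above the 95th
percentile *and* a t-test p < 0.05. VST = (V~T~ − V~S~)/V~T~ with sample
(n−1) variances and V~S~ weighted by group size; V~T~ = 0 is defined as
VST 0. With extreme configurations at very small n, the sample-variance
convention can make VST of identical groups negative rather than zero;
this is documented behaviour, not an error.

## Numerical choices and degenerate inputs

* Undefined statistics are `NA` flags, never silent zeros: π with fewer
  than two observed alleles everywhere, Tajima's D with S = 0, D with zero
  ABBA+BABA mass, r² at monomorphic sites.
* The block jackknife requires ≥ 10 non-empty blocks and advises a smaller
  block size otherwise; identical blocks give SE 0 and an infinite Z flag.
* NJ branch lengths are clamped at zero with a warning; bootstrap subsets
  below 10 sites warn.
* The Welch scenario contrast short-circuits to p = 1 when all values are
  identical.
* Randomization p-values use the +1 correction and can never be zero.
* Seeds: every simulation function takes an explicit seed; the pipeline
  derives per-stage seeds from its global seed by fixed offsets, and
  identical config + seed reproduce all outputs byte-identically.

## Problem sizes

The default desk-scale dataset is ~20,000 segregating sites across a 6 Mb
autosome and a 3 Mb X for 70 sampled males, simulating in roughly half a
minute; a full pipeline run (simulation through sweep scan, 150 bootstrap
replicates, 1000 permutations) takes on the order of one to two minutes.
The acceptance analyses use 20 replicates of a 10,000-site three-island
design for the D-statistic null and 200 sweep-trajectory replicates for the
phenotype-spread and fixation checks.

## Known limitations

* Frequency-level simulation cannot express haplotype-scale introgression
  tracts for *neutral* variation; gene-flow detection rests on
  frequency-covariance asymmetry, which is weaker than block-level signals
  available to chromosome-scale simulators.
* The balanced Oahu polymorphism is a phenomenological frequency-dependence
  model; the real mechanism (possibly a competing silent morph) is unknown.
* The GWAS operates on the X scaffold (the morph is X-linked by
  construction); autosomal association would require a denser desk genome
  than the Bonferroni design allows at 10-vs-10 sample sizes.
* ML trees (Tamura–Nei) are not re-implemented; the clustering test accepts
  any tree, including externally built ML trees, via `ape` Newick I/O.
* CNV *calling* from read depth is upstream of this package; the CNV module
  consumes call tables.
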