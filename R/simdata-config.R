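#' Scenario presets for the island cricket simulator
#'
#' Builds a fully populated simulation configuration for one of the four
#' canonical scenarios used throughout the package:
#'
#' * `"parallel"` — three distinct X-linked causal loci on a shared scaffold,
#'   one per island deme, each arising by independent mutation; migration
#'   moves neutral variation but never a causal allele between demes.
#' * `"introgression"` — a single causal origin in the Kauai-like deme; the
#'   identical allele (and its haplotype) is carried into the Oahu-like and
#'   Hilo-like demes by migrants and then selected locally.
#' * `"no_geneflow"` — migration rates all zero; a causal locus only in the
#'   Kauai-like deme.
#' * `"neutral"` — no causal locus and no selection anywhere.
#'
#' The demographic backbone follows the inferred colonisation history of the
#' Hawaiian populations: an Oahu-like deme founded first (800 years before
#' present), a Hilo-like deme splitting from it (570 years), and a Kauai-like
#' deme splitting from the Hilo lineage (400 years), with a cricket
#' generation time of 0.25 years, i.e. split times of 3200, 2280 and 1600
#' generations. Recent symmetric-within-pair migration among the islands
#' starts 1400 generations ago (~350 years). A distant conspecific deme
#' (Australia-like, never exchanging migrants with the islands) and a fixed
#' outgroup taxon are included for polarisation and control contrasts.
#'
#' @param name One of `"parallel"`, `"introgression"`, `"no_geneflow"`,
#'   `"neutral"`.
#' @param ... Named overrides applied on top of the preset (e.g.
#'   `deme_size = 500`, `include_australia = FALSE`, `migration = m`).
#'   Unknown names are an error.
#' @return A `sim_config` list; see Details for fields.
#'
#' @details Fields of the returned configuration:
#' \describe{
#'   \item{scenario}{preset name.}
#'   \item{deme_size}{diploid individuals per island deme (males carry one X).}
#'   \item{split_gens}{named vector, generations before present at which each
#'     island lineage was founded: oahu 3200, hilo 2280, kauai 1600.}
#'   \item{australia_split_gens}{founding of the distant conspecific deme.}
#'   \item{bottleneck_factor, bottleneck_gens}{post-split size multiplier and
#'     its duration, emulating founder bottlenecks followed by expansion.}
#'   \item{migration}{3x3 per-generation replacement-rate matrix among island
#'     demes (row = recipient), active from `migration_start_gen` onward.}
#'   \item{genome}{data.frame of scaffolds: name, length_bp, is_x, and
#'     n_anc ancestral standing segregating sites.}
#'   \item{mutation_influx}{expected new mutations per island deme per
#'     generation (desk-scale effective rate; see the methods vignette).}
#'   \item{causal}{data.frame of causal loci: deme, scaffold, pos,
#'     origin_gen, w_normal, freq_dependent, p0, target.}
#'   \item{sample_males}{named list: sampled males per deme.}
#'   \item{seed}{default RNG seed.}
#' }
#' @export
#' @examples
#' cfg <- make_scenario("no_geneflow")
#' all(cfg$migration == 0)
make_scenario <- function(name, ...) {
  valid <- c("parallel", "introgression", "no_geneflow", "neutral")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }

  demes <- c("kauai", "oahu", "hilo")
  mig <- matrix(0, 3, 3, dimnames = list(demes, demes))
  if (name %in% c("parallel", "introgression")) {
    # pairwise symmetric rates; magnitudes are free parameters of the model
    mig["kauai", "oahu"] <- mig["oahu", "kauai"] <- 0.002
    mig["oahu", "hilo"]  <- mig["hilo", "oahu"]  <- 0.00002
    mig["kauai", "hilo"] <- mig["hilo", "kauai"] <- 0.00002
  }

  genome <- data.frame(
    scaffold = c("scaffold_A1", "scaffold_X1"),
    length_bp = c(6e6, 3e6),
    is_x = c(FALSE, TRUE),
    n_anc = c(24000L, 5000L),
    stringsAsFactors = FALSE
  )

  # Causal loci all sit on the X scaffold (the trait is X-linked and
  # male-limited).  origin_gen counts generations before present.
  causal <- switch(
    name,
    parallel = data.frame(
      deme = demes,
      scaffold = "scaffold_X1",
      pos = c(600000L, 1500000L, 2400000L),
      origin_gen = c(60L, 50L, 36L),
      w_normal = c(0.1, 1.0, 0.9),
      freq_dependent = c(FALSE, TRUE, FALSE),
      p0 = 0.005,
      target = c("fixed", "balanced", "rare"),
      origin_deme = demes,
      stringsAsFactors = FALSE
    ),
    introgression = data.frame(
      deme = demes,
      scaffold = "scaffold_X1",
      pos = 600000L,
      origin_gen = c(60L, 50L, 36L),
      w_normal = c(0.1, 1.0, 0.9),
      freq_dependent = c(FALSE, TRUE, FALSE),
      p0 = 0.005,
      target = c("fixed", "balanced", "rare"),
      origin_deme = "kauai",
      stringsAsFactors = FALSE
    ),
    no_geneflow = data.frame(
      deme = "kauai",
      scaffold = "scaffold_X1",
      pos = 600000L,
      origin_gen = 60L,
      w_normal = 0.1,
      freq_dependent = FALSE,
      p0 = 0.005,
      target = "fixed",
      origin_deme = "kauai",
      stringsAsFactors = FALSE
    ),
    neutral = data.frame(
      deme = character(), scaffold = character(), pos = integer(),
      origin_gen = integer(), w_normal = numeric(),
      freq_dependent = logical(), p0 = numeric(), target = character(),
      origin_deme = character(), stringsAsFactors = FALSE
    )
  )

  cfg <- list(
    scenario = name,
    demes = demes,
    deme_size = 3000L,
    australia_size = 8000L,
    split_gens = c(oahu = 3200L, hilo = 2280L, kauai = 1600L),
    australia_split_gens = 4000L,
    ancestral_burnin_gens = 100L,
    bottleneck_factor = 0.5,
    bottleneck_gens = 100L,
    migration = mig,
    migration_start_gen = 1500L,
    mutation_rate = 3.5e-9,
    genome = genome,
    mutation_influx = 0.3,
    outgroup_div_per_bp = 0.002,
    causal = causal,
    balanced_equilibrium = 0.45,
    fd_strength = 1.0,
    hitch_halfwidth = 100000L,
    hitch_scale = 2000000L,
    hitch_floor = 50000L,
    include_australia = TRUE,
    sample_males = list(kauai = 20L, oahu = 20L, hilo = 20L,
                        australia = 7L, outgroup = 3L),
    sample_females = list(kauai = 0L, oahu = 0L, hilo = 0L,
                          australia = 0L, outgroup = 0L),
    read_depth = 30,
    seed = 1L
  )

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg <- validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a `sim_config`: split times strictly
#' decreasing toward the present, migration rates in \[0, 1\], relative
#' fitnesses in (0, 1\], deme sizes of at least 2, non-negative mutation
#' parameters, and at least one scaffold.
#'
#' @param cfg A configuration list as built by [make_scenario()].
#' @return The configuration, invisibly classed, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  if (is.null(cfg$causal)) {
    cfg$causal <- data.frame(deme = character(), scaffold = character(),
                             pos = integer(), origin_gen = integer(),
                             w_normal = numeric(), freq_dependent = logical(),
                             p0 = numeric(), target = character(),
                             origin_deme = character(),
                             stringsAsFactors = FALSE)
  }
  s <- cfg$split_gens
  if (!(s["oahu"] > s["hilo"] && s["hilo"] > s["kauai"] && s["kauai"] > 0)) {
    stop("split times must be strictly decreasing toward the present")
  }
  if (cfg$include_australia && cfg$australia_split_gens <= s["oahu"]) {
    stop("the distant conspecific deme must predate the island radiation")
  }
  if (any(cfg$migration < 0) || any(cfg$migration > 1) ||
      any(rowSums(cfg$migration) > 1)) {
    stop("migration rates must lie in [0, 1] with row sums <= 1")
  }
  if (cfg$deme_size < 2L) stop("deme sizes must be >= 2")
  if (nrow(cfg$causal) && (any(cfg$causal$w_normal <= 0) ||
                           any(cfg$causal$w_normal > 1))) {
    stop("relative fitness w_normal must lie in (0, 1]")
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_influx < 0) {
    stop("mutation parameters must be non-negative")
  }
  if (nrow(cfg$genome) == 0L) stop("genome layout needs at least one scaffold")
  if (any(cfg$genome$length_bp <= 0)) stop("scaffold lengths must be positive")
  cfg
}
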