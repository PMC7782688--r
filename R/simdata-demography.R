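#' Forward simulation of the island metapopulation
#'
#' Simulates neutral genome-wide variation plus the scenario's causal
#' locus/loci through the colonisation history encoded in the configuration,
#' and samples individuals into a genotype matrix with full ground truth.
#'
#' The neutral backbone is a frequency-level Wright-Fisher forward simulation
#' under an infinite-sites model: ancestral standing variation is drawn from
#' the neutral site-frequency spectrum (density proportional to 1/p), each
#' lineage then drifts by binomial resampling of allele frequencies at its
#' deme's allele count (2N at autosomal sites, 1.5N at X sites since males
#' are hemizygous), founder bottlenecks shrink that count for
#' `bottleneck_gens` generations after each split, new mutations enter island
#' demes as a Poisson influx, and from `migration_start_gen` onward the
#' island demes exchange migrants by stochastic island-model replacement (the
#' realised per-generation migrant fraction of each deme is recorded as
#' truth, as are deme ancestry proportions).  Deep, migration-free branch
#' segments are advanced with drift-equivalent time compression: a segment of
#' `g` generations at allele count `M` is stepped `g/k` times at count `M/k`,
#' which preserves the frequency diffusion (see the methods vignette); all
#' generations with migration active are simulated one by one.
#'
#' Causal dynamics are simulated at the locus level with
#' [simulate_sweep_trajectory()], conditioned on the scenario target
#' (fixation, balanced polymorphism, or rare presence).  Hitchhiking is
#' emulated at the haplotype level: every carrier inherits a locus-specific
#' sweep haplotype on a contiguous tract around the causal site, consisting
#' of a selection-maintained core (`hitch_floor` bp each side) plus an
#' exponentially distributed retained length (mean `hitch_scale`), emulating
#' recombination breakpoints accumulated since the sweep began.  In the
#' introgression scenario all demes share the single Kauai-origin haplotype;
#' in the parallel scenario each deme sweeps its own.
#'
#' @param config A `sim_config` from [make_scenario()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_dataset` list with elements `genotypes` (a
#'   [geno_matrix()]), `samples` (metadata data.frame: id, deme, sex, morph,
#'   source, migrant_fraction), `truth` (list: causal table with realised
#'   final frequencies, per-deme trajectories, per-generation migrant influx,
#'   final ancestry matrix, sweep haplotypes) and `config`.
#' @export
simulate_demography <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  set.seed(as.integer(seed))

  demes <- config$demes
  N <- config$deme_size
  genome <- config$genome
  rescale <- if (is.null(config$drift_rescale)) 8L else config$drift_rescale
  splits <- config$split_gens
  mig_active <- any(config$migration > 0)
  t_mig <- if (mig_active) config$migration_start_gen else 0L
  if (mig_active && t_mig > splits[["kauai"]]) {
    stop("migration must not start before the youngest deme is founded")
  }

  causal <- config$causal
  causal_pos <- if (nrow(causal)) {
    unique(causal[, c("scaffold", "pos")])
  } else NULL

  ## ---- site table: ancestral standing variation + pre-drawn mutations ----
  draw_pos <- function(i, n) {
    avoid <- if (is.null(causal_pos)) integer(0) else
      causal_pos$pos[causal_pos$scaffold == genome$scaffold[i]]
    pos <- setdiff(sample.int(genome$length_bp[i], n + length(avoid)), avoid)
    pos[seq_len(n)]
  }
  anc <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    pos <- sort(draw_pos(i, genome$n_anc[i]))
    data.frame(scaffold = genome$scaffold[i], pos = pos,
               is_x = genome$is_x[i], birth_gen = NA_integer_,
               birth_deme = NA_character_, stringsAsFactors = FALSE)
  }))

  seg_list <- list(
    list(deme = "oahu", from = splits[["oahu"]], to = 0L),
    list(deme = "hilo", from = splits[["hilo"]], to = 0L),
    list(deme = "kauai", from = splits[["kauai"]], to = 0L)
  )
  births <- do.call(rbind, lapply(seg_list, function(s) {
    span <- s$from - s$to
    n <- stats::rpois(1L, config$mutation_influx * span)
    if (n == 0L) return(NULL)
    sc <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length_bp)
    data.frame(scaffold = genome$scaffold[sc],
               pos = vapply(sc, function(j) draw_pos(j, 1L)[1L], 1L),
               is_x = genome$is_x[sc],
               birth_gen = s$to + sample.int(span, n, replace = TRUE),
               birth_deme = s$deme, stringsAsFactors = FALSE)
  }))
  sites <- rbind(anc, births)
  ns <- nrow(sites)

  ac_of <- function(n_dip) ifelse(sites$is_x, round(1.5 * n_dip), 2L * n_dip)
  ac_island <- ac_of(N)
  ac_bneck <- pmax(4L, ac_of(max(2L, round(N * config$bottleneck_factor))))

  ## ---- drift engine (optionally time-compressed) ----
  drift <- function(p, ac, gens, resc = 1L) {
    if (gens <= 0L) return(p)
    nstep <- max(1L, ceiling(gens / resc))
    ac_eff <- pmax(2L, round(ac * nstep / gens))
    seg <- which(p > 0 & p < 1)
    for (i in seq_len(nstep)) {
      if (!length(seg)) break
      p[seg] <- stats::rbinom(length(seg), ac_eff[seg], p[seg]) / ac_eff[seg]
      seg <- seg[p[seg] > 0 & p[seg] < 1]
    }
    p
  }

  ## ---- ancestral state ----
  ac_root <- ac_of(if (config$include_australia) config$australia_size else N)
  lo <- 1 / ac_root[1L]
  p_root <- lo * ((1 - lo) / lo)^stats::runif(ns)
  p_root[!is.na(sites$birth_gen)] <- 0     # born later
  p_root <- drift(p_root, ac_root, config$ancestral_burnin_gens, rescale)

  ## ---- independent branch phase ----
  if (config$include_australia) {
    p_aus <- drift(p_root, ac_root, config$australia_split_gens, rescale)
    p_haw <- drift(p_root, ac_root,
                   config$australia_split_gens - splits[["oahu"]], rescale)
  } else {
    p_aus <- NULL
    p_haw <- p_root
  }

  found <- function(p_parent, t_found, t_stop) {
    bg <- min(config$bottleneck_gens, t_found - t_stop)
    p <- drift(p_parent, ac_bneck, bg, rescale)
    drift(p, ac_island, (t_found - bg) - t_stop, rescale)
  }
  activate <- function(p, t_hi, t_lo, deme) {
    idx <- which(!is.na(sites$birth_gen) & sites$birth_deme == deme &
                   sites$birth_gen <= t_hi & sites$birth_gen > t_lo)
    if (length(idx)) p[idx] <- 1 / ac_island[idx]
    p
  }

  p_oa <- activate(p_haw, splits[["oahu"]], splits[["hilo"]], "oahu")
  p_oa <- found(p_oa, splits[["oahu"]], splits[["hilo"]])
  p_hi <- activate(p_oa, splits[["hilo"]], splits[["kauai"]], "hilo")
  p_hi <- found(p_hi, splits[["hilo"]], splits[["kauai"]])
  p_oa <- activate(p_oa, splits[["hilo"]], splits[["kauai"]], "oahu")
  p_oa <- drift(p_oa, ac_island, splits[["hilo"]] - splits[["kauai"]], rescale)
  p_ka <- activate(p_hi, splits[["kauai"]], t_mig, "kauai")
  p_ka <- found(p_ka, splits[["kauai"]], t_mig)
  p_hi <- activate(p_hi, splits[["kauai"]], t_mig, "hilo")
  p_hi <- drift(p_hi, ac_island, splits[["kauai"]] - t_mig, rescale)
  p_oa <- activate(p_oa, splits[["kauai"]], t_mig, "oahu")
  p_oa <- drift(p_oa, ac_island, splits[["kauai"]] - t_mig, rescale)

  P <- rbind(kauai = p_ka, oahu = p_oa, hilo = p_hi)

  ## ---- coupled recent phase: migration + births, one generation at a time ----
  mig_frac_rec <- NULL
  ancestry <- diag(3); dimnames(ancestry) <- list(demes, demes)
  if (mig_active && t_mig > 0L) {
    M <- config$migration
    mig_frac_rec <- matrix(0, t_mig, 3, dimnames = list(NULL, demes))
    for (g in seq(t_mig, 1L)) {
      Pnew <- P
      Anew <- ancestry
      for (i in 1:3) {
        fr <- vapply(1:3, function(j) {
          if (i == j || M[i, j] == 0) 0 else stats::rbinom(1L, N, M[i, j]) / N
        }, 0)
        ftot <- sum(fr)
        if (ftot > 0) {
          Pnew[i, ] <- (1 - ftot) * P[i, ] +
            fr[1] * P[1, ] + fr[2] * P[2, ] + fr[3] * P[3, ]
          Anew[i, ] <- (1 - ftot) * ancestry[i, ] +
            fr[1] * ancestry[1, ] + fr[2] * ancestry[2, ] + fr[3] * ancestry[3, ]
        }
        mig_frac_rec[t_mig - g + 1L, i] <- ftot
      }
      ancestry <- Anew
      for (i in 1:3) {
        idx <- which(!is.na(sites$birth_gen) & sites$birth_deme == demes[i] &
                       sites$birth_gen == g)
        if (length(idx)) Pnew[i, idx] <- 1 / ac_island[idx]
      }
      for (i in 1:3) {
        seg <- which(Pnew[i, ] > 0 & Pnew[i, ] < 1)
        if (length(seg)) {
          Pnew[i, seg] <- stats::rbinom(length(seg), ac_island[seg],
                                        Pnew[i, seg]) / ac_island[seg]
        }
      }
      P <- Pnew
    }
  }

  ## ---- causal trajectories (conditioned on the scenario target) ----
  traj <- list()
  if (nrow(causal)) {
    causal$final_freq <- NA_real_
    for (k in seq_len(nrow(causal))) {
      row <- causal[k, ]
      tr <- .conditioned_trajectory(row, N, config, seed + 1000L * k)
      traj[[row$deme]] <- tr
      causal$final_freq[k] <- (tr$p_f[nrow(tr)] + tr$p_m[nrow(tr)]) / 2
    }
  }

  ## ---- sample individuals into a genotype matrix ----
  samp <- .sample_individuals(config, sites, P, p_aus, causal, ancestry)

  truth <- list(causal = causal, trajectories = traj,
                migrant_influx = mig_frac_rec, ancestry = ancestry,
                sweep_haplotypes = samp$haplotypes)
  out <- list(genotypes = samp$gm, samples = samp$meta, truth = truth,
              config = config, seed = as.integer(seed))
  class(out) <- "sim_dataset"
  out
}

# Conditioned causal trajectory: resample until the scenario target is met.
.conditioned_trajectory <- function(row, N, config, seed0) {
  ok <- switch(row$target,
    fixed = function(p) p >= 0.95,
    balanced = function(p) p > 0.15 && p < 0.75,
    rare = function(p) p > 0 && p <= 0.30)
  for (try in 1:500) {
    tr <- simulate_sweep_trajectory(
      seed = seed0 + try, n_generations = row$origin_gen, N = N,
      w_normal = row$w_normal, p0 = row$p0,
      freq_dependent = row$freq_dependent,
      p_eq = config$balanced_equilibrium, fd_strength = config$fd_strength)
    pfin <- (tr$p_f[nrow(tr)] + tr$p_m[nrow(tr)]) / 2
    if (ok(pfin)) return(tr)
  }
  stop("could not realise causal target '", row$target, "' in 500 attempts")
}

# Draw sampled individuals' genotypes, morphs and hitchhiking haplotypes.
.sample_individuals <- function(config, sites, P, p_aus, causal, ancestry) {
  demes <- config$demes
  genome <- config$genome
  ns <- nrow(sites)

  ## outgroup-private fixed derived sites (deep interspecific divergence)
  og_extra <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    n <- stats::rpois(1L, config$outgroup_div_per_bp * genome$length_bp[i])
    if (n == 0L) return(NULL)
    pos <- sample.int(genome$length_bp[i], n)
    pos <- setdiff(pos, c(sites$pos[sites$scaffold == genome$scaffold[i]],
                          causal$pos[causal$scaffold == genome$scaffold[i]]))
    data.frame(scaffold = genome$scaffold[i], pos = sort(pos),
               is_x = genome$is_x[i], birth_gen = NA_integer_,
               birth_deme = "outgroup", stringsAsFactors = FALSE)
  }))

  causal_sites <- if (nrow(causal)) {
    cs <- unique(causal[, c("scaffold", "pos")])
    data.frame(scaffold = cs$scaffold, pos = cs$pos, is_x = TRUE,
               birth_gen = NA_integer_, birth_deme = "causal",
               stringsAsFactors = FALSE)
  } else NULL

  all_sites <- rbind(sites, og_extra, causal_sites)
  n_all <- nrow(all_sites)
  idx_neutral <- seq_len(ns)
  idx_og <- if (is.null(og_extra)) integer(0) else ns + seq_len(nrow(og_extra))
  idx_causal <- if (is.null(causal_sites)) integer(0) else
    (n_all - nrow(causal_sites) + 1L):n_all

  causal_idx_of <- function(scf, pos) {
    idx_causal[all_sites$scaffold[idx_causal] == scf &
                 all_sites$pos[idx_causal] == pos]
  }

  ## one sweep haplotype per distinct causal origin
  hap_list <- list()
  if (nrow(causal)) {
    for (od in unique(causal$origin_deme)) {
      loci <- causal[causal$origin_deme == od, ]
      scf <- loci$scaffold[1L]; cpos <- loci$pos[1L]
      tract <- idx_neutral[sites$scaffold == scf &
                             abs(sites$pos - cpos) <= config$hitch_halfwidth]
      hap_list[[paste0(od, ":", cpos)]] <- list(
        origin = od, scaffold = scf, pos = cpos, tract = tract,
        positions = sites$pos[tract],
        alleles = stats::rbinom(length(tract), 1L, P[od, tract]))
    }
  }

  overlay_hitch <- function(dos, deme) {
    # the carrier inherits the sweeping haplotype on a contiguous tract
    # around the causal site; recombination since the sweep began truncates
    # it at exponentially distributed breakpoints either side
    rows <- causal[causal$deme == deme, , drop = FALSE]
    if (nrow(rows) == 0L) return(dos)
    h <- hap_list[[paste0(rows$origin_deme[1L], ":", rows$pos[1L])]]
    # a selection-maintained core of hitch_floor bp is never separated from
    # the causal allele on this timescale; breakpoints beyond it are
    # exponential with mean hitch_scale
    lft <- config$hitch_floor + stats::rexp(1L, 1 / config$hitch_scale)
    rgt <- config$hitch_floor + stats::rexp(1L, 1 / config$hitch_scale)
    pos <- all_sites$pos[h$tract]
    take <- pos >= h$pos - lft & pos <= h$pos + rgt
    dos[h$tract[take]] <- h$alleles[take]
    dos
  }

  meta <- list()
  cols <- list()
  add_ind <- function(id, deme, sex, morph, source, freqs, carrier, mig_frac) {
    ploidy <- ifelse(all_sites$is_x & sex == "male", 1L, 2L)
    p <- numeric(n_all)
    p[idx_neutral] <- freqs
    if (length(idx_og)) p[idx_og] <- if (deme == "outgroup") 1 else 0
    dos <- stats::rbinom(n_all, ploidy, p)
    if (length(idx_causal)) {
      dos[idx_causal] <- 0L
      if (carrier) {
        crow <- causal[causal$deme == deme, ][1L, ]
        dos[causal_idx_of(crow$scaffold, crow$pos)] <- 1L
        dos <- overlay_hitch(dos, deme)
      }
    }
    cols[[id]] <<- dos
    meta[[id]] <<- data.frame(id = id, deme = deme, sex = sex, morph = morph,
                              source = source, migrant_fraction = mig_frac,
                              stringsAsFactors = FALSE)
  }

  for (d in demes) {
    n_tot <- config$sample_males[[d]]
    mig_frac <- 1 - unname(ancestry[d, d])
    if (d %in% causal$deme) {
      pfin <- causal$final_freq[causal$deme == d][1L]
      n_case <- n_tot %/% 2L
      # where a morph is (near-)absent in the wild it is drawn from lab
      # stock conditioned on carrier state, mirroring the sampling design
      wild_case <- pfin > 0.05
      wild_ctrl <- pfin < 0.95
      for (i in seq_len(n_case)) {
        add_ind(sprintf("%s_fw_%02d", d, i), d, "male", "flatwing",
                if (wild_case) "wild" else "lab", P[d, ], TRUE, mig_frac)
      }
      for (i in seq_len(n_tot - n_case)) {
        add_ind(sprintf("%s_nw_%02d", d, i), d, "male", "normal",
                if (wild_ctrl) "wild" else "lab", P[d, ], FALSE, mig_frac)
      }
    } else if (n_tot > 0L) {
      for (i in seq_len(n_tot)) {
        add_ind(sprintf("%s_nw_%02d", d, i), d, "male", "normal", "wild",
                P[d, ], FALSE, mig_frac)
      }
    }
    nf <- config$sample_females[[d]]
    if (nf > 0L) {
      for (i in seq_len(nf)) {
        add_ind(sprintf("%s_f_%02d", d, i), d, "female", "unknown", "wild",
                P[d, ], FALSE, mig_frac)
      }
    }
  }
  if (config$include_australia && config$sample_males$australia > 0L) {
    for (i in seq_len(config$sample_males$australia)) {
      add_ind(sprintf("australia_nw_%02d", i), "australia", "male", "normal",
              "wild", p_aus, FALSE, 0)
    }
  }
  if (config$sample_males$outgroup > 0L) {
    for (i in seq_len(config$sample_males$outgroup)) {
      add_ind(sprintf("outgroup_%02d", i), "outgroup", "male", "normal",
              "wild", rep(0, ns), FALSE, 0)
    }
  }

  G <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL

  ## retain only sites variable among the sampled alleles
  sex_pl <- ifelse(meta$sex == "male", 1L, 2L)
  pl <- matrix(2L, nrow(G), ncol(G))
  pl[all_sites$is_x, ] <- matrix(rep(sex_pl, each = sum(all_sites$is_x)),
                                 nrow = sum(all_sites$is_x))
  frac <- G / pl
  keep <- rowSums(frac > 0, na.rm = TRUE) > 0 &
    rowSums(frac < 1, na.rm = TRUE) > 0
  G <- G[keep, , drop = FALSE]
  all_sites <- all_sites[keep, , drop = FALSE]

  ord <- order(match(all_sites$scaffold, genome$scaffold), all_sites$pos)
  G <- G[ord, , drop = FALSE]
  all_sites <- all_sites[ord, , drop = FALSE]

  gm <- geno_matrix(
    sites = data.frame(scaffold = all_sites$scaffold, pos = all_sites$pos,
                       is_x = all_sites$is_x, qual = 60,
                       stringsAsFactors = FALSE),
    geno = G,
    samples = data.frame(id = meta$id, pop = meta$deme, sex = meta$sex,
                         morph = meta$morph, mean_depth = config$read_depth,
                         stringsAsFactors = FALSE))
  gm <- simulate_read_depth(gm)

  list(gm = gm, meta = meta, haplotypes = hap_list)
}

#' Attach simulated per-call read depths to a genotype matrix
#'
#' Draws per-call total depths from a Poisson law at the individual's mean
#' (halved for hemizygous male X calls, matching the single-copy template)
#' and splits them binomially at the within-call alternate allele fraction,
#' so the QC rules have honest AD/DP fields to act on.
#'
#' @param gm A [geno_matrix()].
#' @return The matrix with `dp`, `ad_ref`, `ad_alt` filled in.
#' @export
simulate_read_depth <- function(gm) {
  pl <- ploidy_matrix(gm)
  mean_dp <- matrix(rep(gm$samples$mean_depth, each = nrow(gm$sites)),
                    nrow = nrow(gm$sites))
  lam <- mean_dp * pl / 2
  dp <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
  dp[dp < 1L] <- 1L
  alt_frac <- as.vector(gm$geno / pl)
  ad_alt <- rep(NA_integer_, length(alt_frac))
  okv <- !is.na(alt_frac)
  ad_alt[okv] <- stats::rbinom(sum(okv), as.vector(dp)[okv], alt_frac[okv])
  ad_alt <- matrix(ad_alt, nrow = nrow(dp))
  gm$dp <- dp
  gm$ad_ref <- dp - ad_alt
  gm$ad_alt <- ad_alt
  gm
}
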