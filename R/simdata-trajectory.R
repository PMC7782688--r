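#' Simulate one stochastic sweep trajectory of an X-linked male-limited allele
#'
#' Forward Wright-Fisher recursion for a single X-linked locus under
#' male-limited viability selection in an XX/XO population.  Carrier
#' (flatwing) males are silent and escape the acoustically orienting
#' parasitoid; a singing (non-carrier) male survives to adulthood with
#' relative fitness `w_normal`.  Females are unselected.  Inheritance is
#' X-linked: sons receive their single X from their mother; daughters receive
#' one X from each parent (the paternal X coming from the post-selection
#' adult male pool).
#'
#' Per generation, with `p_f` and `p_m` the carrier-allele frequencies in
#' female and male gametes:
#' \deqn{\phi = p_m w_{flat} / (p_m w_{flat} + (1-p_m)\, w_{normal})}
#' \deqn{p_f' = (X + Y)/(2N_f),\; X \sim Bin(N_f, p_f),\; Y \sim Bin(N_f, \phi)}
#' \deqn{p_m' = Z/N_m,\; Z \sim Bin(N_m, p_f)}
#' where \eqn{\phi} is also the flatwing phenotype frequency among surviving
#' adult males.  With `freq_dependent = TRUE` the carrier male fitness is
#' negatively frequency-dependent, \eqn{w_{flat} = \exp(s\,(p_{eq} - \phi_{t-1}))},
#' giving a protected polymorphism with equilibrium `p_eq` (the Oahu-like
#' balanced morph ratio); otherwise \eqn{w_{flat} = 1}.
#'
#' There is no recurrent mutation at the causal site: frequencies absorbed at
#' 0 or 1 stay absorbed.
#'
#' @param config A `sim_config` from [make_scenario()], or `NULL` to use the
#'   explicit parameters below.
#' @param deme Deme name or index selecting the causal locus parameters from
#'   `config$causal`.  Required when `config` is given.
#' @param seed Integer RNG seed.
#' @param n_generations Number of generations to iterate (default 100).
#' @param N Diploid population size (split equally into males and females).
#' @param w_normal Relative viability of singing males (carriers have 1).
#' @param p0 Initial carrier allele frequency in both sexes.
#' @param freq_dependent Use negatively frequency-dependent carrier fitness.
#' @param p_eq,fd_strength Equilibrium phenotype frequency and strength of
#'   the frequency dependence (only used when `freq_dependent`).
#' @return A data.frame of class `allele_trajectory` with columns
#'   `generation` (0 = initial state), `p_f`, `p_m` (gamete frequencies) and
#'   `male_pheno_freq` (flatwing fraction among surviving adult males).
#' @export
#' @examples
#' tr <- simulate_sweep_trajectory(N = 1000, w_normal = 0.1, p0 = 0.005,
#'                                 seed = 7, n_generations = 40)
#' tail(tr$male_pheno_freq, 1)
simulate_sweep_trajectory <- function(config = NULL, deme = NULL, seed = 1L,
                                      n_generations = 100L, N = 1000L,
                                      w_normal = 0.1, p0 = 0.005,
                                      freq_dependent = FALSE, p_eq = 0.45,
                                      fd_strength = 1.0) {
  if (!is.null(config)) {
    if (is.null(deme)) stop("deme must be given with a config")
    row <- config$causal[config$causal$deme == deme |
                           seq_len(nrow(config$causal)) == suppressWarnings(as.integer(deme)), , drop = FALSE]
    if (nrow(row) == 0L) stop("deme '", deme, "' has no causal locus")
    row <- row[1L, ]
    N <- config$deme_size
    w_normal <- row$w_normal
    p0 <- row$p0
    freq_dependent <- row$freq_dependent
    p_eq <- config$balanced_equilibrium
    fd_strength <- config$fd_strength
  }
  stopifnot(N >= 2, w_normal > 0, w_normal <= 1, p0 >= 0, p0 <= 1)
  set.seed(as.integer(seed))
  N_m <- floor(N / 2)
  N_f <- N - N_m

  p_f <- p0
  p_m <- p0
  phi_prev <- p0
  out <- matrix(NA_real_, nrow = n_generations + 1L, ncol = 3L)
  w_flat <- if (freq_dependent) exp(fd_strength * (p_eq - phi_prev)) else 1
  phi0 <- .male_pheno(p_m, w_flat, w_normal)
  out[1L, ] <- c(p_f, p_m, phi0)

  for (g in seq_len(n_generations)) {
    if ((p_f == 0 && p_m == 0) || (p_f == 1 && p_m == 1)) {
      out[g + 1L, ] <- c(p_f, p_m, if (p_f == 1) 1 else 0)
      next
    }
    w_flat <- if (freq_dependent) exp(fd_strength * (p_eq - phi_prev)) else 1
    phi <- .male_pheno(p_m, w_flat, w_normal)
    x <- stats::rbinom(1L, N_f, p_f)
    y <- stats::rbinom(1L, N_f, phi)
    z <- stats::rbinom(1L, N_m, p_f)
    p_f <- (x + y) / (2 * N_f)
    p_m <- z / N_m
    phi_prev <- phi
    out[g + 1L, ] <- c(p_f, p_m,
                       .male_pheno(p_m,
                                   if (freq_dependent) exp(fd_strength * (p_eq - phi)) else 1,
                                   w_normal))
  }
  res <- data.frame(generation = 0:n_generations,
                    p_f = out[, 1L], p_m = out[, 2L],
                    male_pheno_freq = out[, 3L])
  class(res) <- c("allele_trajectory", class(res))
  res
}

# flatwing fraction among surviving adult males
.male_pheno <- function(p_m, w_flat, w_normal) {
  num <- p_m * w_flat
  den <- num + (1 - p_m) * w_normal
  if (den == 0) return(0)
  num / den
}

#' Deterministic sweep recursion (infinite-population limit)
#'
#' The noiseless counterpart of [simulate_sweep_trajectory()]: useful as an
#' oracle for the expected sweep speed.
#'
#' @inheritParams simulate_sweep_trajectory
#' @return data.frame with `generation`, `p_f`, `p_m`, `male_pheno_freq`.
#' @export
deterministic_sweep <- function(n_generations = 100L, w_normal = 0.1,
                                p0 = 0.005) {
  p_f <- p0; p_m <- p0
  out <- matrix(NA_real_, n_generations + 1L, 3L)
  out[1L, ] <- c(p_f, p_m, .male_pheno(p_m, 1, w_normal))
  for (g in seq_len(n_generations)) {
    phi <- .male_pheno(p_m, 1, w_normal)
    p_f_new <- (p_f + phi) / 2
    p_m_new <- p_f
    p_f <- p_f_new; p_m <- p_m_new
    out[g + 1L, ] <- c(p_f, p_m, .male_pheno(p_m, 1, w_normal))
  }
  data.frame(generation = 0:n_generations, p_f = out[, 1L], p_m = out[, 2L],
             male_pheno_freq = out[, 3L])
}
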