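#' Configuration for the neutral three-population simulation
#'
#' Describes a strictly neutral Wright-Fisher history: a single ancestral
#' population of `n_anc` diploids evolves for `t_burn` generations (starting
#' with no variation), then splits into `n_demes` isolated demes of `n_deme`
#' diploids each which drift for `t_split` further generations with no
#' migration.  Chromosomes carry infinite-sites neutral mutations at rate
#' `mu` per bp per generation and crossovers at rate `rec` per bp per
#' generation.  Pool sequencing is emulated by drawing, independently at each
#' site and deme, an integer depth from a truncated normal
#' (`depth_mean`, `depth_sd`, bounds `[depth_min, depth_max]`, rounded) and
#' binomial read counts at that depth.
#'
#' The default values are the full-scale study design: 1000 ancestral
#' diploids, a 1000-generation burn-in, three demes of 1000 for 2500
#' generations, 75-Mb chromosomes, `mu = 2e-7`, `rec = 1.5e-8`, 30
#' chromosomes per pseudo-genome, pool depths ~ truncN(23, 5, [15, 50]) and a
#' global minor-allele-frequency cutoff of 0.05.  Use [scale_config()] (or
#' [desk_config()]) for rescaled desk-size runs that preserve the
#' population-scaled parameters.
#'
#' @param n_anc Diploid size of the ancestral population.
#' @param t_burn Burn-in generations before the split.
#' @param n_demes Number of demes after the split.
#' @param n_deme Diploid size of each post-split deme.
#' @param t_split Generations of isolated drift after the split.
#' @param chrom_len Chromosome length in bp.
#' @param mu Mutation rate per bp per generation.
#' @param rec Crossover rate per bp per generation.
#' @param n_chrom Chromosomes per pseudo-genome.
#' @param depth_mean,depth_sd,depth_min,depth_max Pool-depth model
#'   (chromosome copies sampled per site and pool).
#' @param maf_min Global minor-allele-frequency cutoff applied to pooled
#'   read counts.
#' @param scale Rescaling factor already applied (1 for the full design).
#' @return An object of class `sim_config` (a validated list).
#' @seealso [scale_config()], [simulate_history()], [simulate_pseudo_genome()]
#' @export
sim_config <- function(n_anc = 1000L, t_burn = 1000L, n_demes = 3L,
                       n_deme = 1000L, t_split = 2500L, chrom_len = 75e6,
                       mu = 2e-7, rec = 1.5e-8, n_chrom = 30L,
                       depth_mean = 23, depth_sd = 5, depth_min = 15L,
                       depth_max = 50L, maf_min = 0.05, scale = 1) {
  cfg <- list(
    n_anc = as.integer(n_anc), t_burn = as.integer(t_burn),
    n_demes = as.integer(n_demes), n_deme = as.integer(n_deme),
    t_split = as.integer(t_split), chrom_len = as.numeric(chrom_len),
    mu = as.numeric(mu), rec = as.numeric(rec),
    n_chrom = as.integer(n_chrom), depth_mean = as.numeric(depth_mean),
    depth_sd = as.numeric(depth_sd), depth_min = as.integer(depth_min),
    depth_max = as.integer(depth_max), maf_min = as.numeric(maf_min),
    scale = as.numeric(scale)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (any(c(n_anc, n_demes, n_deme, n_chrom) < 1L))
      stop("population and chromosome counts must be positive")
    if (t_burn < 0L || t_split < 0L) stop("generation counts must be >= 0")
    if (chrom_len < 1) stop("chrom_len must be positive")
    if (mu < 0 || rec < 0) stop("mu and rec must be non-negative")
    if (!(depth_min <= depth_mean && depth_mean <= depth_max))
      stop("depth model requires depth_min <= depth_mean <= depth_max")
    if (depth_sd <= 0) stop("depth_sd must be positive")
    if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
    if (scale < 1) stop("scale must be >= 1")
  })
  invisible(cfg)
}

#' Rescale a simulation design, preserving population-scaled parameters
#'
#' Divides population sizes and generation counts by `lam` (rounded) and
#' multiplies the per-bp mutation and recombination rates by `lam`, so that
#' `4*N*mu`, `4*N*rec` and `t/(2*N)` are unchanged.  The depth model, MAF
#' cutoff and chromosome length are untouched.  Rescaling that would push any
#' deme below 20 diploids is rejected: drift in such small demes is no longer
#' comparable to the full design.
#'
#' @param config A [sim_config()].
#' @param lam Rescaling factor, `>= 1`.
#' @return A rescaled `sim_config` with `scale` multiplied by `lam`.
#' @export
scale_config <- function(config, lam) {
  validate_sim_config(config)
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 1)
  if (lam == 1) return(config)
  n_anc <- as.integer(round(config$n_anc / lam))
  n_deme <- as.integer(round(config$n_deme / lam))
  if (min(n_anc, n_deme) < 20L)
    stop("rescaling by lam = ", lam, " drives a deme below 20 diploids")
  sim_config(
    n_anc = n_anc, t_burn = as.integer(round(config$t_burn / lam)),
    n_demes = config$n_demes, n_deme = n_deme,
    t_split = as.integer(round(config$t_split / lam)),
    chrom_len = config$chrom_len, mu = config$mu * lam,
    rec = config$rec * lam, n_chrom = config$n_chrom,
    depth_mean = config$depth_mean, depth_sd = config$depth_sd,
    depth_min = config$depth_min, depth_max = config$depth_max,
    maf_min = config$maf_min, scale = config$scale * lam
  )
}

#' Desk-scale simulation profile
#'
#' The full study design rescaled by `lam = 10` with 2-Mb chromosomes:
#' 100 ancestral diploids, 100-generation burn-in, three demes of 100 for
#' 250 generations, `mu = 2e-6`, `rec = 1.5e-7`, 30 chromosomes per
#' pseudo-genome.  Population-scaled parameters match the full design;
#' chromosome length is reduced so a pseudo-genome is desk-size.
#'
#' @param chrom_len Chromosome length in bp (default 2 Mb).
#' @param lam Rescaling factor (default 10).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
desk_config <- function(chrom_len = 2e6, lam = 10, ...) {
  scale_config(sim_config(chrom_len = chrom_len, ...), lam)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d anc diploids, %d gens burn-in; %d demes x %d for %d gens\n",
    x$n_anc, x$t_burn, x$n_demes, x$n_deme, x$t_split))
  cat(sprintf("  %d chrom x %.3g bp; mu = %.3g, rec = %.3g (scale %.3g)\n",
              x$n_chrom, x$chrom_len, x$mu, x$rec, x$scale))
  cat(sprintf("  pool depth ~ truncN(%.3g, %.3g, [%d, %d]); MAF > %.3g\n",
              x$depth_mean, x$depth_sd, x$depth_min, x$depth_max, x$maf_min))
  invisible(x)
}
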