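#' Simulate the neutral history of one chromosome
#'
#' Runs the individual-based forward Wright-Fisher model described by
#' `config` for a single chromosome: a burn-in of the ancestral deme starting
#' from no variation, a split into isolated demes, and independent drift with
#' per-generation Poisson crossovers and infinite-sites neutral mutations.
#' Returns the derived-allele frequency of every globally segregating site in
#' each deme (the "truth panel" against which pooled estimates are checked).
#'
#' @param config A [sim_config()].
#' @param chrom_seed Integer seed; all randomness of this chromosome flows
#'   from it.
#' @return A `truth_panel`: list with `positions` (strictly increasing bp),
#'   `freqs` (sites x demes matrix of derived-allele frequencies in
#'   `[0, 1]`), and `n_hap` (chromosome copies per deme).
#' @export
simulate_history <- function(config, chrom_seed) {
  validate_sim_config(config)
  set.seed(as.integer(chrom_seed))
  res <- .wf_sim_chrom(config$n_anc, config$t_burn, config$n_demes,
                       config$n_deme, config$t_split, config$chrom_len,
                       config$mu, config$rec)
  freqs <- res$counts / res$n_hap
  colnames(freqs) <- paste0("pop", seq_len(config$n_demes))
  panel <- list(positions = res$positions, freqs = freqs, n_hap = res$n_hap)
  class(panel) <- "truth_panel"
  panel
}

#' @export
print.truth_panel <- function(x, ...) {
  cat(sprintf("truth_panel: %d segregating sites, %d demes (%d copies each)\n",
              length(x$positions), ncol(x$freqs), x$n_hap))
  invisible(x)
}

#' Multi-deme FST of the truth panel in windows
#'
#' Frequency-based Weir-Cockerham FST (ratio of sums, all demes, haploid
#' sample size `n_hap`) per non-overlapping window of the true deme
#' frequencies.  Used as ground truth for estimator-recovery checks.
#'
#' @param truth A `truth_panel`.
#' @param window Window size in bp.
#' @return data.frame with `window`, `start`, `end`, `n_sites`, `fst_true`.
#' @export
truth_window_fst <- function(truth, window = 1e5) {
  stopifnot(inherits(truth, "truth_panel"))
  S <- length(truth$positions)
  depth <- matrix(truth$n_hap, S, ncol(truth$freqs))
  comp <- fst_snp(depth, truth$freqs, method = "wc")
  win <- window_index(truth$positions, window)
  num <- tapply(comp$num, win, sum)
  den <- tapply(comp$den, win, sum)
  idx <- as.integer(names(num))
  data.frame(
    window = idx, start = (idx - 1L) * as.integer(window) + 1L,
    end = idx * as.integer(window),
    n_sites = as.integer(tapply(comp$num, win, length)),
    fst_true = ifelse(den > 0, num / den, NA_real_),
    row.names = NULL
  )
}
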