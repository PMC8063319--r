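#' Median diversity and divergence by FST bin
#'
#' Splits windows into nested bins of increasing differentiation
#' (`fst > threshold`, strict inequality) and reports, per bin and for the
#' genome-wide set, the median of each requested value column together with
#' its percent decrease relative to the genome-wide median:
#' `100 * (1 - bin median / genome-wide median)`.
#'
#' @param windows A window data.frame (e.g. [fst_windows()] merged with
#'   [diversity_windows()]).
#' @param fst_col Name of the FST column defining the bins.
#' @param value_cols Character vector of columns to summarize (e.g. pi and
#'   dxy columns).
#' @param thresholds Bin thresholds (default 0.2, 0.3, 0.4, 0.5).
#' @return data.frame with one row per bin plus a `genome-wide` row: `bin`,
#'   `threshold`, `n_windows`, `median_<col>` and `pct_decrease_<col>`
#'   columns.  Empty bins report `NA` medians.
#' @export
bin_summary <- function(windows, fst_col, value_cols,
                        thresholds = c(0.2, 0.3, 0.4, 0.5)) {
  stopifnot(fst_col %in% names(windows), all(value_cols %in% names(windows)))
  fst <- windows[[fst_col]]
  sets <- c(lapply(thresholds, function(th) which(!is.na(fst) & fst > th)),
            list(which(!is.na(fst))))
  labels <- c(sprintf("fst > %g", thresholds), "genome-wide")
  out <- data.frame(bin = labels,
                    threshold = c(thresholds, NA_real_),
                    n_windows = vapply(sets, length, 1L))
  gw <- vapply(value_cols, function(cl)
    stats::median(windows[[cl]][sets[[length(sets)]]], na.rm = TRUE), 1)
  for (cl in value_cols) {
    med <- vapply(sets, function(ix)
      if (length(ix)) stats::median(windows[[cl]][ix], na.rm = TRUE)
      else NA_real_, 1)
    out[[paste0("median_", cl)]] <- med
    out[[paste0("pct_decrease_", cl)]] <- pct_decrease(med, gw[[cl]])
  }
  out
}

#' Percent decrease relative to a genome-wide value
#'
#' `100 * (1 - value / genome_wide)`.
#'
#' @param value Bin value(s).
#' @param genome_wide Genome-wide reference value.
#' @return Numeric percent decrease (negative for increases).
#' @export
pct_decrease <- function(value, genome_wide) {
  100 * (1 - value / genome_wide)
}

#' Genome-level FST summary and top-window table
#'
#' The genome-wide FST is the unweighted mean of the defined window
#' estimates.  The top table ranks the highest `top_fraction` of windows
#' (`k = round(valid * top_fraction)`, at least 1), ties broken by
#' (FST descending, chrom, start).
#'
#' @param windows A window data.frame from [fst_windows()].
#' @param fst_col FST column to summarize.
#' @param top_fraction Fraction of valid windows to rank (default 0.001).
#' @return List with `mean_fst`, `n_valid`, `k`, and `top` (the ranked
#'   top-window rows).
#' @export
genome_summary <- function(windows, fst_col, top_fraction = 0.001) {
  stopifnot(fst_col %in% names(windows))
  fst <- windows[[fst_col]]
  valid <- which(!is.na(fst))
  if (!length(valid)) stop("no window has a defined FST estimate")
  k <- max(1L, as.integer(round(length(valid) * top_fraction)))
  ord <- valid[order(-fst[valid], windows$chrom[valid], windows$start[valid])]
  list(mean_fst = mean(fst[valid]), n_valid = length(valid), k = k,
       top = windows[ord[seq_len(k)], , drop = FALSE])
}
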