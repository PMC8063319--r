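#' Build the population kinship matrix F from a SNP table
#'
#' Pairwise Reynolds coancestry distances are computed as
#' `D = -ln(1 - theta)` with `theta` the two-pool Weir-Cockerham estimate
#' pooled over all SNPs (ratio of sums).  For three populations the rooted
#' tree follows from the three-point formulas
#' (`x_A = (d_AB + d_AO - d_BO) / 2`, etc.), with the root placed at the
#' internal node joining the outgroup.  Because the rooted 3-taxon topology
#' is a star about that node, no pair of populations shares drift and the
#' kinship matrix `F` is the diagonal of root-to-tip branch lengths.
#'
#' @param snps A `snp_table` with exactly three pools and at least 100 SNPs.
#' @param outgroup Name of the outgroup pool (roots the tree).
#' @return An object of class `kinship_model`: list with `pops` (tested
#'   order), `outgroup`, `D` (pairwise Reynolds distances), `branch`
#'   (root-to-tip lengths) and `F` (diagonal kinship matrix over `pops`).
#' @export
build_kinship <- function(snps, outgroup) {
  stopifnot(inherits(snps, "snp_table"))
  pools <- snps$pools
  if (length(pools) != 3L)
    stop("kinship construction requires exactly 3 populations")
  if (!outgroup %in% pools) stop("unknown outgroup: ", outgroup)
  if (length(snps$pos) < 100L)
    stop("kinship construction requires >= 100 SNPs")
  D <- matrix(0, 3L, 3L, dimnames = list(pools, pools))
  for (pair in all_pairs(pools)) {
    comp <- fst_snp(snps$depth[, pair, drop = FALSE],
                    snps$freq[, pair, drop = FALSE], method = "wc")
    theta <- sum(comp$num) / sum(comp$den)
    if (!is.finite(theta) || theta >= 1)
      stop("pairwise theta is degenerate; cannot form Reynolds distances")
    D[pair[1], pair[2]] <- D[pair[2], pair[1]] <- -log(1 - theta)
  }
  kinship_from_distances(D, outgroup)
}

#' Kinship model from a pairwise distance matrix
#'
#' Solves the rooted 3-taxon tree by the three-point formulas
#' (`x_A = (d_AB + d_AO - d_BO) / 2` and permutations), roots it at the
#' internal node joining the outgroup, and forms the diagonal kinship matrix
#' of root-to-tip branch lengths.
#'
#' @param D Symmetric 3x3 matrix of Reynolds distances with population
#'   names as dimnames.
#' @param outgroup Name of the outgroup population.
#' @return A `kinship_model` (see [build_kinship()]).
#' @export
kinship_from_distances <- function(D, outgroup) {
  stopifnot(is.matrix(D), nrow(D) == 3L, ncol(D) == 3L,
            !is.null(rownames(D)), isTRUE(all.equal(D, t(D))),
            all(diag(D) == 0))
  pools <- rownames(D)
  if (!outgroup %in% pools) stop("unknown outgroup: ", outgroup)
  others <- setdiff(pools, outgroup)
  a <- others[1]; b <- others[2]; o <- outgroup
  branch <- c(
    (D[a, b] + D[a, o] - D[b, o]) / 2,
    (D[a, b] + D[b, o] - D[a, o]) / 2,
    (D[a, o] + D[b, o] - D[a, b]) / 2
  )
  names(branch) <- c(a, b, o)
  branch <- branch[pools]
  if (any(branch <= 0))
    stop("a root-to-tip branch is not positive, so F is not invertible; ",
         "use more SNPs or check the population labels")
  F <- diag(branch)
  dimnames(F) <- list(pools, pools)
  model <- list(pops = pools, outgroup = outgroup, D = D, branch = branch,
                F = F)
  class(model) <- "kinship_model"
  model
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("kinship_model (outgroup:", x$outgroup, ")\n")
  cat("  root-to-tip branch lengths:\n")
  print(round(x$branch, 4))
  invisible(x)
}
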