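SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Construct a sync table of pooled allele counts
#'
#' The in-memory form of the PoPoolation2-style "sync" format: one row per
#' genomic site with, for each pool, six non-negative integer counts in the
#' fixed order A:T:C:G:N:del.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference bases.
#' @param counts Integer array of dimension `sites x pools x 6`, third
#'   dimension ordered A, T, C, G, N, del.
#' @param pools Pool names (default `pool1..poolK`).
#' @return An object of class `sync_table`.
#' @export
sync_table <- function(chrom, pos, ref, counts, pools = NULL) {
  S <- length(pos)
  stopifnot(length(chrom) == S, length(ref) == S,
            length(dim(counts)) == 3L, dim(counts)[1] == S,
            dim(counts)[3] == 6L)
  if (any(pos < 1L)) stop("positions must be >= 1")
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (is.null(pools)) pools <- paste0("pool", seq_len(dim(counts)[2]))
  if (dim(counts)[2] > 0L) dimnames(counts) <- list(NULL, pools, SYNC_BASES)
  x <- list(chrom = as.character(chrom), pos = as.integer(pos),
            ref = as.character(ref), counts = counts, pools = pools)
  class(x) <- "sync_table"
  x
}

#' @export
print.sync_table <- function(x, ...) {
  cat(sprintf("sync_table: %d sites, %d pools (%s), %d chromosome(s)\n",
              length(x$pos), length(x$pools),
              paste(x$pools, collapse = ", "), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites in a sync table
#' @param x A `sync_table`.
#' @return Integer site count.
#' @export
n_sites <- function(x) {
  stopifnot(inherits(x, "sync_table"))
  length(x$pos)
}

#' Subset the sites of a sync table
#' @param x A `sync_table`.
#' @param i Logical or integer site index.
#' @param ... Unused.
#' @return A `sync_table` with the selected sites.
#' @export
`[.sync_table` <- function(x, i, ...) {
  sync_table(x$chrom[i], x$pos[i], x$ref[i],
             x$counts[i, , , drop = FALSE], pools = x$pools)
}

sync_is_sorted <- function(x) {
  o <- order(x$chrom, x$pos)
  identical(o, seq_along(x$pos))
}

#' Read a sync file of pooled allele counts
#'
#' Streaming parse of the tab-separated sync dialect: chromosome, 1-based
#' position, reference base, then one "A:T:C:G:N:del" column per pool.
#' Malformed lines (wrong column arity, non-integer or missing counts) raise
#' an error naming the offending line.
#'
#' @param path Path to a sync file (no header).
#' @param pools Optional pool names; defaults to `pool1..poolK`.
#' @return A [sync_table()].  An empty file yields an empty table with zero
#'   pools unless `pools` is given.
#' @export
read_sync <- function(path, pools = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- suppressWarnings(
    data.table::fread(path, sep = "\t", header = FALSE,
                      colClasses = "character", fill = TRUE))
  if (nrow(dt) == 0L) {
    np <- if (is.null(pools)) 0L else length(pools)
    return(sync_table(character(0), integer(0), character(0),
                      array(integer(0), c(0L, np, 6L)), pools = pools))
  }
  if (ncol(dt) < 4L)
    stop("sync file needs >= 4 tab-separated columns, found ", ncol(dt))
  npool <- ncol(dt) - 3L
  if (is.null(pools)) pools <- paste0("pool", seq_len(npool))
  stopifnot(length(pools) == npool)
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  if (anyNA(pos)) stop("non-integer position at line ", which(is.na(pos))[1])
  S <- nrow(dt)
  counts <- array(NA_integer_, c(S, npool, 6L))
  for (j in seq_len(npool)) {
    parts <- data.table::tstrsplit(dt[[3L + j]], ":", fixed = TRUE)
    if (length(parts) != 6L) {
      bad <- which(!grepl("^\\d+:\\d+:\\d+:\\d+:\\d+:\\d+$", dt[[3L + j]]))[1]
      stop("pool column ", j, " is not 6 colon-separated integers at line ",
           bad)
    }
    for (b in 1:6) {
      v <- suppressWarnings(as.integer(parts[[b]]))
      if (anyNA(v))
        stop("pool column ", j, " is not 6 colon-separated integers at line ",
             which(is.na(v))[1])
      counts[, j, b] <- v
    }
  }
  sync_table(dt[[1L]], pos, dt[[3L]], counts, pools = pools)
}

#' Write a sync table to disk
#'
#' Inverse of [read_sync()]: tab-separated, no header, per-pool counts as
#' "A:T:C:G:N:del".  Sites must be sorted by (chrom, pos); an empty table
#' writes an empty file.
#'
#' @param x A [sync_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync_table"))
  if (length(x$pos) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!sync_is_sorted(x)) stop("sync records must be sorted by (chrom, pos)")
  cols <- lapply(seq_along(x$pools), function(j) {
    do.call(paste, c(lapply(1:6, function(b) x$counts[, j, b]), sep = ":"))
  })
  dt <- data.table::as.data.table(c(list(x$chrom, x$pos, x$ref), cols))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
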