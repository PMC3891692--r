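#' Filter fragment records: proper pairs, mapping quality, duplicates
#'
#' A pair is kept iff it mapped as a proper pair AND at least one of its two
#' reads reached mapping quality 10 (only pairs in which *neither* read
#' reaches the cut are removed). Among pairs with identical
#' `(chrom, start, end, sample_id)` exactly one survives. Survivors are
#' returned sorted by sample and coordinate, so the operation is
#' deterministic and idempotent.
#'
#' @param records Fragment data.frame with columns `chrom`, `start`, `end`,
#'   `mapq1`, `mapq2`, `proper`, `sample_id`.
#' @param min_mapq Pair-level quality cut (default 10).
#' @return List: `fragments` (the survivors) and `tallies` (named counts:
#'   `n_input`, `n_improper`, `n_low_mapq`, `n_duplicate`, `n_kept`).
#' @export
filter_fragments <- function(records, min_mapq = 10) {
  need <- c("chrom", "start", "end", "mapq1", "mapq2", "proper", "sample_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing fragment columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(records$start < records$end) |
                 records$mapq1 < 0 | records$mapq2 < 0)
  if (length(bad)) stop("malformed fragment record(s) at index ",
                        paste(utils::head(bad, 5), collapse = ", "))
  n_input <- nrow(records)
  keep <- records$proper
  n_improper <- sum(!keep)
  df <- records[keep, , drop = FALSE]

  ok <- pmax(df$mapq1, df$mapq2) >= min_mapq
  n_low <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  df <- df[order(df$sample_id, df$chrom, df$start, df$end), , drop = FALSE]
  dup <- duplicated(df[c("sample_id", "chrom", "start", "end")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  list(fragments = df,
       tallies = c(n_input = n_input, n_improper = n_improper,
                   n_low_mapq = n_low, n_duplicate = n_dup,
                   n_kept = nrow(df)))
}

#' CpG enrichment score of a fragment set
#'
#' Ratio of the mean CpG count per fragment-covered base pair to the mean
#' CpG count per base pair genome-wide. A methylation-agnostic (input-like)
#' sample scores about 1; MeDIP pull-down scores above 1.
#'
#' @param frags Fragment data.frame (one sample).
#' @param genome A `GenomeModel`.
#' @return A positive scalar.
#' @export
enrichment_score <- function(frags, genome) {
  if (nrow(frags) == 0) stop("enrichment_score: empty fragment list")
  obs_cpg <- 0
  for (chr in unique(frags$chrom)) {
    f <- frags[frags$chrom == chr, , drop = FALSE]
    p <- genome$cpg[[chr]]
    if (is.null(p)) stop("unknown chromosome: ", chr)
    obs_cpg <- obs_cpg + sum(findInterval(f$end - 1, p) -
                               findInterval(f$start - 1, p))
  }
  obs <- obs_cpg / sum(frags$end - frags$start)
  expd <- n_cpg(genome) / sum(genome$chrom_sizes)
  obs / expd
}

#' Fraction of genome CpGs covered by fragments, with a fold histogram
#'
#' @param frags Fragment data.frame (one sample).
#' @param genome A `GenomeModel`.
#' @return List: `fraction` (CpGs overlapped by >= 1 fragment) and
#'   `histogram` (named vector; proportion of CpGs at fold 0, 1, 2, ...;
#'   sums to 1).
#' @export
cpg_coverage <- function(frags, genome) {
  folds <- integer(0)
  for (chr in names(genome$cpg)) {
    p <- genome$cpg[[chr]]
    if (!length(p)) next
    f <- frags[frags$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0) { folds <- c(folds, integer(length(p))); next }
    s <- sort(f$start); e <- sort(f$end)
    folds <- c(folds, findInterval(p, s) - findInterval(p, e))
  }
  tab <- tabulate(folds + 1L, nbins = max(folds) + 1L)
  hist <- tab / length(folds)
  names(hist) <- as.character(seq_along(hist) - 1L)
  list(fraction = mean(folds >= 1), histogram = hist)
}

## Fragment-midpoint counts over sliding windows (width `window`, stepped
## by `step`); returns one row per window with counts for each sample.
window_midpoint_counts <- function(frag_list, genome, window = 500,
                                   step = 250) {
  stopifnot(window %% step == 0)
  k <- window %/% step
  out <- list()
  for (chr in names(genome$chrom_sizes)) {
    ncell <- ceiling(genome$chrom_sizes[[chr]] / step)
    if (ncell < k) next
    cellcounts <- vapply(frag_list, function(f) {
      ff <- f[f$chrom == chr, , drop = FALSE]
      mid <- (ff$start + ff$end) %/% 2
      tabulate(mid %/% step + 1L, nbins = ncell)
    }, integer(ncell))
    cellcounts <- matrix(cellcounts, nrow = ncell)
    nwin <- ncell - k + 1
    wins <- vapply(seq_len(ncol(cellcounts)), function(j) {
      cs <- c(0, cumsum(cellcounts[, j]))
      cs[(k + 1):(nwin + k)] - cs[1:nwin]
    }, numeric(nwin))
    out[[chr]] <- matrix(wins, nrow = nwin)
  }
  do.call(rbind, out)
}

#' Between-replicate correlation of windowed fragment counts
#'
#' Fragment counts (midpoint rule) in 500 bp windows advanced in 250 bp
#' steps; windows with fewer than `min_reads` fragments are excluded before
#' computing the Pearson correlation. `min_reads_mode` decides whether the
#' threshold applies to the summed count of the pair (default) or to each
#' sample separately.
#'
#' @param frags_a,frags_b Filtered fragment data.frames.
#' @param genome A `GenomeModel`.
#' @param window,step Window geometry in bp.
#' @param min_reads Minimum fragments for a window to enter the correlation.
#' @param min_reads_mode `"sum"` or `"each"`.
#' @return Pearson r, or NA if fewer than 2 windows qualify.
#' @export
replicate_correlation <- function(frags_a, frags_b, genome, window = 500,
                                  step = 250, min_reads = 5,
                                  min_reads_mode = c("sum", "each")) {
  min_reads_mode <- match.arg(min_reads_mode)
  extra <- setdiff(unique(c(frags_a$chrom, frags_b$chrom)),
                   names(genome$chrom_sizes))
  if (length(extra)) stop("samples mention chromosomes absent from genome: ",
                          paste(extra, collapse = ", "))
  counts <- window_midpoint_counts(list(frags_a, frags_b), genome,
                                   window, step)
  keep <- if (min_reads_mode == "sum") rowSums(counts) >= min_reads
    else counts[, 1] >= min_reads & counts[, 2] >= min_reads
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < 2) return(NA_real_)
  if (stats::sd(counts[, 1]) == 0 || stats::sd(counts[, 2]) == 0)
    return(NA_real_)
  stats::cor(counts[, 1], counts[, 2])
}

#' Quality-control report for a set of samples
#'
#' Applies [filter_fragments()] per sample and computes the CpG enrichment
#' score, CpG coverage fraction and all pairwise replicate correlations.
#'
#' @param frag_list Named list of raw fragment data.frames.
#' @param genome A `GenomeModel`.
#' @param ... Passed to [replicate_correlation()].
#' @return A `QCReport` list: `per_sample` data.frame (`sample_id`,
#'   `n_input`, `n_improper`, `n_low_mapq`, `n_duplicate`, `n_kept`,
#'   `enrichment_score`, `cpg_coverage`), `correlations` (symmetric matrix
#'   with unit diagonal) and `filtered` (list of filtered fragments).
#' @export
qc_report <- function(frag_list, genome, ...) {
  stopifnot(length(frag_list) >= 1, !is.null(names(frag_list)))
  filtered <- list(); rows <- list()
  for (id in names(frag_list)) {
    fl <- filter_fragments(frag_list[[id]])
    filtered[[id]] <- fl$fragments
    t <- fl$tallies
    rows[[id]] <- data.frame(
      sample_id = id, n_input = t[["n_input"]],
      n_improper = t[["n_improper"]], n_low_mapq = t[["n_low_mapq"]],
      n_duplicate = t[["n_duplicate"]], n_kept = t[["n_kept"]],
      enrichment_score = enrichment_score(fl$fragments, genome),
      cpg_coverage = cpg_coverage(fl$fragments, genome)$fraction,
      stringsAsFactors = FALSE)
  }
  ids <- names(frag_list)
  cors <- diag(1, length(ids))
  dimnames(cors) <- list(ids, ids)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      r <- replicate_correlation(filtered[[i]], filtered[[j]], genome, ...)
      cors[i, j] <- cors[j, i] <- r
    }
  }
  structure(list(per_sample = do.call(rbind, c(rows,
                                               make.row.names = FALSE)),
                 correlations = cors, filtered = filtered),
            class = "QCReport")
}
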