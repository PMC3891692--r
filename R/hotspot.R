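#' Count regions in fixed genomic windows and locate the maximum
#'
#' Chromosomes are tiled with non-overlapping `window_size` windows anchored
#' at position 0; each region is assigned to the window containing its
#' midpoint (half-open convention: a midpoint at exactly `window_size` falls
#' in the second window). Ties for the maximum are broken by chromosome
#' order then start; a tie is flagged.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genome A `GenomeModel`.
#' @param window_size Window width in bp (default 100000).
#' @return List: `per_window` (data.frame `chrom`, `start`, `count` for
#'   nonempty windows), `max_count`, `max_window` (list `chrom`, `start`),
#'   `tie` (logical).
#' @export
window_counts <- function(regions, genome, window_size = 100000) {
  if (window_size <= 0) stop("window_size must be positive")
  chroms <- names(genome$chrom_sizes)
  mid <- (regions$start + regions$end) %/% 2
  win <- mid %/% window_size
  key <- paste0(regions$chrom, ":", win)
  tab <- table(key)
  if (length(tab) == 0)
    return(list(per_window = data.frame(chrom = character(),
                                        start = numeric(), count = integer()),
                max_count = 0L, max_window = NULL, tie = FALSE))
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                   start = as.numeric(vapply(parts, `[`, character(1), 2)) *
                     window_size,
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, chroms), df$start), ]
  rownames(df) <- NULL
  mx <- max(df$count)
  hit <- which(df$count == mx)
  list(per_window = df, max_count = mx,
       max_window = list(chrom = df$chrom[hit[1]], start = df$start[hit[1]]),
       tie = length(hit) > 1)
}

#' Permutation test for a DMR hotspot
#'
#' The observed statistic is the maximum number of DMRs falling in any
#' `window_size` window ([window_counts()]). Each permutation draws
#' `nrow(dmrs)` regions from the bump-list uniformly without replacement
#' and recomputes the maximum window count; the empirical p-value is
#' `(1 + #{null max >= observed max}) / (n_permutations + 1)` (so p = 0 is
#' impossible; with `strict_greater = TRUE` the exceedance rule is
#' `>` instead of `>=`).
#'
#' @param dmrs data.frame of observed DMRs (`chrom`, `start`, `end`).
#' @param bumps A `BumpList` (or a data.frame of background regions).
#' @param genome A `GenomeModel`.
#' @param n_permutations Number of null draws (default 1000).
#' @param window_size Window width in bp.
#' @param seed Integer seed for the permutation stream.
#' @param strict_greater Use strictly-greater exceedances.
#' @return A `PermutationSummary`: list with `window_size`,
#'   `observed_max_count`, `observed_window`, `null_max_counts`
#'   (length `n_permutations`), `n_permutations`, `empirical_p`.
#' @export
hotspot_permutation <- function(dmrs, bumps, genome, n_permutations = 1000,
                                window_size = 100000, seed = 1,
                                strict_greater = FALSE) {
  regions <- if (inherits(bumps, "BumpList")) bumps$regions else bumps
  n_dmr <- nrow(dmrs)
  if (nrow(regions) < n_dmr)
    stop("bump-list smaller than the DMR list")
  if (n_dmr == 0) stop("no DMRs to test")
  obs <- window_counts(dmrs, genome, window_size)

  ## compact window id per bump region midpoint
  chroms <- names(genome$chrom_sizes)
  mid <- (regions$start + regions$end) %/% 2
  wid <- (match(regions$chrom, chroms) - 1) *
    (max(ceiling(genome$chrom_sizes / window_size)) + 1) +
    mid %/% window_size
  wid <- match(wid, sort(unique(wid)))
  nw <- max(wid)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(nrow(regions), n_dmr)
      max(tabulate(wid[idx], nbins = nw))
    }, numeric(1))
  })
  k <- if (strict_greater) sum(null_max > obs$max_count)
    else sum(null_max >= obs$max_count)
  structure(list(window_size = window_size,
                 observed_max_count = obs$max_count,
                 observed_window = obs$max_window,
                 null_max_counts = as.integer(null_max),
                 n_permutations = n_permutations,
                 empirical_p = (1 + k) / (n_permutations + 1)),
            class = "PermutationSummary")
}

#' @export
print.PermutationSummary <- function(x, ...) {
  cat(sprintf("Hotspot permutation: observed max %d DMRs in a %g kb window (%s:%g); empirical p = %.4g (%d permutations)\n",
              x$observed_max_count, x$window_size / 1000,
              x$observed_window$chrom, x$observed_window$start,
              x$empirical_p, x$n_permutations))
  invisible(x)
}
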