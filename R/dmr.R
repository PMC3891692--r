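#' Build the candidate-region "bump-list"
#'
#' Adjacent 50 bp bins with a nonzero fragment count summed over all samples
#' of the two compared groups are merged into maximal runs; runs carrying at
#' least `min_total_reads` fragments become candidate regions for DMR
#' testing. Per-sample counts are attached.
#'
#' @param tracks Named list of `MethylomeTrack`s (both groups; other groups
#'   present in the list are ignored).
#' @param genome A `GenomeModel`.
#' @param group_a,group_b The compared groups.
#' @param min_total_reads Minimum summed count for bump-list membership
#'   (default 10).
#' @return A `BumpList`: list with `regions` (data.frame `chrom`, `start`,
#'   `end`, `n_bins`, `total`), `counts` (region x sample matrix),
#'   `samples`, `groups` (per-sample labels) and `bin_size`.
#' @export
build_bump_list <- function(tracks, genome, group_a = "Young",
                            group_b = "Old", min_total_reads = 10) {
  grp <- track_groups(tracks)
  use <- tracks[grp %in% c(group_a, group_b)]
  stopifnot(length(use) >= 2)
  bs <- vapply(use, `[[`, numeric(1), "bin_size")
  if (length(unique(bs)) != 1) stop("tracks are on different bin grids")
  bin_size <- bs[[1]]

  rows <- list(); cnts <- list()
  for (chr in names(genome$chrom_sizes)) {
    m <- vapply(use, function(t) t$counts[[chr]],
                numeric(length(use[[1]]$counts[[chr]])))
    m <- matrix(m, ncol = length(use))
    tot <- rowSums(m)
    r <- rle(tot > 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values)
    for (k in runs) {
      b0 <- starts[k]; b1 <- ends[k]
      region_counts <- colSums(m[b0:b1, , drop = FALSE])
      if (sum(region_counts) < min_total_reads) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = (b0 - 1) * bin_size,
        end = min(b1 * bin_size, genome$chrom_sizes[[chr]]),
        n_bins = b1 - b0 + 1, total = sum(region_counts),
        stringsAsFactors = FALSE)
      cnts[[length(cnts) + 1]] <- region_counts
    }
  }
  regions <- if (length(rows))
    do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  n_bins = integer(), total = numeric())
  counts <- if (length(cnts)) do.call(rbind, cnts)
    else matrix(numeric(0), 0, length(use))
  colnames(counts) <- names(use)
  structure(list(regions = regions, counts = counts,
                 samples = names(use),
                 groups = stats::setNames(track_groups(use), names(use)),
                 group_a = group_a, group_b = group_b, bin_size = bin_size),
            class = "BumpList")
}

#' @export
print.BumpList <- function(x, ...) {
  cat("BumpList:", nrow(x$regions), "candidate regions,",
      length(x$samples), "samples (", x$group_a, "vs", x$group_b, ")\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over regions of the ratio
#' of its count to the across-sample geometric mean of that region's counts,
#' restricted to regions with all-positive counts; factors are rescaled to
#' have product 1. When no all-positive region exists the function falls
#' back to total-count ratios (with a message).
#'
#' @param counts Region x sample count matrix.
#' @return Named numeric vector of positive size factors (product 1).
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    m <- counts[pos, , drop = FALSE]
    loggeo <- rowMeans(log(m))
    sf <- apply(m, 2, function(col) exp(stats::median(log(col) - loggeo)))
  } else {
    message("no region with all-positive counts; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))  # geometric-mean centring: product 1
  stats::setNames(sf, colnames(counts))
}

#' Dispersion trend in the "fit-only" sharing mode
#'
#' Per-region method-of-moments dispersions (pooled within the two groups,
#' shot noise on the common scale subtracted) are regressed on the region
#' mean with the parametric trend `alpha = a0 + a1 / mean`; every region is
#' then assigned the *fitted* value only, floored at `1e-8`. This mirrors
#' dispersion sharing in which individual per-region estimates are replaced
#' by the fitted trend.
#'
#' @param counts Region x sample count matrix.
#' @param size_factors Per-sample size factors.
#' @param groups Per-sample group labels (two levels).
#' @return List: `alpha` (fitted per-region dispersion), `coef`
#'   (`a0`, `a1`), `raw` (per-region moment estimates, NA where undefined).
#' @export
estimate_dispersions <- function(counts, size_factors, groups) {
  stopifnot(ncol(counts) == length(size_factors),
            ncol(counts) == length(groups))
  norm <- sweep(counts, 2, size_factors, `/`)
  glev <- unique(groups)
  q <- rowMeans(norm)
  ## pooled within-group variance of normalised counts
  ss <- 0; df <- 0
  for (g in glev) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    gm <- rowMeans(norm[, cols, drop = FALSE])
    ss <- ss + rowSums((norm[, cols, drop = FALSE] - gm)^2)
    df <- df + length(cols) - 1
  }
  if (df == 0) {
    ## no replication: no variance information, fall back to shot noise only
    alpha <- rep(1e-8, nrow(counts))
    return(list(alpha = alpha, coef = c(a0 = 1e-8, a1 = 0),
                raw = rep(NA_real_, nrow(counts))))
  }
  v <- ss / df
  xi <- mean(1 / size_factors)
  raw <- (v - q * xi) / q^2
  raw[!is.finite(raw)] <- NA

  use <- is.finite(raw) & q > 0
  if (sum(use) >= 2 && stats::sd(1 / q[use]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / q[use]), raw[use])
    a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
    if (!is.finite(a0) || !is.finite(a1)) { a0 <- mean(raw[use]); a1 <- 0 }
  } else {
    a0 <- if (any(use)) mean(raw[use]) else 0
    a1 <- 0
  }
  alpha <- pmax(a0 + a1 / q, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  list(alpha = alpha, coef = c(a0 = unname(a0), a1 = unname(a1)), raw = raw)
}

#' Conditioned negative binomial test for one candidate region
#'
#' Counts are modelled as negative binomial with per-sample means
#' proportional to the size factors and variance `mu + alpha * mu^2`.
#' Conditional on the observed total, the two-sided p-value sums the
#' probabilities of all allocations of the total between the two groups
#' that are no more likely than the observed one. The log2 fold change is
#' computed from the normalised group means with a pseudocount of 0.5.
#'
#' @param counts_a,counts_b Raw counts per sample in group A (reference)
#'   and group B.
#' @param sf_a,sf_b Size factors of the same samples.
#' @param alpha Dispersion for this region.
#' @return List: `p_value`, `log2fc` (B over A), `mean_a`, `mean_b`
#'   (normalised group means).
#' @export
test_region <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  if (!is.finite(alpha) || alpha < 0) stop("nonfinite dispersion")
  ka <- sum(counts_a); kb <- sum(counts_b)
  SA <- sum(sf_a); SB <- sum(sf_b)
  ktot <- ka + kb
  mean_a <- mean(counts_a / sf_a); mean_b <- mean(counts_b / sf_b)
  lfc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  if (ktot == 0) return(list(p_value = 1, log2fc = 0,
                             mean_a = mean_a, mean_b = mean_b))
  q <- ktot / (SA + SB)
  a <- 0:ktot
  pa <- .nb_sum_pmf(a, q * SA, q^2 * alpha * sum(sf_a^2) + q * SA)
  pb <- .nb_sum_pmf(ktot - a, q * SB, q^2 * alpha * sum(sf_b^2) + q * SB)
  pr <- pa * pb
  denom <- sum(pr)
  if (denom <= 0) return(list(p_value = 1, log2fc = lfc,
                              mean_a = mean_a, mean_b = mean_b))
  pobs <- pr[ka + 1]
  p <- sum(pr[pr <= pobs * (1 + 1e-7)]) / denom
  list(p_value = min(p, 1), log2fc = lfc, mean_a = mean_a, mean_b = mean_b)
}

## pmf of a group-sum with mean mu and variance var: negative binomial via
## size = mu^2 / (var - mu), collapsing to Poisson as var -> mu.
.nb_sum_pmf <- function(x, mu, var) {
  if (mu <= 0) return(as.numeric(x == 0))
  if (var <= mu * (1 + 1e-12)) return(stats::dpois(x, mu))
  size <- mu^2 / (var - mu)
  stats::dnbinom(x, mu = mu, size = size)
}

#' Test every bump-list region and call DMRs at an FDR threshold
#'
#' Runs [estimate_size_factors()], [estimate_dispersions()] and
#' [test_region()] over the bump-list, applies Benjamini-Hochberg FDR
#' control across all tested regions, and returns the records passing
#' `fdr_threshold` with their direction (with respect to group B, the older
#' group). A region-by-sample methylation matrix over *all* provided tracks
#' (including groups outside the comparison, e.g. a Mid group), row-scaled
#' to `[0, 1]`, is attached for heatmap display of progressive change.
#'
#' @param bumps A `BumpList`.
#' @param tracks The full named track list (for the heatmap matrix); may
#'   include more groups than the tested pair.
#' @param fdr_threshold FDR cut for calling (default 0.2).
#' @return A `DMRResult`: list with `table` (all tested regions: coords,
#'   per-group normalised means, `log2fc`, `p_value`, `fdr`, `direction`,
#'   `significant`), `dmrs` (the significant subset), `size_factors`,
#'   `dispersion` and `heatmap` (row-scaled matrix for the DMRs).
#' @export
call_dmrs <- function(bumps, tracks = NULL, fdr_threshold = 0.2) {
  stopifnot(inherits(bumps, "BumpList"))
  if (nrow(bumps$regions) == 0) stop("empty bump-list")
  groups <- bumps$groups
  a_cols <- which(groups == bumps$group_a)
  b_cols <- which(groups == bumps$group_b)
  sf <- estimate_size_factors(bumps$counts)
  disp <- estimate_dispersions(bumps$counts, sf, groups)

  res <- vapply(seq_len(nrow(bumps$regions)), function(i) {
    r <- test_region(bumps$counts[i, a_cols], bumps$counts[i, b_cols],
                     sf[a_cols], sf[b_cols], disp$alpha[i])
    c(r$p_value, r$log2fc, r$mean_a, r$mean_b)
  }, numeric(4))

  tab <- bumps$regions
  tab$mean_a <- res[3, ]; tab$mean_b <- res[4, ]
  tab$log2fc <- res[2, ]; tab$p_value <- res[1, ]
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  tab$direction <- ifelse(tab$log2fc > 0, "hyper", "hypo")
  tab$significant <- tab$fdr < fdr_threshold
  tab$region_id <- seq_len(nrow(tab))

  dmrs <- tab[tab$significant, , drop = FALSE]
  heat <- NULL
  if (!is.null(tracks) && nrow(dmrs) > 0) {
    score <- track_matrix(tracks, "score")
    bt_n <- n_bins_from_tracks(tracks)
    offset <- c(0, cumsum(bt_n))[seq_along(bt_n)]
    names(offset) <- names(bt_n)
    bin_size <- tracks[[1]]$bin_size
    heat <- t(vapply(seq_len(nrow(dmrs)), function(i) {
      b0 <- dmrs$start[i] %/% bin_size
      b1 <- (dmrs$end[i] - 1) %/% bin_size
      rows <- offset[[dmrs$chrom[i]]] + seq.int(b0, b1) + 1L
      colMeans(score[rows, , drop = FALSE])
    }, numeric(ncol(score))))
    rng <- apply(heat, 1, function(x) diff(range(x)))
    heat <- (heat - apply(heat, 1, min)) / ifelse(rng > 0, rng, 1)
    rownames(heat) <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end)
  }
  structure(list(table = tab, dmrs = dmrs, size_factors = sf,
                 dispersion = disp, heatmap = heat,
                 fdr_threshold = fdr_threshold,
                 group_a = bumps$group_a, group_b = bumps$group_b),
            class = "DMRResult")
}

n_bins_from_tracks <- function(tracks) lengths(tracks[[1]]$counts)

#' @export
print.DMRResult <- function(x, ...) {
  cat(sprintf("DMRResult (%s vs %s): %d regions tested, %d DMRs at FDR < %g (%d hyper / %d hypo)\n",
              x$group_b, x$group_a, nrow(x$table), nrow(x$dmrs),
              x$fdr_threshold, sum(x$dmrs$direction == "hyper"),
              sum(x$dmrs$direction == "hypo")))
  invisible(x)
}

#' Associate DMRs with nearby genes
#'
#' A gene is associated with a DMR iff the minimum distance between the two
#' intervals is at most `cutoff` bp (0 when they overlap; the boundary is
#' inclusive). All qualifying genes are listed nearest-first, ties broken
#' by gene id.
#'
#' @param dmrs data.frame of DMRs (`chrom`, `start`, `end`).
#' @param features A `FeatureSet` with `gene` rows.
#' @param cutoff Maximum association distance in bp (default 100000).
#' @return List: `dmrs` (the input plus `genes` and `gene_distances`
#'   comma-separated columns) and `fraction_associated`.
#' @export
associate_genes <- function(dmrs, features, cutoff = 100000) {
  genes <- features[features$class == "gene", , drop = FALSE]
  dmrs <- as.data.frame(dmrs)
  dmrs$genes <- ""; dmrs$gene_distances <- ""
  if (nrow(dmrs) == 0 || nrow(genes) == 0)
    return(list(dmrs = dmrs,
                fraction_associated = if (nrow(dmrs)) 0 else NA_real_))
  gr_d <- df_granges(dmrs)
  gr_g <- df_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_d, gr_g, maxgap = cutoff)
  if (length(hits)) {
    d <- GenomicRanges::distance(gr_d[S4Vectors::queryHits(hits)],
                                 gr_g[S4Vectors::subjectHits(hits)])
    keep <- d <= cutoff
    qh <- S4Vectors::queryHits(hits)[keep]
    sh <- S4Vectors::subjectHits(hits)[keep]
    d <- d[keep]
    for (i in unique(qh)) {
      sel <- qh == i
      ord <- order(d[sel], genes$name[sh[sel]])
      dmrs$genes[i] <- paste(genes$name[sh[sel]][ord], collapse = ",")
      dmrs$gene_distances[i] <- paste(d[sel][ord], collapse = ",")
    }
  }
  list(dmrs = dmrs, fraction_associated = mean(dmrs$genes != ""))
}
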