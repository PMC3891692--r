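## Two-sample KS comparison used by the group comparisons: two-sided,
## asymptotic p, exact when both pools are small.
ks_compare <- function(x, y) {
  exact <- length(x) < 50 && length(y) < 50
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

five_num <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Genome-wide methylation comparison between two age groups
#'
#' Restricted to bins that contain at least one CpG and carry at least one
#' fragment in every compared sample (the commonly covered fraction of the
#' methylome), computes per-group means of the normalised scores, a
#' two-sample Kolmogorov-Smirnov test between the group-pooled score
#' distributions, the percent change of group B relative to group A, and
#' per-group five-number summaries for box plots.
#'
#' @param tracks Named list of `MethylomeTrack`s (all on one bin grid).
#' @param genome A `GenomeModel`.
#' @param group_a Reference group (e.g. `"Young"`).
#' @param group_b Comparison group (e.g. `"Old"`).
#' @param bin_cpg Optional precomputed [bin_cpg_counts()] list.
#' @return A `GlobalComparison` list: `group_a`, `group_b`, `n_bins`,
#'   `mean_a`, `mean_b`, `percent_change`
#'   (`100 * (mean_b - mean_a) / mean_a`), `ks_statistic`, `ks_p`,
#'   `summary_a`, `summary_b`.
#' @export
global_comparison <- function(tracks, genome, group_a = "Young",
                              group_b = "Old", bin_cpg = NULL) {
  grp <- track_groups(tracks)
  ta <- tracks[grp == group_a]; tb <- tracks[grp == group_b]
  stopifnot(length(ta) >= 1, length(tb) >= 1)
  both <- c(ta, tb)
  if (is.null(bin_cpg))
    bin_cpg <- bin_cpg_counts(genome, both[[1]]$bin_size)
  cpg_ok <- unlist(bin_cpg, use.names = FALSE) >= 1
  counts <- track_matrix(both, "counts")
  covered <- rowSums(counts >= 1) == ncol(counts)
  keep <- cpg_ok & covered
  if (!any(keep)) stop("no commonly covered CpG-containing bins")

  sa <- track_matrix(ta, "score")[keep, , drop = FALSE]
  sb <- track_matrix(tb, "score")[keep, , drop = FALSE]
  pa <- as.vector(sa); pb <- as.vector(sb)
  ks <- ks_compare(pa, pb)
  mean_a <- mean(pa); mean_b <- mean(pb)
  structure(list(group_a = group_a, group_b = group_b,
                 n_bins = sum(keep), mean_a = mean_a, mean_b = mean_b,
                 percent_change = 100 * (mean_b - mean_a) / mean_a,
                 ks_statistic = ks$statistic, ks_p = ks$p_value,
                 summary_a = five_num(pa), summary_b = five_num(pb)),
            class = "GlobalComparison")
}

#' @export
print.GlobalComparison <- function(x, ...) {
  cat(sprintf("%s vs %s over %d bins: mean %.4g -> %.4g (%+.2f%%), KS D = %.4f, p = %.3g\n",
              x$group_b, x$group_a, x$n_bins, x$mean_a, x$mean_b,
              x$percent_change, x$ks_statistic, x$ks_p))
  invisible(x)
}

#' CpG-island-level methylation comparison between two age groups
#'
#' For every CGI and sample, the CGI score is the mean normalised score
#' over the island's bins. Islands with at least one fragment in every
#' compared sample enter a group comparison of the same form as
#' [global_comparison()].
#'
#' @param tracks Named list of `MethylomeTrack`s.
#' @param features A `FeatureSet` containing `CGI` rows.
#' @param genome A `GenomeModel`.
#' @param group_a,group_b Group labels.
#' @return A `GlobalComparison`-shaped list with an extra `n_cgis` element
#'   and `per_cgi` matrix (CGI x sample scores), or NULL (with a warning)
#'   when the annotation has no CGIs.
#' @export
cgi_comparison <- function(tracks, features, genome, group_a = "Young",
                           group_b = "Old") {
  cgis <- features[features$class == "CGI", , drop = FALSE]
  if (nrow(cgis) == 0) {
    warning("no CGIs in annotation; CGI comparison is empty")
    return(NULL)
  }
  grp <- track_groups(tracks)
  ta <- tracks[grp == group_a]; tb <- tracks[grp == group_b]
  stopifnot(length(ta) >= 1, length(tb) >= 1)
  both <- c(ta, tb)
  bin_size <- both[[1]]$bin_size
  nb <- n_bins(genome, bin_size)
  offset <- c(0, cumsum(nb))[seq_along(nb)]
  names(offset) <- names(nb)

  rows <- lapply(seq_len(nrow(cgis)), function(k) {
    b0 <- cgis$start[k] %/% bin_size
    b1 <- (cgis$end[k] - 1) %/% bin_size
    offset[[cgis$chrom[k]]] + seq.int(b0, b1) + 1L
  })
  score <- track_matrix(both, "score")
  counts <- track_matrix(both, "counts")
  per_cgi <- t(vapply(rows, function(r)
    colMeans(score[r, , drop = FALSE]), numeric(ncol(score))))
  cgi_cov <- t(vapply(rows, function(r)
    colSums(counts[r, , drop = FALSE]), numeric(ncol(counts))))
  keep <- rowSums(cgi_cov >= 1) == ncol(cgi_cov)
  per_cgi <- matrix(per_cgi[keep, , drop = FALSE], ncol = ncol(score),
                    dimnames = list(cgis$name[keep], colnames(score)))
  if (nrow(per_cgi) == 0) stop("no CGIs covered in all compared samples")

  a_cols <- seq_len(length(ta)); b_cols <- length(ta) + seq_len(length(tb))
  pa <- as.vector(per_cgi[, a_cols, drop = FALSE])
  pb <- as.vector(per_cgi[, b_cols, drop = FALSE])
  ks <- ks_compare(pa, pb)
  mean_a <- mean(pa); mean_b <- mean(pb)
  structure(list(group_a = group_a, group_b = group_b,
                 n_cgis = nrow(per_cgi), n_bins = nrow(per_cgi),
                 mean_a = mean_a, mean_b = mean_b,
                 percent_change = 100 * (mean_b - mean_a) / mean_a,
                 ks_statistic = ks$statistic, ks_p = ks$p_value,
                 summary_a = five_num(pa), summary_b = five_num(pb),
                 per_cgi = per_cgi),
            class = "GlobalComparison")
}
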