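#' Genomic-feature enrichment of DMRs against the bump-list background
#'
#' For each direction (hyper, hypo) and feature class (CGI, shore, exon,
#' intron, intergenic), builds the 2x2 table of DMRs versus non-DMR
#' bump-list regions, in versus out of the feature class (a region "is in"
#' a class iff it overlaps at least 1 bp of it; a region may hit several
#' classes), and applies a one-sided (enrichment) Fisher's exact test.
#' Rows are sorted by p-value within direction.
#'
#' @param dmr_table DMR data.frame carrying `chrom`, `start`, `end`,
#'   `direction` (and optionally `region_id` linking back to the bump-list).
#' @param bumps A `BumpList` (the background universe).
#' @param features A `FeatureSet`.
#' @return data.frame of `FeatureEnrichmentRow`s: `direction`, `feature`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
feature_enrichment <- function(dmr_table, bumps, features) {
  regions <- bumps$regions
  gr_bump <- df_granges(regions)

  in_class <- sapply(CLOSURE_CLASSES, function(cl) {
    fr <- features[features$class == cl, , drop = FALSE]
    if (nrow(fr) == 0) return(rep(FALSE, nrow(regions)))
    IRanges::overlapsAny(gr_bump, df_granges(fr))
  })
  in_class <- matrix(in_class, nrow = nrow(regions),
                     dimnames = list(NULL, CLOSURE_CLASSES))

  ## map DMRs onto bump rows (by region_id when present, else coordinates)
  if ("region_id" %in% names(dmr_table)) {
    idx <- dmr_table$region_id
  } else {
    key <- paste(regions$chrom, regions$start, regions$end)
    idx <- match(paste(dmr_table$chrom, dmr_table$start, dmr_table$end), key)
  }
  if (anyNA(idx)) stop("every DMR must be a member of the bump-list universe")

  out <- list()
  for (dir in c("hyper", "hypo")) {
    is_dmr <- rep(FALSE, nrow(regions))
    is_dmr[idx[dmr_table$direction == dir]] <- TRUE
    for (cl in CLOSURE_CLASSES) {
      a <- sum(is_dmr & in_class[, cl])
      b <- sum(is_dmr & !in_class[, cl])
      cc <- sum(!is_dmr & in_class[, cl])
      d <- sum(!is_dmr & !in_class[, cl])
      if (a + b == 0) {
        orat <- NA_real_; p <- 1
      } else {
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                                 alternative = "greater")
        orat <- unname(ft$estimate); p <- ft$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        direction = dir, feature = cl, a = a, b = b, c = cc, d = d,
        odds_ratio = orat, p_value = p, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(out, make.row.names = FALSE))
  df <- df[order(df$direction, df$p_value), ]
  rownames(df) <- NULL
  df
}
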