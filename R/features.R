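#' Feature annotation sets
#'
#' A `FeatureSet` is a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open), `class` and `name`. Recognised classes are
#' `CGI`, `shore`, `exon`, `intron`, `intergenic` and `gene` (gene bodies,
#' used only for DMR-to-gene association; exon/intron partition them).
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `FeatureSet` prepended.
#' @export
feature_set <- function(df) {
  need <- c("chrom", "start", "end", "class", "name")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[need]
  stopifnot(all(df$end > df$start))
  df <- df[order(match(df$class, FEATURE_CLASSES), df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("FeatureSet", "data.frame")
  df
}

## Annotation classes used for base-level closure (gene bodies excluded:
## exon + intron cover them).
FEATURE_CLASSES <- c("CGI", "shore", "exon", "intron", "intergenic", "gene")
CLOSURE_CLASSES <- c("CGI", "shore", "exon", "intron", "intergenic")

## FeatureSet rows of one class as a GRanges (1-based internally to
## GenomicRanges; converted back on the way out).
features_granges <- function(features, classes = NULL) {
  df <- features
  if (!is.null(classes)) df <- df[df$class %in% classes, , drop = FALSE]
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end),
                         name = df$name, class = df$class)
}

df_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Derive CpG island shores from CGI intervals
#'
#' Shores extend `width` bp (default 2000) up- and downstream of each CGI,
#' clipped at chromosome ends and subtracting any CGI bases (their own or a
#' neighbouring island's).
#'
#' @param cgis data.frame of CGI intervals (`chrom`, `start`, `end`).
#' @param genome A `GenomeModel` (for chromosome bounds).
#' @param width Shore width in bp on each side.
#' @return data.frame of shore intervals with `chrom`, `start`, `end`.
#' @export
cgi_shores <- function(cgis, genome, width = 2000) {
  if (nrow(cgis) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (chr in unique(cgis$chrom)) {
    cc <- cgis[cgis$chrom == chr, , drop = FALSE]
    L <- genome$chrom_sizes[[chr]]
    cand <- IRanges::IRanges(
      start = pmax(0, c(cc$start - width, cc$end)) + 1,
      end = pmin(L, c(cc$start, cc$end + width)))
    cand <- cand[IRanges::width(cand) > 0]
    isl <- IRanges::IRanges(start = cc$start + 1, end = cc$end)
    sh <- IRanges::setdiff(IRanges::reduce(cand), IRanges::reduce(isl))
    if (length(sh))
      out[[chr]] <- data.frame(chrom = chr,
                               start = IRanges::start(sh) - 1,
                               end = IRanges::end(sh),
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write / read a feature set as BED with a feature-class column
#'
#' Four columns: chrom, start, end, name; the fifth column holds the feature
#' class. Round-trips losslessly.
#'
#' @param features A `FeatureSet`.
#' @param path Output path.
#' @return `path` invisibly (`write_features`); a `FeatureSet`
#'   (`read_features`).
#' @export
write_features <- function(features, path) {
  df <- data.frame(chrom = features$chrom,
                   start = format(features$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(features$end, scientific = FALSE, trim = TRUE),
                   name = features$name, class = features$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "class"),
                          stringsAsFactors = FALSE)
  feature_set(df[c("chrom", "start", "end", "class", "name")])
}

#' Check that the annotation covers every base of the genome
#'
#' Every base of every chromosome must belong to at least one of CGI, shore,
#' exon, intron or intergenic.
#'
#' @param features A `FeatureSet`.
#' @param genome A `GenomeModel`.
#' @return TRUE if closed; otherwise the number of uncovered bases, as an
#'   attribute of FALSE.
#' @export
annotation_closed <- function(features, genome) {
  uncovered <- 0
  for (chr in names(genome$chrom_sizes)) {
    df <- features[features$chrom == chr &
                     features$class %in% CLOSURE_CLASSES, , drop = FALSE]
    cov <- IRanges::reduce(IRanges::IRanges(start = df$start + 1,
                                            end = df$end))
    uncovered <- uncovered + genome$chrom_sizes[[chr]] - sum(IRanges::width(cov))
  }
  if (uncovered == 0) TRUE else structure(FALSE, uncovered = uncovered)
}
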