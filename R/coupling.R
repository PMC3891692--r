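#' Build the CpG coupling vector
#'
#' For every `bin_size` bin of every chromosome, the coupling factor is the
#' number of CpG positions within `coupling_distance` bp of the bin centre.
#' This is the local CpG density used to normalise MeDIP read counts.
#'
#' @param genome A `GenomeModel`.
#' @param bin_size Bin width in bp (default 50).
#' @param coupling_distance Neighbourhood half-width in bp (default 700,
#'   the fragment-length scale of the capture).
#' @return A `CouplingVector`: list with `bin_size`, `coupling_distance`
#'   and `factors[[chrom]]` integer vectors.
#' @export
build_coupling <- function(genome, bin_size = 50, coupling_distance = 700) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (coupling_distance < 0) stop("coupling_distance must be >= 0")
  nb <- n_bins(genome, bin_size)
  factors <- lapply(names(nb), function(chr) {
    centers <- (seq_len(nb[[chr]]) - 1) * bin_size + bin_size / 2
    p <- genome$cpg[[chr]]
    ## CpGs p with |p - center| <= d  <=>  ceil(center-d) <= p <= floor(center+d)
    as.integer(findInterval(floor(centers + coupling_distance), p) -
                 findInterval(ceiling(centers - coupling_distance) - 1, p))
  })
  names(factors) <- names(nb)
  structure(list(bin_size = bin_size, coupling_distance = coupling_distance,
                 factors = factors),
            class = "CouplingVector")
}

#' Coupling-normalised methylation track for one sample
#'
#' Raw count per bin is the number of fragments whose midpoint lies in the
#' bin (fragments are used as given, not extended). The normalised score is
#' counts-per-million divided by the coupling factor, floored at
#' `coupling_floor` so zero-CpG bins are flagged rather than inflated:
#' `score = (count / (library_size / 1e6)) / max(coupling, coupling_floor)`.
#' With `normalize = "raw"` the track carries the raw counts as scores.
#'
#' @param frags Filtered fragment data.frame for one sample.
#' @param coupling A `CouplingVector` for the same genome.
#' @param genome A `GenomeModel`.
#' @param sample_id,group Labels stored on the track.
#' @param coupling_floor Lower bound of the coupling divisor (default 1).
#' @param normalize `"coupling"` (default) or `"raw"`.
#' @return A `MethylomeTrack`: list with `sample_id`, `group`, `bin_size`,
#'   `library_size`, `counts[[chrom]]`, `score[[chrom]]` and
#'   `has_cpg[[chrom]]` (coupling factor > 0).
#' @export
methylation_track <- function(frags, coupling, genome,
                              sample_id = frags$sample_id[1],
                              group = NA_character_, coupling_floor = 1,
                              normalize = c("coupling", "raw")) {
  normalize <- match.arg(normalize)
  if (nrow(frags) == 0) stop("methylation_track: empty sample")
  bin_size <- coupling$bin_size
  nb <- n_bins(genome, bin_size)
  counts <- lapply(names(nb), function(chr) {
    f <- frags[frags$chrom == chr, , drop = FALSE]
    mid <- (f$start + f$end) %/% 2
    tabulate(mid %/% bin_size + 1L, nbins = nb[[chr]])
  })
  names(counts) <- names(nb)
  lib <- sum(vapply(counts, sum, numeric(1)))
  score <- lapply(names(nb), function(chr) {
    if (normalize == "raw") return(as.numeric(counts[[chr]]))
    cf <- pmax(coupling$factors[[chr]], coupling_floor)
    (counts[[chr]] / (lib / 1e6)) / cf
  })
  names(score) <- names(nb)
  has_cpg <- lapply(coupling$factors, function(f) f > 0)
  structure(list(sample_id = sample_id, group = group, bin_size = bin_size,
                 library_size = lib, counts = counts, score = score,
                 has_cpg = has_cpg),
            class = "MethylomeTrack")
}

#' Build tracks for a whole sample sheet
#'
#' @param frag_list Named list of filtered fragment data.frames.
#' @param samples Sample sheet with `sample_id` and `group`.
#' @param coupling A `CouplingVector`.
#' @param genome A `GenomeModel`.
#' @param ... Passed to [methylation_track()].
#' @return Named list of `MethylomeTrack`s.
#' @export
methylation_tracks <- function(frag_list, samples, coupling, genome, ...) {
  out <- lapply(samples$sample_id, function(id)
    methylation_track(frag_list[[id]], coupling, genome, sample_id = id,
                      group = samples$group[match(id, samples$sample_id)],
                      ...))
  stats::setNames(out, samples$sample_id)
}

## Assemble per-bin matrices (bins x samples) from a list of tracks.
track_matrix <- function(tracks, what = c("counts", "score")) {
  what <- match.arg(what)
  stopifnot(length(tracks) >= 1)
  m <- vapply(tracks, function(t) unlist(t[[what]], use.names = FALSE),
              numeric(sum(lengths(tracks[[1]]$counts))))
  matrix(m, ncol = length(tracks),
         dimnames = list(NULL, vapply(tracks, `[[`, character(1),
                                      "sample_id")))
}

track_groups <- function(tracks)
  vapply(tracks, `[[`, character(1), "group")

#' Write a track (or coupling vector) as bedGraph
#'
#' @param x A `MethylomeTrack` or `CouplingVector`.
#' @param genome A `GenomeModel`.
#' @param path Output path.
#' @param what For tracks: `"score"` or `"counts"`.
#' @return `path` invisibly.
#' @export
write_bedgraph <- function(x, genome, path, what = "score") {
  vals <- if (inherits(x, "CouplingVector")) x$factors else x[[what]]
  bt <- bin_table(genome, x$bin_size)
  v <- unlist(vals, use.names = FALSE)
  df <- data.frame(chrom = bt$chrom,
                   start = format(bt$start, scientific = FALSE, trim = TRUE),
                   end = format(bt$end, scientific = FALSE, trim = TRUE),
                   value = v)
  df <- df[v != 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
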