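#' Genome model: chromosome sizes plus sorted CpG positions
#'
#' The coordinate frame for the whole pipeline. All coordinates are 0-based,
#' half-open; a CpG position is the offset of the C of a CG dinucleotide.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param cpg Named list (same names) of sorted integer CpG positions.
#' @return An object of class `GenomeModel`.
#' @export
genome_model <- function(chrom_sizes, cpg) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), is.list(cpg),
            setequal(names(cpg), names(chrom_sizes)))
  cpg <- cpg[names(chrom_sizes)]
  for (chr in names(chrom_sizes)) {
    p <- as.integer(cpg[[chr]])
    if (is.unsorted(p)) p <- sort(p)
    if (length(p) && (p[1] < 0 || p[length(p)] >= chrom_sizes[[chr]]))
      stop("CpG position outside chromosome ", chr)
    cpg[[chr]] <- p
  }
  structure(list(chrom_sizes = stats::setNames(as.numeric(chrom_sizes),
                                               names(chrom_sizes)),
                 cpg = cpg),
            class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes), big.mark = ","), "bp,",
      format(sum(lengths(x$cpg)), big.mark = ","), "CpGs\n")
  invisible(x)
}

#' Total number of CpGs in a genome model
#' @param genome A `GenomeModel`.
#' @return Integer count.
#' @export
n_cpg <- function(genome) sum(lengths(genome$cpg))

#' Build a genome model from a FASTA file
#'
#' Chromosome sizes are taken from the sequences and CpG positions from all
#' `CG` dinucleotide matches (position of the C, 0-based).
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A `GenomeModel`.
#' @export
genome_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("genome_from_fasta() requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sizes <- stats::setNames(Biostrings::width(seqs), names(seqs))
  hits <- Biostrings::vmatchPattern("CG", seqs)
  cpg <- lapply(seq_along(seqs), function(i)
    as.integer(Biostrings::start(hits[[i]])) - 1L)
  names(cpg) <- names(seqs)
  genome_model(sizes, cpg)
}

#' Write / read a genome model as plain text
#'
#' Two files: `<prefix>.chrom.sizes` (chrom, size) and `<prefix>.cpg.bed`
#' (chrom, start, end) with one row per CpG.
#'
#' @param genome A `GenomeModel`.
#' @param prefix File path prefix.
#' @return The prefix, invisibly (`write_genome`); a `GenomeModel`
#'   (`read_genome`).
#' @export
write_genome <- function(genome, prefix) {
  sizes <- data.frame(chrom = names(genome$chrom_sizes),
                      size = genome$chrom_sizes)
  utils::write.table(sizes, paste0(prefix, ".chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cpg <- do.call(rbind, lapply(names(genome$cpg), function(chr) {
    p <- genome$cpg[[chr]]
    if (!length(p)) return(NULL)
    data.frame(chrom = chr, start = p, end = p + 2L)
  }))
  utils::write.table(cpg, paste0(prefix, ".cpg.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_genome
#' @export
read_genome <- function(prefix) {
  sizes <- utils::read.table(paste0(prefix, ".chrom.sizes"), sep = "\t",
                             col.names = c("chrom", "size"),
                             stringsAsFactors = FALSE)
  cpg_df <- utils::read.table(paste0(prefix, ".cpg.bed"), sep = "\t",
                              col.names = c("chrom", "start", "end"),
                              stringsAsFactors = FALSE)
  cpg <- lapply(stats::setNames(sizes$chrom, sizes$chrom), function(chr)
    sort(cpg_df$start[cpg_df$chrom == chr]))
  genome_model(stats::setNames(sizes$size, sizes$chrom), cpg)
}

## Number of CpGs of `genome` inside [start, end) on `chrom`.
genome_cpg_count <- function(genome, chrom, start, end) {
  p <- genome$cpg[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  count_in_interval(p, start, end)
}

## Bin grid helpers -----------------------------------------------------

n_bins <- function(genome, bin_size) {
  ceiling(genome$chrom_sizes / bin_size)
}

## Flat table of all bins across chromosomes, in chromosome order.
bin_table <- function(genome, bin_size) {
  nb <- n_bins(genome, bin_size)
  chrom <- rep(names(nb), nb)
  idx <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- idx * bin_size
  end <- pmin(start + bin_size, rep(unname(genome$chrom_sizes), nb))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Per-bin CpG content
#'
#' Counts the CpGs lying inside each `bin_size` bin (not the coupling
#' neighbourhood; see [build_coupling()] for that).
#'
#' @param genome A `GenomeModel`.
#' @param bin_size Bin width in bp (default 50).
#' @return Named list of integer vectors, one per chromosome.
#' @export
bin_cpg_counts <- function(genome, bin_size = 50) {
  nb <- n_bins(genome, bin_size)
  out <- lapply(names(nb), function(chr) {
    p <- genome$cpg[[chr]]
    counts <- integer(nb[[chr]])
    if (length(p)) {
      tab <- tabulate(p %/% bin_size + 1L, nbins = nb[[chr]])
      counts <- as.integer(tab)
    }
    counts
  })
  stats::setNames(out, names(nb))
}
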