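#' Simulate a small genome and its feature annotation
#'
#' Draws CpG positions at `cgi_cpg_rate` inside CpG islands and
#' `background_cpg_rate` elsewhere, places genes with exon/intron structure,
#' and derives island shores (`+/-2000` bp, clipped at chromosome ends and
#' island boundaries). Every base of the genome is covered by at least one
#' of CGI, shore, exon, intron or intergenic.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements `genome` (a `GenomeModel`) and `features`
#'   (a `FeatureSet`).
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, "genome"), {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms)

    per_chrom <- diff(floor(seq(0, cfg$cgi_count, length.out =
                                  cfg$n_chromosomes + 1)))
    cgi <- list(); gene <- list(); exon <- list(); intron <- list()
    cpg <- list()
    gi <- 0
    for (ci in seq_along(chroms)) {
      chr <- chroms[ci]
      L <- sizes[[chr]]

      ## CpG islands in evenly spaced slots with random jitter
      nc <- per_chrom[ci]
      if (nc > 0) {
        slot <- L / nc
        len <- pmax(500, round(rnorm(nc, cfg$cgi_mean_length,
                                     cfg$cgi_mean_length / 4)))
        len <- pmin(len, floor(slot * 0.5))
        start <- floor((seq_len(nc) - 1) * slot +
                         runif(nc, 0.05, 0.9) * (slot - len))
        cgi[[chr]] <- data.frame(chrom = chr, start = start,
                                 end = start + len,
                                 name = paste0("CGI_", chr, "_", seq_len(nc)),
                                 stringsAsFactors = FALSE)
      }

      ## CpG positions: background rate, elevated inside islands
      rate <- rep(cfg$background_cpg_rate, L)
      if (nc > 0) {
        for (k in seq_len(nc)) {
          s <- cgi[[chr]]$start[k]; e <- cgi[[chr]]$end[k]
          rate[(s + 1):e] <- cfg$cgi_cpg_rate
        }
      }
      cpg[[chr]] <- which(runif(L) < rate) - 1L

      ## genes with exon/intron structure, in their own slots
      ng <- cfg$genes_per_chromosome
      if (ng > 0) {
        slot <- L / ng
        glen <- round(runif(ng, 5000, min(15000, slot * 0.8)))
        gstart <- floor((seq_len(ng) - 1) * slot +
                          runif(ng, 0, slot - glen - 1))
        for (k in seq_len(ng)) {
          gi <- gi + 1
          gname <- sprintf("gene_%03d", gi)
          gs <- gstart[k]; ge <- gs + glen[k]
          ne <- cfg$exons_per_gene
          elen <- round(runif(ne, 150, 300))
          ## exon starts spread over the gene; first exon at the 5' end
          anchors <- floor(seq(gs, ge - max(elen), length.out = ne))
          es <- anchors; ee <- pmin(anchors + elen, ge)
          ee[ne] <- ge  # genes end with an exon: exon+intron tile the body
          gene[[gname]] <- data.frame(chrom = chr, start = gs, end = ge,
                                      name = gname, stringsAsFactors = FALSE)
          exon[[gname]] <- data.frame(chrom = chr, start = es, end = ee,
                                      name = paste0(gname, "_exon",
                                                    seq_len(ne)),
                                      stringsAsFactors = FALSE)
          if (ne > 1) {
            is <- ee[-ne]; ie <- es[-1]
            keep <- ie > is
            if (any(keep))
              intron[[gname]] <- data.frame(chrom = chr, start = is[keep],
                                            end = ie[keep],
                                            name = paste0(gname, "_intron",
                                                          seq_len(sum(keep))),
                                            stringsAsFactors = FALSE)
          }
        }
      }
    }

    genome <- genome_model(sizes, cpg)
    cgi_df <- if (length(cgi)) do.call(rbind, c(cgi, make.row.names = FALSE))
      else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character())
    shores <- cgi_shores(cgi_df, genome, width = 2000)
    rows <- list()
    if (nrow(cgi_df))
      rows$cgi <- data.frame(cgi_df[c("chrom", "start", "end")],
                             class = "CGI", name = cgi_df$name)
    if (nrow(shores))
      rows$shore <- data.frame(shores, class = "shore",
                               name = paste0("shore_", seq_len(nrow(shores))))
    bind <- function(lst) if (length(lst))
      do.call(rbind, c(lst, make.row.names = FALSE)) else NULL
    gdf <- bind(gene); edf <- bind(exon); idf <- bind(intron)
    if (!is.null(gdf))
      rows$gene <- data.frame(gdf[c("chrom", "start", "end")],
                              class = "gene", name = gdf$name)
    if (!is.null(edf))
      rows$exon <- data.frame(edf[c("chrom", "start", "end")],
                              class = "exon", name = edf$name)
    if (!is.null(idf))
      rows$intron <- data.frame(idf[c("chrom", "start", "end")],
                                class = "intron", name = idf$name)

    ## intergenic = complement of CGI, shore and gene bodies
    inter <- list()
    for (chr in chroms) {
      take <- function(df) if (!is.null(df) && nrow(df)) {
        d <- df[df$chrom == chr, , drop = FALSE]
        IRanges::IRanges(start = d$start + 1, end = d$end)
      } else IRanges::IRanges()
      occ <- IRanges::reduce(c(take(cgi_df), take(shores), take(gdf)))
      gaps <- IRanges::setdiff(IRanges::IRanges(1, sizes[[chr]]), occ)
      if (length(gaps))
        inter[[chr]] <- data.frame(chrom = chr,
                                   start = IRanges::start(gaps) - 1,
                                   end = IRanges::end(gaps),
                                   class = "intergenic",
                                   name = paste0("intergenic_", chr, "_",
                                                 seq_along(gaps)),
                                   stringsAsFactors = FALSE)
    }
    rows$intergenic <- bind(inter)
    features <- feature_set(do.call(rbind, c(rows, make.row.names = FALSE)))
    list(genome = genome, features = features)
  })
}
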