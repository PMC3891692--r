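#' Simulate aligned MeDIP (or input-control) fragments for one sample
#'
#' Fragment midpoints are drawn per 50 bp bin with probability proportional
#' to `(local CpG count)^pulldown_exponent * latent methylation`, where the
#' local count is taken over `pulldown_window` bp around the bin centre;
#' input-control samples are drawn uniformly. Lengths are normal, truncated
#' to `[50, 2 * fragment_length_mean]`. A configured fraction of pairs is
#' improper, low-quality (both reads mapq < 10) or an exact duplicate.
#' Reproducible: the RNG stream is derived from `(cfg$seed, sample_id)`.
#'
#' @param genome A `GenomeModel`.
#' @param surface A `MethylationSurface` (ignored when `input = TRUE`).
#' @param cfg A [sim_config()].
#' @param sample_id Sample identifier (also keys the RNG stream).
#' @param group Group label whose surface to sample from.
#' @param input If TRUE, draw uniformly (input control).
#' @return data.frame of fragment records: `chrom`, `start`, `end`,
#'   `mapq1`, `mapq2`, `proper`, `sample_id`, `pair_id`, sorted by
#'   coordinate.
#' @export
simulate_fragments <- function(genome, surface, cfg, sample_id,
                               group = NULL, input = FALSE) {
  bin_size <- if (input) 50 else surface$bin_size
  nb <- n_bins(genome, bin_size)
  chroms <- names(nb)

  if (input) {
    w <- lapply(chroms, function(chr) rep(1, nb[[chr]]))
  } else {
    stopifnot(inherits(surface, "MethylationSurface"),
              group %in% surface$groups)
    half <- cfg$pulldown_window / 2
    w <- lapply(chroms, function(chr) {
      centers <- (seq_len(nb[[chr]]) - 1) * bin_size + bin_size / 2
      p <- genome$cpg[[chr]]
      cnt <- findInterval(floor(centers + half), p) -
        findInterval(ceiling(centers - half) - 1, p)
      cnt^cfg$pulldown_exponent * surface$levels[[group]][[chr]]
    })
  }
  names(w) <- chroms
  if (all(unlist(w, use.names = FALSE) == 0))
    stop("methylation surface has no sampleable mass")

  bt <- bin_table(genome, bin_size)
  chrom_of_bin <- bt$chrom
  start_of_bin <- bt$start
  size_of <- genome$chrom_sizes

  with_seed(derive_seed(cfg$seed, sample_id), {
    ## biological replicate noise: log-normal capture-efficiency blocks
    if (!input && cfg$replicate_noise_sd > 0) {
      for (chr in chroms) {
        blk <- ((seq_along(w[[chr]]) - 1) * bin_size) %/% cfg$noise_block + 1
        mult <- exp(rnorm(max(blk), 0, cfg$replicate_noise_sd))
        w[[chr]] <- w[[chr]] * mult[blk]
      }
    }
    w_all <- unlist(w, use.names = FALSE)
    n <- cfg$fragments_per_replicate
    n_dup <- floor(cfg$duplicate_rate * n)
    n_base <- n - n_dup

    bins <- sample.int(length(w_all), n_base, replace = TRUE, prob = w_all)
    mid <- start_of_bin[bins] + floor(runif(n_base) * bin_size)
    len <- round(rnorm_trunc(n_base, cfg$fragment_length_mean,
                             cfg$fragment_length_sd, 50,
                             2 * cfg$fragment_length_mean))
    chrom <- chrom_of_bin[bins]
    start <- pmax(0, mid - len %/% 2)
    end <- pmin(unname(size_of[chrom]), start + len)
    start <- pmax(0, pmin(start, end - 1))

    ## mapping qualities: mostly comfortably above the q >= 10 cut; a
    ## configured fraction of pairs has BOTH reads below 10
    mapq1 <- round(runif(n_base, 20, 60))
    mapq2 <- round(runif(n_base, 20, 60))
    fail <- runif(n_base) < cfg$mapq_fail_rate
    mapq1[fail] <- round(runif(sum(fail), 0, 9))
    mapq2[fail] <- round(runif(sum(fail), 0, 9))
    proper <- runif(n_base) >= cfg$improper_rate

    df <- data.frame(chrom = chrom, start = start, end = end,
                     mapq1 = as.integer(mapq1), mapq2 = as.integer(mapq2),
                     proper = proper, sample_id = sample_id,
                     stringsAsFactors = FALSE)
    if (n_dup > 0) {
      dup <- df[sample.int(n_base, n_dup, replace = TRUE), , drop = FALSE]
      df <- rbind(df, dup)
    }
    df$pair_id <- sprintf("p%07d", seq_len(nrow(df)))
    df <- df[order(df$chrom, df$start, df$end, df$pair_id), ]
    rownames(df) <- NULL
    df
  })
}

#' Simulate a complete study: genome, annotation, truth, surface, fragments
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `features`, `truth`, `surface`, `samples`
#'   (the sample sheet) and `fragments` (named list of per-sample fragment
#'   data.frames, input controls included when configured).
#' @export
simulate_dataset <- function(cfg) {
  gf <- simulate_genome(cfg)
  truth <- make_ground_truth(gf$genome, gf$features, cfg)
  surface <- simulate_methylome(gf$genome, gf$features, truth, cfg)
  samples <- sim_sample_sheet(cfg)
  fragments <- lapply(seq_len(nrow(samples)), function(i)
    simulate_fragments(gf$genome, surface, cfg,
                       sample_id = samples$sample_id[i],
                       group = samples$group[i],
                       input = samples$group[i] == "Input"))
  names(fragments) <- samples$sample_id
  list(genome = gf$genome, features = gf$features, truth = truth,
       surface = surface, samples = samples, fragments = fragments)
}

#' Write / read fragment records as BED
#'
#' BED6+2 dialect: chrom, start, end, name (`sample:pairid`), score
#' (minimum mapq of the pair), strand (`+` proper pair, `.` otherwise),
#' then the two per-read mapping qualities so the pair-level quality rule
#' survives a round-trip.
#'
#' @param frags Fragment data.frame (see [simulate_fragments()]).
#' @param path Output path.
#' @return `path` invisibly; `read_fragments_bed` returns the data.frame.
#' @export
write_fragments_bed <- function(frags, path) {
  pair_id <- if ("pair_id" %in% names(frags)) frags$pair_id
    else sprintf("p%07d", seq_len(nrow(frags)))
  df <- data.frame(chrom = frags$chrom,
                   start = format(frags$start, scientific = FALSE, trim = TRUE),
                   end = format(frags$end, scientific = FALSE, trim = TRUE),
                   name = paste0(frags$sample_id, ":", pair_id),
                   score = pmin(frags$mapq1, frags$mapq2),
                   strand = ifelse(frags$proper, "+", "."),
                   mapq1 = frags$mapq1, mapq2 = frags$mapq2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("expected >= 6 BED columns in ", path)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- strsplit(df$name, ":", fixed = TRUE)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    mapq1 = if (ncol(df) >= 8) df[[7]] else df$score,
                    mapq2 = if (ncol(df) >= 8) df[[8]] else df$score,
                    proper = df$strand != ".",
                    sample_id = vapply(parts, `[`, character(1), 1),
                    pair_id = vapply(parts, function(p)
                      paste(p[-1], collapse = ":"), character(1)),
                    stringsAsFactors = FALSE)
  out
}
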