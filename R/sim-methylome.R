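#' Construct the ground truth for a simulated aging methylome
#'
#' Chooses non-overlapping DMR intervals at CpG-bearing loci: a cluster of
#' `hotspot_dmr_count` hypermethylated DMRs confined to one randomly chosen
#' `hotspot_window` on the first chromosome, further hypermethylated DMRs
#' (half of them inside CpG islands, mirroring the age-related CGI gain),
#' and hypomethylated DMRs in non-CGI territory. DMR loci are local CpG
#' maxima (their 500 bp flanks are CpG-poorer), so each injected region
#' dominates the candidate region it will fall in. Baseline
#' (youngest-group) latent methylation is 0.30 for hyper and 0.70 for hypo
#' regions so the default effect fits inside `[0, 1]`.
#'
#' @param genome,features Output of [simulate_genome()].
#' @param cfg A [sim_config()].
#' @return A `GroundTruth` list: `dmrs` (data.frame with `chrom`, `start`,
#'   `end`, `direction`, `effect_log2fc`, `baseline`, `in_hotspot`) and
#'   `hotspot` (`chrom`, `start` of the window; NULL if no hotspot DMRs).
#' @export
make_ground_truth <- function(genome, features, cfg) {
  with_seed(derive_seed(cfg$seed, "truth"), {
    dmrs <- list()
    taken <- list()  # per-chrom matrix of accepted [start,end)

    pad <- 1000  # keep DMRs >= 1 kb apart so each forms its own bump
    overlaps_taken <- function(chr, s, e) {
      tk <- taken[[chr]]
      !is.null(tk) && any(tk[, 1] < e + pad & s - pad < tk[, 2])
    }
    claim <- function(chr, s, e) {
      taken[[chr]] <<- rbind(taken[[chr]], c(s, e))
    }

    ## candidate starts (grid-step 100) inside [lo, hi): at least min_cpg
    ## CpGs inside the interval and CpG-poorer 500 bp flanks on both sides
    ## combined (a local CpG cluster, so the DMR dominates its bump)
    rich_starts <- function(chr, lo, hi, len, min_cpg = 10) {
      starts <- seq(lo, hi - len, by = 100)
      if (!length(starts)) return(numeric(0))
      p <- genome$cpg[[chr]]
      cnt <- findInterval(starts + len - 1, p) - findInterval(starts - 1, p)
      flank <- findInterval(starts + len + 499, p) -
        findInterval(starts - 501, p) - cnt
      starts[cnt >= min_cpg & flank <= cnt]
    }

    place <- function(n, chr_pool, lo = NULL, hi = NULL, direction,
                      baseline, min_cpg = 10) {
      out <- list()
      tries <- 0
      while (length(out) < n && tries < 200) {
        tries <- tries + 1
        chr <- if (length(chr_pool) == 1) chr_pool else sample(chr_pool, 1)
        l0 <- if (is.null(lo)) 0 else lo
        h0 <- if (is.null(hi)) genome$chrom_sizes[[chr]] else hi
        cand <- rich_starts(chr, l0, h0, cfg$dmr_length, min_cpg)
        cand <- cand[!vapply(cand, function(s)
          overlaps_taken(chr, s, s + cfg$dmr_length), logical(1))]
        if (!length(cand)) next
        s <- sample(cand, 1)
        claim(chr, s, s + cfg$dmr_length)
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = s, end = s + cfg$dmr_length,
          direction = direction, effect_log2fc = cfg$dmr_effect_log2fc,
          baseline = baseline, stringsAsFactors = FALSE)
      }
      out
    }

    hotspot <- NULL
    if (cfg$hotspot_dmr_count > 0) {
      chr <- names(genome$chrom_sizes)[1]
      nwin <- floor(genome$chrom_sizes[[chr]] / cfg$hotspot_window)
      wstart <- (sample.int(nwin, 1) - 1) * cfg$hotspot_window
      ## spread the cluster across the window: one DMR per equal slot, so
      ## adjacent cluster members stay distinct regions
      slot <- cfg$hotspot_window / cfg$hotspot_dmr_count
      hs <- list()
      for (k in seq_len(cfg$hotspot_dmr_count)) {
        got <- place(1, chr, wstart + (k - 1) * slot,
                     min(wstart + k * slot, wstart + cfg$hotspot_window),
                     "hyper", 0.30, min_cpg = 10)
        if (!length(got))  # slot without a CpG-rich spot: anywhere in window
          got <- place(1, chr, wstart, wstart + cfg$hotspot_window,
                       "hyper", 0.30, min_cpg = 10)
        hs <- c(hs, got)
      }
      if (length(hs) < cfg$hotspot_dmr_count)
        stop("could not place all hotspot DMRs; enlarge hotspot_window ",
             "or reduce hotspot_dmr_count")
      hotspot <- list(chrom = chr, start = wstart)
      dmrs <- c(dmrs, hs)
    }

    n_rest <- cfg$true_dmr_count - cfg$hotspot_dmr_count
    if (n_rest > 0) {
      n_hyper <- ceiling(n_rest / 2)
      n_hypo <- n_rest - n_hyper
      chroms <- names(genome$chrom_sizes)

      ## half of the dispersed hyper DMRs inside CGIs (CGI methylation gain)
      cgis <- features[features$class == "CGI", , drop = FALSE]
      if (!is.null(hotspot) && nrow(cgis)) {
        inwin <- cgis$chrom == hotspot$chrom &
          cgis$start < hotspot$start + cfg$hotspot_window &
          cgis$end > hotspot$start
        cgis <- cgis[!inwin, , drop = FALSE]
      }
      n_cgi <- min(floor(n_hyper / 2), nrow(cgis))
      if (n_cgi > 0) {
        pick <- sample.int(nrow(cgis), n_cgi)
        for (k in pick) {
          s <- cgis$start[k]
          e <- min(cgis$end[k], s + cfg$dmr_length)
          if (overlaps_taken(cgis$chrom[k], s, e)) next
          claim(cgis$chrom[k], s, e)
          dmrs[[length(dmrs) + 1]] <- data.frame(
            chrom = cgis$chrom[k], start = s, end = e, direction = "hyper",
            effect_log2fc = cfg$dmr_effect_log2fc, baseline = 0.30,
            stringsAsFactors = FALSE)
        }
      }
      placed_cgi <- length(dmrs) - cfg$hotspot_dmr_count
      dmrs <- c(dmrs,
                place(n_hyper - placed_cgi, chroms, direction = "hyper",
                      baseline = 0.30),
                place(n_hypo, chroms, direction = "hypo", baseline = 0.70))
    }

    df <- if (length(dmrs))
      do.call(rbind, c(dmrs, make.row.names = FALSE))
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    direction = character(), effect_log2fc = numeric(),
                    baseline = numeric(), stringsAsFactors = FALSE)
    df$in_hotspot <- rep(FALSE, nrow(df))
    if (!is.null(hotspot) && nrow(df))
      df$in_hotspot[seq_len(cfg$hotspot_dmr_count)] <- TRUE
    df <- df[order(df$chrom, df$start), ]
    rownames(df) <- NULL
    structure(list(dmrs = df, hotspot = hotspot), class = "GroundTruth")
  })
}

#' Write / read a ground-truth manifest
#' @param truth A `GroundTruth`.
#' @param path TSV path.
#' @return `path` invisibly; `read_ground_truth` returns a `GroundTruth`.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$dmrs
  df$hotspot_chrom <- rep(if (is.null(truth$hotspot)) NA
                          else truth$hotspot$chrom, nrow(df))
  df$hotspot_start <- rep(if (is.null(truth$hotspot)) NA
                          else truth$hotspot$start, nrow(df))
  write_tsv(df, path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read_tsv(path)
  hotspot <- NULL
  if (nrow(df) && !is.na(df$hotspot_chrom[1]))
    hotspot <- list(chrom = df$hotspot_chrom[1], start = df$hotspot_start[1])
  df$hotspot_chrom <- NULL; df$hotspot_start <- NULL
  structure(list(dmrs = df, hotspot = hotspot), class = "GroundTruth")
}

#' Simulate the latent methylation surface for every age group
#'
#' Assigns each 50 bp bin a latent methylation level in `[0, 1]`. The
#' youngest group gets `cgi_methylation` inside islands and
#' `baseline_methylation` elsewhere, modulated by a log-normal spatial
#' jitter shared by all groups. The oldest group equals the youngest times
#' `1 - global_shift_fraction` outside CGIs; DMR intervals instead carry
#' their ground-truth baseline shifted by `2^(+/- effect_log2fc)`.
#' Intermediate groups interpolate linearly between the youngest and oldest
#' surface (progressive, directional change).
#'
#' @param genome,features Output of [simulate_genome()].
#' @param truth A `GroundTruth` from [make_ground_truth()].
#' @param cfg A [sim_config()].
#' @param bin_size Bin width in bp.
#' @return A `MethylationSurface`: list with `bin_size`, `groups` and
#'   `levels[[group]][[chrom]]` numeric vectors.
#' @export
simulate_methylome <- function(genome, features, truth, cfg, bin_size = 50) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (nrow(truth$dmrs)) {
    ok <- vapply(seq_len(nrow(truth$dmrs)), function(i) {
      chr <- truth$dmrs$chrom[i]
      chr %in% names(genome$chrom_sizes) &&
        truth$dmrs$end[i] <= genome$chrom_sizes[[chr]] &&
        truth$dmrs$start[i] >= 0
    }, logical(1))
    if (!all(ok)) stop("ground-truth DMR outside genome bounds")
  }
  nb <- n_bins(genome, bin_size)
  cgis <- features[features$class == "CGI", , drop = FALSE]

  bins_of <- function(start, end)  # bin indices overlapped by [start, end)
    seq.int(start %/% bin_size, (end - 1) %/% bin_size) + 1L

  with_seed(derive_seed(cfg$seed, "surface"), {
    young <- list(); cgi_mask <- list()
    for (chr in names(nb)) {
      base <- rep(cfg$baseline_methylation, nb[[chr]])
      mask <- rep(FALSE, nb[[chr]])
      cc <- cgis[cgis$chrom == chr, , drop = FALSE]
      for (k in seq_len(nrow(cc))) {
        b <- bins_of(cc$start[k], cc$end[k])
        base[b] <- cfg$cgi_methylation
        mask[b] <- TRUE
      }
      jit <- exp(rnorm(nb[[chr]], 0, cfg$methylation_jitter_sd))
      young[[chr]] <- pmin(pmax(base * jit, 0.01), 0.95)
      cgi_mask[[chr]] <- mask
    }

    old <- young
    for (chr in names(nb)) {
      shift_bins <- !cgi_mask[[chr]]
      old[[chr]][shift_bins] <-
        young[[chr]][shift_bins] * (1 - cfg$global_shift_fraction)
    }
    ## DMR overrides (applied after the global rule; DMR bins follow their
    ## own trajectory)
    td <- truth$dmrs
    for (i in seq_len(nrow(td))) {
      chr <- td$chrom[i]
      b <- bins_of(td$start[i], td$end[i])
      jit <- young[[chr]][b] / ifelse(cgi_mask[[chr]][b],
                                      cfg$cgi_methylation,
                                      cfg$baseline_methylation)
      y <- pmin(pmax(td$baseline[i] * jit, 0.01), 0.95)
      fc <- 2^(ifelse(td$direction[i] == "hyper", 1, -1) * td$effect_log2fc[i])
      young[[chr]][b] <- y
      old[[chr]][b] <- pmin(pmax(y * fc, 0.01), 1)
    }

    groups <- cfg$groups
    levels <- vector("list", length(groups))
    names(levels) <- groups
    ng <- length(groups)
    for (g in seq_along(groups)) {
      w <- if (ng == 1) 0 else (g - 1) / (ng - 1)
      levels[[g]] <- lapply(names(nb), function(chr)
        (1 - w) * young[[chr]] + w * old[[chr]])
      names(levels[[g]]) <- names(nb)
    }
    structure(list(bin_size = bin_size, groups = groups, levels = levels,
                   cgi_mask = cgi_mask),
              class = "MethylationSurface")
  })
}
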