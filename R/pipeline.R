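#' Pipeline run configuration
#'
#' Bundles the simulation (or input paths), the stage parameters (all
#' defaulting to the study's printed values: 50 bp bins, 700 bp coupling,
#' 10-read bump threshold, 100 kb hotspot windows, 1000 permutations,
#' FDR 0.2, 100 kb gene cut-off, 2000 bp shores) and the primary group
#' comparison.
#'
#' @param sim A [sim_config()] to simulate inputs, or NULL to use
#'   pre-existing files in the run directory.
#' @param group_a,group_b Primary comparison (default youngest vs oldest
#'   simulated group).
#' @param exclude_samples Character vector of sample ids dropped from all
#'   analyses (e.g. a low-correlation replicate).
#' @param bin_size,coupling_distance,min_total_reads,window_size,
#'   n_permutations,fdr_threshold,hotspot_fdr,gene_cutoff Stage parameters.
#' @param seed Master seed for the permutation stream (the simulation has
#'   its own seed inside `sim`).
#' @return A `RunConfig` list.
#' @export
run_config <- function(sim = sim_config(), group_a = NULL, group_b = NULL,
                       exclude_samples = character(0), bin_size = 50,
                       coupling_distance = 700, min_total_reads = 10,
                       window_size = 1e5, n_permutations = 1000,
                       fdr_threshold = 0.2, hotspot_fdr = 0.01,
                       gene_cutoff = 1e5, seed = 1L) {
  if (!is.null(sim)) {
    if (is.null(group_a)) group_a <- sim$groups[1]
    if (is.null(group_b)) group_b <- sim$groups[length(sim$groups)]
  }
  stopifnot(bin_size > 0, coupling_distance >= 0, min_total_reads > 0,
            window_size > 0, n_permutations > 0, fdr_threshold > 0,
            gene_cutoff >= 0, !is.null(group_a), !is.null(group_b))
  structure(list(sim = sim, group_a = group_a, group_b = group_b,
                 exclude_samples = exclude_samples, bin_size = bin_size,
                 coupling_distance = coupling_distance,
                 min_total_reads = min_total_reads,
                 window_size = window_size,
                 n_permutations = n_permutations,
                 fdr_threshold = fdr_threshold, hotspot_fdr = hotspot_fdr,
                 gene_cutoff = gene_cutoff, seed = as.integer(seed)),
            class = "RunConfig")
}

## ---- stages ----------------------------------------------------------
## Every stage reads its inputs from, and writes its outputs to, the run
## directory, so each is runnable standalone on the previous stage's files.

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  if (is.null(cfg)) stop("stage_simulate requires a simulation config")
  ds <- simulate_dataset(cfg)
  write_sim_config(cfg, file.path(dir, "sim_config.txt"))
  write_genome(ds$genome, file.path(dir, "genome"))
  write_features(ds$features, file.path(dir, "features.bed"))
  write_ground_truth(ds$truth, file.path(dir, "ground_truth.tsv"))
  write_tsv(ds$samples, file.path(dir, "samples.tsv"))
  fdir <- file.path(dir, "fragments")
  dir.create(fdir, showWarnings = FALSE)
  for (id in names(ds$fragments))
    write_fragments_bed(ds$fragments[[id]], file.path(fdir,
                                                      paste0(id, ".bed")))
  invisible(dir)
}

read_run_inputs <- function(dir) {
  list(genome = read_genome(file.path(dir, "genome")),
       features = read_features(file.path(dir, "features.bed")),
       samples = read_tsv(file.path(dir, "samples.tsv")))
}

#' @rdname run_pipeline
#' @export
stage_qc <- function(config, dir) {
  inp <- read_run_inputs(dir)
  samples <- inp$samples
  frag_list <- lapply(samples$sample_id, function(id)
    read_fragments_bed(file.path(dir, "fragments", paste0(id, ".bed"))))
  names(frag_list) <- samples$sample_id
  qc <- qc_report(frag_list, inp$genome)
  fdir <- file.path(dir, "filtered")
  dir.create(fdir, showWarnings = FALSE)
  for (id in names(qc$filtered))
    write_fragments_bed(qc$filtered[[id]], file.path(fdir,
                                                     paste0(id, ".bed")))
  write_tsv(qc$per_sample, file.path(dir, "qc_per_sample.tsv"))
  cors <- data.frame(sample_id = rownames(qc$correlations),
                     qc$correlations, check.names = FALSE)
  write_tsv(cors, file.path(dir, "qc_correlations.tsv"))
  jsonlite::write_json(
    list(per_sample = qc$per_sample,
         mean_correlation = mean(qc$correlations[upper.tri(qc$correlations)],
                                 na.rm = TRUE)),
    file.path(dir, "qc.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

load_tracks <- function(config, dir) {
  inp <- read_run_inputs(dir)
  samples <- inp$samples[!(inp$samples$sample_id %in%
                             config$exclude_samples) &
                           inp$samples$group != "Input", , drop = FALSE]
  coupling <- build_coupling(inp$genome, config$bin_size,
                             config$coupling_distance)
  frag_list <- lapply(samples$sample_id, function(id)
    read_fragments_bed(file.path(dir, "filtered", paste0(id, ".bed"))))
  names(frag_list) <- samples$sample_id
  tracks <- methylation_tracks(frag_list, samples, coupling, inp$genome)
  list(inputs = inp, samples = samples, coupling = coupling,
       tracks = tracks)
}

#' @rdname run_pipeline
#' @export
stage_score <- function(config, dir) {
  st <- load_tracks(config, dir)
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)
  write_bedgraph(st$coupling, st$inputs$genome,
                 file.path(tdir, "coupling.bedGraph"))
  for (t in st$tracks)
    write_bedgraph(t, st$inputs$genome,
                   file.path(tdir, paste0(t$sample_id, ".score.bedGraph")))
  glob <- global_comparison(st$tracks, st$inputs$genome,
                            config$group_a, config$group_b)
  cgi <- cgi_comparison(st$tracks, st$inputs$features, st$inputs$genome,
                        config$group_a, config$group_b)
  strip <- function(x) x[setdiff(names(x), "per_cgi")]
  jsonlite::write_json(list(global = unclass(glob),
                            cgi = if (is.null(cgi)) NULL
                              else strip(unclass(cgi))),
                       file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_dmr <- function(config, dir) {
  st <- load_tracks(config, dir)
  bumps <- build_bump_list(st$tracks, st$inputs$genome, config$group_a,
                           config$group_b, config$min_total_reads)
  saveRDS_free_bumps(bumps, dir)
  res <- call_dmrs(bumps, st$tracks, config$fdr_threshold)
  assoc <- associate_genes(res$dmrs, st$inputs$features, config$gene_cutoff)
  tab <- res$table
  write_tsv(tab, file.path(dir, "regions_tested.tsv"))
  write_tsv(assoc$dmrs, file.path(dir, "dmrs.tsv"))
  bed <- assoc$dmrs
  if (nrow(bed)) {
    utils::write.table(
      data.frame(bed$chrom,
                 format(bed$start, scientific = FALSE, trim = TRUE),
                 format(bed$end, scientific = FALSE, trim = TRUE),
                 paste0("DMR_", seq_len(nrow(bed)), "_", bed$direction)),
      file.path(dir, "dmrs.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else file.create(file.path(dir, "dmrs.bed"))
  if (!is.null(res$heatmap))
    write_tsv(data.frame(region = rownames(res$heatmap), res$heatmap,
                         check.names = FALSE),
              file.path(dir, "dmr_heatmap.tsv"))
  jsonlite::write_json(
    list(n_tested = nrow(tab), n_dmrs = nrow(res$dmrs),
         n_hyper = sum(res$dmrs$direction == "hyper"),
         n_hypo = sum(res$dmrs$direction == "hypo"),
         fraction_with_gene = assoc$fraction_associated,
         size_factors = as.list(res$size_factors),
         dispersion_coef = as.list(res$dispersion$coef)),
    file.path(dir, "dmr_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

## bump-list persisted as two plain-text tables (regions + counts)
saveRDS_free_bumps <- function(bumps, dir) {
  write_tsv(bumps$regions, file.path(dir, "bumps.tsv"))
  write_tsv(data.frame(sample_id = colnames(bumps$counts),
                       group = unname(bumps$groups),
                       t(bumps$counts), check.names = FALSE),
            file.path(dir, "bump_counts.tsv"))
  invisible(dir)
}

read_bumps <- function(config, dir) {
  regions <- read_tsv(file.path(dir, "bumps.tsv"))
  ct <- read_tsv(file.path(dir, "bump_counts.tsv"))
  counts <- t(as.matrix(ct[, -(1:2), drop = FALSE]))
  dimnames(counts) <- list(NULL, ct$sample_id)
  structure(list(regions = regions, counts = counts,
                 samples = ct$sample_id,
                 groups = stats::setNames(ct$group, ct$sample_id),
                 group_a = config$group_a, group_b = config$group_b,
                 bin_size = config$bin_size),
            class = "BumpList")
}

#' @rdname run_pipeline
#' @export
stage_hotspot <- function(config, dir) {
  inp <- read_run_inputs(dir)
  bumps <- read_bumps(config, dir)
  tab <- read_tsv(file.path(dir, "regions_tested.tsv"))
  run_one <- function(sub, label) {
    if (nrow(sub) == 0) return(NULL)
    ps <- hotspot_permutation(sub, bumps, inp$genome,
                              config$n_permutations, config$window_size,
                              seed = derive_seed(config$seed,
                                                 paste0("hotspot:", label)))
    unclass(ps)
  }
  all_dmrs <- tab[tab$significant, , drop = FALSE]
  hyper_strict <- tab[tab$fdr < config$hotspot_fdr &
                        tab$direction == "hyper", , drop = FALSE]
  jsonlite::write_json(
    list(all_dmrs = run_one(all_dmrs, "all"),
         hyper_strict = run_one(hyper_strict, "hyper_strict")),
    file.path(dir, "hotspot.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(config, dir) {
  inp <- read_run_inputs(dir)
  bumps <- read_bumps(config, dir)
  tab <- read_tsv(file.path(dir, "regions_tested.tsv"))
  enr <- feature_enrichment(tab[tab$significant, , drop = FALSE], bumps,
                            inp$features)
  write_tsv(enr, file.path(dir, "enrichment.tsv"))
  invisible(dir)
}

#' Run the full pipeline: simulate, QC, score, DMRs, hotspot, enrichment
#'
#' Stages execute in order, each writing its outputs to `dir` before the
#' next begins; any stage can later be re-run standalone on those files.
#' The final `report.json` aggregates the QC table, the global and CGI
#' comparisons, DMR counts by direction, the hotspot permutation summary,
#' the enrichment table, ground-truth recovery metrics (for simulated runs)
#' and the fully resolved configuration, so a run is re-executable from its
#' report alone. Identical config and seed give byte-identical reports.
#'
#' @param config A [run_config()].
#' @param dir Run directory (created if needed).
#' @return The parsed report, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  stages <- list(simulate = stage_simulate, qc = stage_qc,
                 score = stage_score, dmr = stage_dmr,
                 hotspot = stage_hotspot, enrich = stage_enrich)
  if (is.null(config$sim)) stages$simulate <- NULL
  for (nm in names(stages)) {
    ok <- try(stages[[nm]](config, dir), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("pipeline stage '", nm, "' failed: ", attr(ok, "condition")$message)
  }
  report <- build_report(config, dir)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

build_report <- function(config, dir) {
  qc <- jsonlite::read_json(file.path(dir, "qc.json"),
                            simplifyVector = TRUE)
  comparison <- jsonlite::read_json(file.path(dir, "comparison.json"),
                                    simplifyVector = TRUE)
  dmr <- jsonlite::read_json(file.path(dir, "dmr_summary.json"),
                             simplifyVector = TRUE)
  hotspot <- jsonlite::read_json(file.path(dir, "hotspot.json"),
                                 simplifyVector = TRUE)
  enrichment <- read_tsv(file.path(dir, "enrichment.tsv"))
  recovery <- NULL
  truth_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(truth_path)) {
    truth <- read_ground_truth(truth_path)
    dmrs <- read_tsv(file.path(dir, "dmrs.tsv"))
    recovery <- recovery_metrics(truth, dmrs, hotspot, config)
  }
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(config$sim)) unclass(config$sim)
  list(config = cfg, qc = qc, comparison = comparison, dmr = dmr,
       hotspot = hotspot, enrichment = enrichment, recovery = recovery)
}

#' Ground-truth recovery metrics for a simulated run
#'
#' Sensitivity is the fraction of injected DMRs overlapped by at least one
#' called DMR; the false-discovery proportion is the fraction of called
#' DMRs overlapping no injected interval. The hotspot is flagged detected
#' when the permutation p-value is below 0.001 and the observed window is
#' the injected one.
#'
#' @param truth A `GroundTruth`.
#' @param called data.frame of called DMRs.
#' @param hotspot Parsed hotspot summary (or NULL).
#' @param config The `RunConfig`.
#' @return List of metrics.
#' @export
recovery_metrics <- function(truth, called, hotspot = NULL, config = NULL) {
  td <- truth$dmrs
  if (nrow(td) == 0 || nrow(called) == 0) {
    sens <- if (nrow(td)) 0 else NA_real_
    fdp <- if (nrow(called)) 1 else NA_real_
    if (nrow(td) == 0 && nrow(called) == 0) fdp <- 0
  } else {
    gr_t <- df_granges(td); gr_c <- df_granges(called)
    sens <- mean(IRanges::overlapsAny(gr_t, gr_c))
    fdp <- mean(!IRanges::overlapsAny(gr_c, gr_t))
  }
  out <- list(n_injected = nrow(td), n_called = nrow(called),
              sensitivity = sens, false_discovery_proportion = fdp)
  if (!is.null(hotspot) && !is.null(truth$hotspot) &&
      !is.null(hotspot$all_dmrs)) {
    hs <- hotspot$all_dmrs
    out$hotspot_empirical_p <- hs$empirical_p
    out$hotspot_detected <- hs$empirical_p < 0.001 &&
      identical(hs$observed_window$chrom, truth$hotspot$chrom) &&
      hs$observed_window$start == truth$hotspot$start
  }
  out
}
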