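#' Simulation configuration
#'
#' Parameters of the synthetic MeDIP-seq study. Defaults describe a compact
#' desk-scale design: two 1 Mb chromosomes, three age groups (Young, Mid,
#' Old) with three replicates each, 2e5 fragments per replicate, a 5%
#' global loss of non-CGI methylation in Old animals, 20 true DMRs of 1
#' log2 unit effect, 8 of them hypermethylated and clustered inside one
#' 100 kb window.
#'
#' `pulldown_exponent` controls how steeply capture probability grows with
#' local CpG content; `pulldown_window` is the span (bp) around a fragment
#' midpoint over which CpGs are counted for that weight. A small fraction of
#' pairs is made improper, low-quality (both reads mapq < 10) or exact
#' duplicates so the filtering rules have work to do.
#'
#' @param seed Master seed; every sample derives its own stream from it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param cgi_count,cgi_mean_length CpG islands per genome and mean length.
#' @param background_cpg_rate,cgi_cpg_rate CpG probability per bp outside /
#'   inside CGIs.
#' @param groups Ordered age-group labels, youngest first.
#' @param replicates_per_group Biological replicates per group.
#' @param fragments_per_replicate MeDIP fragments simulated per sample.
#' @param fragment_length_mean,fragment_length_sd Fragment length model (bp);
#'   lengths are truncated to `[50, 2 * mean]`.
#' @param pulldown_exponent,pulldown_window Capture-weight model (see above).
#' @param baseline_methylation,cgi_methylation Latent methylation level of
#'   non-CGI and CGI bins in the youngest group.
#' @param methylation_jitter_sd Log-normal spatial heterogeneity (sdlog) of
#'   the latent surface, shared by all groups.
#' @param replicate_noise_sd Between-replicate biological noise: sdlog of a
#'   log-normal capture-efficiency multiplier drawn per sample and per
#'   `noise_block` bp block (sets the negative binomial overdispersion of
#'   region counts to roughly `replicate_noise_sd^2`).
#' @param noise_block Spatial scale (bp) of the replicate noise.
#' @param true_dmr_count,dmr_effect_log2fc,dmr_length Number, effect size
#'   (log2 fold change of the latent level, Old vs Young) and length of
#'   injected DMRs.
#' @param hotspot_dmr_count,hotspot_window Number of hypermethylated DMRs
#'   confined to a single window of this size.
#' @param global_shift_fraction Fractional loss of non-CGI methylation in
#'   the oldest group (0.05 = 5% loss).
#' @param genes_per_chromosome,exons_per_gene Gene annotation density.
#' @param mapq_fail_rate Fraction of pairs in which neither read reaches
#'   mapping quality 10.
#' @param improper_rate Fraction of pairs failing to map as a proper pair.
#' @param duplicate_rate Fraction of fragments that are exact duplicates of
#'   another pair.
#' @param input_control If TRUE, the sample sheet also carries uniform-capture
#'   input control samples.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       cgi_count = 40L,
                       cgi_mean_length = 2000,
                       background_cpg_rate = 0.008,
                       cgi_cpg_rate = 0.15,
                       groups = c("Young", "Mid", "Old"),
                       replicates_per_group = 3L,
                       fragments_per_replicate = 2e5,
                       fragment_length_mean = 200,
                       fragment_length_sd = 30,
                       pulldown_exponent = 1.8,
                       pulldown_window = 200,
                       baseline_methylation = 0.75,
                       cgi_methylation = 0.25,
                       methylation_jitter_sd = 0.1,
                       replicate_noise_sd = 0.1,
                       noise_block = 2000,
                       true_dmr_count = 20L,
                       dmr_effect_log2fc = 1.5,
                       dmr_length = 800,
                       hotspot_dmr_count = 8L,
                       hotspot_window = 1e5,
                       global_shift_fraction = 0.05,
                       genes_per_chromosome = 25L,
                       exons_per_gene = 5L,
                       mapq_fail_rate = 0.02,
                       improper_rate = 0.01,
                       duplicate_rate = 0.01,
                       input_control = FALSE) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      length(seed) == 1, is.finite(seed),
      n_chromosomes >= 1, chrom_length > 0,
      cgi_count >= 0, cgi_mean_length > 0,
      background_cpg_rate >= 0, background_cpg_rate <= 1,
      cgi_cpg_rate >= 0, cgi_cpg_rate <= 1,
      cgi_cpg_rate > background_cpg_rate,
      length(groups) >= 2, !anyDuplicated(groups),
      replicates_per_group >= 1, fragments_per_replicate >= 1,
      fragment_length_mean > 0, fragment_length_sd >= 0,
      pulldown_exponent >= 0, pulldown_window > 0,
      baseline_methylation > 0, baseline_methylation <= 1,
      cgi_methylation > 0, cgi_methylation <= 1,
      methylation_jitter_sd >= 0, replicate_noise_sd >= 0, noise_block > 0,
      true_dmr_count >= 0, dmr_effect_log2fc >= 0, dmr_length > 0,
      hotspot_dmr_count >= 0, hotspot_dmr_count <= true_dmr_count,
      hotspot_window > 0,
      global_shift_fraction >= 0, global_shift_fraction <= 1,
      genes_per_chromosome >= 0, exons_per_gene >= 1,
      mapq_fail_rate >= 0, mapq_fail_rate <= 1,
      improper_rate >= 0, improper_rate <= 1,
      duplicate_rate >= 0, duplicate_rate < 1
    )
    if (cgi_count * (cgi_mean_length + 1000) > n_chromosomes * chrom_length)
      stop("cgi_count * cgi_mean_length exceeds chromosome capacity")
    if (true_dmr_count * dmr_length * 3 > n_chromosomes * chrom_length)
      stop("true_dmr_count * dmr_length exceeds chromosome capacity")
    if (hotspot_dmr_count * dmr_length * 2 > hotspot_window)
      stop("hotspot DMRs do not fit inside one hotspot window")
  })
  invisible(cfg)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param cfg A `SimConfig`.
#' @return data.frame with `sample_id`, `group`, `replicate`. Input control
#'   samples (group `"Input"`), if enabled, are appended.
#' @export
sim_sample_sheet <- function(cfg) {
  ids <- as.vector(t(outer(cfg$groups, seq_len(cfg$replicates_per_group),
                           paste, sep = "_")))
  df <- data.frame(sample_id = ids,
                   group = rep(cfg$groups, each = cfg$replicates_per_group),
                   replicate = rep(seq_len(cfg$replicates_per_group),
                                   times = length(cfg$groups)),
                   stringsAsFactors = FALSE)
  if (isTRUE(cfg$input_control)) {
    df <- rbind(df, data.frame(sample_id = c("Input_1", "Input_2"),
                               group = "Input", replicate = 1:2))
  }
  df
}

#' Write / read a simulation configuration
#'
#' Flat `key=value` text (the default) or JSON; `read_sim_config` accepts
#' either, keyed off the file content.
#'
#' @param cfg A `SimConfig`.
#' @param path File path.
#' @param format `"keyvalue"` or `"json"`.
#' @return `path` invisibly; `read_sim_config` returns a `SimConfig`.
#' @export
write_sim_config <- function(cfg, path, format = c("keyvalue", "json")) {
  format <- match.arg(format)
  x <- unclass(cfg)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(names(x), function(k)
      paste0(k, "=", paste(x[[k]], collapse = ",")), character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) && grepl("^\\s*\\{", txt[1])) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    kv <- strsplit(txt[nzchar(txt)], "=", fixed = TRUE)
    x <- lapply(kv, function(p) {
      v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else if (identical(v, "TRUE")) TRUE
      else if (identical(v, "FALSE")) FALSE else v
    })
    names(x) <- vapply(kv, `[`, character(1), 1)
  }
  do.call(sim_config, x)
}
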