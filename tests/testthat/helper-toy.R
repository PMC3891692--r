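# Shared fixture builders: everything is generated in code.

## toy genome with explicit CpG positions
toy_genome <- function(sizes = c(chrA = 2000), cpg = list(chrA = c(100, 500, 1000))) {
  genome_model(sizes, cpg)
}

## fragment data.frame from parallel vectors (defaults: clean proper pairs)
toy_frags <- function(chrom, start, end, mapq1 = 30, mapq2 = 30,
                      proper = TRUE, sample_id = "S1") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             mapq1 = rep_len(mapq1, n), mapq2 = rep_len(mapq2, n),
             proper = rep_len(proper, n),
             sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
}

## MethylomeTrack built directly from per-chromosome count vectors
toy_track <- function(counts, sample_id, group, bin_size = 50,
                      score = NULL, library_size = NULL) {
  if (!is.list(counts)) counts <- list(chrA = counts)
  lib <- if (is.null(library_size)) sum(unlist(counts)) else library_size
  if (is.null(score))
    score <- lapply(counts, function(x) x / (lib / 1e6))
  if (!is.list(score)) score <- list(chrA = score)
  structure(list(sample_id = sample_id, group = group, bin_size = bin_size,
                 library_size = lib, counts = counts, score = score,
                 has_cpg = lapply(counts, function(x) rep(TRUE, length(x)))),
            class = "MethylomeTrack")
}

## small simulation configs used across tests
small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chromosomes = 1, chrom_length = 3e5,
               cgi_count = 6, genes_per_chromosome = 8,
               replicates_per_group = 2, fragments_per_replicate = 3e4,
               true_dmr_count = 4, hotspot_dmr_count = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

null_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, true_dmr_count = 0, global_shift_fraction = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(small_cfg, args)
}

## filtered tracks for a simulated dataset
sim_tracks <- function(ds) {
  qcf <- lapply(ds$fragments, function(f) filter_fragments(f)$fragments)
  methylation_tracks(qcf, ds$samples, build_coupling(ds$genome), ds$genome)
}

## Benjamini-Hochberg step-up computed from first principles (oracle)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## one-sided (enrichment) Fisher p from the hypergeometric tail, written
## with explicit binomial coefficients (oracle)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  sum(vapply(a:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1)))
}

## conditioned two-group count test by direct enumeration of the
## allocation distribution (oracle for test_region)
nb_test_oracle <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  ka <- sum(counts_a); kb <- sum(counts_b); ktot <- ka + kb
  SA <- sum(sf_a); SB <- sum(sf_b)
  q <- ktot / (SA + SB)
  pmf <- function(x, mu, var) {
    if (mu <= 0) return(as.numeric(x == 0))
    if (var <= mu * (1 + 1e-12)) return(dpois(x, mu))
    dnbinom(x, mu = mu, size = mu^2 / (var - mu))
  }
  pr <- vapply(0:ktot, function(a)
    pmf(a, q * SA, q * SA + alpha * q^2 * sum(sf_a^2)) *
      pmf(ktot - a, q * SB, q * SB + alpha * q^2 * sum(sf_b^2)),
    numeric(1))
  sum(pr[pr <= pr[ka + 1] * (1 + 1e-7)]) / sum(pr)
}
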