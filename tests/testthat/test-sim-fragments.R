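make_surface_ds <- function(cfg) {
  out <- simulate_genome(cfg)
  truth <- make_ground_truth(out$genome, out$features, cfg)
  surf <- simulate_methylome(out$genome, out$features, truth, cfg)
  list(genome = out$genome, features = out$features, truth = truth,
       surface = surf)
}

test_that("fragment simulation is deterministic and per-sample streamed", {
  cfg <- null_cfg(seed = 2, fragments_per_replicate = 5000)
  ds <- make_surface_ds(cfg)
  a1 <- simulate_fragments(ds$genome, ds$surface, cfg, "Young_1", "Young")
  a2 <- simulate_fragments(ds$genome, ds$surface, cfg, "Young_1", "Young")
  expect_identical(a1, a2)
  b <- simulate_fragments(ds$genome, ds$surface, cfg, "Young_2", "Young")
  expect_false(identical(a1$start, b$start))
  ## a different master seed changes the stream
  cfg2 <- null_cfg(seed = 3, fragments_per_replicate = 5000)
  a3 <- simulate_fragments(ds$genome, ds$surface, cfg2, "Young_1", "Young")
  expect_false(identical(a1$start, a3$start))
})

test_that("whole-dataset simulation is reproducible byte for byte", {
  cfg <- null_cfg(seed = 8, fragments_per_replicate = 2000)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$fragments, d2$fragments)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$surface, d2$surface)
})

test_that("input-control midpoints are uniform across the genome", {
  cfg <- null_cfg(seed = 4, fragments_per_replicate = 20000,
                  mapq_fail_rate = 0, improper_rate = 0, duplicate_rate = 0)
  ds <- make_surface_ds(cfg)
  fr <- simulate_fragments(ds$genome, ds$surface, cfg, "Input_1",
                           input = TRUE)
  mid <- (fr$start + fr$end) %/% 2
  slice <- pmin(mid %/% (cfg$chrom_length / 10), 9)
  gof <- chisq.test(tabulate(slice + 1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("a zero pull-down exponent on a flat surface is uniform too", {
  cfg <- null_cfg(seed = 6, fragments_per_replicate = 20000,
                  pulldown_exponent = 0, methylation_jitter_sd = 0,
                  replicate_noise_sd = 0, cgi_methylation = 0.75,
                  mapq_fail_rate = 0, improper_rate = 0, duplicate_rate = 0)
  ds <- make_surface_ds(cfg)
  fr <- simulate_fragments(ds$genome, ds$surface, cfg, "Young_1", "Young")
  mid <- (fr$start + fr$end) %/% 2
  slice <- pmin(mid %/% (cfg$chrom_length / 10), 9)
  gof <- chisq.test(tabulate(slice + 1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("MeDIP samples are CpG-enriched relative to their input", {
  cfg <- null_cfg(seed = 10, fragments_per_replicate = 20000)
  ds <- make_surface_ds(cfg)
  medip <- simulate_fragments(ds$genome, ds$surface, cfg, "Young_1", "Young")
  input <- simulate_fragments(ds$genome, ds$surface, cfg, "Input_1",
                              input = TRUE)
  s_medip <- enrichment_score(filter_fragments(medip)$fragments, ds$genome)
  s_input <- enrichment_score(filter_fragments(input)$fragments, ds$genome)
  expect_gt(s_medip, s_input)
  expect_lt(abs(s_input - 1), 0.1)
})

test_that("fragment records respect the configured length and QC models", {
  cfg <- null_cfg(seed = 12, fragments_per_replicate = 20000)
  ds <- make_surface_ds(cfg)
  fr <- simulate_fragments(ds$genome, ds$surface, cfg, "Old_1", "Old")
  expect_equal(nrow(fr), cfg$fragments_per_replicate)
  len <- fr$end - fr$start
  expect_true(all(len >= 1 & len <= 2 * cfg$fragment_length_mean))
  expect_true(all(fr$start >= 0 & fr$end <= cfg$chrom_length))
  ## both-reads-low pairs appear at roughly the configured rate
  fail <- pmax(fr$mapq1, fr$mapq2) < 10
  expect_gt(mean(fail), cfg$mapq_fail_rate / 3)
  expect_lt(mean(fail), cfg$mapq_fail_rate * 3)
  expect_gt(sum(!fr$proper), 0)
  expect_gt(sum(duplicated(fr[c("chrom", "start", "end")])), 0)
})

test_that("an unsampleable surface is rejected", {
  g <- toy_genome(c(chrA = 10000), list(chrA = integer(0)))  # no CpGs
  cfg <- null_cfg(seed = 1, fragments_per_replicate = 100)
  surf <- structure(list(bin_size = 50, groups = "Young",
                         levels = list(Young = list(chrA = rep(0.5, 200))),
                         cgi_mask = list(chrA = rep(FALSE, 200))),
                    class = "MethylationSurface")
  expect_error(simulate_fragments(g, surf, cfg, "Young_1", "Young"),
               "sampleable")
})

test_that("old/young fragment density in hyper-DMRs grows with effect size", {
  ratios <- vapply(c(0.5, 1.5), function(eff) {
    rr <- vapply(1:3, function(s) {
      cfg <- small_cfg(seed = 100 + s, true_dmr_count = 4,
                       dmr_effect_log2fc = eff, global_shift_fraction = 0,
                       fragments_per_replicate = 2e4)
      ds <- make_surface_ds(cfg)
      hyper <- ds$truth$dmrs[ds$truth$dmrs$direction == "hyper", ]
      if (nrow(hyper) == 0) return(NA_real_)
      yo <- vapply(c("Young", "Old"), function(grp) {
        fr <- simulate_fragments(ds$genome, ds$surface, cfg,
                                 paste0(grp, "_1"), grp)
        mid <- (fr$start + fr$end) %/% 2
        sum(vapply(seq_len(nrow(hyper)), function(i)
          sum(fr$chrom == hyper$chrom[i] & mid >= hyper$start[i] &
                mid < hyper$end[i]), numeric(1)))
      }, numeric(1))
      yo[["Old"]] / yo[["Young"]]
    }, numeric(1))
    mean(rr, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_gt(ratios[2], ratios[1])
})

test_that("fragments round-trip through the BED writer", {
  cfg <- null_cfg(seed = 14, fragments_per_replicate = 500)
  ds <- make_surface_ds(cfg)
  fr <- simulate_fragments(ds$genome, ds$surface, cfg, "Mid_2", "Mid")
  path <- file.path(withr::local_tempdir(), "frags.bed")
  write_fragments_bed(fr, path)
  back <- read_fragments_bed(path)
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  expect_equal(back$mapq1, fr$mapq1)
  expect_equal(back$mapq2, fr$mapq2)
  expect_equal(back$proper, fr$proper)
  expect_equal(back$sample_id, fr$sample_id)
})
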