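## build a bump universe of unit regions at known offsets plus a feature
## set covering a chosen subset, to realize exact 2x2 tables
make_universe <- function(n, in_class, class = "CGI") {
  start <- seq(0, by = 1000, length.out = n)
  regions <- data.frame(chrom = "chrA", start = start, end = start + 200,
                        n_bins = 4, total = 20)
  bumps <- structure(list(regions = regions,
                          counts = matrix(10, n, 2,
                                          dimnames = list(NULL, c("A", "B"))),
                          samples = c("A", "B"),
                          groups = c(A = "Young", B = "Old"),
                          group_a = "Young", group_b = "Old", bin_size = 50),
                     class = "BumpList")
  feats <- feature_set(data.frame(chrom = "chrA",
                                  start = regions$start[in_class],
                                  end = regions$end[in_class],
                                  class = class,
                                  name = paste0(class, seq_along(in_class))))
  list(bumps = bumps, feats = feats)
}

dmr_rows <- function(bumps, idx, direction) {
  out <- bumps$regions[idx, c("chrom", "start", "end")]
  out$direction <- direction
  out$region_id <- idx
  out
}

test_that("balanced composition gives odds ratio near 1 and large p", {
  ## a=5, b=5, c=50, d=50
  u <- make_universe(110, in_class = c(1:5, 11:60))
  dmrs <- dmr_rows(u$bumps, 1:10, "hyper")
  rows <- feature_enrichment(dmrs, u$bumps, u$feats)
  cgi <- rows[rows$direction == "hyper" & rows$feature == "CGI", ]
  expect_equal(unlist(cgi[c("a", "b", "c", "d")], use.names = FALSE),
               c(5, 5, 50, 50))
  expect_gt(cgi$p_value, 0.5)
  expect_lt(abs(cgi$odds_ratio - 1), 0.5)
  ## marginals: a+b+c+d equals the bump-list size on every row
  expect_true(all(rowSums(rows[c("a", "b", "c", "d")]) == 110))
})

test_that("one-sided Fisher p matches the hypergeometric closed form", {
  ## a=10, b=0, c=10, d=90
  u <- make_universe(110, in_class = c(1:10, 21:30))
  dmrs <- dmr_rows(u$bumps, 1:10, "hyper")
  rows <- feature_enrichment(dmrs, u$bumps, u$feats)
  cgi <- rows[rows$direction == "hyper" & rows$feature == "CGI", ]
  expect_equal(unlist(cgi[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 0, 10, 90))
  expect_lt(abs(cgi$p_value - fisher_oracle(10, 0, 10, 90)), 1e-10)
  ## spot-check the oracle against fisher.test on scrambled tables
  set.seed(13)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    expect_lt(abs(fisher_oracle(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2]) -
                    fisher.test(t2, alternative = "greater")$p.value),
              1e-10)
  }
})

test_that("directions without DMRs yield unit p and empty numerators", {
  u <- make_universe(40, in_class = 1:8)
  dmrs <- dmr_rows(u$bumps, 1:5, "hyper")  # no hypo DMRs at all
  rows <- feature_enrichment(dmrs, u$bumps, u$feats)
  hypo <- rows[rows$direction == "hypo", ]
  expect_true(all(hypo$p_value == 1))
  expect_true(all(hypo$a + hypo$b == 0))
  expect_error(feature_enrichment(
    data.frame(chrom = "chrA", start = 1, end = 2, direction = "hyper"),
    u$bumps, u$feats), "member of the bump-list")
})

test_that("CGI-planted hyper-DMRs rank CGI as the top hyper enrichment", {
  cfg <- small_cfg(seed = 121, true_dmr_count = 0, global_shift_fraction = 0,
                   fragments_per_replicate = 4e4, replicates_per_group = 3)
  out <- simulate_genome(cfg)
  cgis <- out$features[out$features$class == "CGI", ][1:4, ]
  truth <- structure(list(
    dmrs = data.frame(chrom = cgis$chrom, start = cgis$start,
                      end = pmin(cgis$end, cgis$start + 800),
                      direction = "hyper", effect_log2fc = 1.5,
                      baseline = 0.30, in_hotspot = FALSE,
                      stringsAsFactors = FALSE),
    hotspot = NULL), class = "GroundTruth")
  surf <- simulate_methylome(out$genome, out$features, truth, cfg)
  samples <- sim_sample_sheet(cfg)
  frags <- lapply(seq_len(nrow(samples)), function(i)
    filter_fragments(simulate_fragments(out$genome, surf, cfg,
                                        samples$sample_id[i],
                                        samples$group[i]))$fragments)
  names(frags) <- samples$sample_id
  tr <- methylation_tracks(frags, samples, build_coupling(out$genome),
                           out$genome)
  bumps <- build_bump_list(tr, out$genome)
  res <- call_dmrs(bumps, tr)
  expect_gt(nrow(res$dmrs), 0)
  rows <- feature_enrichment(res$dmrs, bumps, out$features)
  hyper <- rows[rows$direction == "hyper", ]
  expect_equal(hyper$feature[1], "CGI")
  expect_lt(hyper$p_value[1], 0.01)
})
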