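test_that("pair-level quality rule: only pairs where neither read reaches 10 are removed", {
  fr <- rbind(toy_frags("chrA", 100, 300, mapq1 = 9, mapq2 = 9),
              toy_frags("chrA", 400, 600, mapq1 = 9, mapq2 = 30),
              toy_frags("chrA", 700, 900, mapq1 = 30, mapq2 = 9),
              toy_frags("chrA", 950, 1100, mapq1 = 10, mapq2 = 0))
  out <- filter_fragments(fr)
  expect_equal(out$tallies[["n_low_mapq"]], 1)
  expect_equal(out$fragments$start, c(400, 700, 950))
})

test_that("improper pairs are removed and tallied", {
  fr <- rbind(toy_frags("chrA", 100, 300, proper = FALSE),
              toy_frags("chrA", 400, 600))
  out <- filter_fragments(fr)
  expect_equal(out$tallies[["n_improper"]], 1)
  expect_equal(out$fragments$start, 400)
})

test_that("identical pairs collapse to exactly one survivor", {
  fr <- rbind(toy_frags("chrA", rep(100, 3), rep(300, 3)),
              toy_frags("chrA", 100, 300, sample_id = "S2"))
  out <- filter_fragments(fr)
  expect_equal(out$tallies[["n_duplicate"]], 2)
  expect_equal(nrow(out$fragments), 2)  # one per sample
})

test_that("filtering is idempotent and rejects malformed records", {
  cfg <- null_cfg(seed = 31, fragments_per_replicate = 5000)
  ds <- simulate_dataset(cfg)
  once <- filter_fragments(ds$fragments[[1]])
  twice <- filter_fragments(once$fragments)
  expect_equal(twice$fragments, once$fragments)
  expect_equal(twice$tallies[["n_kept"]], once$tallies[["n_kept"]])
  bad <- toy_frags("chrA", 500, 400)
  expect_error(filter_fragments(bad), "index 1")
  expect_error(filter_fragments(data.frame(chrom = "chrA")), "missing")
})

test_that("enrichment score is 1 for a tiling and exact for a dense region", {
  ## fragments tiling the whole genome exactly once -> observed = background
  g <- toy_genome(c(chrA = 1000), list(chrA = c(10, 240, 510, 770)))
  tiles <- toy_frags("chrA", seq(0, 900, 100), seq(100, 1000, 100))
  expect_equal(enrichment_score(tiles, g), 1.0)
  ## all fragments inside a region with 3x the genome-wide density
  g2 <- toy_genome(c(chrA = 1000),
                   list(chrA = c(seq(10, 490, length.out = 5),
                                 seq(510, 990, length.out = 15))))
  fr <- toy_frags("chrA", c(500, 600, 750), c(600, 750, 1000))
  obs <- 15 / 500            # hand count: 15 CpGs under 500 covered bp
  expected <- 20 / 1000
  expect_equal(enrichment_score(fr, g2), obs / expected)
  expect_error(enrichment_score(fr[0, ], g2), "empty")
})

test_that("enrichment score depends on composition, not depth", {
  g <- toy_genome(c(chrA = 1000), list(chrA = c(100, 150, 700)))
  fr <- toy_frags("chrA", c(50, 600), c(250, 800))
  expect_equal(enrichment_score(rbind(fr, fr, fr), g),
               enrichment_score(fr, g))
})

test_that("CpG coverage fraction and fold histogram are exact on toys", {
  g <- toy_genome(c(chrA = 200), list(chrA = c(10, 60, 110)))
  ## no fragments: all mass at fold 0
  none <- cpg_coverage(toy_frags("chrA", numeric(0), numeric(0)), g)
  expect_equal(none$fraction, 0)
  expect_equal(unname(none$histogram), 1)
  ## one fragment spanning every CpG
  all1 <- cpg_coverage(toy_frags("chrA", 0, 150), g)
  expect_equal(all1$fraction, 1)
  ## half-open: a fragment [0,100) covers CpGs 10 and 60 but not 110
  part <- cpg_coverage(toy_frags("chrA", 0, 100), g)
  expect_equal(part$fraction, 2 / 3)
  expect_equal(sum(part$histogram), 1)
  ## fold histogram counts overlapping fragments per CpG
  two <- cpg_coverage(toy_frags("chrA", c(0, 5), c(100, 100)), g)
  expect_equal(unname(two$histogram),
               c(1 / 3, 0, 2 / 3))  # CpG 110 at 0x, CpGs 10 and 60 at 2x
})

test_that("replicate correlation is 1 against itself and symmetric", {
  cfg <- null_cfg(seed = 41, fragments_per_replicate = 10000)
  ds <- simulate_dataset(cfg)
  f <- lapply(ds$fragments[1:2], function(x) filter_fragments(x)$fragments)
  expect_equal(replicate_correlation(f[[1]], f[[1]], ds$genome), 1.0)
  r12 <- replicate_correlation(f[[1]], f[[2]], ds$genome)
  r21 <- replicate_correlation(f[[2]], f[[1]], ds$genome)
  expect_equal(r12, r21)
  expect_gt(r12, 0.5)  # same capture surface
})

test_that("two uniform samples on a CpG-free genome are uncorrelated", {
  g <- toy_genome(c(chrA = 100000), list(chrA = integer(0)))
  set.seed(77)
  mk <- function(id) {
    s <- sort(round(runif(2000, 0, 99800)))
    toy_frags("chrA", s, s + 200, sample_id = id)
  }
  r <- replicate_correlation(mk("A"), mk("B"), g)
  expect_lt(abs(r), 0.2)
})

test_that("window threshold excludes sparse windows before correlating", {
  ## fragments concentrated so only some windows reach 5 reads combined
  g <- toy_genome(c(chrA = 2000), list(chrA = integer(0)))
  a <- toy_frags("chrA", c(0, 10, 20, 600, 1500), c(100, 110, 120, 700, 1600))
  b <- toy_frags("chrA", c(5, 15, 25, 610, 1510), c(105, 115, 125, 710, 1610),
                 sample_id = "S2")
  ## "each" mode demands 5 in both samples: nothing qualifies
  expect_true(is.na(replicate_correlation(a, b, g, min_reads_mode = "each")))
  expect_error(replicate_correlation(
    toy_frags("chrX", 0, 100), b, g), "absent")
})

test_that("qc report carries tallies, scores and a symmetric correlation matrix", {
  cfg <- null_cfg(seed = 51, fragments_per_replicate = 8000)
  ds <- simulate_dataset(cfg)
  qc <- qc_report(ds$fragments, ds$genome)
  ps <- qc$per_sample
  expect_true(all(ps$n_kept <= ps$n_input))
  expect_true(all(ps$enrichment_score > 0))
  expect_true(all(ps$cpg_coverage >= 0 & ps$cpg_coverage <= 1))
  expect_equal(qc$correlations, t(qc$correlations))
  expect_equal(unname(diag(qc$correlations)), rep(1, nrow(ps)))
})
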