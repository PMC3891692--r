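dense_genome <- function(nbins = 40)
  toy_genome(c(chrA = nbins * 50),
             list(chrA = seq(25, nbins * 50 - 25, by = 50)))

bump_tracks <- function(a, b) {
  list(A1 = toy_track(a, "A1", "Young"), B1 = toy_track(b, "B1", "Old"))
}

test_that("bump-list keeps maximal nonzero runs at the 10-read boundary", {
  g <- dense_genome(6)
  ## an isolated bin with summed count 10 is kept; with 9 it is not
  b10 <- build_bump_list(bump_tracks(c(0, 6, 0, 0, 0, 0),
                                     c(0, 4, 0, 0, 0, 0)), g)
  expect_equal(nrow(b10$regions), 1)
  expect_equal(b10$regions$start, 50)
  expect_equal(b10$regions$end, 100)
  expect_equal(unname(b10$counts[1, ]), c(6, 4))
  b9 <- build_bump_list(bump_tracks(c(0, 5, 0, 0, 0, 0),
                                    c(0, 4, 0, 0, 0, 0)), g)
  expect_equal(nrow(b9$regions), 0)
})

test_that("bump-list merges adjacent nonzero bins before thresholding", {
  g <- dense_genome(6)
  ## summed counts per bin: 0,3,4,0,2,0 -> runs [2,3] (7) and [5] (2)
  tr <- bump_tracks(c(0, 2, 2, 0, 1, 0), c(0, 1, 2, 0, 1, 0))
  none <- build_bump_list(tr, g, min_total_reads = 10)
  expect_equal(nrow(none$regions), 0)
  five <- build_bump_list(tr, g, min_total_reads = 5)
  expect_equal(nrow(five$regions), 1)
  expect_equal(c(five$regions$start, five$regions$end), c(50, 150))
  expect_equal(five$regions$total, 7)
  zero <- build_bump_list(bump_tracks(rep(0, 6), rep(0, 6)), g)
  expect_equal(nrow(zero$regions), 0)
  expect_error(build_bump_list(list(toy_track(1:6, "A1", "Young"),
                                    toy_track(1:3, "B1", "Old",
                                              bin_size = 100)), g),
               "bin grids")
})

test_that("median-of-ratios size factors match closed forms", {
  cnt <- matrix(c(10, 40, 25, 10, 40, 25), ncol = 2)
  colnames(cnt) <- c("A", "B")
  expect_equal(unname(estimate_size_factors(cnt)), c(1, 1))
  cnt2 <- cbind(A = c(10, 40, 26), B = 2 * c(10, 40, 26))
  expect_equal(unname(estimate_size_factors(cnt2)),
               c(1 / sqrt(2), sqrt(2)))
  ## permutation of regions leaves factors unchanged
  expect_equal(estimate_size_factors(cnt2[c(3, 1, 2), ]),
               estimate_size_factors(cnt2))
  ## product is 1 even for unstructured counts
  set.seed(5)
  cnt3 <- matrix(rpois(60, 20) + 1, ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(prod(estimate_size_factors(cnt3)), 1)
  expect_error(estimate_size_factors(cbind(A = c(0, 0), B = c(1, 2))),
               "all-zero")
})

test_that("identical normalized counts give p = 1 and zero fold change", {
  r <- test_region(c(5, 5), c(5, 5), c(1, 1), c(1, 1), alpha = 0.01)
  expect_equal(r$p_value, 1)
  expect_equal(r$log2fc, 0)
})

test_that("the vanishing-dispersion limit matches a binomial exact test", {
  ka <- c(2, 3); kb <- c(20, 25)
  r <- test_region(ka, kb, c(1, 1), c(1, 1), alpha = 1e-12)
  ## oracle: conditional on the total, allocations are binomial; two-sided
  ## p sums allocations no more likely than the observed one
  ktot <- sum(ka) + sum(kb)
  pr <- dbinom(0:ktot, ktot, 0.5)
  p_oracle <- sum(pr[pr <= pr[sum(ka) + 1] * (1 + 1e-7)])
  expect_lt(abs(r$p_value - p_oracle), 1e-6)
})

test_that("conditioned NB p equals direct allocation enumeration for totals <= 40", {
  set.seed(11)
  for (i in 1:25) {
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    ka <- rpois(na, sample(1:5, 1)); kb <- rpois(nb, sample(1:5, 1))
    if (sum(ka) + sum(kb) == 0 || sum(ka) + sum(kb) > 40) next
    sfa <- runif(na, 0.7, 1.4); sfb <- runif(nb, 0.7, 1.4)
    alpha <- sample(c(1e-8, 0.01, 0.2, 1), 1)
    r <- test_region(ka, kb, sfa, sfb, alpha)
    expect_lt(abs(r$p_value - nb_test_oracle(ka, kb, sfa, sfb, alpha)),
              1e-9)
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
    ## swapping groups preserves p and negates the fold change
    s <- test_region(kb, ka, sfb, sfa, alpha)
    expect_equal(s$p_value, r$p_value, tolerance = 1e-12)
    expect_equal(s$log2fc, -r$log2fc, tolerance = 1e-12)
  }
  expect_error(test_region(c(1), c(2), 1, 1, alpha = NaN), "dispersion")
})

test_that("fold-change direction and pseudocount behave at zero counts", {
  r <- test_region(c(0, 0), c(8, 12), c(1, 1), c(1, 1), alpha = 0.01)
  expect_gt(r$log2fc, 0)
  expect_equal(r$log2fc, log2((10 + 0.5) / 0.5))
  expect_lt(r$p_value, 0.05)
})

test_that("BH adjustment equals the hand-computed step-up on the 5-element case", {
  p <- c(0.001, 0.01, 0.02, 0.5, 0.9)
  expect_equal(bh_oracle(p), c(0.005, 0.025, 0.02 * 5 / 3, 0.625, 0.9))
  expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
})

test_that("BH equals a brute-force oracle on random vectors up to length 10", {
  set.seed(23)
  for (n in c(1, 2, 5, 10)) for (rep in 1:20) {
    p <- round(runif(n), 3)
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
})

test_that("dispersion trend is fitted and assigned to every region", {
  set.seed(31)
  q <- runif(300, 5, 300)
  alpha_true <- 0.02
  counts <- t(vapply(q, function(m)
    rnbinom(6, mu = m, size = 1 / alpha_true), numeric(6)))
  colnames(counts) <- paste0("s", 1:6)
  groups <- rep(c("Young", "Old"), each = 3)
  sf <- rep(1, 6)
  disp <- estimate_dispersions(counts, sf, groups)
  expect_length(disp$alpha, 300)
  expect_true(all(disp$alpha >= 1e-8))
  ## fitted dispersion recovers the simulated magnitude
  expect_gt(median(disp$alpha), alpha_true / 3)
  expect_lt(median(disp$alpha), alpha_true * 3)
})

test_that("calling returns no DMRs when both groups share counts", {
  g <- dense_genome(12)
  cnt <- c(0, 8, 9, 0, 0, 12, 4, 0, 0, 7, 6, 0)
  tr <- list(A1 = toy_track(cnt, "A1", "Young"),
             A2 = toy_track(cnt, "A2", "Young"),
             B1 = toy_track(cnt, "B1", "Old"),
             B2 = toy_track(cnt, "B2", "Old"))
  bumps <- build_bump_list(tr, g)
  res <- call_dmrs(bumps, tr)
  expect_equal(nrow(res$dmrs), 0)
  expect_true(all(res$table$p_value == 1))
  expect_true(all(res$table$fdr >= res$table$p_value - 1e-12))
  expect_error(call_dmrs(build_bump_list(
    list(A1 = toy_track(rep(0, 12), "A1", "Young"),
         B1 = toy_track(rep(0, 12), "B1", "Old")), g)), "empty")
})

test_that("DMR count is monotone nondecreasing in the FDR threshold", {
  cfg <- small_cfg(seed = 91, true_dmr_count = 6, replicates_per_group = 3,
                   fragments_per_replicate = 5e4)
  ds <- simulate_dataset(cfg)
  tr <- sim_tracks(ds)
  bumps <- build_bump_list(tr, ds$genome)
  n <- vapply(c(0.01, 0.05, 0.2, 0.5), function(thr)
    nrow(call_dmrs(bumps, tr, fdr_threshold = thr)$dmrs), numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("heatmap rows span [0,1] and cover all three groups", {
  cfg <- small_cfg(seed = 95, groups = c("Young", "Mid", "Old"),
                   true_dmr_count = 4, fragments_per_replicate = 4e4)
  ds <- simulate_dataset(cfg)
  tr <- sim_tracks(ds)
  bumps <- build_bump_list(tr, ds$genome)
  res <- call_dmrs(bumps, tr)
  if (nrow(res$dmrs) > 0) {
    expect_equal(ncol(res$heatmap), length(tr))
    expect_true(all(apply(res$heatmap, 1, min) == 0))
    expect_true(all(apply(res$heatmap, 1, max) <= 1))
  }
})

test_that("gene association respects the inclusive 100 kb cut-off", {
  feats <- feature_set(data.frame(
    chrom = "chrA",
    start = c(500000, 700000, 900000),
    end = c(510000, 710000, 910000),
    class = "gene", name = c("gene_A", "gene_B", "gene_C")))
  ## DMR inside gene_A: distance 0
  inside <- data.frame(chrom = "chrA", start = 502000, end = 503000)
  out <- associate_genes(inside, feats)
  expect_equal(out$dmrs$genes, "gene_A")
  expect_equal(out$dmrs$gene_distances, "0")
  ## boundary: gene start exactly cutoff bp after the DMR end is kept,
  ## one bp further is not
  one_gene <- feature_set(data.frame(chrom = "chrA", start = 700000,
                                     end = 710000, class = "gene",
                                     name = "gene_B"))
  at <- data.frame(chrom = "chrA", start = 599000, end = 600000)
  expect_equal(associate_genes(at, one_gene)$dmrs$genes, "gene_B")
  expect_equal(associate_genes(at, one_gene)$dmrs$gene_distances, "100000")
  just_past <- data.frame(chrom = "chrA", start = 598999, end = 599999)
  expect_equal(associate_genes(just_past, one_gene)$dmrs$genes, "")
  ## three DMRs, two associable -> fraction 2/3; nearest gene listed first
  dmrs <- data.frame(chrom = "chrA",
                     start = c(505000, 760000, 100),
                     end = c(506000, 761000, 1100))
  res <- associate_genes(dmrs, feats)
  expect_equal(res$fraction_associated, 2 / 3)
  expect_equal(strsplit(res$dmrs$genes[2], ",")[[1]][1], "gene_B")
})
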