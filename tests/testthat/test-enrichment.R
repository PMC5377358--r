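test_that("density tracks count element starts per bin", {
  expect_equal(binned_density_track(c(100, 150, 5100), 10000, 5000)[1:2], c(2, 1))
  expect_equal(binned_density_track(integer(0), 10000, 5000), c(0, 0))
  expect_equal(binned_density_track(c(1, 9999), 10000, 10000), 2)
  expect_error(binned_density_track(c(100, 10000), 10000, 5000), "beyond")
})

test_that("Spearman track correlation has the rank-correlation properties", {
  set.seed(4)
  a <- rpois(50, 5)
  b <- rpois(50, 5)
  expect_equal(spearman_track_correlation(a, a), 1)
  v <- sort(sample(100, 30))  # distinct, increasing
  expect_equal(spearman_track_correlation(v, rev(v)), -1)
  expect_equal(spearman_track_correlation(a, b), spearman_track_correlation(b, a))
  # invariant under strictly monotone transforms
  expect_equal(spearman_track_correlation(exp(a), b),
               spearman_track_correlation(a, b))
  expect_warning(rho <- spearman_track_correlation(rep(2, length(a)), a),
                 "constant")
  expect_true(is.na(rho))
  expect_error(spearman_track_correlation(a, b[-1]), "equal length")
})

test_that("TSS flank profiles emit 18 windows per side at the 3/1/20 kb defaults", {
  gene <- make_gene("g1", exon_starts = 50000L, exon_ends = 55000L)
  reps <- data.frame(chrom = "chrX", start = 49500L, end = 49650L,
                     family = "ALU")
  prof <- tss_flank_profile(gene, reps, "Alu")
  expect_equal(sum(prof$side == "upstream"), 18)
  expect_equal(sum(prof$side == "downstream"), 18)
  # element at TSS - 500 is counted only in upstream windows whose distance
  # range (off, off + 3000] covers 500 -- the nearest window alone
  up <- prof[prof$side == "upstream", ]
  expect_equal(up$count, c(1, rep(0, 17)))
  # no family elements within the flank -> all-zero profile
  prof0 <- tss_flank_profile(gene, reps, "B2")
  expect_true(all(prof0$count == 0))
})

test_that("flank window counts agree with a brute-force distance oracle", {
  set.seed(9)
  cfg <- run_config()
  for (strand in c("+", "-")) {
    gene <- make_gene("g1", strand = strand,
                      exon_starts = 100000L, exon_ends = 105000L)
    starts <- sort(sample(seq(gene$tss - 25000, gene$tss + 25000), 120))
    reps <- data.frame(chrom = "chrX", start = starts, end = starts + 150,
                       family = "B4")
    prof <- tss_flank_profile(gene, reps, "B4", cfg)
    # oracle: signed distance along the transcription axis; upstream window k
    # holds distances (off, off+window], downstream window k holds
    # [off, off+window), off = (k-1)*step
    axis <- if (strand == "+") starts - gene$tss else gene$tss - starts
    for (side in c("upstream", "downstream")) {
      expected <- vapply(0:17 * 1000, function(off) {
        if (side == "upstream") sum(-axis > off & -axis <= off + 3000)
        else sum(axis >= off & axis < off + 3000)
      }, numeric(1))
      expect_equal(prof$count[prof$side == side], expected)
    }
  }
})

test_that("each flanking element is counted at most 3 times across windows", {
  set.seed(21)
  gene <- make_gene("g1", exon_starts = 100000L, exon_ends = 105000L)
  starts <- sort(sample(seq(gene$tss - 19999, gene$tss - 1), 60))
  reps <- data.frame(chrom = "chrX", start = starts, end = starts + 150,
                     family = "ID")
  up <- tss_flank_profile(gene, reps, "ID")
  up <- up[up$side == "upstream", ]
  expect_gte(sum(up$count), length(starts))          # each counted >= once
  expect_lte(sum(up$count), 3 * length(starts))      # overlap factor <= 3
})

test_that("intronic density normalises copies per 3 kb of intron", {
  gene <- make_gene("g1", exon_starts = c(0L, 4000L, 10000L),
                    exon_ends = c(1000L, 7000L, 13000L))
  # introns [1000,4000) and [7000,10000): 6 kb total; plant 4 copies inside
  reps <- data.frame(chrom = "chrX",
                     start = c(1500L, 2500L, 7500L, 9500L, 500L, 12000L),
                     end = c(1650L, 2650L, 7650L, 9650L, 650L, 12150L),
                     family = "ALU")
  expect_equal(intronic_density(gene, reps, "Alu"), 4 / (6000 / 3000))
  expect_equal(intronic_density(gene, reps, "B2"), 0)
  single_exon <- make_gene("g2", exon_starts = 0L, exon_ends = 1000L)
  expect_true(is.na(intronic_density(single_exon, reps, "Alu")))
  # invariant under intron re-ordering (same intervals, shuffled exon list is
  # invalid input, so compare two genes with swapped intron lengths instead)
  gene_sw <- make_gene("g3", exon_starts = c(0L, 4000L, 10000L),
                       exon_ends = c(1000L, 7000L, 13000L))
  expect_equal(intronic_density(gene_sw, reps, "Alu"),
               intronic_density(gene, reps, "Alu"))
})

test_that("group comparison reports rank-sum p-values and rejects tiny groups", {
  set.seed(14)
  a <- rpois(20, 6)
  res_same <- group_comparison(a, a)
  expect_gt(res_same$p_value, 0.9)
  expect_equal(res_same$summary$mean[1], res_same$summary$mean[2])
  b <- a + 2 * stats::sd(a)
  res_shift <- group_comparison(b, a)
  expect_lt(res_shift$p_value, 0.05)
  expect_gt(res_shift$summary$mean[1], res_shift$summary$mean[2])
  expect_error(group_comparison(c(1, 2), a), "at least 3")
  # t-test variant runs and agrees on direction
  res_t <- group_comparison(b, a, test = "t")
  expect_lt(res_t$p_value, 0.05)
})
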