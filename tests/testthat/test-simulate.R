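test_that("generators are byte-identical under a fixed seed", {
  p <- sim_params(n_genes = 30, chrom_length_bp = 6e5, rng_seed = 17)
  a1 <- simulate_annotation(p)
  a2 <- simulate_annotation(p)
  expect_identical(a1, a2)
  b1 <- simulate_basecalls(p, "XiXa_mutant", a1, "m1")
  b2 <- simulate_basecalls(p, "XiXa_mutant", a1, "m1")
  expect_identical(b1, b2)
  # different sample labels give different noise
  b3 <- simulate_basecalls(p, "XiXa_mutant", a1, "m2")
  expect_false(identical(b1$countA, b3$countA))
  expect_error(simulate_basecalls(p, "XaXi", a1), "unknown genotype")
  expect_error(sim_params(n_genes = 100, chrom_length_bp = 5e5),
               "too short")
})

test_that("error-free emission puts reads only on the two allele bases", {
  p <- sim_params(n_genes = 20, chrom_length_bp = 5e5, error_rate = 0,
                  rng_seed = 2)
  ann <- simulate_annotation(p)
  bc <- simulate_basecalls(p, "XiXa_control", ann, "c1")
  counts <- as.matrix(bc[, c("countA", "countC", "countG", "countT")])
  allele_mask <- outer(rep(TRUE, nrow(bc)), c("A", "C", "G", "T"), function(i, b)
    b == bc$allele129 | b == bc$alleleCast)
  expect_true(all(counts[!allele_mask] == 0))
  # silenced genes in the control emit exactly zero 129 reads (leakage 0)
  tg <- ann$truth$genes
  sil <- ann$snps$gene_name %in% tg$gene_name[tg$status == "silenced"] &
    ann$snps$panel == "coding"
  c129 <- counts[cbind(seq_len(nrow(bc)),
                       match(bc$allele129, c("A", "C", "G", "T")))]
  expect_true(all(c129[sil] == 0))
})

test_that("pre-XCI cells show balanced allelic fractions at study coverage", {
  p <- sim_params(n_genes = 40, chrom_length_bp = 8e5, rng_seed = 5)
  ann <- simulate_annotation(p)
  bc <- simulate_basecalls(p, "XaXa", ann, "es1")
  # restrict to SNPs whose pre-XCI truth is biallelic (coding panel; a
  # non-coding SNP can be constitutively 129-silenced)
  bc <- bc[bc$snp_id %in% ann$snps$snp_id[ann$snps$panel == "coding"], ]
  at <- estimate_and_correct(bc)
  frac <- at$c129 / (at$c129 + at$ccast)
  expect_gte(mean(abs(frac - 0.5) <= 0.02), 0.95)
})

test_that("read totals scale linearly with mean coverage", {
  p1 <- sim_params(n_genes = 20, chrom_length_bp = 5e5, mean_coverage = 2000,
                   rng_seed = 4)
  p2 <- sim_params(n_genes = 20, chrom_length_bp = 5e5, mean_coverage = 8000,
                   rng_seed = 4)
  ann <- simulate_annotation(p1)
  tot1 <- rowSums(simulate_basecalls(p1, "XaXa", ann, "x")[, 6:9])
  tot2 <- rowSums(simulate_basecalls(p2, "XaXa", ann, "x")[, 6:9])
  expect_equal(mean(tot2) / mean(tot1), 4, tolerance = 0.05)
})

test_that("SINE coupling enriches upstream density of reactivated genes ~3x", {
  ratios <- vapply(1:20, function(s) {
    p <- sim_params(n_genes = 80, chrom_length_bp = 1.6e6, sine_coupling = 3,
                    rng_seed = 100 + s)
    ann <- simulate_annotation(p)
    sine <- ann$repeats[ann$repeats$family %in% c("ALU", "B2", "ID", "B4"), ]
    upstream_count <- function(g) {
      tss <- ann$genes$tss[ann$genes$gene_name == g]
      sum(sine$start >= tss - 10000 & sine$start < tss)
    }
    tg <- ann$truth$genes
    re <- vapply(tg$gene_name[tg$status == "reactivated"], upstream_count, 1)
    sil <- vapply(tg$gene_name[tg$status == "silenced"], upstream_count, 1)
    c(mean(re), mean(sil))
  }, numeric(2))
  ratio <- mean(ratios[1, ]) / mean(ratios[2, ])
  expect_gt(ratio, 2)
  expect_lt(ratio, 4)
})

test_that("without coupling, upstream SINE density is equal in expectation", {
  counts <- vapply(1:20, function(s) {
    p <- sim_params(n_genes = 80, chrom_length_bp = 1.6e6, sine_coupling = 1,
                    rng_seed = 300 + s)
    ann <- simulate_annotation(p)
    sine <- ann$repeats[ann$repeats$family %in% c("ALU", "B2", "ID", "B4"), ]
    tg <- ann$truth$genes
    upstream_count <- function(g) {
      tss <- ann$genes$tss[ann$genes$gene_name == g]
      sum(sine$start >= tss - 10000 & sine$start < tss)
    }
    re <- vapply(tg$gene_name[tg$status == "reactivated"], upstream_count, 1)
    sil <- vapply(tg$gene_name[tg$status == "silenced"], upstream_count, 1)
    c(mean(re), mean(sil))
  }, numeric(2))
  # equal in expectation: pooled means within 15% of each other
  expect_equal(mean(counts[1, ]), mean(counts[2, ]), tolerance = 0.15)
})

test_that("differentiation tables encode the designed time-course contrasts", {
  p <- sim_params(n_genes = 40, chrom_length_bp = 8e5, error_rate = 0,
                  rng_seed = 6)
  ann <- simulate_annotation(p)
  dd <- simulate_differentiation(p, ann)
  expect_named(dd, c("day0", "day4_control", "day4_inhibited"))
  tg <- ann$truth$genes
  get_c129 <- function(df) {
    counts <- as.matrix(df[, c("countA", "countC", "countG", "countT")])
    counts[cbind(seq_len(nrow(df)), match(df$allele129, c("A", "C", "G", "T")))]
  }
  snp_gene <- ann$snps$gene_name[ann$snps$panel == "coding"]
  # XCI-subject non-impaired genes: 129 silenced in both day-4 samples
  quiet <- snp_gene %in% tg$gene_name[tg$xci_subject & !tg$impaired]
  expect_true(all(get_c129(dd$day4_control)[quiet] == 0))
  expect_true(all(get_c129(dd$day4_inhibited)[quiet] == 0))
  # impaired genes recover 129 expression only under inhibition
  imp <- snp_gene %in% tg$gene_name[tg$impaired]
  expect_true(all(get_c129(dd$day4_control)[imp] == 0))
  expect_gt(mean(get_c129(dd$day4_inhibited)[imp]), 0)
  # escapees stay partially biallelic throughout
  esc <- snp_gene %in% tg$gene_name[tg$status == "escapee"]
  if (any(esc)) {
    expect_true(all(get_c129(dd$day4_control)[esc] > 0))
    expect_true(all(get_c129(dd$day4_inhibited)[esc] > 0))
  }
  # day 0 is biallelic everywhere
  frac0 <- get_c129(dd$day0) / rowSums(dd$day0[, 6:9])
  expect_true(all(abs(frac0 - 0.5) < 0.05))
})

test_that("ground-truth labels are consistent with the emitted counts", {
  p <- sim_params(n_genes = 40, chrom_length_bp = 8e5, error_rate = 0,
                  rng_seed = 9)
  ann <- simulate_annotation(p)
  mut <- simulate_basecalls(p, "XiXa_mutant", ann, "m1")
  counts <- as.matrix(mut[, c("countA", "countC", "countG", "countT")])
  c129 <- counts[cbind(seq_len(nrow(mut)),
                       match(mut$allele129, c("A", "C", "G", "T")))]
  tg <- ann$truth$genes
  coding <- ann$snps$panel == "coding"
  sil <- coding & ann$snps$gene_name %in% tg$gene_name[tg$status == "silenced"]
  re <- coding & ann$snps$gene_name %in% tg$gene_name[tg$status == "reactivated"]
  expect_true(all(c129[sil] == 0))
  expect_gt(mean(c129[re] > 0), 0.99)
})
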