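test_that("SNP counts aggregate to genes by exon overlap with zero-gene removal", {
  genes <- rbind(
    make_gene("geneA", exon_starts = c(100L, 500L), exon_ends = c(200L, 600L)),
    make_gene("geneB", exon_starts = 1000L, exon_ends = 1100L)
  )
  at <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4"),
    chrom = "chrX",
    pos = c(150L, 550L, 1050L, 700L),  # s4 is intergenic
    strand = "+", sample_id = "m1",
    c129 = c(100, 50, 0, 7), ccast = c(0, 10, 0, 7),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_gene_counts(at, genes, seed = 1)
  expect_equal(agg$gene_name, "geneA")  # geneB had (0,0): un-allelotyped
  expect_equal(agg$c129, 150)
  expect_equal(agg$ccast, 10)
  expect_equal(agg$n_snps, 2L)
  expect_false(agg$ambiguous)
})

test_that("representative gene IDs are chosen per gene name, deterministically", {
  genes <- rbind(
    make_gene("geneA", gene_id = "uc1.1", exon_starts = 100L, exon_ends = 200L),
    make_gene("geneA", gene_id = "uc1.2", exon_starts = 100L, exon_ends = 250L)
  )
  at <- data.frame(snp_id = "s1", chrom = "chrX", pos = 150L, strand = "+",
                   sample_id = "m1", c129 = 20, ccast = 30,
                   stringsAsFactors = FALSE)
  a1 <- aggregate_gene_counts(at, genes, seed = 99)
  a2 <- aggregate_gene_counts(at, genes, seed = 99)
  expect_identical(a1$representative_gene_id, a2$representative_gene_id)
  expect_true(a1$representative_gene_id %in% c("uc1.1", "uc1.2"))
  # gene_name level combined the two isoforms' shared SNP once per ID
  expect_equal(a1$c129, 40)
  # gene_id level keeps the isoforms separate
  aid <- aggregate_gene_counts(at, genes, level = "gene_id", seed = 99)
  expect_equal(sort(aid$gene_id), c("uc1.1", "uc1.2"))
  expect_equal(aid$c129, c(20, 20))
})

test_that("a SNP in two gene names is assigned to both and flagged ambiguous", {
  genes <- rbind(
    make_gene("geneA", exon_starts = 100L, exon_ends = 300L),
    make_gene("geneB", exon_starts = 200L, exon_ends = 400L)
  )
  at <- data.frame(snp_id = "s1", chrom = "chrX", pos = 250L, strand = "+",
                   sample_id = "m1", c129 = 5, ccast = 50,
                   stringsAsFactors = FALSE)
  agg <- aggregate_gene_counts(at, genes, seed = 1)
  expect_equal(sort(agg$gene_name), c("geneA", "geneB"))
  expect_true(all(agg$ambiguous))
})

test_that("reactivation calls reproduce the two-criterion rule on worked examples", {
  cfg <- run_config()
  ctrl <- make_gene_counts(c("g1", "g2", "g3"),
                           c129 = c(0, 0, 0), ccast = c(8000, 8000, 8000))
  mut <- make_gene_counts(c("g1", "g2", "g3"),
                          c129 = c(90, 12, 900000), ccast = c(2000, 9000, 10))
  calls <- call_reactivation(mut, ctrl, cfg)
  # g1: r_mut = 100/2010, r_ctrl = 10/8010, fold ~ 39.9, biallelic -> called
  expect_equal(calls$r_mut[1], 100 / 2010)
  expect_equal(calls$fold_vs_control[1], (100 / 2010) / (10 / 8010))
  expect_true(calls$reactivated[1])
  # g2: fold ~ 1.96 < 3 -> not called
  expect_equal(calls$r_mut[2], 22 / 9010)
  expect_false(calls$reactivated[2])
  # g3: fold huge but r_mut = 900010/20 > 100 violates the biallelic bound
  expect_true(calls$fold_vs_control[3] >= 3)
  expect_false(calls$reactivated[3])
})

test_that("raising the fold threshold never enlarges the reactivated set", {
  set.seed(7)
  n <- 40
  ctrl <- make_gene_counts(sprintf("g%02d", 1:n),
                           c129 = sample(0:50, n, TRUE),
                           ccast = sample(0:9000, n, TRUE))
  mut <- make_gene_counts(sprintf("g%02d", 1:n),
                          c129 = sample(0:2000, n, TRUE),
                          ccast = sample(0:9000, n, TRUE))
  sets <- lapply(c(1.5, 3, 6, 12), function(f) {
    cfg <- run_config(fold_threshold = f)
    calls <- call_reactivation(mut, ctrl, cfg)
    calls$gene_name[calls$reactivated]
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("escapee exemption and control-biallelic exclusion behave as documented", {
  classes <- data.frame(gene_name = c("esc1", "gx"),
                        class = c("escapee_constitutive", "coding"))
  ctrl <- make_gene_counts(c("esc1", "gx"), c129 = c(500, 500),
                           ccast = c(4000, 4000))   # both biallelic in control
  mut <- make_gene_counts(c("esc1", "gx"), c129 = c(2500, 2500),
                          ccast = c(4000, 4000))    # ~4.8-fold increase
  plain <- call_reactivation(mut, ctrl, gene_classes = classes)
  expect_true(all(plain$reactivated))
  strict <- call_reactivation(mut, ctrl, gene_classes = classes,
                              exclude_control_biallelic = TRUE)
  expect_true(strict$reactivated[strict$gene_name == "esc1"])
  expect_false(strict$reactivated[strict$gene_name == "gx"])
  # mutant-only gene is skipped with a warning
  mut2 <- rbind(mut, make_gene_counts("orphan", 100, 100))
  expect_warning(call_reactivation(mut2, ctrl), "orphan")
})

test_that("frequently reactivated genes require calls in >= min_mutants lines", {
  calls <- data.frame(
    gene_name = c("a", "a", "b", "c", "c", "c"),
    sample_id = c("m1", "m2", "m1", "m1", "m2", "m3"),
    reactivated = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  expect_equal(frequent_reactivation(calls), c("a", "c"))
  expect_equal(frequent_reactivation(calls, min_mutants = 1), c("a", "b", "c"))
  expect_equal(frequent_reactivation(calls, min_mutants = 3), character(0))
})

test_that("long-term culture comparison labels every transition", {
  t0 <- data.frame(gene_name = c("a", "b", "c", "d"),
                   reactivated = c(TRUE, TRUE, FALSE, FALSE))
  t1 <- data.frame(gene_name = c("a", "b", "c", "d"),
                   reactivated = c(TRUE, FALSE, TRUE, FALSE))
  res <- compare_longterm(t0, t1)
  expect_equal(res$counts[["stable_on"]], 1L)
  expect_equal(res$counts[["lost"]], 1L)
  expect_equal(res$counts[["gained"]], 1L)
  expect_equal(res$counts[["stable_off"]], 1L)
  same <- compare_longterm(t0, t0)
  expect_equal(same$counts[["gained"]] + same$counts[["lost"]], 0L)
})
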