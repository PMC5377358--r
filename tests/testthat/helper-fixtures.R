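# Small fixture builders shared across test files.

make_basecalls <- function(snp_id, sample_id, counts, a129, acast,
                           chrom = "chrX", pos = 100L, strand = "+") {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, strand = strand,
             sample_id = sample_id,
             countA = counts[1], countC = counts[2],
             countG = counts[3], countT = counts[4],
             allele129 = a129, alleleCast = acast,
             stringsAsFactors = FALSE)
}

make_gene <- function(gene_name = "g1", gene_id = paste0(gene_name, ".1"),
                      chrom = "chrX", strand = "+",
                      exon_starts = c(1000L, 3000L),
                      exon_ends = c(1500L, 3500L),
                      class = "coding") {
  tss <- if (strand == "+") exon_starts[1] else exon_ends[length(exon_ends)] - 1L
  data.frame(gene_name = gene_name, gene_id = gene_id, chrom = chrom,
             strand = strand, tss = tss,
             exon_starts = paste(exon_starts, collapse = ","),
             exon_ends = paste(exon_ends, collapse = ","),
             class = class, stringsAsFactors = FALSE)
}

make_gene_counts <- function(gene_name, c129, ccast, sample_id = "s") {
  data.frame(gene_name = gene_name,
             representative_gene_id = paste0(gene_name, ".1"),
             sample_id = sample_id, c129 = c129, ccast = ccast,
             n_snps = 1L, ambiguous = FALSE, stringsAsFactors = FALSE)
}

make_snp_table <- function(pos, strand = "+", region = "intergenic",
                           atg_score = 0L, chrom = "chrX") {
  n <- length(pos)
  data.frame(snp_id = sprintf("snp%03d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos),
             strand = rep_len(strand, n), region = rep_len(region, n),
             atg_score = rep_len(as.integer(atg_score), n),
             stringsAsFactors = FALSE)
}

# Does the boundary-proximal region of the subtractive log map carry more
# signal than the TAD interiors? Used by the 5C tests.
boundary_exceeds_interior <- function(sim, bin = 4, halfwidth = 4) {
  tot <- mean(c(sum(sim$control$values), sum(sim$treated$values)))
  L <- subtract_and_log(depth_normalize(sim$treated, tot),
                        depth_normalize(sim$control, tot), bin = bin)
  n_frag <- nrow(sim$control$values)
  frag_bin <- ceiling(seq_len(n_frag) / bin)
  bbins <- unique(frag_bin[abs(seq_len(n_frag) - sim$tad_boundary) <= halfwidth])
  nb <- nrow(L$values)
  near <- matrix(FALSE, nb, nb)
  near[bbins, bbins] <- TRUE
  mean(abs(L$values[near])) > mean(abs(L$values[!near]))
}
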