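#' Binned density track along a chromosome
#'
#' Counts elements per fixed-size bin; an element is assigned to the bin
#' containing its start coordinate (for genes or SNPs, pass TSS / SNP
#' positions). Start-assignment counts each element exactly once per track.
#'
#' @param positions Integer vector of 0-based start coordinates.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @return Numeric vector of per-bin counts, length `ceiling(chrom_length /
#'   bin_size)`.
#' @export
binned_density_track <- function(positions, chrom_length, bin_size) {
  stopifnot(bin_size > 0, chrom_length > 0)
  if (length(positions) && (any(positions < 0) || any(positions >= chrom_length)))
    stop("element position beyond chromosome bounds")
  n_bins <- ceiling(chrom_length / bin_size)
  tabulate(positions %/% bin_size + 1L, nbins = n_bins)
}

#' Spearman correlation between two density tracks
#'
#' Rank correlation with average ranks for ties. A constant track has no
#' rank variation; the correlation is undefined and `NA` is returned with a
#' warning.
#'
#' @param track_a,track_b Equal-length numeric vectors.
#' @return Spearman's rho, or `NA` for a constant track.
#' @export
spearman_track_correlation <- function(track_a, track_b) {
  if (length(track_a) != length(track_b))
    stop("tracks must have equal length")
  if (stats::sd(track_a) == 0 || stats::sd(track_b) == 0) {
    warning("constant track: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(track_a, track_b, method = "spearman")
}

# Sliding-window coordinates for one flank of a TSS, strand-aware.
# Windows are ordered by increasing distance from the TSS; window k covers
# distances [(k-1)*step, (k-1)*step + window) along the flank direction.
.flank_windows <- function(tss, strand, side, window_bp, step_bp, flank_bp) {
  n_win <- (flank_bp - window_bp) / step_bp + 1
  if (n_win != round(n_win))
    stop("(flank - window) must be a multiple of step")
  k <- seq_len(n_win) - 1
  off <- k * step_bp
  # distance conventions: upstream window k holds distances (off, off+window]
  # (the TSS base itself is downstream distance 0), downstream window k holds
  # distances [off, off+window); distances run along the transcription axis
  if (strand == "+" && side == "upstream") {
    start <- tss - off - window_bp; end <- tss - off
  } else if (strand == "+" && side == "downstream") {
    start <- tss + off; end <- tss + off + window_bp
  } else if (strand == "-" && side == "upstream") {
    start <- tss + off + 1; end <- tss + off + window_bp + 1
  } else {
    start <- tss - off - window_bp + 1; end <- tss - off + 1
  }
  data.frame(window = seq_len(n_win), dist_bp = off, start = start, end = end)
}

#' Sliding-window repeat profile around a gene's TSS
#'
#' Scans the upstream and downstream flanks of a gene's transcription start
#' site with overlapping sliding windows (defaults: 20 kb flank, 3 kb
#' window, 1 kb step, giving 18 windows per side) and counts the repeat
#' elements of one family whose start coordinate falls inside each window.
#' Upstream/downstream are strand-aware. Windows are ordered by increasing
#' distance from the TSS; windows reaching beyond the chromosome simply
#' count nothing there.
#'
#' @param gene One gene-model row (needs `gene_name`, `chrom`, `strand`,
#'   `tss`).
#' @param repeats Repeat-element data frame from [read_repeats()].
#' @param family Repeat family name (matched upper-case).
#' @param config A [run_config()] supplying window/step/flank sizes (kb).
#' @return Data frame `gene_name`, `side`, `window`, `dist_bp`, `count` with
#'   `(flank - window)/step + 1` rows per side.
#' @export
tss_flank_profile <- function(gene, repeats, family, config = run_config()) {
  starts <- repeats$start[repeats$chrom == gene$chrom &
                            repeats$family == toupper(family)]
  window_bp <- config$window_kb * 1000
  step_bp <- config$step_kb * 1000
  flank_bp <- config$flank_kb * 1000
  out <- lapply(c("upstream", "downstream"), function(side) {
    w <- .flank_windows(gene$tss, gene$strand, side,
                        window_bp, step_bp, flank_bp)
    w$count <- vapply(seq_len(nrow(w)), function(i)
      sum(starts >= w$start[i] & starts < w$end[i]), numeric(1))
    data.frame(gene_name = gene$gene_name, side = side,
               window = w$window, dist_bp = w$dist_bp, count = w$count,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intronic repeat density of a gene
#'
#' The average copy number of a repeat family within a 3 kb intronic region:
#' total family elements whose start lies inside the gene's introns, divided
#' by total intron length in units of 3 kb. Intron order does not affect the
#' value. Intronless genes have no defined intronic density (`NA`).
#'
#' @param gene One gene-model row.
#' @param repeats Repeat-element data frame.
#' @param family Repeat family name.
#' @param per_bp Normalisation unit in bp (default 3000).
#' @return Copies per `per_bp` of intron, or `NA` for an intronless gene.
#' @export
intronic_density <- function(gene, repeats, family, per_bp = 3000) {
  ex <- gene_exons(gene)
  if (nrow(ex) < 2L) return(NA_real_)
  intron_start <- ex$end[-nrow(ex)]
  intron_end <- ex$start[-1]
  total_len <- sum(intron_end - intron_start)
  if (total_len <= 0) return(NA_real_)
  starts <- repeats$start[repeats$chrom == gene$chrom &
                            repeats$family == toupper(family)]
  copies <- sum(vapply(starts, function(s)
    any(s >= intron_start & s < intron_end), logical(1)))
  copies / (total_len / per_bp)
}

#' Compare repeat copy numbers between two gene groups
#'
#' Summarises each group (mean, SEM, n) and compares the distributions with
#' a two-sided Mann-Whitney rank-sum test (robust to the skewed copy-number
#' distributions typical of repeat counts); a Welch t-test is available via
#' `test = "t"`.
#'
#' @param values_a,values_b Numeric vectors of per-gene copy numbers, each
#'   with at least 3 values.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return List with `summary` (data frame per group), `statistic`,
#'   `p_value`, `method`.
#' @export
group_comparison <- function(values_a, values_b, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("each group needs at least 3 values")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    group = c("A", "B"),
    n = c(length(values_a), length(values_b)),
    mean = c(mean(values_a), mean(values_b)),
    sem = c(sem(values_a), sem(values_b))
  )
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(values_a, values_b,
                                        alternative = "two.sided"))
  } else {
    stats::t.test(values_a, values_b, alternative = "two.sided")
  }
  list(summary = summary, statistic = unname(ht$statistic),
       p_value = ht$p.value, method = ht$method)
}
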