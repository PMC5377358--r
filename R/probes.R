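#' Filter candidate SNPs for padlock probe design
#'
#' Applies the SNP-selection rules for a padlock library on a SNP table:
#'
#' * only SNPs with ATG (above-threshold genotype) score 0 or 1 are kept
#'   (confirmed SNPs with high-quality genotype calls);
#' * in `coding` mode, only exonic SNPs are kept, and SNPs within `arm_bp`
#'   of an exon boundary are dropped (no room for a probe arm within the
#'   exon);
#' * in `noncoding` mode, only intronic and intergenic SNPs are kept;
#' * SNPs with a second SNP within `arm_bp` on either side are dropped —
#'   the neighbouring SNP would interfere with arm hybridisation (the
#'   "shoulder" effect); both members of such a pair are dropped, and
#'   conflicts are evaluated against all input SNPs, not only the
#'   candidates surviving the other filters;
#' * an optional eligibility predicate stands in for probe-level
#'   thermodynamic screening (melting temperature, template secondary
#'   structure), defaulting to always-true.
#'
#' @param snps SNP data frame with columns `snp_id`, `chrom`, `pos`
#'   (0-based), `strand`, `region` (`exonic`/`intronic`/`intergenic`),
#'   `atg_score`.
#' @param genes Gene-model data frame (used for exon boundaries in coding
#'   mode).
#' @param arm_bp Probe arm length in bp (default 20).
#' @param region_mode `"coding"` or `"noncoding"`.
#' @param eligible Optional predicate `function(snps) -> logical vector`.
#' @return The retained subset of `snps`.
#' @export
filter_candidate_snps <- function(snps, genes, arm_bp = 20,
                                  region_mode = c("coding", "noncoding"),
                                  eligible = NULL) {
  region_mode <- match.arg(region_mode)
  stopifnot(arm_bp > 0)
  keep <- snps$atg_score %in% c(0L, 1L)
  if (region_mode == "coding") {
    keep <- keep & snps$region == "exonic"
    # exon-boundary rule: the SNP must sit at least arm_bp inside some exon
    ok_boundary <- rep(FALSE, nrow(snps))
    for (g in seq_len(nrow(genes))) {
      ex <- gene_exons(genes[g, ])
      on_chrom <- snps$chrom == genes$chrom[g]
      for (e in seq_len(nrow(ex))) {
        inside <- on_chrom &
          snps$pos - ex$start[e] >= arm_bp &
          (ex$end[e] - 1) - snps$pos >= arm_bp
        ok_boundary <- ok_boundary | inside
      }
    }
    keep <- keep & ok_boundary
  } else {
    keep <- keep & snps$region %in% c("intronic", "intergenic")
  }
  # shoulder conflicts against the full input SNP set
  conflict <- rep(FALSE, nrow(snps))
  for (chrom in unique(snps$chrom)) {
    idx <- which(snps$chrom == chrom)
    pos <- sort(snps$pos[idx])
    gaps <- diff(pos)
    close_pos <- unique(c(pos[which(gaps <= arm_bp)],
                          pos[which(gaps <= arm_bp) + 1L]))
    conflict[idx] <- snps$pos[idx] %in% close_pos
  }
  keep <- keep & !conflict
  if (!is.null(eligible)) keep <- keep & eligible(snps)
  snps[keep, , drop = FALSE]
}

#' Randomly sample non-coding probe targets per 5 kb window
#'
#' Tiles the chromosome into fixed windows `[k*region_bp, (k+1)*region_bp)`
#' anchored at coordinate 0 and, within each window, selects at most one
#' candidate SNP per strand uniformly at random. A window with no eligible
#' candidate on a strand contributes no probe for that strand (the region is
#' excluded from detection). Selection is deterministic under the seed.
#'
#' @param candidates Pre-filtered SNP data frame (see
#'   [filter_candidate_snps()]) with `chrom`, `pos`, `strand`.
#' @param region_bp Window size in bp (default 5000).
#' @param seed Integer seed.
#' @return The selected subset of `candidates`, sorted by position.
#' @export
sample_noncoding_probes <- function(candidates, region_bp = 5000, seed = 1L) {
  if (nrow(candidates) == 0L) return(candidates)
  win <- candidates$pos %/% region_bp
  key <- paste(candidates$chrom, win, candidates$strand, sep = "\r")
  groups <- split(seq_len(nrow(candidates)), key)
  groups <- groups[order(names(groups))]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  chosen <- vapply(groups, function(idx) {
    idx <- idx[order(candidates$pos[idx])]
    idx[sample.int(length(idx), 1L)]
  }, integer(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out <- candidates[sort(unname(chosen)), , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}
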