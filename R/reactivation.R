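#' Aggregate per-SNP allele counts to genes
#'
#' SNPs are assigned to genes by exonic overlap of the SNP position with the
#' gene's exons (intronic SNPs belong to the non-coding analysis). Counts are
#' summed per gene, either per annotation ID (`level = "gene_id"`) or with
#' all IDs under one gene name combined (`level = "gene_name"`, the default,
#' which is the level at which reactivation is called). Genes with zero reads
#' on both alleles in a sample are un-allelotyped and removed. For each gene
#' name one representative annotation ID is selected uniformly at random
#' under the given seed, for use in downstream positional analyses.
#'
#' A SNP falling in the exons of two or more distinct gene names is assigned
#' to all of them and the affected genes are flagged `ambiguous`.
#'
#' @param snp_results Per-SNP allelotype table from [allelotype_table()]
#'   (must retain `chrom` and `pos`).
#' @param genes Gene-model data frame (see [read_gene_models()]).
#' @param level `"gene_name"` or `"gene_id"`.
#' @param seed Integer seed for representative-ID selection.
#' @return Data frame with one row per gene per sample: `gene_name`,
#'   `representative_gene_id`, `sample_id`, `c129`, `ccast`, `n_snps`,
#'   `ambiguous`.
#' @export
aggregate_gene_counts <- function(snp_results, genes,
                                  level = c("gene_name", "gene_id"),
                                  seed = 1L) {
  level <- match.arg(level)
  maps <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    ex <- gene_exons(genes[g, ])
    hit <- snp_results$chrom == genes$chrom[g]
    if (!any(hit)) next
    pos <- snp_results$pos
    in_exon <- rep(FALSE, nrow(snp_results))
    for (e in seq_len(nrow(ex)))
      in_exon <- in_exon | (hit & pos >= ex$start[e] & pos < ex$end[e])
    idx <- which(in_exon)
    if (length(idx))
      maps[[g]] <- data.frame(row = idx,
                              gene_name = genes$gene_name[g],
                              gene_id = genes$gene_id[g],
                              stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  if (is.null(map) || nrow(map) == 0L)
    return(data.frame(gene_name = character(), representative_gene_id = character(),
                      sample_id = character(), c129 = numeric(), ccast = numeric(),
                      n_snps = integer(), ambiguous = logical()))

  # SNPs hitting >= 2 gene names mark those genes ambiguous
  names_per_row <- tapply(map$gene_name, map$row, function(x) unique(x))
  multi_rows <- as.integer(names(names_per_row)[lengths(names_per_row) > 1])
  ambiguous_genes <- unique(map$gene_name[map$row %in% multi_rows])

  key <- if (level == "gene_name") map$gene_name else map$gene_id
  dat <- data.frame(
    key = key,
    gene_name = map$gene_name,
    sample_id = snp_results$sample_id[map$row],
    c129 = snp_results$c129[map$row],
    ccast = snp_results$ccast[map$row]
  )
  agg <- stats::aggregate(cbind(c129, ccast) ~ key + gene_name + sample_id,
                          data = dat, FUN = sum)
  nsnp <- stats::aggregate(list(n_snps = dat$c129),
                           by = list(key = dat$key, gene_name = dat$gene_name,
                                     sample_id = dat$sample_id),
                           FUN = length)
  agg <- merge(agg, nsnp, by = c("key", "gene_name", "sample_id"))

  # un-allelotyped: no reads from either allele
  agg <- agg[agg$c129 > 0 | agg$ccast > 0, , drop = FALSE]

  # representative annotation ID per gene name, random but seed-deterministic
  ids_by_name <- tapply(map$gene_id, map$gene_name, function(x) sort(unique(x)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rep_id <- vapply(ids_by_name, function(ids) ids[sample.int(length(ids), 1L)], "")
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  out <- data.frame(
    gene_name = agg$gene_name,
    representative_gene_id = unname(rep_id[agg$gene_name]),
    sample_id = agg$sample_id,
    c129 = agg$c129,
    ccast = agg$ccast,
    n_snps = agg$n_snps,
    ambiguous = agg$gene_name %in% ambiguous_genes,
    stringsAsFactors = FALSE
  )
  if (level == "gene_id") out$gene_id <- agg$key
  out[order(out$gene_name, out$sample_id), , drop = FALSE]
}

#' Call gene reactivation in a mutant line against its control
#'
#' A gene is reactivated along the Xist-deleted Xi when (i) its pseudo-counted
#' allelotype in the mutant is at least `fold_threshold` times its allelotype
#' in the control and (ii) the gene is biallelically expressed in the mutant
#' (`lo < r_mut < hi`). Escapee-class genes are evaluated with the same rule
#' but are exempt from the control-silenced expectation encoded by
#' `exclude_control_biallelic`: with that flag set, non-escapee genes already
#' biallelic in the control are not callable (the stricter list that excludes
#' constitutive escapees and control-biallelic genes).
#'
#' @param gene_counts_mutant,gene_counts_control Aggregated gene tables from
#'   [aggregate_gene_counts()] (one sample each).
#' @param config A [run_config()].
#' @param gene_classes Optional data frame `gene_name`, `class` used for the
#'   escapee exemption (classes beginning with `"escapee"`).
#' @param exclude_control_biallelic If `TRUE`, suppress calls on non-escapee
#'   genes whose control allelotype is already within the biallelic bounds.
#' @return Data frame with per-gene `r_ctrl`, `r_mut`, `fold_vs_control`,
#'   `control_biallelic`, `reactivated`, `escapee`.
#' @export
call_reactivation <- function(gene_counts_mutant, gene_counts_control,
                              config = run_config(),
                              gene_classes = NULL,
                              exclude_control_biallelic = FALSE) {
  miss <- setdiff(gene_counts_mutant$gene_name, gene_counts_control$gene_name)
  if (length(miss))
    warning("skipping ", length(miss),
            " gene(s) present in mutant but absent in control: ",
            paste(utils::head(miss, 5), collapse = ", "))
  m <- merge(
    gene_counts_mutant[, c("gene_name", "representative_gene_id", "c129", "ccast")],
    gene_counts_control[, c("gene_name", "c129", "ccast")],
    by = "gene_name", suffixes = c("_mut", "_ctrl")
  )
  pc <- config$pseudo_count
  lo <- config$biallelic_bounds[1]
  hi <- config$biallelic_bounds[2]
  r_mut <- (m$c129_mut + pc) / (m$ccast_mut + pc)
  r_ctrl <- (m$c129_ctrl + pc) / (m$ccast_ctrl + pc)
  fold <- r_mut / r_ctrl
  escapee <- rep(FALSE, nrow(m))
  if (!is.null(gene_classes)) {
    cls <- gene_classes$class[match(m$gene_name, gene_classes$gene_name)]
    escapee <- !is.na(cls) & startsWith(as.character(cls), "escapee")
  }
  control_biallelic <- r_ctrl > lo & r_ctrl < hi
  reactivated <- fold >= config$fold_threshold & r_mut > lo & r_mut < hi
  if (exclude_control_biallelic)
    reactivated <- reactivated & (escapee | !control_biallelic)
  data.frame(
    gene_name = m$gene_name,
    representative_gene_id = m$representative_gene_id,
    c129_mut = m$c129_mut, ccast_mut = m$ccast_mut,
    c129_ctrl = m$c129_ctrl, ccast_ctrl = m$ccast_ctrl,
    r_mut = r_mut, r_ctrl = r_ctrl,
    fold_vs_control = fold,
    control_biallelic = control_biallelic,
    escapee = escapee,
    reactivated = reactivated,
    stringsAsFactors = FALSE
  )
}

#' Frequently reactivated genes across mutant lines
#'
#' Genes reactivated in `min_mutants` or more mutant samples.
#'
#' @param calls Data frame binding [call_reactivation()] outputs over mutant
#'   lines, with an added `sample_id` column identifying the mutant.
#' @param min_mutants Minimum number of mutants (default 2).
#' @return Sorted character vector of gene names.
#' @export
frequent_reactivation <- function(calls, min_mutants = 2L) {
  hits <- calls[calls$reactivated, c("gene_name", "sample_id")]
  hits <- unique(hits)
  n <- table(hits$gene_name)
  sort(names(n)[n >= min_mutants])
}

#' Compare reactivation calls between two time points
#'
#' Labels each gene's transition between an earlier and a later call set
#' (e.g. before and after long-term culture): `gained` (silenced to
#' reactivated), `lost` (reactivated to silenced), `stable_on`, `stable_off`.
#'
#' @param calls_t0,calls_t1 [call_reactivation()] outputs on the same gene
#'   universe.
#' @return List with `per_gene` (data frame `gene_name`, `transition`) and
#'   `counts` (named vector over the four transition types).
#' @export
compare_longterm <- function(calls_t0, calls_t1) {
  m <- merge(calls_t0[, c("gene_name", "reactivated")],
             calls_t1[, c("gene_name", "reactivated")],
             by = "gene_name", suffixes = c("_t0", "_t1"))
  transition <- ifelse(m$reactivated_t0 & m$reactivated_t1, "stable_on",
                ifelse(!m$reactivated_t0 & m$reactivated_t1, "gained",
                ifelse(m$reactivated_t0 & !m$reactivated_t1, "lost",
                       "stable_off")))
  counts <- vapply(c("gained", "lost", "stable_on", "stable_off"),
                   function(t) sum(transition == t), integer(1))
  list(per_gene = data.frame(gene_name = m$gene_name, transition = transition,
                             stringsAsFactors = FALSE),
       counts = counts)
}
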