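#' Classify ncSNP expression patterns across three cell types
#'
#' A non-coding SNP's expression pattern is defined from its allelotypes in
#' the three cell types: pre-XCI ES cells (Xa129 XaCast), post-XCI control
#' fibroblasts (Xi129 XaCast) and the Xist-deleted mutant (Xi129-1lox
#' XaCast). A transcription activity is Xist-regulated when the SNP is
#' biallelic in ES cells and cast-specific in the control; within the
#' Xist-regulated class, `R = r_mut / r_ctrl` distinguishes `reactivated`
#' (`R >= fold_threshold` and biallelic in the mutant) from `silenced`. All
#' other combinations are `non_xist_regulated`. A SNP not allelotyped
#' (undetected) in any of the three cell types gets pattern `NA` and is
#' excluded from downstream counts.
#'
#' @param r_es,r_ctrl,r_mut Allelotype ratios in the three cell types
#'   (vectors; `NA` = undetected).
#' @param label_es,label_ctrl,label_mut Matching allelotype labels from
#'   [classify_allelotype()].
#' @param config A [run_config()].
#' @return Data frame with columns `R` and `pattern` (one of
#'   `xist_regulated_silenced`, `xist_regulated_reactivated`,
#'   `non_xist_regulated`, or `NA`).
#' @export
classify_pattern <- function(r_es, r_ctrl, r_mut,
                             label_es, label_ctrl, label_mut,
                             config = run_config()) {
  n <- length(r_es)
  stopifnot(length(r_ctrl) == n, length(r_mut) == n,
            length(label_es) == n, length(label_ctrl) == n,
            length(label_mut) == n)
  detected <- label_es != "undetected" & label_ctrl != "undetected" &
    label_mut != "undetected"
  xist <- label_es == "biallelic" & label_ctrl == "cast_specific"
  R <- ifelse(xist, r_mut / r_ctrl, NA_real_)
  pattern <- rep(NA_character_, n)
  pattern[detected & !xist] <- "non_xist_regulated"
  reactivated <- xist & R >= config$fold_threshold & label_mut == "biallelic"
  pattern[detected & xist & reactivated] <- "xist_regulated_reactivated"
  pattern[detected & xist & !reactivated] <- "xist_regulated_silenced"
  R[!detected] <- NA_real_
  data.frame(R = R, pattern = pattern, stringsAsFactors = FALSE)
}

#' Per-SNP pattern table for one cell-line combination
#'
#' Joins the per-SNP allelotype rows of one ES, one control and one mutant
#' sample and applies [classify_pattern()]. Only SNPs measured in all three
#' samples are retained; SNPs undetected in any sample carry pattern `NA`.
#'
#' @param allelo Allelotype table from [allelotype_table()] covering the
#'   three samples.
#' @param es,ctrl,mut Sample identifiers for the three cell types.
#' @param config A [run_config()].
#' @param combo_id Optional label recorded in the output.
#' @return Data frame with one row per SNP: r values, labels, `R`, `pattern`.
#' @export
pattern_table <- function(allelo, es, ctrl, mut, config = run_config(),
                          combo_id = NA_character_) {
  pick <- function(sid) {
    x <- allelo[allelo$sample_id == sid, c("snp_id", "r", "label")]
    if (nrow(x) == 0L) stop("no allelotype rows for sample '", sid, "'")
    x
  }
  a <- pick(es); b <- pick(ctrl); d <- pick(mut)
  m <- merge(merge(a, b, by = "snp_id", suffixes = c("_es", "_ctrl")),
             stats::setNames(d, c("snp_id", "r_mut", "label_mut")),
             by = "snp_id")
  cls <- classify_pattern(m$r_es, m$r_ctrl, m$r_mut,
                          m$label_es, m$label_ctrl, m$label_mut, config)
  data.frame(
    snp_id = m$snp_id, combo_id = combo_id,
    r_es = m$r_es, r_ctrl = m$r_ctrl, r_mut = m$r_mut,
    label_es = m$label_es, label_ctrl = m$label_ctrl, label_mut = m$label_mut,
    R = cls$R, pattern = cls$pattern,
    stringsAsFactors = FALSE
  )
}

#' Run pattern classification over several cell-line combinations
#'
#' Each combination ("combo") names one sample per cell type; the same SNP
#' set is classified once per combo to test the consistency of calls across
#' cell lines.
#'
#' @param allelo Allelotype table covering all referenced samples.
#' @param combos Data frame with columns `es`, `ctrl`, `mut` and optionally
#'   `combo_id`, one row per combination.
#' @param config A [run_config()].
#' @return Named list of [pattern_table()] data frames, one per combo.
#' @export
run_combos <- function(allelo, combos, config = run_config()) {
  stopifnot(all(c("es", "ctrl", "mut") %in% names(combos)))
  if (is.null(combos$combo_id))
    combos$combo_id <- paste0("combo", seq_len(nrow(combos)))
  referenced <- unique(unlist(combos[, c("es", "ctrl", "mut")]))
  absent <- setdiff(referenced, unique(allelo$sample_id))
  if (length(absent))
    stop("combo references missing sample(s): ", paste(absent, collapse = ", "))
  out <- lapply(seq_len(nrow(combos)), function(i)
    pattern_table(allelo, combos$es[i], combos$ctrl[i], combos$mut[i],
                  config, combo_id = combos$combo_id[i]))
  stats::setNames(out, combos$combo_id)
}

#' Default cell-line combinations
#'
#' All ES-by-control pairings crossed with a fixed (first) mutant sample,
#' truncated to `max_combos`.
#'
#' @param es_ids,ctrl_ids,mut_ids Sample identifier vectors per cell type.
#' @param max_combos Maximum number of combinations (default 4).
#' @return Data frame of combos suitable for [run_combos()].
#' @export
default_combos <- function(es_ids, ctrl_ids, mut_ids, max_combos = 4L) {
  grid <- expand.grid(es = es_ids, ctrl = ctrl_ids,
                      stringsAsFactors = FALSE)
  grid$mut <- mut_ids[1]
  grid <- utils::head(grid, max_combos)
  grid$combo_id <- paste0("combo", seq_len(nrow(grid)))
  grid
}

#' Consensus sets of non-Xist-regulated SNP calls across combos
#'
#' From the per-combo pattern tables, computes the union and intersection of
#' SNPs called `non_xist_regulated`, the subset never called Xist-regulated
#' in any combo (`only_non_xist`), and the SNPs called both ways across
#' combos (`conflicted`). By construction `only_non_xist` is a subset of
#' `union` and `conflicted = union \ only_non_xist`.
#'
#' @param combo_results List of [pattern_table()] data frames.
#' @return List with character vectors `union`, `intersection`,
#'   `only_non_xist`, `conflicted`.
#' @export
consensus_sets <- function(combo_results) {
  stopifnot(length(combo_results) >= 1L)
  non_sets <- lapply(combo_results, function(d)
    d$snp_id[!is.na(d$pattern) & d$pattern == "non_xist_regulated"])
  xist_sets <- lapply(combo_results, function(d)
    d$snp_id[!is.na(d$pattern) & d$pattern %in%
               c("xist_regulated_silenced", "xist_regulated_reactivated")])
  u <- sort(Reduce(union, non_sets))
  inter <- sort(Reduce(intersect, non_sets))
  ever_xist <- Reduce(union, xist_sets)
  list(
    union = u,
    intersection = inter,
    only_non_xist = setdiff(u, ever_xist),
    conflicted = intersect(u, ever_xist)
  )
}

#' XCI detection and Pol III impairment calls in a differentiation course
#'
#' For each gene allelotyped at day 0 (undifferentiated, biallelic), day 4
#' control and day 4 under Pol III inhibition, two ratios are formed:
#' `Rc = r_ctrl / r_day0` quantifies loss of 129-allele expression upon
#' differentiation (XCI detected when `Rc <= 1/fold_threshold`), and
#' `Ri = r_inh / r_ctrl` quantifies the recovery of 129 expression under
#' inhibition (XCI impaired when XCI was detected and
#' `Ri >= fold_threshold`).
#'
#' @param r_day0,r_ctrl,r_inh Pseudo-counted gene allelotypes in the three
#'   samples (vectors; `NA` excluded).
#' @param config A [run_config()].
#' @return Data frame with `Rc`, `Ri`, `xci_detected`, `impaired`.
#' @export
call_xci_effects <- function(r_day0, r_ctrl, r_inh, config = run_config()) {
  n <- length(r_day0)
  stopifnot(length(r_ctrl) == n, length(r_inh) == n)
  Rc <- r_ctrl / r_day0
  Ri <- r_inh / r_ctrl
  xci_detected <- !is.na(Rc) & Rc <= 1 / config$fold_threshold
  impaired <- xci_detected & !is.na(Ri) & Ri >= config$fold_threshold
  data.frame(Rc = Rc, Ri = Ri, xci_detected = xci_detected,
             impaired = impaired)
}

#' Gene-level XCI-impairment table from three aggregated samples
#'
#' Merges three [aggregate_gene_counts()] outputs (day 0, day 4 control,
#' day 4 inhibited), computes pseudo-counted allelotypes and applies
#' [call_xci_effects()]. Genes must be allelotyped in all three samples.
#'
#' @param agg_day0,agg_ctrl,agg_inh Aggregated gene tables (one sample each).
#' @param config A [run_config()].
#' @return Data frame with per-gene `r_day0`, `r_ctrl`, `r_inh`, `Rc`, `Ri`,
#'   `xci_detected`, `impaired`.
#' @export
xci_table <- function(agg_day0, agg_ctrl, agg_inh, config = run_config()) {
  pc <- config$pseudo_count
  take <- function(d, tag) {
    out <- d[, c("gene_name", "c129", "ccast")]
    out[[paste0("r_", tag)]] <- (out$c129 + pc) / (out$ccast + pc)
    out[, c("gene_name", paste0("r_", tag))]
  }
  m <- merge(merge(take(agg_day0, "day0"), take(agg_ctrl, "ctrl"),
                   by = "gene_name"),
             take(agg_inh, "inh"), by = "gene_name")
  calls <- call_xci_effects(m$r_day0, m$r_ctrl, m$r_inh, config)
  cbind(m, calls)
}
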