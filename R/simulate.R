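#' Simulation parameters
#'
#' Parameters of the synthetic X-chromosome study used for validating the
#' pipeline against known ground truth. Defaults encode the study
#' conditions: ~9,000 reads per allelotyped SNP, ~6% of X-linked genes
#' reactivated per mutant line, non-coding SNP probes at one per strand per
#' 5 kb, XCI detected on ~70% of allelotyped genes after differentiation
#' with ~79% of those impaired under Pol III inhibition. Quantities the
#' study does not fix (reactivation effect size, escapee leak level, repeat
#' base densities) are free parameters with documented defaults.
#'
#' @param n_genes Number of genes tiled along the chromosome.
#' @param chrom_length_bp Chromosome length; must allow >= 18 kb per gene
#'   slot (gene body plus a private 10 kb upstream region).
#' @param snps_per_gene Exonic SNPs placed per gene.
#' @param nc_snp_spacing_bp One non-coding SNP per strand per this many bp.
#' @param mean_coverage Mean reads per SNP (Poisson).
#' @param error_rate Per-read miscall probability; a miscalled read lands on
#'   a uniformly chosen other base.
#' @param reactivated_fraction Fraction of genes reactivated in the mutant.
#' @param escapee_fraction Fraction of genes that escape XCI.
#' @param reactivation_effect Fraction of expression restored on Xi for a
#'   reactivated gene (129-allele read probability in the mutant).
#' @param sine_coupling Multiplier on SINE-family repeat density in the
#'   10 kb upstream of reactivated genes (1 = no coupling).
#' @param leakage Residual 129-allele read probability of a silenced gene
#'   (default 0: silencing is exact).
#' @param escapee_p129 129-allele read probability of an escapee on Xi.
#' @param nc_pattern_probs Named probabilities of the four non-coding SNP
#'   truth patterns (`xist_silenced`, `xist_reactivated`,
#'   `nonxist_129_silenced`, `nonxist_129_active`).
#' @param xci_fraction Fraction of genes subject to XCI in the
#'   differentiation course.
#' @param impaired_fraction Fraction of XCI-subject genes impaired by Pol
#'   III inhibition.
#' @param impair_effect 129-allele read probability restored in impaired
#'   genes under inhibition.
#' @param rng_seed Integer seed; all generators are deterministic under it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 150,
                       chrom_length_bp = 3e6,
                       snps_per_gene = 3,
                       nc_snp_spacing_bp = 5000,
                       mean_coverage = 9000,
                       error_rate = 0.002,
                       reactivated_fraction = 0.06,
                       escapee_fraction = 0.04,
                       reactivation_effect = 0.05,
                       sine_coupling = 1,
                       leakage = 0,
                       escapee_p129 = 0.2,
                       nc_pattern_probs = c(xist_silenced = 0.4,
                                            xist_reactivated = 0.1,
                                            nonxist_129_silenced = 0.25,
                                            nonxist_129_active = 0.25),
                       xci_fraction = 0.7,
                       impaired_fraction = 0.79,
                       impair_effect = 0.1,
                       rng_seed = 1L) {
  stopifnot(reactivated_fraction >= 0, reactivated_fraction <= 1,
            escapee_fraction >= 0, escapee_fraction + reactivated_fraction <= 1,
            mean_coverage > 0, error_rate >= 0, error_rate < 1,
            sine_coupling >= 0, leakage >= 0, leakage < 1,
            xci_fraction >= 0, xci_fraction <= 1,
            impaired_fraction >= 0, impaired_fraction <= 1)
  if (chrom_length_bp <= n_genes * 10000)
    stop("chromosome too short for the requested number of genes")
  probs <- nc_pattern_probs
  req <- c("xist_silenced", "xist_reactivated",
           "nonxist_129_silenced", "nonxist_129_active")
  if (!setequal(names(probs), req) || abs(sum(probs) - 1) > 1e-8)
    stop("'nc_pattern_probs' must name the four patterns and sum to 1")
  structure(as.list(environment())[names(formals(sim_params))],
            class = "sim_params")
}

# Repeat families and baseline densities (copies per kb) of the toy
# chromosome. The SINE class comprises Alu, B2, ID and B4.
.REPEAT_RATES <- c(L1 = 0.15, ALU = 0.08, B2 = 0.06, ID = 0.02, B4 = 0.05)
.SINE_FAMILIES <- c("ALU", "B2", "ID", "B4")
.REPEAT_LENGTHS <- c(L1 = 3000, ALU = 150, B2 = 150, ID = 150, B4 = 150)

#' Simulate a toy annotated X chromosome
#'
#' Tiles `n_genes` genes along a synthetic chromosome (each in its own slot
#' with a 5 kb three-exon body and a private 10 kb upstream region), places
#' exonic SNPs inside exons and non-coding SNPs on both strands (one per
#' strand per `nc_snp_spacing_bp` window, rejection-sampled away from
#' exons), and scatters repeat elements of the families L1, Alu, B2, ID and
#' B4 at baseline densities. The SINE-family density in the 10 kb upstream
#' of truth-reactivated genes is multiplied by `sine_coupling`. Ground-truth
#' labels (gene status, XCI/impairment flags, per-ncSNP expression pattern)
#' are returned alongside the annotation.
#'
#' All genes are drawn on the `+` strand, which keeps every upstream region
#' inside its gene's slot; strand-aware flank logic is exercised through
#' user-supplied gene models.
#'
#' @param params A [sim_params()] object.
#' @return List with `genes` (gene models), `snps` (SNP table with `panel`
#'   column `coding`/`noncoding`), `repeats`, and `truth` (list with `genes`
#'   and `ncsnps` truth tables).
#' @export
simulate_annotation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  chrom <- "chrX"
  n <- params$n_genes
  slot <- floor(params$chrom_length_bp / n)
  if (slot < 18000)
    stop("infeasible packing: need >= 18 kb per gene slot, have ", slot)

  # gene bodies: 5 kb with exons at offsets [0,600), [2200,2800), [4400,5000)
  body_start <- (seq_len(n) - 1L) * slot + 11000L
  exon_off_start <- c(0L, 2200L, 4400L)
  exon_off_end <- c(600L, 2800L, 5000L)
  genes <- data.frame(
    gene_name = sprintf("gene%03d", seq_len(n)),
    gene_id = sprintf("uc%03d.1", seq_len(n)),
    chrom = chrom,
    strand = "+",
    tss = body_start,
    exon_starts = vapply(body_start, function(s)
      paste(s + exon_off_start, collapse = ","), ""),
    exon_ends = vapply(body_start, function(s)
      paste(s + exon_off_end, collapse = ","), ""),
    stringsAsFactors = FALSE
  )

  # gene truth: escapees, reactivated (disjoint), XCI-subject and impaired
  status <- rep("silenced", n)
  n_esc <- round(params$escapee_fraction * n)
  n_re <- round(params$reactivated_fraction * n)
  pick <- sample.int(n, n_esc + n_re)
  esc_idx <- pick[seq_len(n_esc)]
  re_idx <- pick[n_esc + seq_len(n_re)]
  status[esc_idx] <- "escapee"
  status[re_idx] <- "reactivated"
  genes$class <- ifelse(status == "escapee", "escapee_constitutive", "coding")
  non_esc <- which(status != "escapee")
  n_xci <- min(length(non_esc), round(params$xci_fraction * n))
  xci_idx <- sample(non_esc, n_xci)
  xci_subject <- seq_len(n) %in% xci_idx
  imp_idx <- sample(xci_idx, round(params$impaired_fraction * n_xci))
  impaired <- seq_len(n) %in% imp_idx

  # exonic SNPs
  exon_offsets <- unlist(mapply(seq, exon_off_start, exon_off_end - 1L,
                                SIMPLIFY = FALSE))
  snp_list <- lapply(seq_len(n), function(g) {
    off <- sort(sample(exon_offsets, params$snps_per_gene))
    a129 <- sample(.BASES, params$snps_per_gene, replace = TRUE)
    acast <- vapply(a129, function(b) sample(setdiff(.BASES, b), 1L), "")
    data.frame(
      snp_id = sprintf("%s_s%d", genes$gene_name[g], seq_len(params$snps_per_gene)),
      chrom = chrom, pos = body_start[g] + off, strand = "+",
      region = "exonic", panel = "coding",
      gene_name = genes$gene_name[g],
      atg_score = sample(c(0L, 1L, 2L), params$snps_per_gene,
                         replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      allele129 = a129, alleleCast = unname(acast),
      stringsAsFactors = FALSE
    )
  })
  coding_snps <- do.call(rbind, snp_list)

  # non-coding SNPs: one per strand per spacing window, never exonic
  exon_starts_all <- rep(body_start, each = 3L) + exon_off_start
  exon_ends_all <- rep(body_start, each = 3L) + exon_off_end
  in_exon <- function(p) any(p >= exon_starts_all & p < exon_ends_all)
  n_win <- floor(params$chrom_length_bp / params$nc_snp_spacing_bp)
  nc_list <- lapply(c("+", "-"), function(strand) {
    pos <- integer(n_win)
    for (w in seq_len(n_win)) {
      repeat {
        p <- (w - 1L) * params$nc_snp_spacing_bp +
          sample.int(params$nc_snp_spacing_bp, 1L) - 1L
        if (!in_exon(p)) break
      }
      pos[w] <- p
    }
    in_body <- vapply(pos, function(p)
      any(p >= body_start & p < body_start + 5000L), logical(1))
    a129 <- sample(.BASES, n_win, replace = TRUE)
    acast <- vapply(a129, function(b) sample(setdiff(.BASES, b), 1L), "")
    data.frame(
      snp_id = sprintf("nc_%s_w%04d", ifelse(strand == "+", "s", "a"),
                       seq_len(n_win)),
      chrom = chrom, pos = pos, strand = strand,
      region = ifelse(in_body, "intronic", "intergenic"),
      panel = "noncoding", gene_name = NA_character_,
      atg_score = sample(c(0L, 1L, 2L), n_win, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1)),
      allele129 = a129, alleleCast = unname(acast),
      stringsAsFactors = FALSE
    )
  })
  nc_snps <- do.call(rbind, nc_list)
  nc_pattern <- sample(names(params$nc_pattern_probs), nrow(nc_snps),
                       replace = TRUE, prob = params$nc_pattern_probs)

  # repeat elements: baseline density everywhere; SINE density scaled by
  # sine_coupling in the 10 kb upstream of truth-reactivated genes
  up_start <- body_start[re_idx] - 10000L
  up_end <- body_start[re_idx]
  rep_list <- lapply(names(.REPEAT_RATES), function(fam) {
    rate <- .REPEAT_RATES[[fam]]
    len <- .REPEAT_LENGTHS[[fam]]
    starts <- .sample_piecewise_poisson(
      chrom_length = params$chrom_length_bp, rate_per_kb = rate,
      hot_start = if (fam %in% .SINE_FAMILIES) up_start else integer(0),
      hot_end = if (fam %in% .SINE_FAMILIES) up_end else integer(0),
      hot_multiplier = params$sine_coupling
    )
    if (!length(starts)) return(NULL)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + len, params$chrom_length_bp),
               family = fam, stringsAsFactors = FALSE)
  })
  repeats <- do.call(rbind, rep_list)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  list(
    genes = genes,
    snps = rbind(coding_snps, nc_snps),
    repeats = repeats,
    truth = list(
      genes = data.frame(gene_name = genes$gene_name, status = status,
                         xci_subject = xci_subject, impaired = impaired,
                         stringsAsFactors = FALSE),
      ncsnps = data.frame(snp_id = nc_snps$snp_id, pattern = nc_pattern,
                          stringsAsFactors = FALSE)
    )
  )
}

# Homogeneous Poisson starts at rate_per_kb outside the hot intervals and
# rate * hot_multiplier inside them.
.sample_piecewise_poisson <- function(chrom_length, rate_per_kb,
                                      hot_start, hot_end, hot_multiplier) {
  n_base <- stats::rpois(1, rate_per_kb * chrom_length / 1000)
  starts <- if (n_base > 0)
    sort(sample.int(chrom_length, n_base, replace = TRUE) - 1L) else integer(0)
  if (length(hot_start) == 0L || hot_multiplier == 1) return(starts)
  in_hot <- function(p) {
    res <- rep(FALSE, length(p))
    for (i in seq_along(hot_start))
      res <- res | (p >= hot_start[i] & p < hot_end[i])
    res
  }
  if (hot_multiplier < 1) {
    hot <- in_hot(starts)
    keep <- !hot | stats::runif(length(starts)) < hot_multiplier
    return(starts[keep])
  }
  extra <- lapply(seq_along(hot_start), function(i) {
    len <- hot_end[i] - hot_start[i]
    k <- stats::rpois(1, (hot_multiplier - 1) * rate_per_kb * len / 1000)
    if (k > 0) hot_start[i] + sample.int(len, k, replace = TRUE) - 1L
    else integer(0)
  })
  sort(c(starts, unlist(extra)))
}

# Per-SNP 129-allele read probability for one genotype.
.p129_for <- function(snps, truth, genotype, params) {
  p <- numeric(nrow(snps))
  coding <- snps$panel == "coding"
  status <- truth$genes$status[match(snps$gene_name, truth$genes$gene_name)]
  pattern <- truth$ncsnps$pattern[match(snps$snp_id, truth$ncsnps$snp_id)]
  if (genotype == "XaXa") {
    p[coding] <- 0.5
    p[!coding] <- c(xist_silenced = 0.5, xist_reactivated = 0.5,
                    nonxist_129_silenced = 0, nonxist_129_active = 0.5
    )[pattern[!coding]]
  } else if (genotype == "XiXa_control") {
    p[coding] <- ifelse(status[coding] == "escapee", params$escapee_p129,
                        params$leakage)
    p[!coding] <- c(xist_silenced = 0, xist_reactivated = 0,
                    nonxist_129_silenced = 0, nonxist_129_active = 0.5
    )[pattern[!coding]]
  } else if (genotype == "XiXa_mutant") {
    p[coding] <- ifelse(status[coding] == "escapee", params$escapee_p129,
                 ifelse(status[coding] == "reactivated",
                        params$reactivation_effect, params$leakage))
    p[!coding] <- c(xist_silenced = 0,
                    xist_reactivated = params$reactivation_effect,
                    nonxist_129_silenced = 0, nonxist_129_active = 0.5
    )[pattern[!coding]]
  } else {
    stop("unknown genotype tag '", genotype, "'")
  }
  p
}

# Emit a base-call table for given per-SNP p129: read totals Poisson,
# allele of origin Binomial, miscalls uniform over the 3 alternative bases.
.emit_basecalls <- function(snps, p129, params, sample_id) {
  n <- nrow(snps)
  total <- stats::rpois(n, params$mean_coverage)
  n129 <- stats::rbinom(n, total, p129)
  ncast <- total - n129
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, .BASES))
  i129 <- match(snps$allele129, .BASES)
  icast <- match(snps$alleleCast, .BASES)
  spread <- function(n_src, i_src) {
    err <- stats::rbinom(n, n_src, params$error_rate)
    kept <- n_src - err
    # distribute miscalls uniformly over the 3 bases other than the source
    x1 <- stats::rbinom(n, err, 1 / 3)
    x2 <- stats::rbinom(n, err - x1, 1 / 2)
    x3 <- err - x1 - x2
    others <- vapply(i_src, function(b) seq_len(4L)[-b], integer(3))
    idx <- cbind(seq_len(n), i_src)
    counts[idx] <<- counts[idx] + kept
    counts[cbind(seq_len(n), others[1, ])] <<-
      counts[cbind(seq_len(n), others[1, ])] + x1
    counts[cbind(seq_len(n), others[2, ])] <<-
      counts[cbind(seq_len(n), others[2, ])] + x2
    counts[cbind(seq_len(n), others[3, ])] <<-
      counts[cbind(seq_len(n), others[3, ])] + x3
  }
  spread(n129, i129)
  spread(ncast, icast)
  data.frame(
    snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
    strand = snps$strand, sample_id = sample_id,
    countA = counts[, "A"], countC = counts[, "C"],
    countG = counts[, "G"], countT = counts[, "T"],
    allele129 = snps$allele129, alleleCast = snps$alleleCast,
    stringsAsFactors = FALSE
  )
}

# Deterministic per-sample seed derived from the run seed and sample label.
.sample_seed <- function(rng_seed, label) {
  (as.integer(rng_seed) %% 1000003L) * 1000L +
    sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 997L
}

#' Simulate a base-call table for one cell-type genotype
#'
#' Emits allele-resolved counts for every SNP of the annotation under one of
#' the three cell-type genotypes: `XaXa` (pre-XCI, biallelic), `XiXa_control`
#' (X129 inactivated), `XiXa_mutant` (Xist deleted from Xi129; truth-
#' reactivated genes and ncSNPs express the 129 allele at
#' `reactivation_effect`). Read totals are Poisson(`mean_coverage`), the
#' allele of origin is Binomial, and each read is miscalled to a uniformly
#' chosen other base with probability `error_rate` — so with `error_rate =
#' 0` the two non-allele base counts are exactly zero, and a silenced gene
#' in the control has exactly zero 129 counts when `leakage = 0`.
#'
#' @param params A [sim_params()].
#' @param genotype `"XaXa"`, `"XiXa_control"` or `"XiXa_mutant"`.
#' @param annotation Output of [simulate_annotation()].
#' @param sample_id Sample label; also seeds the sample-specific RNG stream,
#'   so different labels give independent noise while the pair
#'   (`rng_seed`, `sample_id`) is fully deterministic.
#' @return A base-call data frame (see [read_basecall_table()]).
#' @export
simulate_basecalls <- function(params, genotype, annotation,
                               sample_id = genotype) {
  stopifnot(inherits(params, "sim_params"))
  p <- .p129_for(annotation$snps, annotation$truth, genotype, params)
  set.seed(.sample_seed(params$rng_seed, paste0(genotype, ":", sample_id)))
  .emit_basecalls(annotation$snps, p, params, sample_id)
}

#' Simulate a differentiation time course
#'
#' Emits base-call tables for the coding-gene panel at three points of an
#' in vitro ES-cell differentiation: `day0` (undifferentiated, biallelic),
#' `day4_control` (XCI established: XCI-subject genes silence the 129
#' allele; escapees retain partial 129 expression), and `day4_inhibited`
#' (Pol III inhibited during differentiation: truth-impaired genes recover
#' 129 expression at `impair_effect`, all others behave as the control).
#'
#' @param params A [sim_params()].
#' @param annotation Output of [simulate_annotation()].
#' @return Named list of three base-call data frames: `day0`,
#'   `day4_control`, `day4_inhibited`.
#' @export
simulate_differentiation <- function(params, annotation) {
  stopifnot(inherits(params, "sim_params"))
  snps <- annotation$snps[annotation$snps$panel == "coding", , drop = FALSE]
  tg <- annotation$truth$genes
  status <- tg$status[match(snps$gene_name, tg$gene_name)]
  xci <- tg$xci_subject[match(snps$gene_name, tg$gene_name)]
  imp <- tg$impaired[match(snps$gene_name, tg$gene_name)]
  esc <- status == "escapee"
  p_day0 <- rep(0.5, nrow(snps))
  p_ctrl <- ifelse(esc, params$escapee_p129,
                   ifelse(xci, params$leakage, 0.5))
  p_inh <- ifelse(esc, params$escapee_p129,
                  ifelse(xci & imp, params$impair_effect,
                         ifelse(xci, params$leakage, 0.5)))
  emit <- function(pvec, sid) {
    set.seed(.sample_seed(params$rng_seed, sid))
    .emit_basecalls(snps, pvec, params, sid)
  }
  list(day0 = emit(p_day0, "day0"),
       day4_control = emit(p_ctrl, "day4_control"),
       day4_inhibited = emit(p_inh, "day4_inhibited"))
}

#' Simulate two-TAD 5C contact matrices
#'
#' Generates a control and a treated contact matrix over `n_frags` equal
#' fragments containing two topologically associating domains split at
#' `tad_boundary`. Expected counts follow a power-law distance decay,
#' multiplied by `tad_strength` for within-TAD pairs; counts are Poisson and
#' the matrices are exactly symmetric. The treated sample adds
#' boundary-proximal interactions: expected counts are inflated by
#' `1 + perturbation * exp(-(|i-b| + |j-b|) / boundary_width)`, emulating
#' gained contacts around the domain boundary. With `perturbation = 0` the
#' two samples are drawn from the identical model.
#'
#' @param n_frags Number of fragments.
#' @param tad_boundary Fragment index of the boundary (first TAD is
#'   fragments `1..tad_boundary`).
#' @param perturbation Boundary-interaction gain of the treated sample.
#' @param seed Integer seed.
#' @param frag_bp Fragment size in bp (default 5000).
#' @param depth Expected self-interaction count scale (default 500).
#' @param tad_strength Within-TAD enrichment factor (default 3).
#' @param decay Distance-decay exponent (default 1).
#' @param boundary_width Decay length (fragments) of the boundary
#'   perturbation kernel (default 5).
#' @return List with `control` and `treated` [contact_matrix()] objects and
#'   `tad_boundary`.
#' @export
simulate_contact_matrices <- function(n_frags, tad_boundary, perturbation = 1,
                                      seed = 1L, frag_bp = 5000, depth = 500,
                                      tad_strength = 3, decay = 1,
                                      boundary_width = 5) {
  stopifnot(tad_boundary > 0, tad_boundary < n_frags)
  set.seed(seed)
  i <- matrix(seq_len(n_frags), n_frags, n_frags)
  j <- t(i)
  same_tad <- (i <= tad_boundary) == (j <= tad_boundary)
  expected <- depth * (1 + abs(i - j))^(-decay) *
    ifelse(same_tad, tad_strength, 1)
  boundary_gain <- 1 + perturbation *
    exp(-(abs(i - tad_boundary) + abs(j - tad_boundary)) / boundary_width)
  draw <- function(mu) {
    x <- matrix(0, n_frags, n_frags)
    upper <- upper.tri(mu, diag = TRUE)
    x[upper] <- stats::rpois(sum(upper), mu[upper])
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    x
  }
  frag_start <- (seq_len(n_frags) - 1) * frag_bp
  frag_end <- frag_start + frag_bp
  list(
    control = contact_matrix(draw(expected), frag_start, frag_end, "control"),
    treated = contact_matrix(draw(expected * boundary_gain),
                             frag_start, frag_end, "treated"),
    tad_boundary = tad_boundary
  )
}
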