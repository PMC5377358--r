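#' Estimate and deduct the per-SNP sequencing error
#'
#' At every SNP only two bases are genuine alleles (the 129 base and the Cast
#' base); reads carrying either of the two remaining bases must be sequencing
#' errors. Pooling those two error bases gives a per-substitution error-rate
#' estimate `eps = N_err / (2 * N_tot)` (`N_err` counts reads at the two
#' non-allele bases, `N_tot` all reads at the SNP). Since a miscall is equally
#' likely to land on any of the three alternative bases, the expected number
#' of reads from the Cast allele miscalled as the 129 base is `eps * n_cast`,
#' and symmetrically; this cross-contamination is subtracted from each allele
#' count and clamped at zero.
#'
#' @param records Base-call data frame (see [read_basecall_table()]).
#' @return A data frame with one row per input record: `c129_raw`,
#'   `ccast_raw` (raw counts at the allele bases), `error_rate_hat`, and the
#'   corrected real-valued counts `c129`, `ccast`.
#' @examples
#' rec <- data.frame(countA = 4800, countC = 5, countG = 190, countT = 5,
#'                   allele129 = "A", alleleCast = "G")
#' estimate_and_correct(rec)  # eps = 0.001, c129 = 4799.81, ccast = 185.2
#' @export
estimate_and_correct <- function(records) {
  counts <- as.matrix(records[, paste0("count", .BASES)])
  i129 <- match(records$allele129, .BASES)
  icast <- match(records$alleleCast, .BASES)
  n <- nrow(records)
  c129_raw <- counts[cbind(seq_len(n), i129)]
  ccast_raw <- counts[cbind(seq_len(n), icast)]
  total <- rowSums(counts)
  n_err <- total - c129_raw - ccast_raw
  eps <- ifelse(total > 0, n_err / (2 * total), 0)
  data.frame(
    c129_raw = c129_raw,
    ccast_raw = ccast_raw,
    error_rate_hat = eps,
    c129 = pmax(0, c129_raw - eps * ccast_raw),
    ccast = pmax(0, ccast_raw - eps * c129_raw)
  )
}

#' Apply the per-allele detection threshold
#'
#' An allele whose (corrected) read count is less than or equal to the
#' detection threshold is considered undetected and its count is set to 0.
#'
#' @param c Numeric vector of corrected allele counts (may be real-valued).
#' @param threshold Detection threshold (default 10).
#' @return `c` with values `<= threshold` replaced by 0.
#' @export
apply_detection_threshold <- function(c, threshold = 10) {
  stopifnot(all(c >= 0))
  ifelse(c <= threshold, 0, c)
}

#' Pseudo-counted allelotype ratio r
#'
#' `r = (c129 + pseudo) / (ccast + pseudo)`. If both thresholded counts are
#' zero the SNP is undetected and `r` is `NA` (such SNPs are excluded from
#' further analysis).
#'
#' @param c129,ccast Thresholded allele counts (vectors).
#' @param pseudo_count Pseudo-count (default 10).
#' @return Numeric vector of ratios, `NA` where both counts are 0.
#' @examples
#' compute_r(0, 5000)  # 10/5010
#' compute_r(5000, 0)  # 5010/10 = 501
#' compute_r(0, 0)     # NA: undetected
#' @export
compute_r <- function(c129, ccast, pseudo_count = 10) {
  r <- (c129 + pseudo_count) / (ccast + pseudo_count)
  r[c129 == 0 & ccast == 0] <- NA_real_
  r
}

#' Five-way allelotype classification
#'
#' Classifies the allelotype ratio into `cast_specific` (`r <= t1`),
#' `biallelic` (`t2 < r < t3`), `129_specific` (`r >= t4`) or `undetermined`
#' (the buffer zones `(t1, t2]` and `[t3, t4)`); `NA` ratios (both alleles
#' undetected) map to `undetected`. With the default thresholds
#' `(0.01, 0.01, 100, 100)` the undetermined buffers are empty and the three
#' informative labels partition all positive ratios.
#'
#' @param r Numeric vector of allelotype ratios (`NA` = undetected).
#' @param thresholds Length-4 vector `(t1, t2, t3, t4)`, `t1 <= t2 < t3 <= t4`.
#' @return Character vector of labels.
#' @export
classify_allelotype <- function(r, thresholds = c(0.01, 0.01, 100, 100)) {
  if (length(thresholds) != 4L ||
      !(thresholds[1] <= thresholds[2] && thresholds[2] < thresholds[3] &&
        thresholds[3] <= thresholds[4]))
    stop("thresholds must satisfy t1 <= t2 < t3 <= t4")
  out <- rep("undetermined", length(r))
  out[r <= thresholds[1]] <- "cast_specific"
  out[r > thresholds[2] & r < thresholds[3]] <- "biallelic"
  out[r >= thresholds[4]] <- "129_specific"
  out[is.na(r)] <- "undetected"
  out
}

#' Per-SNP allelotyping pipeline
#'
#' Runs the full per-SNP chain on a base-call table: sequencing-error
#' estimation and deduction ([estimate_and_correct()]), per-allele detection
#' thresholding ([apply_detection_threshold()]), pseudo-counted ratio
#' ([compute_r()]) and five-way classification ([classify_allelotype()]).
#'
#' @param records Base-call data frame.
#' @param config A [run_config()] object.
#' @return A data frame with the identifying columns of `records` plus
#'   `c129_raw`, `ccast_raw`, `error_rate_hat`, `c129`, `ccast`, `r`, `label`.
#' @export
allelotype_table <- function(records, config = run_config()) {
  validate_basecalls(records)
  corr <- estimate_and_correct(records)
  c129 <- apply_detection_threshold(corr$c129, config$detection_threshold)
  ccast <- apply_detection_threshold(corr$ccast, config$detection_threshold)
  r <- compute_r(c129, ccast, config$pseudo_count)
  label <- classify_allelotype(r, config$allelotype_thresholds)
  cbind(
    records[, c("snp_id", "chrom", "pos", "strand", "sample_id")],
    data.frame(
      c129_raw = corr$c129_raw, ccast_raw = corr$ccast_raw,
      error_rate_hat = corr$error_rate_hat,
      c129 = c129, ccast = ccast, r = r, label = label
    )
  )
}
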