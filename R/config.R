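#' Analysis configuration
#'
#' Bundles the numeric thresholds used throughout the allelotyping pipeline
#' into a single validated object. The defaults are the ones used for the
#' primary analysis: a per-allele detection threshold of 10 reads, a
#' pseudo-count of 10 added to both allele counts before forming the
#' allelotype ratio `r = reads129/readsCast`, a 3-fold change requirement for
#' reactivation calls, and biallelic bounds `0.01 < r < 100`.
#'
#' @param detection_threshold Per-allele read-count detection threshold.
#'   A corrected allele count less than or equal to this value is set to 0
#'   (the allele is "undetected").
#' @param pseudo_count Pseudo-count added to each allele count before taking
#'   the ratio, preventing division by zero.
#' @param fold_threshold Minimum fold change of the allelotype (mutant over
#'   control, or between differentiation time points) required for a
#'   reactivation / XCI-impairment call.
#' @param biallelic_bounds Length-2 numeric `(lo, hi)`: a sample is called
#'   biallelic when `lo < r < hi`.
#' @param allelotype_thresholds Length-4 numeric `(t1, t2, t3, t4)` with
#'   `t1 <= t2 < t3 <= t4`. Classification: `r <= t1` cast-specific,
#'   `t2 < r < t3` biallelic, `r >= t4` 129-specific, anything in `(t1, t2]`
#'   or `[t3, t4)` undetermined. The defaults collapse the undetermined
#'   buffers to empty sets.
#' @param window_kb,step_kb,flank_kb Sliding-window parameters (kb) for the
#'   TSS flank repeat profiles: 3 kb windows, 1 kb step, 20 kb flanks.
#' @param bin_size 5C matrix binning factor (median over `bin_size` x
#'   `bin_size` blocks).
#' @param fivec_pseudocount Pseudocount replacing a subtractive 5C
#'   interaction of exactly zero before the logarithm.
#' @param rng_seed Seed recorded for operations that draw random numbers
#'   (e.g. representative gene-ID selection).
#'
#' @return An object of class `run_config` (a named list).
#' @examples
#' cfg <- run_config()
#' cfg$pseudo_count
#' @export
run_config <- function(detection_threshold = 10,
                       pseudo_count = 10,
                       fold_threshold = 3,
                       biallelic_bounds = c(0.01, 100),
                       allelotype_thresholds = c(0.01, 0.01, 100, 100),
                       window_kb = 3,
                       step_kb = 1,
                       flank_kb = 20,
                       bin_size = 4,
                       fivec_pseudocount = 1,
                       rng_seed = 1L) {
  if (length(allelotype_thresholds) != 4L || any(!is.finite(allelotype_thresholds)))
    stop("'allelotype_thresholds' must be four finite numbers (t1, t2, t3, t4)")
  t <- allelotype_thresholds
  if (any(t <= 0))
    stop("allelotype thresholds must be positive")
  if (!(t[1] <= t[2] && t[2] < t[3] && t[3] <= t[4]))
    stop("allelotype thresholds must satisfy t1 <= t2 < t3 <= t4")
  if (length(biallelic_bounds) != 2L || biallelic_bounds[1] >= biallelic_bounds[2] ||
      any(biallelic_bounds <= 0))
    stop("'biallelic_bounds' must be positive with lo < hi")
  if (pseudo_count < 0) stop("'pseudo_count' must be >= 0")
  if (detection_threshold < 0) stop("'detection_threshold' must be >= 0")
  if (fold_threshold <= 0) stop("'fold_threshold' must be > 0")
  if (window_kb <= 0 || step_kb <= 0 || flank_kb <= 0)
    stop("window/step/flank sizes must be > 0")
  if (bin_size < 1) stop("'bin_size' must be >= 1")
  structure(list(
    detection_threshold = detection_threshold,
    pseudo_count = pseudo_count,
    fold_threshold = fold_threshold,
    biallelic_bounds = biallelic_bounds,
    allelotype_thresholds = allelotype_thresholds,
    window_kb = window_kb,
    step_kb = step_kb,
    flank_kb = flank_kb,
    bin_size = bin_size,
    fivec_pseudocount = fivec_pseudocount,
    rng_seed = as.integer(rng_seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("padlockxci run configuration\n")
  cat(sprintf("  detection threshold : %g reads per allele\n", x$detection_threshold))
  cat(sprintf("  pseudo-count        : %g\n", x$pseudo_count))
  cat(sprintf("  fold threshold      : %g\n", x$fold_threshold))
  cat(sprintf("  biallelic bounds    : %g < r < %g\n",
              x$biallelic_bounds[1], x$biallelic_bounds[2]))
  cat(sprintf("  allelotype thresholds: (%s)\n",
              paste(x$allelotype_thresholds, collapse = ", ")))
  cat(sprintf("  TSS flanks          : %g kb windows, %g kb step, %g kb flank\n",
              x$window_kb, x$step_kb, x$flank_kb))
  cat(sprintf("  5C binning          : %g x %g median, pseudocount %g\n",
              x$bin_size, x$bin_size, x$fivec_pseudocount))
  cat(sprintf("  rng seed            : %d\n", x$rng_seed))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file whose keys are a subset of the [run_config()] arguments
#' and merges them with the defaults. With `path = NULL` the defaults are
#' returned unchanged. Unknown keys are an error (they would otherwise be
#' silently ignored, hiding typos).
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A `run_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  for (key in c("biallelic_bounds", "allelotype_thresholds"))
    if (!is.null(vals[[key]])) vals[[key]] <- as.numeric(unlist(vals[[key]]))
  do.call(run_config, vals)
}
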