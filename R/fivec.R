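#' 5C contact matrix
#'
#' A square symmetric matrix of interaction counts over an ordered list of
#' genomic fragments.
#'
#' @param values Square numeric matrix, symmetric, non-negative.
#' @param frag_start,frag_end Fragment interval coordinates (0-based
#'   half-open), one per matrix row.
#' @param sample_id Sample identifier.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, frag_start, frag_end,
                           sample_id = "sample") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (length(frag_start) != nrow(values) || length(frag_end) != nrow(values))
    stop("fragment coordinates must match matrix dimension")
  if (any(frag_start >= frag_end)) stop("fragment start must be < end")
  if (any(values < 0)) stop("contact counts must be non-negative")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8)))
    stop("contact matrix must be symmetric")
  structure(list(values = values, frag_start = frag_start,
                 frag_end = frag_end, sample_id = sample_id),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix '%s': %d fragments spanning %d-%d bp, total %g\n",
              x$sample_id, nrow(x$values), min(x$frag_start),
              max(x$frag_end), sum(x$values)))
  invisible(x)
}

#' Normalise a contact matrix by sequencing depth
#'
#' Scales every entry by `reference_total / sum(values)` so that samples
#' sequenced to different depths become comparable. The default reference is
#' the matrix's own total (identity); to compare samples, pass a common
#' reference such as the mean of the sample totals.
#'
#' @param m A [contact_matrix()].
#' @param reference_total Target total count.
#' @return A depth-normalised `contact_matrix`.
#' @export
depth_normalize <- function(m, reference_total = NULL) {
  total <- sum(m$values)
  if (total <= 0) stop("cannot depth-normalize a matrix with zero total")
  if (is.null(reference_total)) reference_total <- total
  contact_matrix(m$values * (reference_total / total),
                 m$frag_start, m$frag_end, m$sample_id)
}

# Median binning of a plain matrix: output cell (a,b) is the median of the
# k x k input block (edge blocks may be smaller). The even-count median is
# the mean of the two central values (stats::median).
.bin_median_matrix <- function(x, k) {
  stopifnot(k >= 1)
  n <- nrow(x)
  groups <- split(seq_len(n), ceiling(seq_len(n) / k))
  m <- length(groups)
  out <- matrix(0, m, m)
  for (a in seq_len(m))
    for (b in seq_len(m))
      out[a, b] <- stats::median(x[groups[[a]], groups[[b]]])
  out
}

#' Median-bin a contact matrix
#'
#' Bins the matrix `k x k` by taking the median of each block (the display
#' resolution used for 5C heatmaps). Fragment coordinates of a binned row
#' span from the first to the last constituent fragment.
#'
#' @param m A [contact_matrix()] (or a plain matrix, returned as such).
#' @param k Binning factor (default 4); `k = 1` is the identity.
#' @return A binned `contact_matrix` (or plain matrix).
#' @export
bin_median <- function(m, k = 4) {
  if (is.matrix(m)) return(.bin_median_matrix(m, k))
  n <- nrow(m$values)
  groups <- split(seq_len(n), ceiling(seq_len(n) / k))
  contact_matrix(
    .bin_median_matrix(m$values, k),
    frag_start = unname(vapply(groups, function(g) m$frag_start[g[1]],
                               numeric(1))),
    frag_end = unname(vapply(groups, function(g) m$frag_end[g[length(g)]],
                             numeric(1))),
    sample_id = m$sample_id
  )
}

#' Subtractive contact map with sign-preserving log
#'
#' Computes the difference map between a treated and a control sample
#' (both already depth-normalised to a common total), bins it `bin x bin` by
#' the median, and applies a sign-preserving logarithm:
#' `L = sign(D) * log10(|D|)`, where a binned difference of exactly zero is
#' replaced by the pseudocount (so `L = 0` with the default pseudocount 1).
#' Swapping the two samples negates the output entrywise.
#'
#' Note a sharp corner of this transform: a difference with `0 < |D| < 1`
#' has `log10(|D|) < 0`, so the sign-preserving product flips its sign
#' (magnitude of the log, sign of the raw difference times the log's own
#' sign). The pseudocount applies only at exactly zero. With count-scale
#' data, binned medians below 1 in magnitude are rare.
#'
#' @param treated,control [contact_matrix()] objects on identical fragments.
#' @param pseudocount Replacement for `|D| == 0` before the log (default 1).
#' @param bin Median-binning factor applied to the difference (default 4).
#' @param base Logarithm base (default 10).
#' @return An object of class `signed_log_matrix`: `values` (signed log
#'   matrix), `frag_start`, `frag_end` (binned), `provenance`.
#' @export
subtract_and_log <- function(treated, control, pseudocount = 1, bin = 4,
                             base = 10) {
  if (!isTRUE(all.equal(treated$frag_start, control$frag_start)) ||
      !isTRUE(all.equal(treated$frag_end, control$frag_end)))
    stop("treated and control matrices have mismatched fragment coordinates")
  d <- treated$values - control$values
  D <- .bin_median_matrix(d, bin)
  Dabs <- abs(D)
  Dabs[Dabs == 0] <- pseudocount
  L <- sign(D) * log(Dabs, base = base)
  n <- nrow(treated$values)
  groups <- split(seq_len(n), ceiling(seq_len(n) / bin))
  structure(list(
    values = L,
    frag_start = unname(vapply(groups, function(g) treated$frag_start[g[1]],
                               numeric(1))),
    frag_end = unname(vapply(groups, function(g) treated$frag_end[g[length(g)]],
                             numeric(1))),
    provenance = list(treated_id = treated$sample_id,
                      control_id = control$sample_id,
                      pseudocount = pseudocount, bin = bin, log_base = base)
  ), class = "signed_log_matrix")
}

#' Interaction profile of one anchor fragment
#'
#' Extracts the row of a (binned) contact matrix at the anchor fragment,
#' with fragment midpoints for plotting, ordered by genomic distance from
#' the anchor (the anchor's self-interaction comes first). By symmetry the
#' row equals the corresponding column.
#'
#' @param m A [contact_matrix()] or `signed_log_matrix`.
#' @param anchor_index 1-based fragment index.
#' @return Data frame `frag`, `midpoint_bp`, `distance_bp`, `value`, sorted
#'   by `distance_bp`.
#' @export
anchor_profile <- function(m, anchor_index) {
  n <- nrow(m$values)
  if (anchor_index < 1 || anchor_index > n)
    stop("anchor index out of range [1, ", n, "]")
  mid <- (m$frag_start + m$frag_end) / 2
  out <- data.frame(
    frag = seq_len(n),
    midpoint_bp = mid,
    distance_bp = abs(mid - mid[anchor_index]),
    value = m$values[anchor_index, ]
  )
  out[order(out$distance_bp, out$frag), , drop = FALSE]
}
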