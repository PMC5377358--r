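# fixed base order used everywhere counts are stored
.BASES <- c("A", "C", "G", "T")

#' Read a per-SNP base-call count table
#'
#' The base-call table is the pipeline's primary input: one row per SNP per
#' sample, with the raw A/C/G/T base-call counts observed at the SNP position
#' and the two known allele bases (129 strain and Castaneus strain). Counts
#' are stored in fixed A,C,G,T column order so files diff cleanly.
#'
#' @param path Path to a tab-separated file with header columns
#'   `snp_id, chrom, pos, strand, sample_id, countA, countC, countG, countT,
#'   allele129, alleleCast`. `pos` is 0-based.
#' @return A data frame with one validated row per SNP x sample.
#' @details Validation: counts must be non-negative integers; the two allele
#'   bases must differ and be one of A/C/G/T; duplicate
#'   `(snp_id, sample_id)` pairs are rejected.
#' @seealso [write_basecall_table()], [allelotype_table()]
#' @export
read_basecall_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  required <- c("snp_id", "chrom", "pos", "strand", "sample_id",
                "countA", "countC", "countG", "countT",
                "allele129", "alleleCast")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("base-call table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[, required]
  if (nrow(df) == 0L) return(df)
  validate_basecalls(df)
  df
}

# shared row validation for base-call tables (also applied to simulated ones)
validate_basecalls <- function(df) {
  counts <- as.matrix(df[, paste0("count", .BASES)])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("malformed count at line %d (column %s)",
                 bad[1, 1], paste0("count", .BASES)[bad[1, 2]]))
  if (any(df$pos < 0)) stop("'pos' must be >= 0")
  if (!all(df$allele129 %in% .BASES) || !all(df$alleleCast %in% .BASES))
    stop("allele bases must be one of A, C, G, T")
  same <- df$allele129 == df$alleleCast
  if (any(same))
    stop("allele129 equals alleleCast for SNP ", df$snp_id[which(same)[1]])
  key <- paste(df$snp_id, df$sample_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate record for SNP '%s' in sample '%s'",
                 df$snp_id[i], df$sample_id[i]))
  }
  invisible(df)
}

#' Write a base-call table
#'
#' @param df A base-call data frame as returned by [read_basecall_table()] or
#'   [simulate_basecalls()].
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_basecall_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat-element annotations
#'
#' Supports BED4 (`chrom start end family`, 0-based half-open) and
#' RepeatMasker `.out` files (1-based inclusive coordinates, converted to
#' 0-based half-open on read; the family is taken from the class/family
#' column, using the part after the `/` when present). Families are
#' upper-cased into a single registry so that e.g. `Alu` and `ALU` collapse.
#'
#' @param path Input file path.
#' @param dialect `"bed"` or `"repeatmasker_out"`.
#' @return A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `family`.
#' @export
read_repeats <- function(path, dialect = c("bed", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "family"))
  } else {
    lines <- readLines(path)
    # RepeatMasker .out carries a 3-line header block (two header rows + blank)
    if (length(lines) >= 3L && grepl("^\\s*SW", lines[1]))
      lines <- lines[-(1:3)]
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(fields) < 11L))
      stop("malformed RepeatMasker .out line (fewer than 11 fields)")
    chrom <- vapply(fields, `[[`, "", 5L)
    begin <- as.integer(vapply(fields, `[[`, "", 6L))
    end <- as.integer(vapply(fields, `[[`, "", 7L))
    fam <- vapply(fields, `[[`, "", 11L)
    fam <- vapply(strsplit(fam, "/", fixed = TRUE), function(x) x[length(x)], "")
    df <- data.frame(chrom = chrom, start = begin - 1L, end = end,
                     family = fam, stringsAsFactors = FALSE)
  }
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop("non-numeric repeat coordinates")
  if (any(df$start >= df$end))
    stop("repeat interval with start >= end at line ",
         which(df$start >= df$end)[1])
  df$family <- toupper(df$family)
  df
}

#' Read and write gene models
#'
#' Gene models are stored as a knownGene-like tab-separated table with one
#' row per annotation ID: `gene_name, gene_id, chrom, strand, tss,
#' exon_starts, exon_ends, class`. Exon starts/ends are comma-separated
#' 0-based half-open coordinate lists; `tss` is the strand-appropriate
#' transcript start. `class` is one of `coding`, `escapee_constitutive`,
#' `escapee_facultative`.
#'
#' @param path File path.
#' @return A gene-model data frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_name", "gene_id", "chrom", "strand", "tss",
                "exon_starts", "exon_ends", "class")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("gene-model table is missing columns: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ex <- gene_exons(df[i, ])
    if (nrow(ex) == 0L) stop("gene ", df$gene_id[i], " has no exons")
    if (any(ex$start >= ex$end))
      stop("gene ", df$gene_id[i], " has an exon with start >= end")
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("gene ", df$gene_id[i], " exons must be sorted and non-overlapping")
  }
  df
}

#' @rdname read_gene_models
#' @param df A gene-model data frame.
#' @export
write_gene_models <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exon intervals of one gene model row
#'
#' @param gene A single gene-model row (data frame with `exon_starts` and
#'   `exon_ends` comma-separated strings).
#' @return Data frame with `start` and `end` columns (0-based half-open).
#' @export
gene_exons <- function(gene) {
  starts <- as.integer(strsplit(as.character(gene$exon_starts), ",")[[1]])
  ends <- as.integer(strsplit(as.character(gene$exon_ends), ",")[[1]])
  if (length(starts) != length(ends))
    stop("exon_starts and exon_ends have different lengths")
  data.frame(start = starts, end = ends)
}

#' Read and write 5C contact matrices
#'
#' The on-disk format is a square tab-separated matrix preceded by two
#' columns holding the fragment start/end coordinates: columns `start`,
#' `end`, then one numeric column per fragment.
#'
#' @param path File path.
#' @param sample_id Sample identifier attached to the returned object.
#' @return A [contact_matrix()] object.
#' @export
read_contact_matrix <- function(path, sample_id = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("start", "end") %in% names(df)[1:2]))
    stop("contact-matrix file must begin with 'start' and 'end' columns")
  vals <- as.matrix(df[, -(1:2)])
  dimnames(vals) <- NULL
  contact_matrix(vals, frag_start = df$start, frag_end = df$end,
                 sample_id = sample_id)
}

#' @rdname read_contact_matrix
#' @param m A `contact_matrix` object.
#' @export
write_contact_matrix <- function(m, path) {
  df <- data.frame(start = m$frag_start, end = m$frag_end)
  df <- cbind(df, as.data.frame(m$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
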