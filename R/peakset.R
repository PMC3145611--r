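#' Construct a peak set
#'
#' A `peak_set` is the universal currency of the toolkit: an ordered table of
#' genomic intervals in 0-based half-open coordinates (BED convention), one
#' row per peak. Extra columns beyond the core five are preserved opaquely.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, 0-based exclusive end positions (`end > start`).
#' @param id optional peak labels; auto-generated (`peak_1`, ...) when `NULL`.
#' @param score optional numeric scores.
#' @param source provenance string stored as an attribute.
#' @param ... additional equal-length columns to carry along.
#' @return A data frame of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `id`, `score` (and any extras).
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     id = NULL, score = NULL, source = "", ...) {
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("peak_set: chromosome names must be non-empty")
    if (any(start < 0)) stop("peak_set: start positions must be >= 0")
    bad <- which(end <= start)
    if (length(bad))
      stop("peak_set: end <= start at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(id)) id <- if (n) paste0("peak_", seq_len(n)) else character()
  if (is.null(score)) score <- rep(NA_real_, n)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = as.character(id), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  attr(df, "source") <- source
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Coerce a data frame to a peak set
#' @param x data frame with at least `chrom`, `start`, `end` columns.
#' @param source provenance string.
#' @return A `peak_set`.
#' @export
as_peak_set <- function(x, source = "") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  ps <- peak_set(x$chrom, x$start, x$end,
                 id = if ("id" %in% names(x)) x$id else NULL,
                 score = if ("score" %in% names(x)) x$score else NULL,
                 source = source)
  for (nm in setdiff(names(x), c("chrom", "start", "end", "id", "score")))
    ps[[nm]] <- x[[nm]]
  ps
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peak(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# subsetting keeps the class and source attribute
#' @export
`[.peak_set` <- function(x, ...) {
  src <- attr(x, "source")
  out <- NextMethod()
  if (is.data.frame(out) && all(c("chrom", "start", "end") %in% names(out))) {
    class(out) <- c("peak_set", "data.frame")
    attr(out, "source") <- src
  }
  out
}

peak_lengths <- function(peaks) peaks$end - peaks$start

#' Construct a read set
#'
#' Mapped sequencing reads reduced to (chromosome, 0-based start, strand)
#' triplets plus a fragment-extension length used when computing coverage.
#'
#' @param reads data frame with columns `chrom`, `start` (0-based), `strand`
#'   (`"+"` or `"-"`), and optionally `read_len`.
#' @param fragment_length extension length in bp (default 200).
#' @param skipped count of unusable (e.g. unmapped) records dropped on input.
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, fragment_length = 200L, skipped = 0L) {
  stopifnot(all(c("chrom", "start", "strand") %in% names(reads)),
            fragment_length > 0)
  if (!"read_len" %in% names(reads))
    reads$read_len <- rep(NA_integer_, nrow(reads))
  reads$start <- as.integer(reads$start)
  structure(list(reads = reads,
                 total_reads = nrow(reads),
                 fragment_length = as.integer(fragment_length),
                 skipped = as.integer(skipped)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d read(s), fragment length %d bp, %d skipped\n",
              x$total_reads, x$fragment_length, x$skipped))
  invisible(x)
}

#' Construct a gene-model table
#'
#' Transcript models in half-open coordinates with parallel exon lists, the
#' representation behind all promoter/exon/intron/downstream logic. The
#' transcription start site (TSS) is `tx_start` on the `+` strand and
#' `tx_end - 1` on the `-` strand.
#'
#' @param name transcript identifiers.
#' @param symbol gene symbols.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per transcript.
#' @param tx_start,tx_end transcript bounds, 0-based half-open.
#' @param exon_starts,exon_ends lists of integer vectors (parallel, sorted).
#' @return A data frame of class `gene_table` with list-columns
#'   `exon_starts`, `exon_ends`.
#' @export
gene_table <- function(name, symbol, chrom, strand, tx_start, tx_end,
                       exon_starts, exon_ends) {
  n <- length(name)
  stopifnot(all(strand %in% c("+", "-")),
            length(exon_starts) == n, length(exon_ends) == n)
  tx_start <- as.integer(tx_start); tx_end <- as.integer(tx_end)
  for (i in seq_len(n)) {
    es <- as.integer(exon_starts[[i]]); ee <- as.integer(exon_ends[[i]])
    if (length(es) != length(ee) || any(ee <= es) || is.unsorted(es))
      stop("gene_table: malformed exon structure for transcript ", name[i])
    if (es[1] < tx_start[i] || ee[length(ee)] > tx_end[i])
      stop("gene_table: exons outside transcript bounds for ", name[i])
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
  }
  df <- data.frame(name = as.character(name), symbol = as.character(symbol),
                   chrom = as.character(chrom), strand = as.character(strand),
                   tx_start = tx_start, tx_end = tx_end,
                   stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Transcription start sites of a gene table
#' @param genes a `gene_table`.
#' @return Integer vector of 0-based TSS positions (strand-aware).
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' Transcription end sites of a gene table
#' @param genes a `gene_table`.
#' @return Integer vector of 0-based TES positions (strand-aware).
#' @export
tes <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
}
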