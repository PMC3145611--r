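# Read-density matrices: binned coverage around TSS/TES/summit anchors,
# per-peak read-count summaries across datasets, RPKM normalization, and a
# per-gene-part density summary.

#' Binned read-density matrix around genomic anchors
#'
#' Centers a `window`-bp window on each region's anchor (TSS or TES of
#' genes, summit or midpoint of peaks), splits it into `window / bin` bins
#' and fills each bin with the mean per-base extended-read coverage. Rows of
#' `-` strand genes are flipped so column 1 is always 5'-most. With
#' `normalize = "rpkm"` values are scaled by `1e9 / (bin_bp * total_reads)`.
#' Windows running off a chromosome end are zero-filled and flagged in the
#' `truncated` attribute.
#'
#' @param anchor `"tss"`, `"tes"` (gene regions) or `"summit"` (peaks).
#' @param regions a [gene_table()] (tss/tes) or [peak_set()] (summit).
#' @param reads a [read_set()].
#' @param chrom_sizes named integer vector.
#' @param window total window in bp (default 4000).
#' @param bin bin width in bp (default 10; must divide `window`).
#' @param normalize `"none"` or `"rpkm"`.
#' @return Numeric matrix (regions x bins) with attributes `anchor`,
#'   `window`, `bin`, `normalize`, `truncated`.
#' @export
density_matrix <- function(anchor = c("tss", "tes", "summit"), regions, reads,
                           chrom_sizes, window = 4000L, bin = 10L,
                           normalize = c("none", "rpkm")) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  stopifnot(window %% bin == 0)
  nb <- window %/% bin
  if (anchor %in% c("tss", "tes")) {
    ctr <- if (anchor == "tss") tss(regions) else tes(regions)
    strand <- regions$strand
    chrom <- regions$chrom
    ids <- regions$name
  } else {
    ctr <- profile_center(regions, "summit")
    strand <- rep("+", nrow(regions))
    chrom <- regions$chrom
    ids <- regions$id
  }
  cov <- coverage_vector(reads, chrom_sizes)
  half <- window %/% 2L
  n <- length(ctr)
  mat <- matrix(0, n, nb, dimnames = list(ids, NULL))
  truncated <- logical(n)
  for (i in seq_len(n)) {
    L <- chrom_sizes[[chrom[i]]]
    ws <- ctr[i] - half; we <- ws + window
    if (is.null(L)) { truncated[i] <- TRUE; next }
    v <- numeric(window)
    from <- max(ws, 0L); to <- min(we, L)
    if (from < to)
      v[(from - ws + 1L):(to - ws)] <- cov[[chrom[i]]][(from + 1L):to]
    if (ws < 0 || we > L) truncated[i] <- TRUE
    row <- colMeans(matrix(v, nrow = bin))
    if (strand[i] == "-") row <- rev(row)   # 5' -> 3' orientation
    mat[i, ] <- row
  }
  if (normalize == "rpkm")
    mat <- mat * 1e9 / (bin * max(1L, reads$total_reads))
  attr(mat, "anchor") <- anchor
  attr(mat, "window") <- window
  attr(mat, "bin") <- bin
  attr(mat, "normalize") <- normalize
  attr(mat, "truncated") <- truncated
  mat
}

#' Per-peak read-count matrix across datasets
#'
#' For each peak and each dataset, the maximum or mean per-base coverage
#' over the peak; with `normalize = "rpkm"`, values are scaled by
#' `1e9 / (peak_length * total_reads)` per dataset.
#'
#' @param peaks a [peak_set()].
#' @param datasets named list of [read_set()]s.
#' @param stat `"max"` or `"avg"`.
#' @param chrom_sizes named integer vector.
#' @param normalize `"none"` or `"rpkm"`.
#' @return Numeric matrix (peaks x datasets).
#' @export
read_count_matrix <- function(peaks, datasets, stat = c("max", "avg"),
                              chrom_sizes, normalize = c("none", "rpkm")) {
  stat <- match.arg(stat)
  normalize <- match.arg(normalize)
  stopifnot(length(datasets) >= 1)
  if (is.null(names(datasets))) names(datasets) <- paste0("dataset", seq_along(datasets))
  mat <- matrix(0, nrow(peaks), length(datasets),
                dimnames = list(peaks$id, names(datasets)))
  lens <- peak_lengths(peaks)
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    if (ds$total_reads == 0) warning("dataset '", names(datasets)[d], "' has no reads")
    cov <- coverage_vector(ds, chrom_sizes)
    vals <- vapply(seq_len(nrow(peaks)), function(i) {
      v <- cov[[peaks$chrom[i]]]
      if (is.null(v)) return(0)
      seg <- v[(peaks$start[i] + 1L):min(peaks$end[i], length(v))]
      if (stat == "max") max(seg) else mean(seg)
    }, 0)
    if (normalize == "rpkm")
      vals <- vals * 1e9 / (lens * max(1L, ds$total_reads))
    mat[, d] <- vals
  }
  mat
}

#' Mean read density per gene-part category
#'
#' Labels the genome by annotation category and reports the mean extended-
#' read coverage over each category's territory — a plot-ready summary of
#' where the signal sits.
#'
#' @param reads a [read_set()].
#' @param genes a [gene_table()].
#' @param chrom_sizes named integer vector.
#' @param cfg an [annotation_config()].
#' @return Data frame `category, bases, mean_coverage`.
#' @export
summarize_density_in_geneparts <- function(reads, genes, chrom_sizes,
                                           cfg = annotation_config()) {
  labels <- label_genome(genes, chrom_sizes, cfg)
  cov <- coverage_vector(reads, chrom_sizes)
  sums <- numeric(length(PEAK_CATEGORIES))
  bases <- numeric(length(PEAK_CATEGORIES))
  for (ch in names(labels)) {
    lab <- labels[[ch]]
    v <- cov[[ch]]
    sums <- sums + vapply(seq_along(PEAK_CATEGORIES),
                          function(k) sum(v[lab == k]), 0)
    bases <- bases + tabulate(lab, length(PEAK_CATEGORIES))
  }
  data.frame(category = PEAK_CATEGORIES, bases = bases,
             mean_coverage = ifelse(bases > 0, sums / bases, 0),
             stringsAsFactors = FALSE)
}

#' Write a density or count matrix as TSV
#' @param mat numeric matrix with row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
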