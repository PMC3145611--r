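# Gene-level annotation of peaks: promoter / exon / first intron / intron /
# downstream / distal / other, with per-category peak lists, a gene-parts
# matrix, expected genomic fractions, closest genes and distal peaks.
#
# A peak may touch several transcripts and gather several candidate labels;
# its single primary category is resolved by the fixed priority
#   promoter > exon > first_intron > intron > downstream > distal > other
# so that the categories partition the peak set.

PEAK_CATEGORIES <- c("promoter", "exon", "first_intron", "intron",
                     "downstream", "distal", "other")

#' Annotation configuration
#'
#' @param promoter_window total promoter width in bp, centered on the TSS
#'   (default 4000, i.e. 2 kb either side); the downstream half is clipped at
#'   the transcript's downstream extremity.
#' @param downstream_window width in bp of the downstream region past the TES
#'   (default 2000).
#' @param distal_min minimum distance in bp from any transcript for a peak to
#'   count as distal/intergenic (default 2000).
#' @param database free-text label of the gene-model source.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_window = 4000L, downstream_window = 2000L,
                              distal_min = 2000L, database = "custom") {
  stopifnot(promoter_window > 0, downstream_window > 0, distal_min >= 0)
  structure(list(promoter_window = as.integer(promoter_window),
                 downstream_window = as.integer(downstream_window),
                 distal_min = as.integer(distal_min),
                 database = database),
            class = "annotation_config")
}

# Promoter window per transcript: symmetric around the TSS but never
# extending past the transcript's downstream extremity; clamped at 0.
promoter_windows <- function(genes, cfg) {
  half <- cfg$promoter_window %/% 2L
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tx_start - half, pmax(genes$tx_end - half, genes$tx_start))
  end <- ifelse(plus, pmin(genes$tx_start + half, genes$tx_end), genes$tx_end + half)
  data.frame(chrom = genes$chrom, start = pmax(as.integer(start), 0L),
             end = as.integer(end), stringsAsFactors = FALSE)
}

downstream_windows <- function(genes, cfg) {
  dw <- cfg$downstream_window
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tx_end, pmax(genes$tx_start - dw, 0L))
  end <- ifelse(plus, genes$tx_end + dw, genes$tx_start)
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# first intron in transcription order; transcripts with < 2 exons have none
first_introns <- function(genes) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 2) return(NULL)
    if (genes$strand[i] == "+")
      c(ee[1], es[2])
    else
      c(ee[length(ee) - 1L], es[length(es)])
  })
  keep <- !vapply(out, is.null, TRUE)
  data.frame(chrom = genes$chrom[keep],
             start = vapply(out[keep], `[`, 0L, 1L),
             end = vapply(out[keep], `[`, 0L, 2L), stringsAsFactors = FALSE)
}

all_introns <- function(genes) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 2) return(NULL)
    data.frame(chrom = genes$chrom[i], start = ee[-length(ee)], end = es[-1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

all_exons <- function(genes) {
  data.frame(chrom = rep(genes$chrom, lengths(genes$exon_starts)),
             start = unlist(genes$exon_starts),
             end = unlist(genes$exon_ends), stringsAsFactors = FALSE)
}

empty_frame <- function() data.frame(chrom = character(), start = integer(),
                                     end = integer(), stringsAsFactors = FALSE)

# Per-base priority labeling of the genome: integer codes into
# PEAK_CATEGORIES. Lower-priority labels are written first and overwritten.
label_genome <- function(genes, chrom_sizes, cfg) {
  labels <- lapply(chrom_sizes, function(L) {
    v <- integer(L); v[] <- match("distal", PEAK_CATEGORIES); v
  })
  paint <- function(frame, category) {
    if (is.null(frame) || !nrow(frame)) return()
    code <- match(category, PEAK_CATEGORIES)
    for (i in seq_len(nrow(frame))) {
      ch <- frame$chrom[i]
      if (is.null(labels[[ch]])) next
      L <- length(labels[[ch]])
      s <- max(frame$start[i], 0L); e <- min(frame$end[i], L)
      if (e > s) labels[[ch]][(s + 1L):e] <<- code
    }
  }
  # 'other': within distal_min of a transcript but (so far) in no part
  tx <- data.frame(chrom = genes$chrom,
                   start = pmax(genes$tx_start - cfg$distal_min, 0L),
                   end = genes$tx_end + cfg$distal_min,
                   stringsAsFactors = FALSE)
  if (cfg$distal_min > 0) paint(tx, "other")
  paint(downstream_windows(genes, cfg), "downstream")
  paint(all_introns(genes), "intron")
  paint(first_introns(genes), "first_intron")
  paint(all_exons(genes), "exon")
  paint(promoter_windows(genes, cfg), "promoter")
  labels
}

# run-length encode label vectors into category territory segments
territory_segments <- function(labels) {
  res <- lapply(names(labels), function(ch) {
    r <- rle(labels[[ch]])
    end <- cumsum(r$lengths)
    data.frame(chrom = ch, start = end - r$lengths, end = end,
               category = PEAK_CATEGORIES[r$values], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Expected genomic fraction of each annotation category
#'
#' Labels every base of the genome with its primary category (same priority
#' rule as [classify_peaks()]) and returns the fraction of the genome in
#' each category — the null expectation against which observed peak
#' fractions are compared.
#'
#' @param genes a [gene_table()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param cfg an [annotation_config()].
#' @return Named numeric vector over the seven categories, summing to 1.
#' @export
expected_fractions <- function(genes, chrom_sizes, cfg = annotation_config()) {
  labels <- label_genome(genes, chrom_sizes, cfg)
  counts <- Reduce(`+`, lapply(labels, function(v) tabulate(v, length(PEAK_CATEGORIES))))
  stats::setNames(counts / sum(counts), PEAK_CATEGORIES)
}

peak_overlaps_frame <- function(peaks, frame) {
  if (is.null(frame) || !nrow(frame)) return(logical(nrow(peaks)))
  overlaps_any(peaks, merge_peak_frame(frame))
}

# minimum gap from each peak to any transcript (0 on overlap); Inf if the
# peak's chromosome carries no gene
distance_to_genes <- function(peaks, genes) {
  out <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    for (i in sel) {
      gap <- pmax(g$tx_start - peaks$end[i], peaks$start[i] - g$tx_end)
      out[i] <- max(0, min(gap))
    }
  }
  out
}

#' Classify peaks into gene-part categories
#'
#' Each peak gathers candidate labels against every transcript (whole-peak
#' overlap with the promoter window, exons, first intron, introns, or the
#' downstream window) and is assigned one primary category by the priority
#' promoter > exon > first_intron > intron > downstream. Peaks touching no
#' gene part are `distal` when at least `distal_min` bp from every
#' transcript, `other` when nearer. Peaks on chromosomes without genes are
#' distal.
#'
#' @param peaks a [peak_set()].
#' @param genes a non-empty [gene_table()].
#' @param cfg an [annotation_config()].
#' @return A list of class `annotation_result`:
#'   * `category` — character vector, primary category per peak;
#'   * `by_category` — named list of [peak_set()]s partitioning the input;
#'   * `gene_links` — data frame `peak_id, symbol, category, distance`
#'     (distance signed: negative when the peak lies 5' of the TSS in
#'     genomic coordinates);
#'   * `observed_fractions` — category fractions of the input, summing to 1;
#'   * `config` — the configuration used.
#' @export
classify_peaks <- function(peaks, genes, cfg = annotation_config()) {
  if (!nrow(genes)) stop("classify_peaks: empty gene table")
  n <- nrow(peaks)
  prio <- matrix(FALSE, n, 5L,
                 dimnames = list(NULL, PEAK_CATEGORIES[1:5]))
  links <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    onchrom <- peaks$chrom == g$chrom
    if (!any(onchrom)) next
    pw <- promoter_windows(g, cfg); dw <- downstream_windows(g, cfg)
    fi <- first_introns(g); ex <- all_exons(g); intr <- all_introns(g)
    ov <- function(frame) {
      if (is.null(frame) || !nrow(frame)) return(logical(n))
      r <- logical(n)
      for (j in seq_len(nrow(frame)))
        r <- r | (onchrom & peaks$start < frame$end[j] & peaks$end > frame$start[j])
      r
    }
    lab <- cbind(promoter = ov(pw), exon = ov(ex), first_intron = ov(fi),
                 intron = ov(intr), downstream = ov(dw))
    prio <- prio | lab
    hit <- which(rowSums(lab) > 0)
    if (length(hit)) {
      cat_i <- PEAK_CATEGORIES[apply(lab[hit, , drop = FALSE], 1, which.max)]
      mid <- (peaks$start[hit] + peaks$end[hit]) %/% 2L
      tss_i <- if (g$strand == "+") g$tx_start else g$tx_end - 1L
      links[[length(links) + 1L]] <-
        data.frame(peak_id = peaks$id[hit], symbol = g$symbol,
                   category = cat_i, distance = mid - tss_i,
                   stringsAsFactors = FALSE)
    }
  }
  category <- rep(NA_character_, n)
  for (cat in PEAK_CATEGORIES[1:5])
    category[is.na(category) & prio[, cat]] <- cat
  unlabeled <- which(is.na(category))
  if (length(unlabeled)) {
    dist <- distance_to_genes(peaks[unlabeled, , drop = FALSE], genes)
    nogene <- !peaks$chrom[unlabeled] %in% genes$chrom
    if (any(nogene))
      warning("peak(s) on chromosome(s) without genes classified distal")
    category[unlabeled] <- ifelse(dist >= cfg$distal_min, "distal", "other")
    # link distal/other peaks to their closest gene(s)
    cl <- find_closest_genes(peaks[unlabeled, , drop = FALSE], genes)
    cl$category <- category[unlabeled][match(cl$peak_id, peaks$id[unlabeled])]
    links[[length(links) + 1L]] <- cl[, c("peak_id", "symbol", "category", "distance")]
  }
  gene_links <- if (length(links)) do.call(rbind, links)
                else data.frame(peak_id = character(), symbol = character(),
                                category = character(), distance = integer(),
                                stringsAsFactors = FALSE)
  by_category <- lapply(stats::setNames(PEAK_CATEGORIES, PEAK_CATEGORIES),
                        function(cat) peaks[category == cat, , drop = FALSE])
  obs <- table(factor(category, levels = PEAK_CATEGORIES))
  structure(list(category = category,
                 by_category = by_category,
                 gene_links = gene_links,
                 observed_fractions = stats::setNames(
                   as.numeric(obs) / max(1L, n), PEAK_CATEGORIES),
                 config = cfg,
                 peaks = peaks),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("annotation_result:\n")
  print(round(x$observed_fractions, 3))
  invisible(x)
}

#' Gene-parts matrix
#'
#' Cross-tabulates peak-gene links: one row per gene symbol, one column per
#' category, cells counting linked peaks — e.g. to find genes with both
#' promoter and distal peaks.
#'
#' @param result an [classify_peaks()] result.
#' @return An integer matrix (genes x categories).
#' @export
geneparts_matrix <- function(result) {
  gl <- result$gene_links
  if (!nrow(gl))
    return(matrix(0L, 0, length(PEAK_CATEGORIES),
                  dimnames = list(NULL, PEAK_CATEGORIES)))
  m <- table(factor(gl$symbol), factor(gl$category, levels = PEAK_CATEGORIES))
  mat <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  mat
}

#' Closest gene(s) for each peak
#'
#' Distance is 0 when the peak overlaps the transcript, otherwise the gap
#' between peak and transcript boundaries; all genes tied at the minimum are
#' reported. The `distance` column is signed: negative when the peak lies
#' left of the transcript in genomic coordinates.
#'
#' @param peaks a [peak_set()].
#' @param genes a non-empty [gene_table()].
#' @return Data frame `peak_id, symbol, name, distance`.
#' @export
find_closest_genes <- function(peaks, genes) {
  if (!nrow(genes)) stop("find_closest_genes: empty gene table")
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    right_gap <- g$tx_start - peaks$end[i]   # gene right of peak
    left_gap <- peaks$start[i] - g$tx_end    # gene left of peak
    gap <- pmax(0L, pmax(right_gap, left_gap))
    signed <- ifelse(gap == 0L, 0L, ifelse(right_gap > 0L, gap, -gap))
    best <- which(gap == min(gap))
    res[[length(res) + 1L]] <-
      data.frame(peak_id = peaks$id[i], symbol = g$symbol[best],
                 name = g$name[best], distance = signed[best],
                 stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(peak_id = character(), symbol = character(),
                      name = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Peaks at least a given distance from every gene
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_table()] (may be empty: all peaks qualify).
#' @param d minimum distance in bp (>= 0); overlapping peaks never qualify.
#' @return The qualifying subset of `peaks`.
#' @export
find_distal_peaks <- function(peaks, genes, d = 2000L) {
  stopifnot(d >= 0)
  if (!nrow(genes)) return(peaks)
  dist <- distance_to_genes(peaks, genes)
  tx <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                   end = genes$tx_end, stringsAsFactors = FALSE)
  overlapping <- peak_overlaps_frame(peaks, tx)
  peaks[!overlapping & dist >= d, , drop = FALSE]
}

#' Compare two gene lists
#'
#' @param a,b character vectors of gene symbols (case-sensitive).
#' @return `list(common =, only_a =, only_b =)` of unique symbols.
#' @export
compare_genes <- function(a, b) {
  a <- unique(a); b <- unique(b)
  list(common = intersect(a, b), only_a = setdiff(a, b), only_b = setdiff(b, a))
}

#' Annotate peaks against arbitrary interval tracks
#'
#' For each supplied track (repeats, CpG islands, segmental duplications,
#' external peak sets, ...) reports the subset of peaks overlapping it and
#' the randomization-based significance of the overlap.
#'
#' @param peaks a [peak_set()].
#' @param tracks named list of [peak_set()]s.
#' @param genes a [gene_table()] (drives the randomization's gene-part
#'   stratification).
#' @param chrom_sizes named integer vector.
#' @param n_rand randomizations per track.
#' @param seed RNG seed.
#' @param cfg an [annotation_config()].
#' @return Named list per track: `list(overlapping = peak_set, stats =
#'   overlap_stats or NULL for empty tracks)`.
#' @export
nongenic_annotate <- function(peaks, tracks, genes, chrom_sizes,
                              n_rand = 100L, seed = 1L,
                              cfg = annotation_config()) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  out <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (!nrow(tr)) {
      out[[nm]] <- list(overlapping = tr, stats = NULL,
                        note = "empty track; significance skipped")
      next
    }
    out[[nm]] <- list(
      overlapping = compare_intervals(peaks, tr, "overlap"),
      stats = overlap_significance(peaks, tr, genes, chrom_sizes,
                                   n_rand = n_rand, seed = seed, cfg = cfg))
  }
  out
}
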