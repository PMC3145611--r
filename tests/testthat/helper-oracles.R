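# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles deliberately avoid the package's own data paths: plain loops and
# linear scans only.

# exhaustive linear-scan overlap query (the oracle for the interval tree)
naive_overlap_rows <- function(df, chrom, qs, qe) {
  hits <- integer()
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] == chrom && df$start[i] < qe && qs < df$end[i])
      hits <- c(hits, i)
  }
  hits
}

# random peak frame on a couple of chromosomes
random_peak_frame <- function(n, chroms = c("chr1", "chr2"),
                              max_pos = 10000L, max_len = 300L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  peak_set(chrom, start, start + len)
}

# hand-built two-gene table used across annotation tests:
#   geneA chr1 + [10000,20000) exons [10000,12000)+[18000,20000)
#   geneB chr1 + [40000,44000) single exon
toy_genes <- function() {
  gene_table(name = c("txA", "txB"), symbol = c("geneA", "geneB"),
             chrom = c("chr1", "chr1"), strand = c("+", "+"),
             tx_start = c(10000L, 40000L), tx_end = c(20000L, 44000L),
             exon_starts = list(c(10000L, 18000L), 40000L),
             exon_ends = list(c(12000L, 20000L), 44000L))
}
toy_sizes <- c(chr1 = 100000L)

# mirror a gene table and peaks through position G - x (strand flip oracle)
mirror_genes <- function(genes, G) {
  gene_table(name = genes$name, symbol = genes$symbol, chrom = genes$chrom,
             strand = ifelse(genes$strand == "+", "-", "+"),
             tx_start = G - genes$tx_end, tx_end = G - genes$tx_start,
             exon_starts = lapply(seq_len(nrow(genes)), function(i)
               sort(G - genes$exon_ends[[i]])),
             exon_ends = lapply(seq_len(nrow(genes)), function(i)
               sort(G - genes$exon_starts[[i]])))
}
mirror_peaks <- function(peaks, G) {
  peak_set(peaks$chrom, G - peaks$end, G - peaks$start, id = peaks$id)
}

# per-base annotation labeling oracle: independent loop over windows
naive_label_genome <- function(genes, chrom_sizes, cfg) {
  out <- lapply(chrom_sizes, function(L) rep("distal", L))
  half <- cfg$promoter_window %/% 2
  # paint in priority-ascending passes over all genes
  paint_all <- function(frame, lab) {
    for (j in seq_len(nrow(frame))) {
      ch <- frame$chrom[j]
      s <- max(frame$start[j], 0); e <- min(frame$end[j], chrom_sizes[[ch]])
      if (e > s) out[[ch]][(s + 1):e] <<- lab
    }
  }
  near <- data.frame(chrom = genes$chrom,
                     start = genes$tx_start - cfg$distal_min,
                     end = genes$tx_end + cfg$distal_min)
  paint_all(near, "other")
  dw <- data.frame(chrom = genes$chrom,
                   start = ifelse(genes$strand == "+", genes$tx_end,
                                  genes$tx_start - cfg$downstream_window),
                   end = ifelse(genes$strand == "+",
                                genes$tx_end + cfg$downstream_window,
                                genes$tx_start))
  paint_all(dw, "downstream")
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) >= 2)
      paint_all(data.frame(chrom = genes$chrom[i], start = ee[-length(ee)],
                           end = es[-1]), "intron")
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) >= 2) {
      fi <- if (genes$strand[i] == "+") c(ee[1], es[2])
            else c(ee[length(ee) - 1], es[length(es)])
      paint_all(data.frame(chrom = genes$chrom[i], start = fi[1], end = fi[2]),
                "first_intron")
    }
  }
  for (i in seq_len(nrow(genes)))
    paint_all(data.frame(chrom = genes$chrom[i],
                         start = genes$exon_starts[[i]],
                         end = genes$exon_ends[[i]]), "exon")
  pw <- data.frame(chrom = genes$chrom,
                   start = ifelse(genes$strand == "+",
                                  genes$tx_start - half,
                                  pmax(genes$tx_end - half, genes$tx_start)),
                   end = ifelse(genes$strand == "+",
                                pmin(genes$tx_start + half, genes$tx_end),
                                genes$tx_end + half))
  paint_all(pw, "promoter")
  out
}

# naive per-window Berg-von Hippel scan (the oracle for scan_pwm)
naive_scan <- function(seq, counts, pc, tau) {
  width <- ncol(counts)
  bases <- c("A", "C", "G", "T")
  w <- matrix(0, 4, width)
  for (j in seq_len(width)) {
    mx <- max(counts[, j])
    for (b in 1:4) w[b, j] <- log((counts[b, j] + pc) / (mx + pc))
  }
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (o in seq_len(max(0, nchar(seq) - width + 1))) {
    sc <- 0; ok <- TRUE
    for (j in seq_len(width)) {
      b <- match(chars[o + j - 1], bases)
      if (is.na(b)) { ok <- FALSE; break }
      sc <- sc + w[b, j]
    }
    if (ok && exp(sc) >= tau)
      hits[[length(hits) + 1L]] <- c(offset = o - 1L, score = sc)
  }
  hits
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exhaustive hypergeometric upper tail by subset enumeration
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)   # pathway = elements 1..K
  mean(overlaps >= k)
}

# one shared default fixture bundle per test run (generation is cheap but
# several files reuse it)
.fixture_cache <- new.env(parent = emptyenv())
shared_fixture <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("peakatlas_fx_", seed))
    .fixture_cache[[key]] <- make_fixture(fixture_spec(seed = seed), dir)
  }
  .fixture_cache[[key]]
}
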