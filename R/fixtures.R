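# Deterministic synthetic-fixture generator: a small genome with gene
# models, spiked ChIP reads over known truth peaks, a matched control, a
# conservation track elevated over the truth peaks, CpG-island / repeat /
# histone-mark annotation tracks, an embedded motif, and gene sets planted
# on the genes nearest the truth peaks — everything needed to exercise the
# whole toolkit offline, with a ground-truth manifest.

#' Fixture specification
#'
#' Defaults describe a compact two-chromosome genome (350 kb) with ChIP
#' enrichment typical of a point-source factor: Poisson background at
#' 0.02 reads/bp, truth peaks of 500 bp at 10x local enrichment, a strong
#' 10-bp motif embedded in 80% of truth peaks, and a conservation contrast
#' of 0.8 (truth) vs 0.1 (background).
#'
#' @param seed RNG seed; the whole bundle is a deterministic function of it.
#' @param chrom_sizes named integer vector.
#' @param n_genes number of non-overlapping genes.
#' @param n_truth_peaks number of planted peaks.
#' @param peak_width truth-peak width in bp.
#' @param fold local enrichment of truth peaks over background coverage.
#' @param background_rate background read density in reads/bp.
#' @param fragment_length,read_len fragment extension and read length in bp.
#' @param motif_frac fraction of truth peaks carrying the embedded motif.
#' @param cpg_frac fraction of truth peaks overlapping a CpG island.
#' @param cons_base,cons_peak conservation scores outside/inside truth peaks.
#' @param mark1_frac,mark2_frac,cofactor_frac fraction of truth peaks
#'   covered by each annotation mark track.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         chrom_sizes = c(chr1 = 200000L, chr2 = 150000L),
                         n_genes = 20L, n_truth_peaks = 30L,
                         peak_width = 500L, fold = 10,
                         background_rate = 0.02,
                         fragment_length = 200L, read_len = 36L,
                         motif_frac = 0.8, cpg_frac = 0.3,
                         cons_base = 0.1, cons_peak = 0.8,
                         mark1_frac = 0.7, mark2_frac = 0.3,
                         cofactor_frac = 0.5) {
  structure(as.list(environment()), class = "fixture_spec")
}

# default embedded motif: strong, non-palindromic 10-mer
default_fixture_pwm <- function() {
  consensus <- c("T", "G", "A", "C", "T", "C", "A", "G", "G", "T")
  counts <- matrix(1, 4, length(consensus), dimnames = list(BASES, NULL))
  counts[cbind(match(consensus, BASES), seq_along(consensus))] <- 17
  structure(list(name = "FIXTURE_MOTIF", counts = counts), class = "pwm")
}

pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$counts, 2, which.max)], collapse = "")
}

write_fasta_with_index <- function(seqs, path, width = 70L) {
  con <- file(path, "wb")  # binary: byte offsets must be exact
  offset <- 0
  fai <- character()
  for (nm in names(seqs)) {
    hdr <- paste0(">", nm, "\n")
    writeChar(hdr, con, eos = NULL)
    offset <- offset + nchar(hdr)
    s <- seqs[[nm]]
    n <- nchar(s)
    fai <- c(fai, paste(nm, n, offset, width, width + 1L, sep = "\t"))
    starts <- seq(1L, n, by = width)
    body <- paste0(paste(substring(s, starts, pmin(starts + width - 1L, n)),
                         collapse = "\n"), "\n")
    writeChar(body, con, eos = NULL)
    offset <- offset + nchar(body)
  }
  close(con)
  writeLines(fai, paste0(path, ".fai"))
  invisible(path)
}

# rejection-sample n non-overlapping intervals of the given widths
place_nonoverlapping <- function(chrom_sizes, widths, margin, gap,
                                 max_tries = 20000L) {
  n <- length(widths)
  chrom <- character(n); start <- integer(n)
  placed <- list()
  probs <- as.numeric(chrom_sizes) / sum(as.numeric(chrom_sizes))
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      ch <- sample(names(chrom_sizes), 1L, prob = probs)
      lo <- margin; hi <- chrom_sizes[[ch]] - margin - widths[i]
      if (hi <= lo) next
      s <- lo + sample.int(hi - lo, 1L)
      e <- s + widths[i]
      ok <- TRUE
      for (p in placed)
        if (p$chrom == ch && s < p$end + gap && e > p$start - gap) { ok <- FALSE; break }
      if (ok) {
        chrom[i] <- ch; start[i] <- s
        placed[[length(placed) + 1L]] <- list(chrom = ch, start = s, end = e)
        break
      }
      if (try == max_tries) stop("could not place interval ", i, "; genome too crowded")
    }
  }
  data.frame(chrom = chrom, start = start, end = start + widths,
             stringsAsFactors = FALSE)
}

random_genes <- function(spec) {
  n <- spec$n_genes
  structures <- lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1L)
    exw <- sample(200:400, k, replace = TRUE)
    inw <- sample(300:1500, k - 1L, replace = TRUE)
    rel_starts <- cumsum(c(0L, exw[-k] + inw))
    list(exw = exw, rel_starts = rel_starts, len = sum(exw) + sum(inw))
  })
  lens <- vapply(structures, `[[`, 0L, "len")
  pos <- place_nonoverlapping(spec$chrom_sizes, lens, margin = 5000L, gap = 4500L)
  gene_table(name = sprintf("TX%02d", seq_len(n)),
             symbol = sprintf("GENE%02d", seq_len(n)),
             chrom = pos$chrom,
             strand = sample(c("+", "-"), n, replace = TRUE),
             tx_start = pos$start, tx_end = pos$end,
             exon_starts = lapply(seq_len(n), function(i)
               pos$start[i] + structures[[i]]$rel_starts),
             exon_ends = lapply(seq_len(n), function(i)
               pos$start[i] + structures[[i]]$rel_starts + structures[[i]]$exw))
}

# background + spike reads as a BED6-ready frame
simulate_reads <- function(spec, truth = NULL, reads_per_peak = 0L) {
  rows <- list()
  for (ch in names(spec$chrom_sizes)) {
    len <- spec$chrom_sizes[[ch]]
    n_bg <- stats::rpois(1L, spec$background_rate * len)
    lo <- spec$fragment_length; hi <- len - spec$fragment_length - spec$read_len
    fs <- lo + sample.int(hi - lo, n_bg, replace = TRUE)
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    # position read starts so the extended fragment starts at fs
    start <- ifelse(strand == "+", fs, fs + spec$fragment_length - spec$read_len)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch, start = start, strand = strand,
                 stringsAsFactors = FALSE)
  }
  if (!is.null(truth) && reads_per_peak > 0) {
    for (i in seq_len(nrow(truth))) {
      half <- spec$fragment_length %/% 2L
      fs <- sample((truth$start[i] - half):(truth$end[i] - half - 1L),
                   reads_per_peak, replace = TRUE)
      strand <- sample(c("+", "-"), reads_per_peak, replace = TRUE)
      start <- ifelse(strand == "+", fs, fs + spec$fragment_length - spec$read_len)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = truth$chrom[i], start = start, strand = strand,
                   stringsAsFactors = FALSE)
    }
  }
  rd <- do.call(rbind, rows)
  rd$read_len <- spec$read_len
  read_set(rd[sample.int(nrow(rd)), , drop = FALSE], spec$fragment_length)
}

#' Generate a complete synthetic input bundle
#'
#' Writes into `outdir`: `genome.fa` (+ `.fai`), `genes.refGene`,
#' `chip.bed` / `control.bed` reads, `peaks_truth.bed`, `cons.bedgraph`,
#' `cpg.bed`, `repeats.bed`, `mark1.bed` / `mark2.bed` / `cofactor.bed`,
#' `motifs.pfm`, `genesets.gmt` and a `truth.json` manifest. The same spec
#' always produces byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created).
#' @return Invisibly, a list with the manifest (`truth`) and all file paths.
#' @export
make_fixture <- function(spec = fixture_spec(), outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  force(spec)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  cs <- spec$chrom_sizes
  pth <- function(f) file.path(outdir, f)

  # genes
  genes <- random_genes(spec)
  write_genes(genes, pth("genes.refGene"))

  # truth peaks (anywhere on the genome, well separated)
  truth <- place_nonoverlapping(cs, rep(spec$peak_width, spec$n_truth_peaks),
                                margin = 2500L, gap = 1500L)
  if (any(truth$end > cs[truth$chrom])) stop("truth peak beyond chromosome end")
  truth$id <- sprintf("truth_%02d", seq_len(nrow(truth)))
  write_peaks(peak_set(truth$chrom, truth$start, truth$end, id = truth$id),
              pth("peaks_truth.bed"))

  # genome sequence: i.i.d. uniform, CpG islands GC-rich, motif embedded
  seqs <- lapply(cs, function(len)
    paste(sample(BASES, len, replace = TRUE), collapse = ""))
  pwm <- default_fixture_pwm()
  consensus <- pwm_consensus(pwm)
  n_motif <- round(spec$motif_frac * nrow(truth))
  motif_carriers <- sort(sample.int(nrow(truth), n_motif))
  for (i in motif_carriers) {
    at <- (truth$start[i] + truth$end[i]) %/% 2L  # 0-based insertion point
    substr(seqs[[truth$chrom[i]]], at + 1L, at + nchar(consensus)) <- consensus
  }

  # CpG islands: one over a fraction of truth peaks, plus decoys elsewhere
  n_cpg_peaks <- round(spec$cpg_frac * nrow(truth))
  cpg_on <- sort(sample.int(nrow(truth), n_cpg_peaks))
  cpg <- data.frame(chrom = truth$chrom[cpg_on],
                    start = pmax((truth$start[cpg_on] + truth$end[cpg_on]) %/% 2L - 500L, 0L),
                    stringsAsFactors = FALSE)
  cpg$end <- cpg$start + 1000L
  decoys <- place_nonoverlapping(cs, rep(1000L, 10L), margin = 2000L, gap = 500L)
  # keep decoy islands off every truth peak so the overlap fraction is exact
  keep <- !overlaps_any(decoys, merge_peak_frame(truth))
  cpg <- rbind(cpg, decoys[keep, c("chrom", "start", "end")])
  gc_rich <- function(n) paste(sample(BASES, n, replace = TRUE,
                                      prob = c(0.15, 0.35, 0.35, 0.15)),
                               collapse = "")
  for (j in seq_len(nrow(cpg))) {
    s <- cpg$start[j]; e <- min(cpg$end[j], cs[[cpg$chrom[j]]])
    substr(seqs[[cpg$chrom[j]]], s + 1L, e) <- gc_rich(e - s)
  }
  # islands may have overwritten an embedded motif: re-embed
  for (i in motif_carriers) {
    at <- (truth$start[i] + truth$end[i]) %/% 2L
    substr(seqs[[truth$chrom[i]]], at + 1L, at + nchar(consensus)) <- consensus
  }
  write_peaks(as_peak_set(cpg), pth("cpg.bed"))
  write_fasta_with_index(seqs, pth("genome.fa"))
  write_pfm(list(pwm), pth("motifs.pfm"))

  # repeats: random decoy intervals
  reps <- place_nonoverlapping(cs, sample(200:800, 15L, replace = TRUE),
                               margin = 1000L, gap = 200L)
  write_peaks(as_peak_set(reps), pth("repeats.bed"))

  # reads: background coverage b = rate * fragment_length; spike adds
  # (fold - 1) * b over the peak, i.e. reads_per_peak = (fold-1)*b*w/L
  b <- spec$background_rate * spec$fragment_length
  reads_per_peak <- ceiling((spec$fold - 1) * b * spec$peak_width /
                              spec$fragment_length)
  chip <- simulate_reads(spec, truth, reads_per_peak)
  control <- simulate_reads(spec)
  write_reads(chip, pth("chip.bed"))
  write_reads(control, pth("control.bed"))

  # conservation: baseline everywhere, elevated over truth peaks
  con <- file(pth("cons.bedgraph"), "w")
  for (ch in names(cs)) {
    tp <- truth[truth$chrom == ch, , drop = FALSE]
    tp <- tp[order(tp$start), , drop = FALSE]
    bounds <- c(0L, rbind(tp$start, tp$end), cs[[ch]])
    vals <- rep(c(spec$cons_base, spec$cons_peak), length.out = length(bounds) - 1L)
    keep <- diff(bounds) > 0
    writeLines(paste(ch, bounds[-length(bounds)][keep], bounds[-1][keep],
                     vals[keep], sep = "\t"), con)
  }
  close(con)

  # histone-mark / cofactor tracks: jittered windows over random subsets of
  # the truth peaks, plus decoy intervals off every truth peak
  mark_track <- function(frac, fname) {
    n_on <- round(frac * nrow(truth))
    on <- sort(sample.int(nrow(truth), n_on))
    iv <- data.frame(chrom = truth$chrom[on],
                     start = truth$start[on] - sample(0:200, n_on, replace = TRUE),
                     stringsAsFactors = FALSE)
    iv$end <- truth$end[on] + sample(0:200, n_on, replace = TRUE)
    dec <- place_nonoverlapping(cs, sample(300:700, 20L, replace = TRUE),
                                margin = 1000L, gap = 200L)
    dec <- dec[!overlaps_any(dec, merge_peak_frame(truth)), , drop = FALSE]
    write_peaks(as_peak_set(rbind(iv, dec[, c("chrom", "start", "end")])),
                pth(fname))
    on
  }
  mark1_on <- mark_track(spec$mark1_frac, "mark1.bed")
  mark2_on <- mark_track(spec$mark2_frac, "mark2.bed")
  cofactor_on <- mark_track(spec$cofactor_frac, "cofactor.bed")

  # gene sets: planted set = genes closest to truth peaks, plus decoys
  closest <- find_closest_genes(peak_set(truth$chrom, truth$start, truth$end,
                                         id = truth$id), genes)
  planted <- sort(unique(closest$symbol))
  sets <- list(TRUTH_PATHWAY = planted)
  for (j in 1:8)
    sets[[sprintf("DECOY_%02d", j)]] <- sort(sample(genes$symbol, 6L))
  write_gmt(sets, pth("genesets.gmt"))

  truth_manifest <- list(
    seed = spec$seed,
    chrom_sizes = as.list(cs),
    peaks = data.frame(truth,
                       has_motif = seq_len(nrow(truth)) %in% motif_carriers,
                       cpg = seq_len(nrow(truth)) %in% cpg_on,
                       mark1 = seq_len(nrow(truth)) %in% mark1_on,
                       mark2 = seq_len(nrow(truth)) %in% mark2_on,
                       cofactor = seq_len(nrow(truth)) %in% cofactor_on,
                       stringsAsFactors = FALSE),
    motif = list(name = pwm$name, consensus = consensus,
                 fraction = spec$motif_frac),
    reads_per_peak = reads_per_peak,
    background_rate = spec$background_rate,
    fold = spec$fold,
    planted_pathway = "TRUTH_PATHWAY",
    planted_genes = planted,
    cons = list(base = spec$cons_base, peak = spec$cons_peak))
  jsonlite::write_json(truth_manifest, pth("truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list(genome = pth("genome.fa"), genes = pth("genes.refGene"),
                chip = pth("chip.bed"), control = pth("control.bed"),
                truth_peaks = pth("peaks_truth.bed"),
                cons = pth("cons.bedgraph"), cpg = pth("cpg.bed"),
                repeats = pth("repeats.bed"), motifs = pth("motifs.pfm"),
                genesets = pth("genesets.gmt"),
                mark1 = pth("mark1.bed"), mark2 = pth("mark2.bed"),
                cofactor = pth("cofactor.bed"),
                truth_json = pth("truth.json"))
  invisible(list(spec = spec, truth = truth_manifest, files = files,
                 genes = genes, chrom_sizes = cs))
}
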