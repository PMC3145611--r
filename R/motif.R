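# Motif scanning over peak sequences. PWMs are scored with the
# Berg-von Hippel scheme: each column contributes the log-ratio of the
# observed base's (pseudocounted) count to the column's most frequent
# base's count, so the consensus word scores 0 and every other word scores
# below 0. A window is a hit when its relative affinity exp(score) reaches
# the threshold tau. Regular-expression (consensus) scanning and the four
# background-sequence generators (random / adjacent / CGI / 1MM) used for
# enrichment analysis live here too.

BASES <- c("A", "C", "G", "T")

#' Motif-scan configuration
#'
#' @param tau relative-affinity acceptance threshold in (0, 1] (default 0.5).
#' @param pseudocount added to every count before taking ratios (default 0.5).
#' @param both_strands scan the reverse complement too? (default `TRUE`).
#' @return A list of class `motif_scan_config`.
#' @export
motif_scan_config <- function(tau = 0.5, pseudocount = 0.5, both_strands = TRUE) {
  stopifnot(tau > 0, tau <= 1, pseudocount > 0)
  structure(list(tau = tau, pseudocount = pseudocount,
                 both_strands = both_strands),
            class = "motif_scan_config")
}

#' Berg-von Hippel weights of a PWM
#'
#' `w[b, i] = ln((n[b, i] + pc) / (n[b*, i] + pc))` where `b*` is the most
#' frequent base of column `i`. Consensus bases weigh 0; all weights are
#' `<= 0`.
#'
#' @param pwm a `pwm` object (see [read_pfm()]) or a 4 x width counts matrix
#'   with rows A, C, G, T.
#' @param pseudocount pseudocount (default 0.5).
#' @return A 4 x width numeric weight matrix, rows A, C, G, T.
#' @export
bvh_weights <- function(pwm, pseudocount = 0.5) {
  counts <- if (inherits(pwm, "pwm")) pwm$counts else pwm
  stopifnot(nrow(counts) == 4, all(counts >= 0), all(colSums(counts) > 0))
  colmax <- apply(counts, 2, max)
  w <- log(sweep(counts + pseudocount, 2, colmax + pseudocount, "/"))
  rownames(w) <- BASES
  w
}

# score every window of one sequence against a weight matrix; returns the
# numeric score vector (NA where the window contains a non-ACGT base)
score_windows <- function(seq, w) {
  width <- ncol(w)
  n <- nchar(seq)
  if (n < width) return(numeric())
  codes <- match(strsplit(seq, "")[[1]], BASES)
  nwin <- n - width + 1L
  sc <- numeric(nwin)
  ok <- rep(TRUE, nwin)
  for (j in seq_len(width)) {
    cj <- codes[j:(j + nwin - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + w[cbind(cj, j)]
  }
  sc[!ok] <- NA_real_
  sc
}

#' Scan sequences with a PWM (Berg-von Hippel)
#'
#' Slides a window of the motif width over every sequence (and, if
#' configured, its reverse complement) and accepts windows whose relative
#' affinity `exp(score)` is at least `tau`. Windows containing a non-ACGT
#' base are rejected. Hit offsets are on the forward strand; a `-` strand
#' hit at offset o covers the same forward-strand positions `[o, o + width)`.
#'
#' @param seqs a `peak_seqs` data frame from [fetch_sequences()] (columns
#'   `id`, `seq`), or any data frame with those columns.
#' @param pwm a `pwm` object or counts matrix.
#' @param cfg a [motif_scan_config()].
#' @return `list(peaks_with_motif = character ids, hits = data.frame(id,
#'   offset, strand, score, affinity))`.
#' @export
scan_pwm <- function(seqs, pwm, cfg = motif_scan_config()) {
  w <- bvh_weights(pwm, cfg$pseudocount)
  width <- ncol(w)
  hits <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- toupper(seqs$seq[i])
    if (nchar(s) < width) {
      warning("sequence ", seqs$id[i], " shorter than motif; skipped")
      next
    }
    fwd <- score_windows(s, w)
    acc <- which(!is.na(fwd) & exp(fwd) >= cfg$tau)
    if (length(acc))
      hits[[length(hits) + 1L]] <-
        data.frame(id = seqs$id[i], offset = acc - 1L, strand = "+",
                   score = fwd[acc], affinity = exp(fwd[acc]),
                   stringsAsFactors = FALSE)
    if (cfg$both_strands) {
      rev <- score_windows(revcomp(s), w)
      accr <- which(!is.na(rev) & exp(rev) >= cfg$tau)
      if (length(accr)) {
        # map reverse-complement offsets back to forward coordinates
        fwd_off <- nchar(s) - width - (accr - 1L)
        hits[[length(hits) + 1L]] <-
          data.frame(id = seqs$id[i], offset = fwd_off, strand = "-",
                     score = rev[accr], affinity = exp(rev[accr]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(id = character(), offset = integer(),
                          strand = character(), score = numeric(),
                          affinity = numeric(), stringsAsFactors = FALSE)
  list(peaks_with_motif = unique(hits$id), hits = hits)
}

#' Scan sequences with a consensus / regular expression
#'
#' Case-insensitive matching of an IUPAC-free regular expression over the
#' alphabet classes of ACGT (e.g. `TCCAAT`, `[AT]CG[CT]`) on the forward
#' strand and on the reverse complement; overlapping matches are all
#' reported.
#'
#' @param seqs as in [scan_pwm()].
#' @param pattern the regular expression.
#' @return `list(peaks_with_motif, hits)` with hit offsets in forward-strand
#'   coordinates.
#' @export
scan_regex <- function(seqs, pattern) {
  ok <- tryCatch({ suppressWarnings(grepl(pattern, "ACGT")); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("invalid regular expression: ", pattern)
  find_all <- function(s) {
    # overlapping matches: probe every start position
    m <- gregexpr(paste0("(?=(", pattern, "))"), s,
                  perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "capture.length")[, 1]
    data.frame(offset = as.integer(m) - 1L, len = as.integer(len))
  }
  hits <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- toupper(seqs$seq[i])
    f <- find_all(s)
    if (!is.null(f))
      hits[[length(hits) + 1L]] <-
        data.frame(id = seqs$id[i], offset = f$offset, strand = "+",
                   length = f$len, stringsAsFactors = FALSE)
    r <- find_all(revcomp(s))
    if (!is.null(r))
      hits[[length(hits) + 1L]] <-
        data.frame(id = seqs$id[i],
                   offset = nchar(s) - r$offset - r$len, strand = "-",
                   length = r$len, stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(id = character(), offset = integer(),
                          strand = character(), length = integer(),
                          stringsAsFactors = FALSE)
  list(peaks_with_motif = unique(hits$id), hits = hits)
}

#' Background-sequence configuration
#'
#' @param mode `"random"` (uniform genomic placement), `"adjacent"`
#'   (immediately flanking the peaks, alternating sides), `"CGI"` (random
#'   placement stratified to reproduce the peaks' CpG-island overlap
#'   fraction within 0.05), or `"1MM"` (per-peak synthetic sequence from the
#'   peak's own first-order Markov chain).
#' @param seed RNG seed.
#' @param cpg_track a [peak_set()] of CpG islands (required for `"CGI"`).
#' @return A list of class `background_config`.
#' @export
background_config <- function(mode = c("random", "adjacent", "CGI", "1MM"),
                              seed = 1L, cpg_track = NULL) {
  mode <- match.arg(mode)
  if (mode == "CGI" && is.null(cpg_track))
    stop("CGI background mode requires a cpg_track")
  structure(list(mode = mode, seed = seed, cpg_track = cpg_track),
            class = "background_config")
}

random_interval_in <- function(chrom_sizes, len) {
  ok <- names(chrom_sizes)[chrom_sizes >= len]
  w <- as.numeric(chrom_sizes[ok] - len + 1L)
  ch <- sample(ok, 1L, prob = w)
  s <- sample.int(chrom_sizes[[ch]] - len + 1L, 1L) - 1L
  c(chrom = ch, start = s)
}

markov1_generate <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 1) return(seq)
  mono <- table(factor(chars, levels = BASES))
  trans <- table(factor(chars[-n], levels = BASES),
                 factor(chars[-1], levels = BASES))
  out <- character(n)
  out[1] <- chars[1]                    # chain starts at the source's first base
  for (i in 2:n) {
    row <- trans[out[i - 1L], ]
    if (sum(row) == 0) row <- mono      # unseen context: mononucleotide fallback
    if (sum(row) == 0) row <- stats::setNames(rep(1, 4), BASES)
    out[i] <- sample(BASES, 1L, prob = as.numeric(row))
  }
  paste(out, collapse = "")
}

#' Generate matched background sequences
#'
#' One background per input peak, of identical length. See
#' [background_config()] for the four modes. Genomic modes return real
#' coordinates; `"1MM"` returns synthetic sequences with ids
#' `<peak_id>_1MM`.
#'
#' @param peaks a [peak_set()].
#' @param genome FASTA path or named `DNAStringSet`.
#' @param chrom_sizes named integer vector.
#' @param cfg a [background_config()].
#' @return A `peak_seqs`-style data frame `id, chrom, start, end, seq`
#'   (synthetic rows carry `NA` coordinates).
#' @export
make_background <- function(peaks, genome, chrom_sizes, cfg) {
  stopifnot(inherits(cfg, "background_config"))
  force(cfg)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  lens <- peak_lengths(peaks)
  if (cfg$mode == "1MM") {
    src <- fetch_sequences(genome, peaks)
    seqs <- vapply(src$seq, markov1_generate, "", USE.NAMES = FALSE)
    out <- data.frame(id = paste0(peaks$id, "_1MM"), chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_, seq = seqs,
                      stringsAsFactors = FALSE)
    class(out) <- c("peak_seqs", "data.frame")
    return(out)
  }
  if (cfg$mode == "adjacent") {
    # alternate left/right flanks; shift inward when off-chromosome
    side_left <- seq_len(nrow(peaks)) %% 2L == 1L
    s <- ifelse(side_left, peaks$start - lens, peaks$end)
    e <- s + lens
    clen <- chrom_sizes[peaks$chrom]
    shift_right <- pmax(0L, -s)
    shift_left <- pmax(0L, e - clen)
    s <- as.integer(s + shift_right - shift_left)
    bg <- peak_set(peaks$chrom, s, s + lens, id = paste0(peaks$id, "_adj"),
                   source = "background:adjacent")
    return(fetch_sequences(genome, bg))
  }
  if (cfg$mode == "random") {
    rows <- lapply(lens, function(L) random_interval_in(chrom_sizes, L))
    ch <- vapply(rows, `[[`, "", "chrom")
    s <- as.integer(vapply(rows, `[[`, "", "start"))
    bg <- peak_set(ch, s, s + lens, id = paste0(peaks$id, "_rand"),
                   source = "background:random")
    return(fetch_sequences(genome, bg))
  }
  # CGI: reproduce the peaks' CpG-island overlap fraction by stratified
  # placement: the right number of backgrounds is drawn overlapping an
  # island, the rest strictly outside
  cpg <- merge_peak_frame(cfg$cpg_track[, c("chrom", "start", "end"), drop = FALSE])
  frac_peaks <- mean(overlaps_any(peaks, cpg))
  n <- nrow(peaks)
  want_overlap <- round(frac_peaks * n)
  ord <- sample.int(n)                  # which peaks get island backgrounds
  overlap_flag <- logical(n); overlap_flag[ord[seq_len(want_overlap)]] <- TRUE
  ch <- character(n); s <- integer(n)
  for (i in seq_len(n)) {
    for (try in seq_len(10000L)) {
      cand <- random_interval_in(chrom_sizes, lens[i])
      cs <- as.integer(cand[["start"]])
      hit <- any(cpg$chrom == cand[["chrom"]] & cpg$start < cs + lens[i] &
                   cpg$end > cs)
      if (hit == overlap_flag[i]) { ch[i] <- cand[["chrom"]]; s[i] <- cs; break }
      if (try == 10000L)
        stop("CGI background placement failed; achieved fraction ",
             signif(mean(overlap_flag[seq_len(i - 1L)]), 3))
    }
  }
  bg <- peak_set(ch, s, s + lens, id = paste0(peaks$id, "_cgi"),
                 source = "background:CGI")
  fetch_sequences(genome, bg)
}

#' Pooled dinucleotide frequencies of a sequence set
#' @param seqs character vector of DNA sequences.
#' @return Named numeric vector over the 16 dinucleotides, summing to 1.
#' @export
dinucleotide_frequencies <- function(seqs) {
  dints <- as.vector(outer(BASES, BASES, paste0))
  counts <- stats::setNames(numeric(16), dints)
  for (s in seqs) {
    chars <- strsplit(toupper(s), "")[[1]]
    n <- length(chars)
    if (n < 2) next
    d <- paste0(chars[-n], chars[-1])
    tb <- table(factor(d, levels = dints))
    counts <- counts + as.numeric(tb)
  }
  counts / max(1, sum(counts))
}
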