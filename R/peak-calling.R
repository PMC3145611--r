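# Read-density peak caller: reads are extended to the fragment length in
# their strand direction, candidate bases are those where the ChIP coverage
# reaches a threshold t, nearby candidate runs are merged, short regions
# dropped, and (optionally) regions are kept only when their library-size
# normalized ChIP/control ratio reaches a fold cutoff.

#' Peak-caller configuration
#'
#' @param t per-base read-count threshold (> 0, default 15).
#' @param fold minimum normalized ChIP/control ratio (>= 1, default 2).
#' @param max_gap candidate runs closer than this many bp are merged
#'   (default 200).
#' @param min_len minimum peak length in bp (default 100).
#' @param fragment_length read extension length in bp (default 200).
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(t = 15, fold = 2, max_gap = 200L,
                             min_len = 100L, fragment_length = 200L) {
  if (t <= 0) stop("peak_call_config: t must be > 0")
  stopifnot(fold >= 1, min_len > 0, max_gap >= 0, fragment_length > 0)
  structure(list(t = t, fold = fold, max_gap = as.integer(max_gap),
                 min_len = as.integer(min_len),
                 fragment_length = as.integer(fragment_length)),
            class = "peak_call_config")
}

#' Per-base fragment coverage
#'
#' Extends every read to `fragment_length` bp in its strand direction
#' (`+` reads rightward from their start; `-` reads leftward from their 3'
#' end, i.e. from `start + read_len`; strandless reads rightward) and counts,
#' at every base, how many extended fragments cover it. Fragments are
#' truncated at chromosome ends.
#'
#' @param reads a [read_set()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return Named list of numeric per-base coverage vectors, one per
#'   chromosome in `chrom_sizes`.
#' @export
coverage_vector <- function(reads, chrom_sizes) {
  rd <- reads$reads
  L <- reads$fragment_length
  out <- lapply(chrom_sizes, function(len) numeric(len))
  if (!nrow(rd)) return(out)
  rl <- ifelse(is.na(rd$read_len), 0L, rd$read_len)
  fs <- ifelse(rd$strand == "-", rd$start + rl - L, rd$start)
  fe <- fs + L
  truncated <- FALSE
  for (ch in intersect(unique(rd$chrom), names(chrom_sizes))) {
    len <- chrom_sizes[[ch]]
    sel <- rd$chrom == ch
    s <- pmax(fs[sel], 0L); e <- pmin(fe[sel], len)
    if (any(fe[sel] > len) || any(fs[sel] < 0L)) truncated <- TRUE
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    # difference-array accumulation: +1 at starts, -1 at ends, then cumsum
    delta <- numeric(len + 1L)
    add_s <- tabulate(s + 1L, len)
    add_e <- tabulate(e + 1L, len + 1L)
    delta[seq_len(len)] <- add_s
    delta <- delta - add_e
    out[[ch]] <- cumsum(delta[seq_len(len)])
  }
  if (truncated) warning("fragment(s) extending beyond chromosome ends truncated")
  out
}

# candidate runs of TRUE in a logical vector -> (start, end) half-open
runs_of <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values
  cbind(start = start[keep], end = end[keep])
}

#' Call peaks from ChIP (and optional control) reads
#'
#' Candidate bases are those with ChIP coverage `>= t`; candidate runs
#' separated by fewer than `max_gap` bp are merged; merged regions shorter
#' than `min_len` are dropped. With a control, a region is kept only when
#' `(chip_mean / chip_total) / (control_mean' / control_total')` reaches
#' `fold`, where the control mean carries a one-read pseudocount
#' (`fragment_length / region_length` coverage) and the control total one
#' extra read. Each peak reports `score` = maximum ChIP coverage and
#' `summit` = the leftmost position attaining it.
#'
#' @param chip a [read_set()].
#' @param control optional [read_set()] or `NULL`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param cfg a [peak_call_config()].
#' @return A [peak_set()] with extra column `summit`, sorted and disjoint.
#' @export
call_peaks <- function(chip, control = NULL, chrom_sizes,
                       cfg = peak_call_config()) {
  stopifnot(inherits(cfg, "peak_call_config"))
  cov <- coverage_vector(chip, chrom_sizes)
  ctrl_cov <- if (!is.null(control)) coverage_vector(control, chrom_sizes)
  chip_total <- max(chip$total_reads, 1L)
  ctrl_total <- if (!is.null(control)) control$total_reads + 1L
  rows <- list()
  for (ch in names(chrom_sizes)) {
    v <- cov[[ch]]
    cand <- runs_of(v >= cfg$t)
    if (!nrow(cand)) next
    # merge runs separated by < max_gap
    if (nrow(cand) > 1) {
      gap <- cand[-1, "start"] - cand[-nrow(cand), "end"]
      grp <- cumsum(c(1L, as.integer(gap >= cfg$max_gap)))
      cand <- cbind(start = as.integer(tapply(cand[, "start"], grp, min)),
                    end = as.integer(tapply(cand[, "end"], grp, max)))
    }
    cand <- cand[cand[, "end"] - cand[, "start"] >= cfg$min_len, , drop = FALSE]
    if (!nrow(cand)) next
    for (k in seq_len(nrow(cand))) {
      s <- cand[k, "start"]; e <- cand[k, "end"]
      seg <- v[(s + 1L):e]
      if (!is.null(control)) {
        reg_len <- e - s
        chip_mean <- mean(seg)
        ctrl_mean <- mean(ctrl_cov[[ch]][(s + 1L):e]) +
          cfg$fragment_length / reg_len
        ratio <- (chip_mean / chip_total) / (ctrl_mean / ctrl_total)
        if (ratio < cfg$fold) next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e,
                   score = max(seg), summit = s + which.max(seg) - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(peak_set(source = "call_peaks"))
  df <- do.call(rbind, rows)
  ps <- peak_set(df$chrom, df$start, df$end, score = df$score,
                 source = "call_peaks")
  ps$summit <- df$summit
  ps
}
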