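# Randomization null for peak-overlap significance. Random peak lists
# conserve, exactly: the number of peaks, the per-chromosome multiset of
# peak lengths, and the gene-part category of every peak (promoter, exon,
# first intron, intron, downstream, distal, other). Placement is uniform
# over the positions on the peak's own chromosome where a peak of its
# length classifies into its own category, which reproduces the chromosomal
# and genomic distribution of the original list under the null.
#
# Sampling: a peak's category is determined by the highest-priority
# territory base it covers (for distal: by covering distal bases only), so
# valid positions are found by proposing uniformly over placements touching
# the target category's territory and rejecting those that touch
# higher-priority territory. The original position is always valid, so
# acceptance is guaranteed to have positive probability.

# category code of a candidate placement from the per-base label vector:
# highest-priority (lowest code) part label covered; else 'other' (7) wins
# over 'distal' (6) because any covered near-gene base pulls the whole peak
# under the distance cutoff
window_category_code <- function(lab, start, len) {
  v <- lab[(start + 1L):(start + len)]
  m <- min(v)
  if (m <= 5L) m else if (max(v) == 7L) 7L else 6L
}

# Per-peak sampling plan over its (chromosome, category) territory.
build_placement <- function(peaks, category, labels, segments) {
  n <- nrow(peaks)
  plc <- vector("list", n)
  codes <- match(category, PEAK_CATEGORIES)
  for (i in seq_len(n)) {
    L <- peaks$end[i] - peaks$start[i]
    ch <- peaks$chrom[i]
    chrom_len <- length(labels[[ch]])
    seg <- segments[segments$chrom == ch &
                      segments$category == category[i], , drop = FALSE]
    if (!nrow(seg))
      stop("no territory for category '", category[i], "' on ", ch)
    if (codes[i] == match("distal", PEAK_CATEGORIES)) {
      # distal peaks must lie wholly inside distal territory: no rejection
      w <- pmax(seg$end - seg$start - L + 1L, 0L)
      if (any(w > 0)) {
        keep <- w > 0
        plc[[i]] <- list(mode = "fit", len = L, code = codes[i], chrom = ch,
                         lo = seg$start[keep], cw = cumsum(as.numeric(w[keep])))
        next
      }
    } else {
      # proposal: any placement covering >= 1 territory base, then reject
      # placements whose classification differs
      lo <- pmax(seg$start - L + 1L, 0L)
      hi <- pmin(seg$end - 1L, chrom_len - L)
      w <- pmax(hi - lo + 1L, 0L)
      if (any(w > 0)) {
        keep <- w > 0
        plc[[i]] <- list(mode = "reject", len = L, code = codes[i], chrom = ch,
                         lo = lo[keep], cw = cumsum(as.numeric(w[keep])))
        next
      }
    }
    # degenerate territory: fall back to midpoint-inside-territory placement
    plc[[i]] <- list(mode = "midpoint", len = L, code = codes[i], chrom = ch,
                     lo = seg$start,
                     cw = cumsum(as.numeric(seg$end - seg$start)),
                     chrom_len = chrom_len)
  }
  if (any(vapply(plc, `[[`, "", "mode") == "midpoint"))
    warning("territory shorter than peak for some peak(s); ",
            "falling back to midpoint-inside-territory placement")
  plc
}

sample_from_plan <- function(p, k) {
  total <- p$cw[length(p$cw)]
  u <- stats::runif(k) * total
  seg <- findInterval(u, p$cw, left.open = TRUE) + 1L
  p$lo[seg] + as.integer(floor(u - c(0, p$cw)[seg]))
}

# n_rand random start positions for every peak (matrix n_peaks x n_rand)
draw_starts <- function(plc, labels, n_rand, max_tries = 60L) {
  n <- length(plc)
  starts <- matrix(0L, n, n_rand)
  for (i in seq_len(n)) {
    p <- plc[[i]]
    if (p$mode == "fit") {
      starts[i, ] <- sample_from_plan(p, n_rand)
    } else if (p$mode == "midpoint") {
      mid <- sample_from_plan(p, n_rand)
      s <- mid - p$len %/% 2L
      starts[i, ] <- pmin(pmax(s, 0L), max(p$chrom_len - p$len, 0L))
    } else {
      lab <- labels[[p$chrom]]
      res <- integer(n_rand)
      todo <- seq_len(n_rand)
      for (it in seq_len(max_tries)) {
        cand <- sample_from_plan(p, length(todo))
        ok <- vapply(cand, function(s)
          window_category_code(lab, s, p$len) == p$code, TRUE)
        res[todo[ok]] <- cand[ok]
        todo <- todo[!ok]
        if (!length(todo)) break
      }
      if (length(todo)) {
        # extremely tight territory: keep the last proposals regardless
        warning("placement acceptance not reached for ", length(todo),
                " draw(s); nearest proposals kept")
        res[todo] <- sample_from_plan(p, length(todo))
      }
      starts[i, ] <- res
    }
  }
  starts
}

#' Randomize a peak set preserving its genomic distribution
#'
#' Produces a random peak list with the same number of peaks, the same
#' per-chromosome length multiset, and the same gene-part category for every
#' peak as the input; placement is uniform over the positions of the
#' matching category's territory on the same chromosome.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_table()] used to define category territories.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param seed RNG seed.
#' @param cfg an [annotation_config()].
#' @return A [peak_set()] of randomized peaks.
#' @export
randomize_peaks <- function(peaks, genes, chrom_sizes, seed = 1L,
                            cfg = annotation_config()) {
  ann <- classify_peaks(peaks, genes, cfg)
  labels <- label_genome(genes, chrom_sizes, cfg)
  plc <- build_placement(peaks, ann$category, labels,
                         territory_segments(labels))
  force(seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  starts <- draw_starts(plc, labels, 1L)
  peak_set(peaks$chrom, starts[, 1], starts[, 1] + peak_lengths(peaks),
           id = peaks$id, source = "randomized")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Randomization-based significance of peak-set overlap
#'
#' Holds `b` fixed, generates `n_rand` random versions of `a` with
#' [randomize_peaks()]'s conservation laws, and counts, per randomization,
#' how many random peaks overlap `b`. The empirical p-value is
#' `(1 + #(rand >= observed)) / (1 + n_rand)` (add-one smoothing keeps it
#' positive); the z-score is the distance of the observed count from the
#' randomized mean in standard deviations, `NA` (flagged) when the
#' randomized counts are constant.
#'
#' @param a,b [peak_set()]s; `a` is randomized, `b` held fixed.
#' @param genes a [gene_table()].
#' @param chrom_sizes named integer vector.
#' @param n_rand number of randomizations (>= 1).
#' @param seed RNG seed, recorded in the result.
#' @param cfg an [annotation_config()].
#' @return A list of class `overlap_stats`: `observed`, `n_rand`,
#'   `rand_counts`, `p_value`, `z_score`, `z_defined`, `seed`.
#' @export
overlap_significance <- function(a, b, genes, chrom_sizes, n_rand = 100L,
                                 seed = 1L, cfg = annotation_config()) {
  stopifnot(n_rand >= 1)
  bm <- merge_peak_frame(b[, c("chrom", "start", "end"), drop = FALSE])
  observed <- sum(overlaps_any(a, bm))
  ann <- classify_peaks(a, genes, cfg)
  labels <- label_genome(genes, chrom_sizes, cfg)
  plc <- build_placement(a, ann$category, labels,
                         territory_segments(labels))
  force(seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  starts <- draw_starts(plc, labels, n_rand)
  lens <- peak_lengths(a)
  # flatten all randomizations into one frame; count overlaps per column
  flat <- data.frame(chrom = rep(a$chrom, n_rand),
                     start = as.integer(as.vector(starts)),
                     end = as.integer(as.vector(starts)) + rep(lens, n_rand),
                     stringsAsFactors = FALSE)
  hit <- overlaps_any(flat, bm)
  rand_counts <- as.integer(rowsum(as.integer(hit),
                                   rep(seq_len(n_rand), each = nrow(a))))
  p <- (1 + sum(rand_counts >= observed)) / (1 + n_rand)
  s <- stats::sd(rand_counts)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mean(rand_counts)) / s
  structure(list(observed = observed, n_rand = as.integer(n_rand),
                 rand_counts = rand_counts, p_value = p,
                 z_score = z, z_defined = !is.na(z), seed = seed),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap_stats: observed = %d, E[rand] = %.2f, p = %.4g, z = %s\n",
              x$observed, mean(x$rand_counts), x$p_value,
              if (x$z_defined) sprintf("%.2f", x$z_score) else "undefined"))
  invisible(x)
}
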