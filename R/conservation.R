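# Conservation analysis: per-peak mean conservation with strict-threshold
# filtering, and binned profiles around peak summits compared against
# randomly placed regions of the same sizes.

#' Conservation-profile configuration
#'
#' @param window total window width in bp around the profile center
#'   (default 2000); must be divisible by `n`.
#' @param n bin size in bp (default 10).
#' @param threshold mean-score cutoff for the peak filter (default 0.5;
#'   phastCons scores live in \[0, 1\]).
#' @param missing_policy `"zero"` treats uncovered bases as 0 (phastCons
#'   tracks are near-complete); `"skip"` excludes them from means.
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(window = 2000L, n = 10L, threshold = 0.5,
                           missing_policy = c("zero", "skip")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(window > 0, n > 0, window %% n == 0)
  structure(list(window = as.integer(window), n = as.integer(n),
                 threshold = threshold, missing_policy = missing_policy),
            class = "profile_config")
}

interval_mean_score <- function(track, chrom, start, end, policy) {
  v <- track_scores(track, chrom, start, end,
                    missing = if (policy == "zero") 0 else NA)
  if (policy == "skip") {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
  }
  mean(v)
}

#' Mean conservation per peak with threshold filter
#'
#' Computes the mean track score over each peak's bases and returns the
#' peaks whose mean is strictly greater than the threshold.
#'
#' @param peaks a [peak_set()].
#' @param track a `score_track` from [read_score_track()].
#' @param cfg a [profile_config()].
#' @return `list(means = numeric per peak, passing = peak_set)`; `passing`
#'   carries the means in its `score` column.
#' @export
peak_mean_conservation <- function(peaks, track, cfg = profile_config()) {
  if (length(setdiff(unique(peaks$chrom), names(track))))
    warning("peak(s) on chromosome(s) absent from the score track")
  means <- vapply(seq_len(nrow(peaks)), function(i)
    interval_mean_score(track, peaks$chrom[i], peaks$start[i], peaks$end[i],
                        cfg$missing_policy), 0)
  pass <- !is.na(means) & means > cfg$threshold
  passing <- peaks[pass, , drop = FALSE]
  passing$score <- means[pass]
  list(means = means, passing = passing)
}

profile_center <- function(peaks, center) {
  if (center == "summit" && "summit" %in% names(peaks) &&
      !all(is.na(peaks$summit)))
    return(as.integer(peaks$summit))
  (peaks$start + peaks$end) %/% 2L
}

#' Binned conservation profile around region centers
#'
#' For each region, a `window`-bp window is centered on the summit (or
#' midpoint) and divided into `window / n` bins in genomic orientation; each
#' bin's value is the mean score over its bases. The group profile averages
#' the per-region vectors; regions whose window runs off a chromosome end
#' are flagged as truncated and excluded from the group mean.
#'
#' @param regions a [peak_set()] (a `summit` column is used when present).
#' @param track a `score_track`.
#' @param cfg a [profile_config()].
#' @param center `"summit"` or `"midpoint"`.
#' @param chrom_sizes optional named lengths used to flag truncation; when
#'   omitted, only windows starting below 0 are flagged.
#' @param label group label stored on the result.
#' @return A list of class `conservation_profile`: `profiles` (regions x
#'   bins matrix), `mean_profile`, `truncated` (logical), `label`, `config`.
#' @export
conservation_profile <- function(regions, track, cfg = profile_config(),
                                 center = c("summit", "midpoint"),
                                 chrom_sizes = NULL, label = "peaks") {
  center <- match.arg(center)
  nb <- cfg$window %/% cfg$n
  ctr <- profile_center(regions, center)
  ws <- ctr - cfg$window %/% 2L
  we <- ws + cfg$window
  truncated <- ws < 0
  if (!is.null(chrom_sizes))
    truncated <- unname(truncated | we > chrom_sizes[regions$chrom])
  prof <- matrix(NA_real_, nrow(regions), nb)
  for (i in seq_len(nrow(regions))) {
    if (truncated[i]) next
    v <- track_scores(track, regions$chrom[i], ws[i], we[i],
                      missing = if (cfg$missing_policy == "zero") 0 else NA)
    m <- matrix(v, nrow = cfg$n)
    prof[i, ] <- if (cfg$missing_policy == "skip") colMeans(m, na.rm = TRUE)
                 else colMeans(m)
  }
  keep <- !truncated
  mean_profile <- if (any(keep)) colMeans(prof[keep, , drop = FALSE], na.rm = TRUE)
                  else rep(NA_real_, nb)
  structure(list(profiles = prof, mean_profile = mean_profile,
                 truncated = truncated, label = label, config = cfg),
            class = "conservation_profile")
}

#' Conservation profile of random regions matched to the input
#'
#' Places the same number of regions, with the same lengths, uniformly at
#' random on the genome and profiles them identically — the comparison group
#' for peak-conservation plots.
#'
#' @inheritParams conservation_profile
#' @param chrom_sizes named integer vector (placement universe).
#' @param seed RNG seed.
#' @return A `conservation_profile` with label `"random"`.
#' @export
random_regions_profile <- function(regions, track, chrom_sizes,
                                   cfg = profile_config(), seed = 1L) {
  force(seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lens <- peak_lengths(regions)
  rows <- lapply(lens, function(L) random_interval_in(chrom_sizes, L))
  ch <- vapply(rows, `[[`, "", "chrom")
  s <- as.integer(vapply(rows, `[[`, "", "start"))
  rnd <- peak_set(ch, s, s + lens, source = "random_regions")
  conservation_profile(rnd, track, cfg, center = "midpoint",
                       chrom_sizes = chrom_sizes, label = "random")
}

#' Write a peaks-vs-random profile table
#' @param peak_profile,random_profile `conservation_profile` objects.
#' @param path output TSV (`bin_start_offset, peaks_mean, random_mean`).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(peak_profile, random_profile, path) {
  cfg <- peak_profile$config
  off <- seq(-cfg$window %/% 2L, by = cfg$n, length.out = cfg$window %/% cfg$n)
  utils::write.table(
    data.frame(bin_start_offset = off,
               peaks_mean = peak_profile$mean_profile,
               random_mean = random_profile$mean_profile),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
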