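# Augmented interval tree over genomic intervals. One balanced binary search
# tree per chromosome, keyed on interval start; every node also stores the
# maximum end coordinate in its subtree, which lets a query prune whole
# subtrees that cannot contain an overlap. The query is the all-overlaps
# variant: it walks every branch whose subtree max exceeds the query start
# instead of stopping at the first hit.

# Nodes are stored in parallel vectors (index-linked), built balanced from
# start-sorted input, so the structure is immutable but O(log n) to query.
build_chrom_tree <- function(start, end, idx) {
  n <- length(start)
  o <- order(start, end)
  start <- start[o]; end <- end[o]; idx <- idx[o]
  left <- integer(n); right <- integer(n); maxend <- integer(n)
  # recursive median split over the sorted order keeps the BST balanced
  build <- function(lo, hi) {
    if (lo > hi) return(0L)
    mid <- (lo + hi) %/% 2L
    left[mid] <<- build(lo, mid - 1L)
    right[mid] <<- build(mid + 1L, hi)
    m <- end[mid]
    if (left[mid]) m <- max(m, maxend[left[mid]])
    if (right[mid]) m <- max(m, maxend[right[mid]])
    maxend[mid] <<- m
    mid
  }
  root <- build(1L, n)
  list(start = start, end = end, idx = idx,
       left = left, right = right, maxend = maxend, root = root)
}

#' Build an interval tree from a peak set
#'
#' Builds one augmented binary search tree per chromosome: each node holds an
#' interval and the maximum end coordinate of its subtree, supporting fast
#' retrieval of all stored intervals overlapping a query.
#'
#' @param peaks a [peak_set()].
#' @return An object of class `interval_tree`.
#' @export
build_tree <- function(peaks) {
  trees <- list()
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    trees[[ch]] <- build_chrom_tree(peaks$start[sel], peaks$end[sel], sel)
  }
  structure(list(trees = trees, peaks = peaks), class = "interval_tree")
}

#' @export
print.interval_tree <- function(x, ...) {
  cat(sprintf("interval_tree: %d interval(s) on %d chromosome(s)\n",
              nrow(x$peaks), length(x$trees)))
  invisible(x)
}

# iterative stack-based walk; returns row indices into the original peak set
query_chrom_tree <- function(tr, qstart, qend) {
  if (is.null(tr) || tr$root == 0L) return(integer())
  hits <- integer()
  stack <- tr$root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    # subtree cannot overlap if its max end is <= query start
    if (tr$maxend[node] <= qstart) next
    if (tr$left[node]) stack <- c(stack, tr$left[node])
    if (tr$start[node] < qend) {
      if (tr$end[node] > qstart) hits <- c(hits, tr$idx[node])
      if (tr$right[node]) stack <- c(stack, tr$right[node])
    }
  }
  hits
}

#' Find all stored intervals overlapping a query
#'
#' Overlap is strict positive-width intersection on half-open intervals:
#' abutting intervals do not overlap. Unknown chromosomes yield an empty
#' result.
#'
#' @param tree an [build_tree()] result.
#' @param chrom,start,end the query interval.
#' @return A [peak_set()] of the overlapping stored intervals.
#' @export
query_all_overlaps <- function(tree, chrom, start, end) {
  hits <- query_chrom_tree(tree$trees[[chrom]], start, end)
  tree$peaks[sort(hits), , drop = FALSE]
}

# Vectorized membership: for each interval of `a`, does it overlap any
# interval of the merged, disjoint, start-sorted set `bm`? Used on the hot
# path of the randomization test.
overlaps_any <- function(a, bm) {
  out <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    sel <- a$chrom == ch
    bs <- bm$start[bm$chrom == ch]
    be <- bm$end[bm$chrom == ch]
    if (!length(bs)) next
    # merged intervals are disjoint and sorted; locate the rightmost b-start
    # at or left of each a-start, then check that block and the next one
    j <- findInterval(a$start[sel], bs)
    hit <- (j >= 1L & be[pmax(j, 1L)] > a$start[sel]) |
           (j < length(bs) & bs[pmin(j + 1L, length(bs))] < a$end[sel])
    out[sel] <- hit
  }
  out
}

# Coalesce transitively-overlapping intervals into disjoint spanning blocks.
merge_peak_frame <- function(df) {
  df <- as.data.frame(df)[, c("chrom", "start", "end")]
  if (nrow(df) <= 1) return(df)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  newblock <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                  df$start[-1] >= cummax_by_chrom(df))
  grp <- cumsum(newblock)
  data.frame(chrom = tapply(df$chrom, grp, `[`, 1L),
             start = as.integer(tapply(df$start, grp, min)),
             end = as.integer(tapply(df$end, grp, max)),
             stringsAsFactors = FALSE)
}

# running max of ends within chromosome, shifted by one (for block breaks)
cummax_by_chrom <- function(df) {
  res <- integer(nrow(df) - 1L)
  cm <- df$end[1]; ch <- df$chrom[1]
  for (i in 2:nrow(df)) {
    if (df$chrom[i] != ch) { cm <- df$end[i]; ch <- df$chrom[i]; res[i - 1L] <- 0L }
    else { res[i - 1L] <- cm; cm <- max(cm, df$end[i]) }
  }
  res
}

#' Compare two peak sets
#'
#' `mode = "overlap"` returns the peaks of `a` overlapping at least one peak
#' of `b`; `"unique"` returns the peaks of `a` overlapping none; `"merge"`
#' returns the union of both sets with transitively-overlapping intervals
#' coalesced into single spanning intervals. For any `a`, `b`:
#' `overlap(a, b)` and `unique(a, b)` partition `a`.
#'
#' @param a,b [peak_set()]s.
#' @param mode `"overlap"`, `"unique"` or `"merge"`.
#' @return A [peak_set()].
#' @export
compare_intervals <- function(a, b, mode = c("overlap", "unique", "merge")) {
  mode <- match.arg(mode)
  if (mode == "merge") {
    both <- rbind(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
    m <- merge_peak_frame(both)
    return(peak_set(m$chrom, m$start, m$end, source = "merge"))
  }
  bm <- merge_peak_frame(b[, c("chrom", "start", "end"), drop = FALSE])
  hit <- overlaps_any(a, bm)
  if (mode == "overlap") a[hit, , drop = FALSE] else a[!hit, , drop = FALSE]
}

#' Pairwise Jaccard similarity of peak files
#'
#' For each pair of sets, all intervals of both are merged into connected
#' components (maximal blocks of transitively-overlapping intervals); the
#' Jaccard index is the number of components containing at least one peak
#' from each set, divided by the total number of components. Two empty sets
#' have index 0 by convention.
#'
#' @param sets named list of [peak_set()]s (at least 2).
#' @return A symmetric matrix of Jaccard coefficients with unit diagonal
#'   for non-empty sets.
#' @export
jaccard_index <- function(sets) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  d <- length(sets)
  J <- matrix(0, d, d, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(d)) {
    J[i, i] <- if (nrow(sets[[i]])) 1 else 0
    for (j in seq_len(d)) {
      if (j <= i) next
      J[i, j] <- J[j, i] <- jaccard_pair(sets[[i]], sets[[j]])
    }
  }
  J
}

jaccard_pair <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) return(0)
  both <- rbind(data.frame(chrom = a$chrom, start = a$start, end = a$end,
                           from = rep("a", na), stringsAsFactors = FALSE),
                data.frame(chrom = b$chrom, start = b$start, end = b$end,
                           from = rep("b", nb), stringsAsFactors = FALSE))
  o <- order(both$chrom, both$start, both$end)
  both <- both[o, , drop = FALSE]
  if (nrow(both) == 1) return(0)
  newblock <- c(TRUE, both$chrom[-1] != both$chrom[-nrow(both)] |
                  both$start[-1] >= cummax_by_chrom(both))
  grp <- cumsum(newblock)
  has_a <- tapply(both$from == "a", grp, any)
  has_b <- tapply(both$from == "b", grp, any)
  sum(has_a & has_b) / length(unique(grp))
}
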