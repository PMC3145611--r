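# Gene-set (pathway) association of peak-linked genes. The test is the
# upper hypergeometric tail: drawing n peak-linked genes out of a universe
# of N, of which K belong to the pathway, what is the chance of seeing k or
# more pathway members? Counting is gene-level: a gene with many peaks
# still contributes once.

#' Hypergeometric pathway association
#'
#' @param genes_of_peaks named list mapping gene symbol to a [peak_set()]
#'   of its linked peaks (see [peak_category_filter()]), or simply a
#'   character vector of symbols.
#' @param pathway name of a set in `gsc`.
#' @param gsc a `gene_set_collection` from [read_gmt()].
#' @param universe character vector of background symbols; defaults to
#'   `gsc$universe` or, failing that, the union of all set members.
#' @return A list of class `pathway_match`: `pathway`, `N`, `K`, `n`, `k`,
#'   `p_value`, `member_hits` (gene -> peak_set for overlap genes, when peak
#'   sets were supplied).
#' @export
pathway_match <- function(genes_of_peaks, pathway, gsc, universe = NULL) {
  if (!pathway %in% names(gsc$sets)) {
    near <- utils::head(agrep(pathway, names(gsc$sets), value = TRUE,
                              ignore.case = TRUE), 5)
    stop("pathway not found: '", pathway, "'",
         if (length(near)) paste0("; close matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  symbols <- if (is.list(genes_of_peaks)) names(genes_of_peaks) else genes_of_peaks
  if (is.null(universe)) universe <- gsc$universe
  if (is.null(universe)) universe <- unique(unlist(gsc$sets))
  universe <- unique(universe)
  members <- intersect(gsc$sets[[pathway]], universe)
  input <- intersect(unique(symbols), universe)
  overlap <- intersect(input, members)
  N <- length(universe); K <- length(members)
  n <- length(input); k <- length(overlap)
  # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  member_hits <- if (is.list(genes_of_peaks)) genes_of_peaks[overlap] else NULL
  structure(list(pathway = pathway, N = N, K = K, n = n, k = k,
                 p_value = p, member_hits = member_hits),
            class = "pathway_match")
}

#' @export
print.pathway_match <- function(x, ...) {
  cat(sprintf("pathway_match: %s  k=%d/K=%d (n=%d of N=%d), p = %.4g\n",
              x$pathway, x$k, x$K, x$n, x$N, x$p_value))
  invisible(x)
}

#' Enrichment scan over a gene-set collection
#'
#' Applies [pathway_match()] to every set with at least `min_set` members in
#' the universe and adjusts the p-values across the tested family
#' (Benjamini-Hochberg by default, `correction = "none"` for raw p only).
#'
#' @inheritParams pathway_match
#' @param min_set minimum universe-restricted set size to test (default 5).
#' @param correction `"BH"` or `"none"`.
#' @return Data frame of class `enrichment_table` with columns `pathway, N,
#'   K, n, k, p_value, q_value`, sorted by `p_value`.
#' @export
enriched_pathways <- function(genes_of_peaks, gsc, universe = NULL,
                              min_set = 5L, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(min_set >= 1)
  if (!length(gsc$sets)) stop("empty gene-set collection")
  if (is.null(universe)) universe <- gsc$universe
  if (is.null(universe)) universe <- unique(unlist(gsc$sets))
  keep <- names(gsc$sets)[vapply(gsc$sets, function(s)
    length(intersect(s, universe)) >= min_set, TRUE)]
  if (!length(keep)) stop("no gene set passes min_set = ", min_set)
  res <- lapply(keep, function(nm)
    pathway_match(genes_of_peaks, nm, gsc, universe))
  tab <- data.frame(pathway = keep,
                    N = vapply(res, `[[`, 0L, "N"),
                    K = vapply(res, `[[`, 0L, "K"),
                    n = vapply(res, `[[`, 0L, "n"),
                    k = vapply(res, `[[`, 0L, "k"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  tab$q_value <- if (correction == "BH") stats::p.adjust(tab$p_value, "BH")
                 else tab$p_value
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "member_hits") <- stats::setNames(
    lapply(res, `[[`, "member_hits"), keep)
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Restrict peak-gene links to chosen annotation categories
#'
#' Builds the gene -> peaks mapping that pathway tests consume, keeping only
#' links whose peak's primary category is among `categories` (e.g. promoter
#' peaks only).
#'
#' @param annotation an [classify_peaks()] result.
#' @param categories character vector of categories to keep.
#' @return Named list mapping gene symbol to a [peak_set()].
#' @export
peak_category_filter <- function(annotation, categories = PEAK_CATEGORIES) {
  if (!length(categories)) stop("no categories selected")
  unknown <- setdiff(categories, PEAK_CATEGORIES)
  if (length(unknown))
    stop("unknown categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  peaks <- annotation$peaks
  primary <- annotation$category[match(annotation$gene_links$peak_id, peaks$id)]
  gl <- annotation$gene_links[primary %in% categories, , drop = FALSE]
  out <- list()
  for (sym in unique(gl$symbol)) {
    ids <- unique(gl$peak_id[gl$symbol == sym])
    out[[sym]] <- peaks[peaks$id %in% ids, , drop = FALSE]
  }
  out
}

#' Export gene-to-category membership for external enrichment tools
#' @param annotation an [classify_peaks()] result.
#' @param path output TSV (`gene<TAB>category` per link).
#' @return `path`, invisibly.
#' @export
write_gene_categories <- function(annotation, path) {
  gl <- annotation$gene_links
  primary <- annotation$category[match(gl$peak_id, annotation$peaks$id)]
  utils::write.table(unique(data.frame(gene = gl$symbol, category = primary)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
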