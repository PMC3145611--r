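# Readers and writers for the plain-text genomics formats the toolkit
# consumes. Everything is normalized to 0-based half-open coordinates on
# input; writers emit the dialect's native convention (SAM 1-based,
# fixedStep wiggle 1-based).

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

is_comment_line <- function(lines) {
  grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
}

#' Read a BED peak file
#'
#' Accepts BED3+ (tab-separated `chrom start end [id score strand ...]`);
#' comment, `track` and `browser` lines are skipped. Coordinates are kept
#' as-is (BED is already 0-based half-open). Extra columns beyond the sixth
#' are preserved in columns `extra1`, `extra2`, ...
#'
#' @param path path to a BED file.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  lines <- read_text_lines(path)
  keep <- !is_comment_line(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(peak_set(source = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", lineno[which(is.na(start) | is.na(end))[1]],
         " in ", path, ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], " in ", path, ": end <= start")
  id <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA_character_)))
  ps <- peak_set(chrom, start, end,
                 id = if (all(is.na(id))) NULL else ifelse(is.na(id), paste0("peak_", seq_along(id)), id),
                 score = score, source = path)
  if (any(nf >= 6))
    ps$strand <- ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", ""), ".")
  maxf <- max(nf)
  if (maxf > 6) {
    for (j in 7:maxf) {
      ps[[paste0("extra", j - 6L)]] <-
        vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_, "")
    }
  }
  ps
}

#' Write a peak set as BED
#'
#' @param peaks a [peak_set()].
#' @param path output file.
#' @param track_header optional UCSC `track` line name; `NULL` writes bare BED.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, track_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_header))
    writeLines(sprintf('track name="%s" description="%s"', track_header, track_header), con)
  if (nrow(peaks)) {
    cols <- list(peaks$chrom, peaks$start, peaks$end, peaks$id,
                 ifelse(is.na(peaks$score), "0", format(peaks$score, trim = TRUE, scientific = FALSE)))
    if ("strand" %in% names(peaks)) cols <- c(cols, list(peaks$strand))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read mapped reads from BED or SAM
#'
#' BED input uses columns 1-3 for position and column 6 for strand; a missing
#' strand column defaults to `"+"` with a warning. SAM input converts the
#' 1-based `POS` to 0-based, takes strand from flag bit 0x10, and skips
#' unmapped records (flag bit 0x4 or `RNAME == "*"`), counting them in the
#' result's `skipped` field.
#'
#' @param path input file.
#' @param format `"bed"` or `"sam"`.
#' @param fragment_length fragment extension length stored on the result.
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = c("bed", "sam"), fragment_length = 200L) {
  format <- match.arg(format)
  lines <- read_text_lines(path)
  if (format == "bed") {
    lines <- lines[!is_comment_line(lines)]
    if (!length(lines))
      return(read_set(data.frame(chrom = character(), start = integer(),
                                 strand = character()), fragment_length))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3)) stop("malformed BED read line in ", path)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    if (any(nf < 6)) {
      warning("BED reads without strand column: defaulting to '+'")
      strand <- rep("+", length(lines))
      strand[nf >= 6] <- vapply(fields[nf >= 6], `[[`, "", 6L)
    } else {
      strand <- vapply(fields, `[[`, "", 6L)
    }
    strand[!strand %in% c("+", "-")] <- "+"
    rd <- data.frame(chrom = chrom, start = start, strand = strand,
                     read_len = end - start, stringsAsFactors = FALSE)
    return(read_set(rd, fragment_length))
  }
  # SAM: header lines start with '@'
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines))
    return(read_set(data.frame(chrom = character(), start = integer(),
                               strand = character()), fragment_length))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) stop("malformed SAM record in ", path)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  seq <- vapply(fields, `[[`, "", 10L)
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
  rd <- data.frame(chrom = rname[!unmapped],
                   start = pos[!unmapped] - 1L,   # SAM POS is 1-based
                   strand = ifelse(bitwAnd(flag[!unmapped], 16L) != 0L, "-", "+"),
                   read_len = nchar(seq[!unmapped]),
                   stringsAsFactors = FALSE)
  read_set(rd, fragment_length, skipped = sum(unmapped))
}

#' Write a read set as BED6
#' @param reads a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  rd <- reads$reads
  len <- ifelse(is.na(rd$read_len), 36L, rd$read_len)
  writeLines(paste(rd$chrom, rd$start, rd$start + len,
                   paste0("read_", seq_len(nrow(rd))), 0, rd$strand, sep = "\t"),
             path)
  invisible(path)
}

#' Split a read set into one BED file per chromosome
#'
#' @param reads a [read_set()].
#' @param outdir writable output directory.
#' @param overwrite overwrite pre-existing per-chromosome files?
#' @return Character vector of written file paths (one per chromosome).
#' @export
split_reads_by_chromosome <- function(reads, outdir, overwrite = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rd <- reads$reads
  if (!nrow(rd)) return(character())
  paths <- character()
  for (ch in unique(rd$chrom)) {
    p <- file.path(outdir, paste0(ch, ".bed"))
    if (file.exists(p) && !overwrite)
      stop("output file already exists (use overwrite = TRUE): ", p)
    sub <- read_set(rd[rd$chrom == ch, , drop = FALSE], reads$fragment_length)
    write_reads(sub, p)
    paths <- c(paths, p)
  }
  paths
}

#' Read a refGene-style transcript table
#'
#' Expects the UCSC refGene column layout: `name chrom strand txStart txEnd
#' cdsStart cdsEnd exonCount exonStarts exonEnds name2`, with
#' comma-terminated exon lists. An optional leading `bin` column is detected
#' and dropped.
#'
#' @param path path to the table.
#' @return A [gene_table()].
#' @export
read_genes <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty gene table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # refGene dumps sometimes have a leading numeric 'bin' column
  f1 <- fields[[1]]
  offset <- if (length(f1) >= 4 && !(f1[3] %in% c("+", "-")) &&
                f1[4] %in% c("+", "-")) 1L else 0L
  get <- function(i) vapply(fields, `[[`, "", i + offset)
  parse_list <- function(v) lapply(strsplit(v, ",", fixed = TRUE), as.integer)
  gene_table(name = get(1), symbol = get(11), chrom = get(2), strand = get(3),
             tx_start = as.integer(get(4)), tx_end = as.integer(get(5)),
             exon_starts = parse_list(get(9)), exon_ends = parse_list(get(10)))
}

#' Write a gene table in refGene layout
#' @param genes a [gene_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  fmt_list <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), "")
  cds_start <- genes$tx_start
  cds_end <- genes$tx_end
  writeLines(paste(genes$name, genes$chrom, genes$strand, genes$tx_start,
                   genes$tx_end, cds_start, cds_end,
                   lengths(genes$exon_starts),
                   fmt_list(genes$exon_starts), fmt_list(genes$exon_ends),
                   genes$symbol, sep = "\t"),
             path)
  invisible(path)
}

#' Read chromosome sizes
#' @param path two-column tab file `chrom<TAB>length`.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Fetch peak sequences from a genome
#'
#' Extracts the plus-strand sequence under each interval from a FASTA genome,
#' uppercased. Sequences are returned in input order; intervals falling
#' outside their chromosome raise an error naming the offenders.
#'
#' @param genome path to a FASTA file, or a named `DNAStringSet`.
#' @param intervals a [peak_set()].
#' @return A data frame `id, chrom, start, end, seq` of class `peak_seqs`.
#' @export
fetch_sequences <- function(genome, intervals) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  names(genome) <- nm
  missing_chr <- setdiff(unique(intervals$chrom), nm)
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), nm)
  oob <- which(intervals$end > lens[intervals$chrom])
  if (length(oob))
    stop("interval(s) beyond chromosome end: ",
         paste(intervals$id[utils::head(oob, 5)], collapse = ", "))
  seqs <- character(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    sel <- intervals$chrom == ch
    seqs[sel] <- as.character(Biostrings::subseq(
      rep(genome[ch], sum(sel)),
      start = intervals$start[sel] + 1L, end = intervals$end[sel]))
  }
  out <- data.frame(id = intervals$id, chrom = intervals$chrom,
                    start = intervals$start, end = intervals$end,
                    seq = toupper(seqs), stringsAsFactors = FALSE)
  class(out) <- c("peak_seqs", "data.frame")
  out
}

#' Reverse-complement DNA strings
#' @param seqs character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Write a UCSC browser track
#'
#' `kind = "peaks"` writes a BED track with a `track` header line;
#' `kind = "density"` writes fixedStep wiggle (1-based start, step/span 1)
#' from a per-base coverage vector.
#'
#' @param x a [peak_set()] (peaks) or a list of per-chromosome numeric
#'   coverage vectors (density).
#' @param kind `"peaks"` or `"density"`.
#' @param path output file.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, kind = c("peaks", "density"), path, name = "peakatlas") {
  kind <- match.arg(kind)
  if (kind == "peaks") return(write_peaks(x, path, track_header = name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s"', name), con)
  for (ch in names(x)) {
    v <- x[[ch]]
    if (!length(v)) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ch), con)
    writeLines(format(v, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a per-base score track (fixedStep wiggle or bedGraph)
#'
#' Supports fixedStep wiggle with `step=1` (optionally `span=1`) and
#' four-column bedGraph. Scores are stored as per-chromosome runs of
#' consecutive per-base values.
#'
#' @param path input file.
#' @param format `"wig"` or `"bedgraph"` (`"auto"` sniffs the content).
#' @return An object of class `score_track`: a named list (per chromosome)
#'   of runs, each `list(start =, scores =)` with `start` 0-based.
#' @export
read_score_track <- function(path, format = c("auto", "wig", "bedgraph")) {
  format <- match.arg(format)
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (format == "auto")
    format <- if (any(grepl("^fixedStep", lines))) "wig" else "bedgraph"
  runs <- list()
  if (format == "wig") {
    hdr <- grepl("^fixedStep", lines)
    if (!any(hdr)) stop("no fixedStep header in ", path)
    block_id <- cumsum(hdr)
    for (b in unique(block_id[hdr])) {
      sel <- block_id == b
      h <- lines[sel][1]
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", h)
      start1 <- as.integer(sub(".*start=([0-9]+).*", "\\1", h))
      step <- if (grepl("step=", h)) as.integer(sub(".*step=([0-9]+).*", "\\1", h)) else 1L
      if (step != 1L) stop("only step=1 fixedStep wiggle is supported")
      vals <- as.numeric(lines[sel][-1])
      runs[[chrom]] <- c(runs[[chrom]],
                         list(list(start = start1 - 1L, scores = vals)))
    }
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4)) stop("malformed bedGraph line in ", path)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    for (i in seq_along(chrom)) {
      runs[[chrom[i]]] <- c(runs[[chrom[i]]],
                            list(list(start = start[i],
                                      scores = rep(val[i], end[i] - start[i]))))
    }
  }
  # order runs, check non-overlap
  for (ch in names(runs)) {
    o <- order(vapply(runs[[ch]], `[[`, 0L, "start"))
    runs[[ch]] <- runs[[ch]][o]
    ends <- vapply(runs[[ch]], function(r) r$start + length(r$scores), 0L)
    starts <- vapply(runs[[ch]], `[[`, 0L, "start")
    if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("overlapping score runs on ", ch)
  }
  structure(runs, class = "score_track")
}

#' Extract per-base scores over an interval
#'
#' @param track a `score_track` from [read_score_track()].
#' @param chrom,start,end the interval (0-based half-open).
#' @param missing value substituted at uncovered bases (`NA` to mark them).
#' @return Numeric vector of length `end - start`.
#' @export
track_scores <- function(track, chrom, start, end, missing = 0) {
  out <- rep(missing, end - start)
  ch <- track[[chrom]]
  if (is.null(ch)) return(out)
  for (r in ch) {
    rend <- r$start + length(r$scores)
    if (rend <= start || r$start >= end) next
    from <- max(start, r$start); to <- min(end, rend)
    out[(from - start + 1L):(to - start)] <- r$scores[(from - r$start + 1L):(to - r$start)]
  }
  out
}

#' Read position frequency matrices in JASPAR PFM format
#'
#' Accepts the JASPAR text layout: a `>name` header followed by four rows of
#' counts, either bare or wrapped as `A [ 4 19 0 ... ]`.
#'
#' @param path PFM file (may contain several matrices).
#' @return A named list of `pwm` objects (`list(name, counts)` with a
#'   4 x width counts matrix, rows A, C, G, T).
#' @export
read_pfm <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no '>' header in PFM file: ", path)
  block <- cumsum(hdr)
  out <- list()
  for (b in unique(block[hdr])) {
    sel <- lines[block == b]
    name <- sub("^>\\s*", "", sel[1])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- sel[-1]
    if (length(rows) < 4) stop("PFM block '", name, "' lacks 4 count rows")
    parse_row <- function(s) {
      s <- gsub("^[ACGTacgt]\\s*\\[?", "", s)
      s <- gsub("\\]", "", s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    }
    counts <- do.call(rbind, lapply(rows[1:4], parse_row))
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(colSums(counts) <= 0)) stop("PFM '", name, "' has an empty column")
    out[[name]] <- structure(list(name = name, counts = counts), class = "pwm")
  }
  out
}

#' Write PFMs in JASPAR format
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(p$counts[b, ], collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return An object of class `gene_set_collection`:
#'   `list(sets = named list of symbol vectors, universe = NULL)`.
#' @export
read_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("malformed GMT line in ", path)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  structure(list(sets = sets, universe = NULL), class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param gsc a `gene_set_collection` or named list of symbol vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  sets <- if (inherits(gsc, "gene_set_collection")) gsc$sets else gsc
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
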