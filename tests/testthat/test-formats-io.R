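test_that("BED peak reading maps fields directly and round-trips", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t50\t80\tmyPeak\t3.5\t+"), p)
  ps <- read_peaks(p)
  expect_s3_class(ps, "peak_set")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$start, c(100L, 50L))
  expect_equal(ps$end, c(200L, 80L))
  expect_equal(ps$id[2], "myPeak")
  expect_equal(ps$score[2], 3.5)

  # round trip preserves coordinates, names, strand
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_peaks(ps, p2)
  ps2 <- read_peaks(p2)
  expect_equal(ps2$chrom, ps$chrom)
  expect_equal(ps2$start, ps$start)
  expect_equal(ps2$end, ps$end)
  expect_equal(ps2$id, ps$id)

  # empty file -> empty peak set
  p3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), p3)
  expect_equal(nrow(read_peaks(p3)), 0)
})

test_that("malformed BED lines are rejected with their line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30"), p)
  expect_error(read_peaks(p), "line 2")
  writeLines(c("chr1\t50\t40"), p)
  expect_error(read_peaks(p), "end <= start")
})

test_that("SAM reads convert POS to 0-based and skip unmapped records", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    paste("r1", 0, "chr1", 1001, 60, "5M", "*", 0, 0, "ACGTA", "IIIII", sep = "\t"),
    paste("r2", 16, "chr1", 2001, 60, "5M", "*", 0, 0, "ACGTA", "IIIII", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTA", "IIIII", sep = "\t")), p)
  rs <- read_reads(p, "sam")
  expect_equal(rs$total_reads, 2)
  expect_equal(rs$skipped, 1)
  expect_equal(rs$reads$start, c(1000L, 2000L))
  expect_equal(rs$reads$strand, c("+", "-"))
})

test_that("BED reads default missing strand to + with a warning", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t36", "chr2\t100\t136"), p)
  expect_warning(rs <- read_reads(p, "bed"), "strand")
  expect_equal(rs$reads$strand, c("+", "+"))
})

test_that("mixed-chromosome read counts are conserved and splitting round-trips", {
  set.seed(11)
  n <- 1000
  rd <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
                   start = sample.int(50000, n) - 1L,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   read_len = 36L)
  rs <- read_set(rd)
  expect_equal(sum(table(rs$reads$chrom)), n)

  outdir <- withr::local_tempdir()
  paths <- split_reads_by_chromosome(rs, outdir)
  expect_equal(length(paths), 3)
  back <- do.call(rbind, lapply(paths, function(p) read_reads(p, "bed")$reads))
  expect_equal(nrow(back), n)
  key <- function(d) sort(paste(d$chrom, d$start, d$strand))
  expect_equal(key(back), key(rd))
  # collision protection
  expect_error(split_reads_by_chromosome(rs, outdir), "exists")
  expect_silent(invisible(split_reads_by_chromosome(rs, outdir, overwrite = TRUE)))

  # empty read set -> no files
  empty <- read_set(rd[0, ])
  expect_length(split_reads_by_chromosome(empty, withr::local_tempdir()), 0)
})

test_that("fetch_sequences returns uppercase plus-strand sequence of exact length", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtACGTacgt"), fa)
  ps <- peak_set("chr1", c(0L, 4L), c(4L, 10L))
  sq <- fetch_sequences(fa, ps)
  expect_equal(sq$seq, c("ACGT", "ACGTAC"))
  expect_equal(nchar(sq$seq), ps$end - ps$start)
  expect_error(fetch_sequences(fa, peak_set("chr1", 5L, 20L)), "beyond")
  expect_error(fetch_sequences(fa, peak_set("chrX", 0L, 2L)), "absent")

  # strand consistency: fetching then reverse-complementing
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp(sq$seq[2]), "GTACGT")
})

test_that("track writing round-trips peaks and emits per-base wiggle", {
  ps <- peak_set(rep("chr1", 3), c(0L, 50L, 90L), c(10L, 60L, 130L))
  p <- withr::local_tempfile(fileext = ".bed")
  write_tracks(ps, "peaks", p, name = "test")
  lines <- readLines(p)
  expect_match(lines[1], "^track")
  expect_length(lines, 4)
  back <- read_peaks(p)   # header skipped by the reader
  expect_equal(back$start, ps$start)
  expect_equal(back$end, ps$end)

  wig <- withr::local_tempfile(fileext = ".wig")
  write_tracks(list(chr1 = rep(2, 100)), "density", wig)
  tr <- read_score_track(wig)
  expect_equal(track_scores(tr, "chr1", 0, 100), rep(2, 100))
})

test_that("score tracks parse fixedStep wiggle and bedGraph identically", {
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=11 step=1",
               "0.1", "0.2", "0.3"), wig)
  tr <- read_score_track(wig)
  expect_equal(track_scores(tr, "chr1", 10, 13), c(0.1, 0.2, 0.3))
  expect_equal(track_scores(tr, "chr1", 8, 11, missing = 0), c(0, 0, 0.1))

  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t10\t13\t0.5", "chr1\t20\t22\t0.9"), bg)
  tb <- read_score_track(bg)
  expect_equal(track_scores(tb, "chr1", 10, 14), c(0.5, 0.5, 0.5, 0))
  expect_equal(track_scores(tb, "chr1", 20, 22), c(0.9, 0.9))
})

test_that("refGene tables round-trip through write_genes/read_genes", {
  genes <- toy_genes()
  p <- withr::local_tempfile(fileext = ".txt")
  write_genes(genes, p)
  back <- read_genes(p)
  expect_equal(back$name, genes$name)
  expect_equal(back$symbol, genes$symbol)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$tx_start, genes$tx_start)
  expect_equal(back$exon_starts, genes$exon_starts)
  expect_equal(back$exon_ends, genes$exon_ends)
  expect_equal(tss(genes), c(10000L, 40000L))
})

test_that("JASPAR PFM and GMT collections parse and round-trip", {
  pfm <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 testmotif",
               "A [ 4 0 1 ]", "C [ 0 4 1 ]", "G [ 0 0 1 ]", "T [ 0 0 1 ]"), pfm)
  pw <- read_pfm(pfm)
  expect_named(pw, "M1")
  expect_equal(dim(pw$M1$counts), c(4L, 3L))
  expect_equal(unname(pw$M1$counts["A", 1]), 4)
  p2 <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(pw, p2)
  expect_equal(read_pfm(p2)$M1$counts, pw$M1$counts)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG4"), gmt)
  gsc <- read_gmt(gmt)
  expect_equal(sort(names(gsc$sets)), c("setA", "setB"))
  expect_equal(gsc$sets$setB, c("G2", "G4"))
})
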