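test_that("classification reproduces hand-computed window arithmetic", {
  genes <- toy_genes()
  cfg <- annotation_config()
  peaks <- peak_set(rep("chr1", 6),
                    c(9000L, 13000L, 30000L, 11000L, 20500L, 22500L),
                    c(9100L, 13100L, 30100L, 11100L, 20600L, 22600L),
                    id = paste0("p", 1:6))
  ann <- classify_peaks(peaks, genes, cfg)
  expect_equal(ann$category[1], "promoter")      # 2 kb upstream of the TSS
  expect_equal(ann$category[2], "first_intron")  # inside [12000, 18000)
  expect_equal(ann$category[3], "distal")        # 10 kb past the TES
  expect_equal(ann$category[4], "promoter")      # exonic but promoter wins
  expect_equal(ann$category[5], "downstream")    # within 2 kb past TES
  expect_equal(ann$category[6], "distal")        # gap 2500 >= distal_min

  # with a wider distal cutoff the same peak is near-gene-but-no-part
  ann3 <- classify_peaks(peaks, genes, annotation_config(distal_min = 3000L))
  expect_equal(ann3$category[6], "other")

  # peaks on a chromosome without genes are distal, with a warning
  offchrom <- peak_set("chr9", 100L, 200L)
  expect_warning(ann2 <- classify_peaks(offchrom, genes, cfg), "without genes")
  expect_equal(ann2$category, "distal")
  expect_error(classify_peaks(peaks, genes[0, ], cfg), "empty gene table")
})

test_that("primary categories partition the peaks and fractions sum to 1", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  ann <- classify_peaks(truth, fx$genes)
  expect_equal(sum(vapply(ann$by_category, nrow, 0L)), nrow(truth))
  expect_equal(sum(ann$observed_fractions), 1)
  # each peak appears in exactly the by_category set of its category
  for (cat in names(ann$by_category))
    expect_setequal(ann$by_category[[cat]]$id, truth$id[ann$category == cat])
})

test_that("promoter windows never pass the transcript's downstream extremity", {
  # a gene much shorter than half the promoter window
  short <- gene_table("txS", "geneS", "chr1", "+", 10000L, 11000L,
                      list(10000L), list(11000L))
  pw <- peakatlas:::promoter_windows(short, annotation_config())
  expect_equal(pw$end, 11000L)    # clipped at tx_end, not tss + 2000
  expect_equal(pw$start, 8000L)
  neg <- gene_table("txS", "geneS", "chr1", "-", 10000L, 11000L,
                    list(10000L), list(11000L))
  pwn <- peakatlas:::promoter_windows(neg, annotation_config())
  expect_equal(pwn$start, 10000L) # clipped at tx_start on the minus strand
  expect_equal(pwn$end, 13000L)
})

test_that("strand mirroring mirrors promoter/downstream/first-intron labels", {
  G <- 100000L
  genes <- toy_genes()
  mg <- mirror_genes(genes, G)
  peaks <- peak_set(rep("chr1", 5),
                    c(9000L, 13000L, 20500L, 30000L, 11000L),
                    c(9100L, 13100L, 20600L, 30100L, 11100L))
  mp <- mirror_peaks(peaks, G)
  a <- classify_peaks(peaks, genes)
  b <- classify_peaks(mp, mg)
  expect_equal(a$category, b$category)
  # expected fractions are mirror-invariant too
  expect_equal(expected_fractions(genes, toy_sizes),
               expected_fractions(mg, toy_sizes))
})

test_that("expected fractions match the per-base labeling oracle", {
  cfg <- annotation_config()
  genes <- toy_genes()
  got <- expected_fractions(genes, toy_sizes, cfg)
  want <- naive_label_genome(genes, toy_sizes, cfg)
  oracle <- table(factor(unlist(want), levels = names(got))) / sum(toy_sizes)
  expect_equal(as.numeric(got), as.numeric(oracle))
  expect_equal(sum(got), 1)

  # no genes at all -> everything distal (labeling level)
  labs <- peakatlas:::label_genome(genes[0, ], toy_sizes, cfg)
  expect_true(all(labs$chr1 == match("distal", peakatlas:::PEAK_CATEGORIES)))
})

test_that("gene-parts matrix counts links per gene and category", {
  genes <- toy_genes()
  peaks <- peak_set(rep("chr1", 3), c(9000L, 13000L, 43000L),
                    c(9100L, 13100L, 43100L), id = c("p1", "p2", "p3"))
  ann <- classify_peaks(peaks, genes)
  m <- geneparts_matrix(ann)
  expect_equal(m["geneA", "promoter"], 1L)
  expect_equal(m["geneA", "first_intron"], 1L)
  expect_equal(m["geneB", "exon"], 1L)
  expect_equal(sum(m), nrow(ann$gene_links))
  # no peaks -> empty matrix
  empty <- classify_peaks(peak_set(), genes)
  expect_equal(nrow(geneparts_matrix(empty)), 0)
})

test_that("closest genes match a brute-force distance scan, keeping ties", {
  genes <- toy_genes()
  # equidistant peak: 500 bp from geneA's end (20000) and from a mirror gene
  twin <- gene_table(c("txA", "txC"), c("geneA", "geneC"), "chr1",
                     c("+", "+"), c(10000L, 21500L), c(20000L, 25000L),
                     list(10000L, 21500L), list(20000L, 25000L))
  tie <- peak_set("chr1", 20500L, 21000L)
  cl <- find_closest_genes(tie, twin)
  expect_setequal(cl$symbol, c("geneA", "geneC"))
  expect_equal(abs(cl$distance), c(500L, 500L))

  inside <- find_closest_genes(peak_set("chr1", 15000L, 15100L), twin)
  expect_equal(inside$distance, 0L)

  set.seed(81)
  peaks <- random_peak_frame(200, chroms = "chr1", max_pos = 90000L)
  cl <- find_closest_genes(peaks, genes)
  for (id in unique(cl$peak_id)) {
    i <- match(id, peaks$id)
    gaps <- pmax(0, pmax(genes$tx_start - peaks$end[i],
                         peaks$start[i] - genes$tx_end))
    expect_setequal(cl$symbol[cl$peak_id == id],
                    genes$symbol[gaps == min(gaps)])
  }
})

test_that("distal peak finding is consistent with classification", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  genes <- fx$genes
  ann <- classify_peaks(truth, genes)
  d <- find_distal_peaks(truth, genes, d = 2000L)
  expect_setequal(d$id, ann$by_category$distal$id)
  # d = 0 keeps all non-overlapping peaks; no genes keeps everything
  d0 <- find_distal_peaks(truth, genes, d = 0L)
  expect_gte(nrow(d0), nrow(d))
  expect_equal(nrow(find_distal_peaks(truth, genes[0, ])), nrow(truth))
})

test_that("gene-list comparison equals set algebra", {
  expect_equal(compare_genes(c("A", "B"), c("A", "B")),
               list(common = c("A", "B"), only_a = character(),
                    only_b = character()))
  expect_equal(compare_genes("A", "B")$common, character())
  set.seed(91)
  for (i in 1:10) {
    a <- sample(LETTERS, 10)
    b <- sample(LETTERS, 10)
    cg <- compare_genes(a, b)
    expect_setequal(c(cg$common, cg$only_a), a)
    expect_setequal(c(cg$common, cg$only_b), b)
    expect_length(intersect(cg$only_a, cg$only_b), 0)
  }
})

test_that("nongenic annotation flags track overlaps with significance", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  genes <- fx$genes
  cs <- unlist(fx$truth$chrom_sizes)
  cpg <- read_peaks(fx$files$cpg)
  res <- nongenic_annotate(truth, list(cpg = cpg, self = truth),
                           genes, cs, n_rand = 19, seed = 4)
  # overlap lists equal the compare_intervals oracle
  expect_setequal(res$cpg$overlapping$id,
                  compare_intervals(truth, cpg, "overlap")$id)
  # track = peaks themselves: full overlap at minimum p
  expect_equal(nrow(res$self$overlapping), nrow(truth))
  expect_equal(res$self$stats$p_value, 1 / 20)
  # empty track: no overlap, stats skipped
  res2 <- nongenic_annotate(truth, list(none = peak_set()), genes, cs,
                            n_rand = 9, seed = 1)
  expect_equal(nrow(res2$none$overlapping), 0)
  expect_null(res2$none$stats)
})
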