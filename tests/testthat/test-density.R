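simple_reads <- function(df, fraglen = 200L) {
  if (!"read_len" %in% names(df)) df$read_len <- rep(36L, nrow(df))
  read_set(df, fraglen)
}

test_that("density matrix has window/bin columns and matches coverage", {
  genes <- toy_genes()
  cs <- toy_sizes
  # defaults: 4 kb window, 10 nt bins -> 400 columns
  none <- simple_reads(data.frame(chrom = character(), start = integer(),
                                  strand = character()))
  m0 <- density_matrix("tss", genes, none, cs)
  expect_equal(ncol(m0), 400L)
  expect_true(all(m0 == 0))

  # one + read at the TSS with L = 50: exactly bins 201..205 equal 1
  rd <- simple_reads(data.frame(chrom = "chr1", start = 10000L, strand = "+",
                                read_len = 36L), fraglen = 50L)
  m1 <- density_matrix("tss", genes, rd, cs, window = 4000L, bin = 10L)
  expect_equal(which(m1["txA", ] == 1), 201:205)
  expect_true(all(m1["txA", -(201:205)] == 0))

  # coverage conservation: sum(bins) * bin_bp = extended-read overlap
  set.seed(181)
  rd2 <- simple_reads(data.frame(
    chrom = "chr1", start = sample(8000:12000, 300, replace = TRUE),
    strand = sample(c("+", "-"), 300, replace = TRUE), read_len = 36L))
  m2 <- density_matrix("tss", genes["chr1" == genes$chrom, ][1, ], rd2, cs)
  cov <- coverage_vector(rd2, cs)$chr1
  expect_equal(sum(m2[1, ]) * 10, sum(cov[(10000 - 2000 + 1):(10000 + 2000)]))
})

test_that("minus-strand rows are flipped so column 1 is 5'-most", {
  cs <- c(chr1 = 30000L)
  minus <- gene_table("t2", "g2", "chr1", "-", 10000L, 12000L,
                      list(10000L), list(12000L))
  # a plus-strand twin anchored at the same genomic TSS position (11999)
  twin <- gene_table("t3", "g3", "chr1", "+", 11999L, 13999L,
                     list(11999L), list(13999L))
  rd <- simple_reads(data.frame(chrom = "chr1", start = 11500L,
                                strand = "+", read_len = 36L))
  mm <- density_matrix("tss", minus, rd, cs, window = 2000L, bin = 10L)
  mt <- density_matrix("tss", twin, rd, cs, window = 2000L, bin = 10L)
  # same window, opposite orientation: the minus row is the reverse
  expect_equal(as.numeric(mm[1, ]), rev(as.numeric(mt[1, ])))
  expect_gt(sum(mm[1, ]), 0)
})

test_that("RPKM normalization is invariant under read duplication", {
  genes <- toy_genes()
  cs <- toy_sizes
  set.seed(191)
  df <- data.frame(chrom = "chr1",
                   start = sample(8000:12000, 200, replace = TRUE),
                   strand = "+", read_len = 36L)
  one <- simple_reads(df)
  two <- simple_reads(rbind(df, df))
  m1 <- density_matrix("tss", genes, one, cs, normalize = "rpkm")
  m2 <- density_matrix("tss", genes, two, cs, normalize = "rpkm")
  expect_equal(m1, m2)
  # linearity of the raw values
  r1 <- density_matrix("tss", genes, one, cs)
  r2 <- density_matrix("tss", genes, two, cs)
  expect_equal(2 * r1, r2)
})

test_that("read-count matrix summarizes coverage with max >= avg", {
  cs <- toy_sizes
  peaks <- peak_set(rep("chr1", 3), c(1000L, 5000L, 9000L),
                    c(1500L, 5400L, 9600L))
  set.seed(201)
  ds1 <- simple_reads(data.frame(
    chrom = "chr1", start = sample(500:10000, 400, replace = TRUE),
    strand = sample(c("+", "-"), 400, replace = TRUE), read_len = 36L))
  ds2 <- simple_reads(data.frame(chrom = character(), start = integer(),
                                 strand = character()))
  expect_warning(
    mx <- read_count_matrix(peaks, list(a = ds1, b = ds2), "max", cs),
    "no reads")
  av <- suppressWarnings(
    read_count_matrix(peaks, list(a = ds1, b = ds2), "avg", cs))
  expect_true(all(mx >= av))
  expect_true(all(mx[, "b"] == 0))
  # oracle recomputation of both statistics
  cov <- coverage_vector(ds1, cs)$chr1
  for (i in 1:3) {
    seg <- cov[(peaks$start[i] + 1):peaks$end[i]]
    expect_equal(mx[i, "a"], max(seg))
    expect_equal(av[i, "a"], mean(seg))
  }
  # RPKM: doubling reads leaves values unchanged
  dbl <- simple_reads(rbind(ds1$reads, ds1$reads))
  n1 <- suppressWarnings(read_count_matrix(peaks, list(a = ds1), "avg", cs,
                                           normalize = "rpkm"))
  n2 <- suppressWarnings(read_count_matrix(peaks, list(a = dbl), "avg", cs,
                                           normalize = "rpkm"))
  expect_equal(n1, n2)
})

test_that("gene-part density summary picks out promoter-spiked signal", {
  genes <- toy_genes()
  cs <- toy_sizes
  # pile reads into geneA's promoter region only
  rd <- simple_reads(data.frame(
    chrom = "chr1", start = sample(8000:9500, 300, replace = TRUE),
    strand = "+", read_len = 36L))
  tab <- summarize_density_in_geneparts(rd, genes, cs)
  expect_equal(tab$category[which.max(tab$mean_coverage)], "promoter")
  # no reads -> all zeros
  none <- simple_reads(data.frame(chrom = character(), start = integer(),
                                  strand = character()))
  expect_true(all(summarize_density_in_geneparts(none, genes, cs)$mean_coverage == 0))
})

test_that("SOM clustering separates planted groups deterministically", {
  set.seed(211)
  centers <- matrix(c(rep(0, 20), rep(5, 20), rep(c(0, 5), 10)), 3, 20,
                    byrow = TRUE)
  mat <- centers[rep(1:3, each = 10), ] + matrix(rnorm(600, sd = 0.1), 30, 20)
  som <- som_cluster(mat, grid = c(2, 2), epochs = 40, seed = 6)
  planted <- rep(1:3, each = 10)
  # identical-group rows land on a single node each, distinct across groups
  for (g in 1:3)
    expect_length(unique(som$cluster[planted == g]), 1)
  expect_length(unique(vapply(1:3, function(g)
    som$cluster[planted == g][1], 0L)), 3)
  # fixed seed -> byte-identical assignments
  expect_identical(som$cluster, som_cluster(mat, grid = c(2, 2),
                                            epochs = 40, seed = 6)$cluster)
  # 1x1 grid puts everything in one cluster
  expect_length(unique(som_cluster(mat, grid = c(1, 1), epochs = 5,
                                   seed = 1)$cluster), 1)
})

test_that("k-means recovers planted partitions; hierarchical cuts consistently", {
  recovered <- vapply(1:10, function(s) {
    set.seed(300 + s)
    mat <- rbind(matrix(rnorm(200, 0, 0.3), 20),
                 matrix(rnorm(200, 4, 0.3), 20))
    km <- kmeans_cluster(mat, 2, seed = s)
    planted <- rep(1:2, each = 20)
    agree <- max(mean(km$cluster == planted), mean(km$cluster == 3 - planted))
    agree
  }, 0)
  expect_true(all(recovered >= 0.95))

  set.seed(221)
  mat <- matrix(rnorm(100), 10)
  expect_error(kmeans_cluster(mat, 0), "positive")
  # k = rows: singletons
  expect_equal(sort(kmeans_cluster(mat, 10, seed = 1)$cluster), 1:10)
  # duplicated rows always co-cluster
  dup <- rbind(mat, mat[1, , drop = FALSE])
  km <- kmeans_cluster(dup, 3, seed = 2)
  expect_equal(km$cluster[1], km$cluster[11])
  expect_identical(kmeans_cluster(mat, 3, seed = 9)$cluster,
                   kmeans_cluster(mat, 3, seed = 9)$cluster)

  hc <- hierarchical_cluster(rbind(matrix(0, 5, 4), matrix(9, 5, 4)), 2)
  expect_length(unique(hc$cluster[1:5]), 1)
  expect_length(unique(hc$cluster[6:10]), 1)
  expect_equal(length(unique(hc$cluster)), 2)
})

test_that("cluster region lists export one file per cluster", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  chip <- read_reads(fx$files$chip, "bed")
  cs <- unlist(fx$truth$chrom_sizes)
  m <- density_matrix("summit", truth, chip, cs, window = 1000L, bin = 50L)
  km <- kmeans_cluster(m, 3, seed = 4)
  outdir <- withr::local_tempdir()
  paths <- write_cluster_regions(km, truth, outdir)
  expect_length(paths, length(unique(km$cluster)))
  back <- do.call(rbind, lapply(paths, read_peaks))
  expect_equal(nrow(back), nrow(truth))
})
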