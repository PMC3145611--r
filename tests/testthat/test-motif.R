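test_that("Berg-von Hippel weights are log-ratios to the column maximum", {
  counts <- matrix(c(4, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  w <- bvh_weights(counts, pseudocount = 0.5)
  expect_equal(unname(w["A", 1]), 0)
  expect_equal(unname(w["C", 1]), log(0.5 / 4.5))
  # uniform column: all weights 0 by symmetry
  uni <- matrix(2, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(as.numeric(bvh_weights(uni)), rep(0, 4))
  # every column's max weight is exactly 0; all weights <= 0
  set.seed(101)
  counts <- matrix(rpois(4 * 8, 5) + 1, 4, 8,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  w <- bvh_weights(counts)
  expect_equal(as.numeric(apply(w, 2, max)), rep(0, 8))
  expect_true(all(w <= 0))
})

test_that("PWM scan equals the naive per-window oracle on random sequences", {
  pwm <- peakatlas:::default_fixture_pwm()
  consensus <- peakatlas:::pwm_consensus(pwm)

  # consensus scores affinity 1 at offset 0 for any tau
  seqs <- data.frame(id = "c1", seq = consensus, stringsAsFactors = FALSE)
  hit <- scan_pwm(seqs, pwm, motif_scan_config(tau = 1))
  expect_equal(hit$hits$offset, 0L)
  expect_equal(hit$hits$affinity, 1)
  expect_equal(hit$hits$strand, "+")

  # reverse complement hits on the minus strand at the same footprint
  rc <- data.frame(id = "r1", seq = revcomp(consensus))
  hit2 <- scan_pwm(rc, pwm, motif_scan_config(tau = 1))
  expect_equal(hit2$hits$strand, "-")
  expect_equal(hit2$hits$offset, 0L)

  # N-containing windows are rejected
  withN <- data.frame(id = "n1", seq = sub("G", "N", consensus))
  expect_equal(nrow(scan_pwm(withN, pwm)$hits), 0)

  # oracle agreement on 100 random 200-nt sequences (forward strand)
  set.seed(111)
  sqs <- data.frame(id = paste0("s", 1:100),
                    seq = vapply(1:100, function(i) random_dna(200), ""),
                    stringsAsFactors = FALSE)
  got <- scan_pwm(sqs, pwm, motif_scan_config(tau = 0.2, both_strands = FALSE))
  for (i in seq_len(nrow(sqs))) {
    want <- naive_scan(sqs$seq[i], pwm$counts, 0.5, 0.2)
    sub <- got$hits[got$hits$id == sqs$id[i], , drop = FALSE]
    expect_equal(sort(sub$offset),
                 sort(vapply(want, `[[`, 0, "offset")))
  }

  # strand symmetry: reverse-complementing all sequences preserves counts
  both <- scan_pwm(sqs, pwm, motif_scan_config(tau = 0.2))
  flipped <- scan_pwm(transform(sqs, seq = revcomp(seq)), pwm,
                      motif_scan_config(tau = 0.2))
  expect_equal(nrow(both$hits), nrow(flipped$hits))
})

test_that("regex scanning reports overlapping matches on both strands", {
  sqs <- data.frame(id = "x", seq = "ACGC", stringsAsFactors = FALSE)
  hit <- scan_regex(sqs, "[AT]CG[CT]")
  fwd <- hit$hits[hit$hits$strand == "+", ]
  expect_equal(fwd$offset, 0L)

  # absent pattern excludes the peak
  expect_length(scan_regex(data.frame(id = "y", seq = "GGGGG"),
                           "TCCAAT")$peaks_with_motif, 0)
  expect_error(scan_regex(sqs, "[unclosed"), "invalid")

  # overlapping matches are all reported
  hit2 <- scan_regex(data.frame(id = "z", seq = "AAAA"), "AA")
  expect_equal(sum(hit2$hits$strand == "+"), 3)

  # random sequences: forward-strand counts match a naive slide
  set.seed(121)
  for (i in 1:20) {
    s <- random_dna(120)
    pat <- "[AT]CG[CT]"
    naive <- sum(vapply(1:(nchar(s) - 3), function(o)
      grepl(paste0("^", pat), substr(s, o, o + 3)), TRUE))
    got <- scan_regex(data.frame(id = "q", seq = s), pat)
    expect_equal(sum(got$hits$strand == "+"), naive)
  }
})

test_that("background generators conserve lengths and match their targets", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  cs <- unlist(fx$truth$chrom_sizes)
  genome <- fx$files$genome

  for (mode in c("random", "adjacent")) {
    bg <- make_background(truth, genome, cs,
                          background_config(mode = mode, seed = 5))
    expect_equal(nchar(bg$seq), truth$end - truth$start)
  }

  # adjacent backgrounds flank the peaks
  adj <- make_background(truth, genome, cs,
                         background_config(mode = "adjacent", seed = 5))
  gap <- pmin(abs(adj$start - truth$end), abs(truth$start - adj$end))
  expect_true(all(gap == 0))

  # seeded runs are bit-reproducible
  b1 <- make_background(truth, genome, cs, background_config("1MM", seed = 9))
  b2 <- make_background(truth, genome, cs, background_config("1MM", seed = 9))
  expect_identical(b1$seq, b2$seq)
})

test_that("1MM backgrounds preserve dinucleotide structure", {
  # deterministic chain: a homopolymer regenerates itself
  one <- peak_set("chr1", 0L, 8L, id = "h")
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAAAAA"))
  bg <- make_background(one, genome, c(chr1 = 10L),
                        background_config("1MM", seed = 1))
  expect_equal(bg$seq, "AAAAAAAA")

  # pooled dinucleotide frequencies within 0.02 on 50 GC-rich peaks
  set.seed(131)
  n <- 50L; L <- 400L
  gseq <- paste(vapply(1:n, function(i) random_dna(L, gc = 0.7), ""),
                collapse = "")
  genome2 <- Biostrings::DNAStringSet(c(chr1 = gseq))
  peaks <- peak_set(rep("chr1", n), seq(0L, by = L, length.out = n),
                    seq(L, by = L, length.out = n))
  bg2 <- make_background(peaks, genome2, c(chr1 = n * L),
                         background_config("1MM", seed = 17))
  src <- fetch_sequences(genome2, peaks)
  expect_true(all(abs(dinucleotide_frequencies(bg2$seq) -
                        dinucleotide_frequencies(src$seq)) <= 0.02))
})

test_that("CGI backgrounds reproduce the peaks' island-overlap fraction", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  cs <- unlist(fx$truth$chrom_sizes)
  cpg <- read_peaks(fx$files$cpg)
  expect_error(background_config("CGI"), "cpg_track")
  bg <- make_background(truth, fx$files$genome, cs,
                        background_config("CGI", seed = 23, cpg_track = cpg))
  frac_peaks <- nrow(compare_intervals(truth, cpg, "overlap")) / nrow(truth)
  bg_set <- peak_set(bg$chrom, bg$start, bg$end)
  frac_bg <- nrow(compare_intervals(bg_set, cpg, "overlap")) / nrow(bg_set)
  expect_lte(abs(frac_bg - frac_peaks), 0.05)
  expect_equal(nchar(bg$seq), truth$end - truth$start)
})

test_that("embedded fixture motif is recovered at the planted fraction", {
  fx <- shared_fixture()
  truth <- read_peaks(fx$files$truth_peaks)
  pwm <- read_pfm(fx$files$motifs)[[1]]
  seqs <- fetch_sequences(fx$files$genome, truth)
  hit <- scan_pwm(seqs, pwm, motif_scan_config(tau = 0.5))
  frac <- length(hit$peaks_with_motif) / nrow(truth)
  expect_lte(abs(frac - fx$truth$motif$fraction), 0.1)
  # the planted carriers are all found
  carriers <- fx$truth$peaks$id[fx$truth$peaks$has_motif]
  expect_true(all(carriers %in% hit$peaks_with_motif))
})
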