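test_that("FASTA and FASTQ parsing handle minimal records and round-trip", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(">s1\nACGT", fa)
  x <- parse_fastx(fa, "fasta")
  expect_equal(x$id, "s1")
  expect_equal(x$seq, "ACGT")

  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  y <- parse_fastx(fq, "fastq")
  expect_equal(sortvir:::phred_to_int(y$qual)[[1]], rep(40L, 4))

  # multi-line FASTA
  writeLines(c(">m1", "ACGT", "TTGG"), fa)
  expect_equal(parse_fastx(fa)$seq, "ACGTTTGG")

  set.seed(42)
  n <- 100
  lens <- sample(20:80, n, replace = TRUE)
  recs <- nuc_set(sprintf("r%03d", 1:n),
                  vapply(lens, rand_dna, ""),
                  vapply(lens, function(L)
                    rawToChar(as.raw(sample(33:74, L, replace = TRUE))), ""))
  for (fmt in c("fasta", "fastq")) {
    f <- tempfile()
    serialize_fastx(recs, f, fmt)
    back <- parse_fastx(f, fmt)
    expect_equal(back$id, recs$id)
    expect_equal(back$seq, recs$seq)
    if (fmt == "fastq") expect_equal(back$qual, recs$qual)
  }
})

test_that("malformed records are rejected with their line number", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(parse_fastx(fq, "fastq"), "line 4")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), fq)
  expect_error(parse_fastx(fq, "fastq"), "line 5")
  writeLines(c("@r1", "ACGT", "+"), fq)
  expect_error(parse_fastx(fq, "fastq"), "truncated")
  expect_error(nuc_set("x", "ACGT", "III"), "length")
  expect_error(nuc_set("x", "AC!T"), "invalid")
})

test_that("quality trimming matches an exhaustive window-scan oracle", {
  mk <- function(q) nuc_set("r", strrep("A", length(q)),
                            rawToChar(as.raw(q + 33L)))
  # all high quality: unchanged
  t1 <- quality_trim(mk(rep(40, 100)))
  expect_equal(nchar(t1$seq), 100)
  # all below the leading cut: dropped
  t2 <- quality_trim(mk(rep(2, 100)))
  expect_equal(nrow(t2), 0)
  expect_equal(attr(t2, "dropped"), "r")
  # quality cliff: cut where the first failing window starts
  q <- c(rep(40, 60), rep(10, 20))
  t3 <- quality_trim(mk(q), min_len = 1)
  expect_equal(nchar(t3$seq), diff(trim_oracle(q)) + 1)
  # randomized agreement with the brute-force scan
  set.seed(7)
  for (i in 1:50) {
    q <- sample(0:41, sample(30:120, 1), replace = TRUE)
    b <- trim_oracle(q)
    keep_len <- max(0L, b[2] - b[1] + 1L)
    got <- quality_trim(mk(q), min_len = 1)
    if (keep_len < 1) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nchar(got$seq), keep_len)
      # output is a contiguous substring of the input
      expect_equal(got$seq, strrep("A", keep_len))
    }
  }
  expect_error(quality_trim(nuc_set("r", "ACGT")), "qualities")
})

test_that("six-frame translation agrees with an explicit codon table", {
  expect_equal(unname(six_frame_translate("ATGAAA")[1]), "MK")
  set.seed(11)
  for (i in 1:5) {
    s <- rand_dna(300)
    fr <- six_frame_translate(s)
    rc <- rc_oracle(s)
    for (f in 0:2) {
      expect_equal(unname(fr[f + 1]), translate_oracle(substr(s, f + 1, 300)))
      expect_equal(unname(fr[f + 4]), translate_oracle(substr(rc, f + 1, 300)))
    }
  }
  # N codons become X
  expect_equal(unname(six_frame_translate("ATGNNN")[1]), "MX")
})

test_that("canonical k-mer pooling matches brute force and is strand-invariant", {
  all4 <- apply(expand.grid(DNA, DNA, DNA, DNA), 1, paste0, collapse = "")
  canon <- unique(pmin(all4, vapply(all4, rc_oracle, "")))
  expect_equal(length(canon), 136)
  k <- canonical_kmer_counts(strrep("A", 20))
  expect_equal(length(k), 136)
  expect_equal(unname(k[["AAAA"]]), 1)
  expect_equal(sum(k), 1)
  set.seed(3)
  for (i in 1:5) {
    s <- rand_dna(500)
    expect_equal(canonical_kmer_counts(s), canonical_kmer_counts(rc_oracle(s)))
  }
  short <- canonical_kmer_counts("ACG")
  expect_true(attr(short, "empty"))
})

test_that("GC content and the moving window behave as defined", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_true(is.na(gc_content("NNNN")))
  expect_equal(gc_content("GGNN"), 1) # N excluded from denominator
  s <- paste0(strrep("G", 1000), strrep("A", 1000))
  mg <- moving_gc(s, window = 1000)
  expect_equal(mg$gc[1], 1)
  expect_equal(mg$gc[mg$start == 1001], 0)
  expect_equal(unique(diff(mg$start)), 500)
})

test_that("local alignment equals a full dynamic-programming oracle", {
  a <- rand_dna(50)
  h <- local_align(a, a)
  expect_equal(h$pct_identity, 100)
  expect_equal(h$aligned_len, 50)
  # a 1000 bp pair differing at exactly 7 positions
  set.seed(5)
  b <- rand_dna(1000)
  b2 <- b
  for (p in sample(1000, 7)) {
    substr(b2, p, p) <- chartr("ACGT", "CGTA", substr(b2, p, p))
  }
  h2 <- local_align(b, b2)
  expect_equal(h2$pct_identity, 99.3, tolerance = 1e-3)
  # DP oracle on short strings
  set.seed(13)
  for (i in 1:25) {
    x <- rand_dna(sample(8:20, 1))
    y <- rand_dna(sample(8:20, 1))
    got <- local_align(x, y, both_strands = FALSE)
    want <- sw_oracle(x, y)
    got_raw <- if (nrow(got)) got$raw_score else 0
    if (want == 0) expect_true(got_raw <= 0 || nrow(got) == 0)
    else expect_equal(got_raw, want)
    # score symmetry under query/target swap
    swapped <- local_align(y, x, both_strands = FALSE)
    if (nrow(got) && nrow(swapped)) {
      expect_equal(got$raw_score, swapped$raw_score)
    }
  }
  expect_equal(nrow(local_align("", "ACGT")), 0)
})

test_that("reverse-strand hits come back on forward coordinates", {
  set.seed(9)
  g <- rand_dna(400)
  q <- rc_oracle(substr(g, 101, 200))
  h <- local_align(q, g)
  expect_equal(h$strand, "-")
  expect_equal(h$t_start, 101)
  expect_equal(h$t_end, 200)
  expect_equal(h$q_start, 1)
  expect_equal(h$q_end, 100)
})

test_that("blast6 export has 12 tab-separated fields", {
  h <- local_align(rand_dna(60), rand_dna(60))
  if (nrow(h)) {
    line <- format_blast6(h)
    expect_equal(length(strsplit(line, "\t")[[1]]), 12)
  } else succeed()
})
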