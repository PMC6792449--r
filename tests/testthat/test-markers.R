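test_that("profile construction matches hand-computed log-odds", {
  aln <- c(s1 = "AWD", s2 = "AWK", s3 = "AWD", s4 = "CWD")
  pf <- build_profile(aln, alpha = 1)
  b <- 1 / 20
  lo <- function(c, n) log2(((c + b) / (n + 1)) / b)
  expect_equal(unname(pf$matrix[1, "A"]), lo(3, 4))
  expect_equal(unname(pf$matrix[1, "C"]), lo(1, 4))
  expect_equal(unname(pf$matrix[1, "W"]), lo(0, 4))
  expect_equal(unname(pf$matrix[2, "W"]), lo(4, 4))
  expect_equal(unname(pf$matrix[3, "D"]), lo(3, 4))
  expect_equal(unname(pf$matrix[3, "K"]), lo(1, 4))

  # single-residue column with vanishing pseudocount: log2(1/b) for the
  # residue, large negative elsewhere
  pf2 <- build_profile(c(a = "W", b = "W"), alpha = 1e-9)
  expect_equal(unname(pf2$matrix[1, "W"]), log2(20), tolerance = 1e-6)
  expect_lt(unname(pf2$matrix[1, "A"]), -20)

  # a column matching the background has log-odds 0 everywhere
  pf3 <- build_profile(setNames(AA20, paste0("s", 1:20)), alpha = 1e-9)
  expect_true(all(abs(pf3$matrix) < 1e-6))

  # columns with > 50% gaps are dropped; ragged alignments are rejected
  pf4 <- build_profile(c(a = "A-W", b = "A-W", c = "AK-"))
  expect_equal(pf4$length, 2)
  expect_error(build_profile(c(a = "AW", b = "AWK")), "ragged")
})

test_that("ORF prediction recovers planted genes at exact coordinates", {
  set.seed(5)
  pep <- rand_pep(300)
  cds <- paste0("ATG", sortvir:::back_translate(pep, 0.4), "TAA")
  bg1 <- rand_dna(1000); bg2 <- rand_dna(1000)
  contig <- paste0(bg1, cds, bg2)
  orfs <- predict_orfs(contig, min_aa = 60)
  # the planted gene comes back as a forward ORF ending at its stop codon
  hit <- orfs[orfs$strand == "+" & grepl(pep, orfs$peptide, fixed = TRUE), ]
  expect_equal(nrow(hit), 1)
  expect_lte(hit$start, 1001)
  expect_equal(hit$end, 1000 + nchar(cds) - 3)

  # reverse-strand gene reported with strand '-' and forward coordinates
  contig_rc <- rc_oracle(contig)
  orfs_rc <- predict_orfs(contig_rc, min_aa = 60)
  hit_rc <- orfs_rc[orfs_rc$strand == "-" &
                      grepl(pep, orfs_rc$peptide, fixed = TRUE), ]
  expect_equal(nrow(hit_rc), 1)
  expect_equal(nchar(contig) - hit_rc$end + 1, hit$start)
  expect_equal(nchar(contig) - hit_rc$start + 1, hit$end)

  # postconditions on random sequence
  set.seed(6)
  ro <- predict_orfs(rand_dna(2000), min_aa = 60)
  if (nrow(ro)) {
    expect_true(all(nchar(ro$peptide) >= 60))
    expect_false(any(grepl("*", ro$peptide, fixed = TRUE)))
  } else succeed()
})

test_that("the marker screen finds diverged markers and rejects shuffles", {
  fams <- synthetic_marker_families(n_families = 12, seed = 99)
  cfg <- community_config(41, list(
    entity_spec("v", "giant_virus", genome_len = 8e4, gc_target = 0.28,
                n_markers_planted = 10)))
  gen <- simulate_genomes(cfg, marker_families = fams)
  orfs <- predict_orfs(nuc_set("v", gen$genomes[["v"]]), min_aa = 60)
  hits <- scan_markers(orfs, fams)
  planted <- gen$truth$features$name[gen$truth$features$type == "marker"]
  expect_gte(length(intersect(unique(hits$marker), planted)), 9)

  # hit coordinates overlap the planted loci
  for (nm in intersect(hits$marker, planted)) {
    h <- hits[hits$marker == nm, ][1, ]
    f <- gen$truth$features[gen$truth$features$name == nm, ]
    expect_gt(interval_jaccard(h$orf_start, h$orf_end, f$start, f$end), 0.5)
  }

  # composition-preserving shuffles of the planted peptides score nothing
  set.seed(1)
  shuf <- orfs
  shuf$peptide <- vapply(strsplit(orfs$peptide, ""), function(ch)
    paste(sample(ch), collapse = ""), "")
  shuf_hits <- scan_markers(shuf, fams)
  expect_equal(nrow(shuf_hits), 0)

  expect_equal(nrow(scan_markers(orfs[0, ], fams)), 0)
  expect_error(scan_markers(orfs, list()), "no profiles")
})

test_that("rRNA detection reports planted operons with strand and overlap", {
  refs <- synthetic_rrna_refs()
  cfg <- community_config(43, list(
    entity_spec("h", "host_eukaryote", genome_len = 6e4, gc_target = 0.45,
                has_rrna = TRUE),
    entity_spec("v", "giant_virus", genome_len = 3e4, gc_target = 0.28)),
    contig_len_meanlog = log(3e4), n_sub1kb = 0, n_overlap_pairs = 0)
  gen <- simulate_genomes(cfg, rrna_refs = refs)
  truth_rr <- gen$truth$features[gen$truth$features$type == "rrna", ]
  hcontig <- nuc_set(c("h", "v"), unname(gen$genomes))
  rr <- detect_rrna(hcontig, refs)
  expect_equal(rr$contig_id, "h")
  expect_gte(interval_jaccard(rr$start, rr$end, truth_rr$start, truth_rr$end),
             0.9)
  expect_equal(rr$strand, truth_rr$strand)
})

test_that("bin verdicts follow the marker/rRNA rule with rRNA precedence", {
  assign <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                       bin = c("b1", "b1", "b2", "b3"),
                       length = rep(2000, 4), gc = rep(0.3, 4),
                       stringsAsFactors = FALSE)
  bins <- structure(list(assignment = assign), class = "bin_assignment")
  mh <- data.frame(contig_id = c(rep("c1", 3), rep("c2", 3), "c3", "c3", "c4"),
                   marker = c(paste0("m", 1:6), "m1", "m2", "m9"),
                   stringsAsFactors = FALSE)
  rh <- data.frame(contig_id = "c3", stringsAsFactors = FALSE)
  bc <- classify_bins(bins, mh, rh, min_markers = 5)
  v <- setNames(bc$verdict, bc$bin)
  expect_equal(v[["b1"]], "NCLDV")       # 6 distinct markers, no rRNA
  expect_equal(v[["b2"]], "cellular")    # rRNA beats stray markers
  expect_equal(v[["b3"]], "ambiguous")   # 1 marker, no rRNA
  expect_true(all(bc$n_distinct_markers <= 47))
})
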