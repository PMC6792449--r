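test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- small_community(5, n_pairs = 100)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$reads$fwd, s2$reads$fwd)
  expect_identical(s1$reads$rev, s2$reads$rev)
})

test_that("genomes hit their GC target and separate in composition", {
  gcs <- vapply(1:10, function(sd) {
    cfg <- community_config(sd, list(
      entity_spec("v", "giant_virus", genome_len = 1e5, gc_target = 0.28,
                  markov_order = 3)))
    gen <- simulate_genomes(cfg)
    gc_content(gen$genomes[["v"]])
  }, 0)
  expect_true(all(gcs >= 0.26 & gcs <= 0.30))

  # virus and host mean 4-mer vectors are farther apart than the host's
  # own window-to-window spread
  cfg <- small_community(11, n_pairs = 10)
  gen <- simulate_genomes(cfg)
  win <- function(g, n = 20) {
    L <- nchar(g)
    starts <- floor(seq(1, L - 5000, length.out = n))
    t(vapply(starts, function(s)
      as.numeric(canonical_kmer_counts(substr(g, s, s + 4999))), numeric(136)))
  }
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  hw <- win(gen$genomes[["host"]])
  vw <- win(gen$genomes[["virus"]])
  hmu <- colMeans(hw); vmu <- colMeans(vw)
  intra <- mean(apply(hw, 1, cosd, v = hmu))
  expect_gt(cosd(hmu, vmu), intra)
})

test_that("planted features are recorded faithfully", {
  cfg <- community_config(3, list(
    entity_spec("v", "giant_virus", genome_len = 2e5, gc_target = 0.28,
                n_markers_planted = 30)))
  gen <- simulate_genomes(cfg)
  mk <- gen$truth$features[gen$truth$features$type == "marker", ]
  expect_equal(nrow(mk), 30)
  expect_equal(length(unique(mk$name)), 30)
  expect_true(all(mk$end <= 2e5 & mk$start >= 1))
  # error when the genome cannot host the features
  tiny <- community_config(3, list(
    entity_spec("v", "giant_virus", genome_len = 500, gc_target = 0.28,
                n_markers_planted = 5)))
  expect_error(simulate_genomes(tiny), "too short")
})

test_that("contigs respect the size classes and the planted overlap", {
  cfg <- small_community(9, n_pairs = 10)
  gen <- simulate_genomes(cfg)
  ctg <- make_contigs(gen$genomes, cfg)
  asm <- ctg$truth$class == "assembly"
  expect_true(all(nchar(ctg$contigs$seq[asm]) >= 1000))
  expect_true(any(ctg$truth$class == "sub1kb"))
  # planted overlap pair: suffix of A equals prefix of B over overlap_len
  ov <- ctg$truth[!is.na(ctg$truth$overlap_mate), ]
  expect_equal(nrow(ov), 2)
  a <- ctg$contigs$seq[ctg$contigs$id == ov$contig_id[1]]
  b <- ctg$contigs$seq[ctg$contigs$id == ov$contig_id[2]]
  expect_equal(substr(a, nchar(a) - 149, nchar(a)), substr(b, 1, 150))
  # per-entity assembly span ~ genome length (+ overlap duplication)
  for (en in c("host", "virus")) {
    tot <- sum(nchar(ctg$contigs$seq[asm & ctg$truth$entity == en]))
    glen <- nchar(gen$genomes[[en]])
    expect_true(abs(tot - glen) <= 150)
  }
})

test_that("reads reproduce origin abundances and error settings", {
  # error-free reads are exact substrings (or reverse complements)
  cfg <- community_config(13, list(
    entity_spec("v", "giant_virus", genome_len = 5e4, gc_target = 0.30)),
    n_pairs = 2000, error_rate = 0, mda_sigma = 0)
  gen <- simulate_genomes(cfg)
  rds <- simulate_reads(gen$genomes, cfg)
  g <- gen$genomes[["v"]]
  expect_true(all(vapply(rds$fwd$seq[1:50], function(s)
    grepl(s, g, fixed = TRUE), TRUE)))
  expect_true(all(vapply(rds$rev$seq[1:50], function(s)
    grepl(rc_oracle(s), g, fixed = TRUE), TRUE)))

  # abundance 9:1 recovered within exact binomial bounds
  cfg2 <- community_config(17, list(
    entity_spec("h", "host_eukaryote", genome_len = 5e4, gc_target = 0.45,
                abundance = 9),
    entity_spec("v", "giant_virus", genome_len = 5e4, gc_target = 0.28,
                abundance = 1)), n_pairs = 2000, error_rate = 0)
  gen2 <- simulate_genomes(cfg2)
  rds2 <- simulate_reads(gen2$genomes, cfg2)
  n_h <- sum(rds2$truth$entity == "h")
  ci <- qbinom(c(0.0005, 0.9995), 2000, 0.9)
  expect_true(n_h >= ci[1] && n_h <= ci[2])

  # mda_sigma = 0 gives roughly uniform depth; a large sigma does not
  depth_cv <- function(truth, glen, rl = 150) {
    cov <- numeric(glen)
    for (i in seq_len(nrow(truth))) {
      s <- truth$start[i]
      cov[s:min(glen, s + rl - 1)] <- cov[s:min(glen, s + rl - 1)] + 1
    }
    mid <- cov[1000:(glen - 1000)]
    sd(mid) / mean(mid)
  }
  cv0 <- depth_cv(rds$truth, 5e4)
  cfgb <- community_config(13, list(
    entity_spec("v", "giant_virus", genome_len = 5e4, gc_target = 0.30)),
    n_pairs = 2000, error_rate = 0, mda_sigma = 2)
  rdsb <- simulate_reads(gen$genomes, cfgb)
  cvb <- depth_cv(rdsb$truth, 5e4)
  expect_lt(cv0, 1)
  expect_gt(cvb, cv0)
})

test_that("community outputs serialize to standard files", {
  cfg <- small_community(21, n_pairs = 50)
  sim <- simulate_community(cfg)
  d <- tempfile()
  write_community(sim, d)
  expect_true(all(file.exists(file.path(d, c(
    "contigs.fasta", "reads_R1.fastq", "reads_R2.fastq",
    "truth.tsv", "features.tsv")))))
  back <- parse_fastx(file.path(d, "reads_R1.fastq"))
  expect_equal(back$seq, sim$reads$fwd$seq)
  unlink(d, recursive = TRUE)
})
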