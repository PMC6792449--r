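# Shared fixtures and independent oracles used across the suite.

DNA <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_dna <- function(n, gc = 0.5) {
  paste(sample(DNA, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_pep <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# reverse complement written independently of the package
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# standard genetic code as an explicit lookup table
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

translate_oracle <- function(s) {
  n <- (nchar(s) %/% 3) * 3
  if (n == 0) return("")
  cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
  aa <- CODON_TABLE[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Trimmomatic-style trim bounds by brute force: LEADING/TRAILING, then an
# exhaustive scan of every window; returns c(start, end) (start > end
# when everything goes).
trim_oracle <- function(q, leading = 3, trailing = 3, w = 25, wq = 30) {
  s <- 1L; e <- length(q)
  while (s <= e && q[s] < leading) s <- s + 1L
  while (e >= s && q[e] < trailing) e <- e - 1L
  if (e - s + 1L >= w) {
    for (i in s:(e - w + 1L)) {
      if (mean(q[i:(i + w - 1L)]) < wq) {
        e <- i - 1L
        break
      }
    }
  }
  c(s, e)
}

# Full affine-gap Smith-Waterman oracle (three-matrix DP), gap of length
# L costing open + L * ext, match/mismatch scores as given.
sw_oracle <- function(a, b, match = 1, mismatch = -2, open = 5, ext = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sub <- if (x[i - 1] == y[j - 1]) match else mismatch
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub)
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# connected components by union-find, independent of igraph
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, 0L)
}

interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  uni <- max(a2, b2) - min(a1, b1) + 1
  inter / uni
}

# small two-entity community used by several suites
small_community <- function(seed = 7, n_pairs = 200) {
  community_config(seed, list(
    entity_spec("host", "host_eukaryote", genome_len = 1.2e5, gc_target = 0.45,
                has_rrna = TRUE, abundance = 3),
    entity_spec("virus", "giant_virus", genome_len = 6e4, gc_target = 0.28,
                n_markers_planted = 8, abundance = 1)
  ), n_pairs = n_pairs)
}
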