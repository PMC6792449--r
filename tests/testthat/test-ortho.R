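make_block_proteomes <- function(seed = 21) {
  set.seed(seed)
  fam <- replicate(30, rand_pep(250))
  mk <- function(famidx, nm, npriv = 4) {
    shared <- setNames(vapply(fam[famidx], function(p)
      sortvir:::mutate_protein(p, 0.1), ""),
      sprintf("%s_s%02d", nm, famidx))
    priv <- setNames(replicate(npriv, rand_pep(200)),
                     sprintf("%s_p%02d", nm, seq_len(npriv)))
    c(shared, priv)
  }
  list(g1 = mk(1:15, "g1"), g2 = mk(c(1:12, 14:15), "g2"),
       g3 = mk(1:14, "g3"),
       g4 = mk(16:30, "g4"), g5 = mk(c(16:28, 30), "g5"),
       g6 = mk(17:30, "g6"))
}

test_that("orthogroups are connected components matching a union-find oracle", {
  prot <- make_block_proteomes(21)
  om <- infer_orthogroups(prot)
  # identical proteomes: everything shared, zero private
  dup <- list(a = prot$g1, b = setNames(prot$g1, paste0("b_", names(prot$g1))))
  omd <- infer_orthogroups(dup)
  expect_equal(unname(omd$private), c(0L, 0L))
  expect_true(all(omd$presence == 1))

  # planted family membership is recovered exactly
  mem <- om$membership
  mem$fam <- sub("^g\\d_s", "fam", mem$protein)
  shared_mem <- mem[grepl("_s", mem$protein), ]
  fam_of_og <- tapply(sub(".*_s", "", shared_mem$protein),
                      shared_mem$orthogroup, function(x) length(unique(x)))
  expect_true(all(fam_of_og == 1))

  # component count equals a brute-force union-find on the same edges
  peps <- unlist(prot, use.names = FALSE)
  ids <- om$membership$protein
  edges <- sortvir:::protein_pair_hits(peps, bit_floor = 50, cov_min = 0.5)
  comp <- uf_components(length(peps), as.matrix(edges[, c("a", "b")]))
  expect_equal(length(unique(comp)),
               length(unique(om$membership$orthogroup)))

  # order invariance of the grouping itself (labels are arbitrary)
  om2 <- infer_orthogroups(rev(prot))
  part <- function(x) unname(sort(vapply(x$groups, function(g)
    paste(sort(g), collapse = ","), "")))
  expect_equal(part(om2), part(om))
  expect_equal(om2$private[names(om$private)], om$private)
})

test_that("presence-absence clustering recovers lifestyle blocks with support", {
  set.seed(33)
  mat <- rbind(
    g1 = c(rep(1, 15), rep(0, 15), rbinom(20, 1, 0.5)),
    g2 = c(rep(1, 15), rep(0, 15), rbinom(20, 1, 0.5)),
    g3 = c(rep(1, 15), rep(0, 15), rbinom(20, 1, 0.5)),
    g4 = c(rep(0, 15), rep(1, 15), rbinom(20, 1, 0.5)),
    g5 = c(rep(0, 15), rep(1, 15), rbinom(20, 1, 0.5)),
    g6 = c(rep(0, 15), rep(1, 15), rbinom(20, 1, 0.5)))
  sd1 <- cluster_presence_absence(mat, n_boot = 500, seed = 5)
  blockA <- sd1$nodes[sd1$nodes$members == "g1,g2,g3", ]
  blockB <- sd1$nodes[sd1$nodes$members == "g4,g5,g6", ]
  expect_equal(nrow(blockA), 1)
  expect_gte(blockA$bp, 0.95)
  expect_gte(blockB$bp, 0.95)
  expect_gte(blockA$au, 0.9)
  # block-node support is stable across seeds
  sd2 <- cluster_presence_absence(mat, n_boot = 500, seed = 6)
  m <- merge(sd1$nodes, sd2$nodes, by = "members")
  blocks <- m$members %in% c("g1,g2,g3", "g4,g5,g6")
  expect_true(all(abs(m$bp.x[blocks] - m$bp.y[blocks]) <= 0.03))
  # duplicated genomes: their pair is supported at BP = AU = 1
  mat2 <- rbind(mat, g1b = mat["g1", ])
  sd3 <- cluster_presence_absence(mat2, n_boot = 200, seed = 2)
  pairnode <- sd3$nodes[sd3$nodes$members == "g1,g1b", ]
  expect_equal(pairnode$bp, 1)
  expect_equal(pairnode$au, 1)
  expect_error(cluster_presence_absence(mat[1:2, ]), ">= 3")
})

test_that("taxonomy affiliation reflects the top-ten hit composition", {
  set.seed(44)
  base <- rand_pep(220)
  # 5 close NCLDV refs, 5 slightly farther eukaryote refs, plus noise
  refs <- c(vapply(1:5, function(i) sortvir:::mutate_protein(base, 0.05), ""),
            vapply(1:5, function(i) sortvir:::mutate_protein(base, 0.12), ""),
            replicate(5, rand_pep(220)))
  names(refs) <- sprintf("ref%02d", 1:15)
  lin <- c(rep("NCLDV", 5), rep("Eukaryote", 5), rep("Prokaryote", 5))
  q <- c(q1 = base, q2 = rand_pep(180))
  ta <- taxonomy_affiliation(q, refs, lin)
  expect_equal(ta$per_protein$category[1], "Eukaryote+NCLDV")
  expect_equal(ta$per_protein$category[2], "no-hit")
  # top-ten all one lineage when only those exist
  ta2 <- taxonomy_affiliation(c(q1 = base), refs[1:5], lin[1:5])
  expect_equal(ta2$per_protein$category, "NCLDV")
})

test_that("rhodopsin typing reads motif and tuning site through the alignment", {
  set.seed(3)
  ref <- rand_pep(220)
  refaln <- c(ref1 = ref, ref2 = ref)
  q <- ref
  substr(q, 80, 80) <- "D"; substr(q, 84, 84) <- "T"; substr(q, 90, 90) <- "V"
  substr(q, 105, 105) <- "M"
  rm <- rhodopsin_motif(q, refaln, motif_columns = c(80, 84, 90),
                        tuning_column = 105)
  expect_equal(rm$motif, "DTV")
  expect_equal(rm$tuning_call, "green")
  # self-query returns the reference's own residues
  rs <- rhodopsin_motif(ref, refaln, c(80, 84, 90), 105)
  expect_equal(rs$motif, paste0(substr(ref, 80, 80), substr(ref, 84, 84),
                                substr(ref, 90, 90)))
  # non-methionine tuning residue: no spectral claim
  q2 <- q; substr(q2, 105, 105) <- "L"
  expect_equal(rhodopsin_motif(q2, refaln, c(80, 84, 90), 105)$tuning_call,
               "unknown")
  # unalignable query: no call
  expect_equal(rhodopsin_motif(rand_pep(200), refaln, c(80, 84, 90),
                               105)$tuning_call, "no-call")
})

test_that("the NJ tree is exact on additive distances and groups clades", {
  # disjoint mutation sites give additive p-distances on the true tree
  L <- 200
  base <- strrep("A", L)
  put <- function(s, sites) {
    for (p in sites) substr(s, p, p) <- "C"
    s
  }
  aln <- c(A = put(base, 1:2), B = put(base, 11:13),
           C = put(base, c(21:24, 31:32)), D = put(base, c(21:24, 41:45)))
  # d(A,B)=5, d(A,C)=2+4+2=8 ... internal edge = 4 sites
  tr <- marker_concat_tree(list(aln))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  bl <- setNames(tr$edge.length,
                 c(tr$tip.label, rep(NA, tr$Nnode))[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 2 / L, tolerance = 1e-9)
  expect_equal(unname(bl["B"]), 3 / L, tolerance = 1e-9)
  expect_equal(unname(bl["D"]), 5 / L, tolerance = 1e-9)

  # identical sequences: star tree with zero branch lengths
  st <- marker_concat_tree(list(c(A = base, B = base, C = base, D = base)))
  expect_true(all(abs(st$edge.length) < 1e-12))

  # two divergent families are monophyletic; missing markers tolerated
  set.seed(77)
  f1 <- rand_pep(120); f2 <- rand_pep(120)
  clade <- function(f, nm) setNames(vapply(1:3, function(i)
    sortvir:::mutate_protein(f, 0.05), ""), paste0(nm, 1:3))
  a1 <- c(clade(f1, "x"), clade(f2, "y"))
  a2 <- a1[-2] # one genome missing this marker
  tr2 <- marker_concat_tree(list(a1, a2))
  expect_true(ape::is.monophyletic(tr2, paste0("x", 1:3)))
  expect_true(ape::is.monophyletic(tr2, paste0("y", 1:3)))
})
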