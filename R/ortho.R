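# Comparative content analysis: orthogroup inference, presence-absence
# clustering with BP/AU multiscale bootstrap support, protein taxonomy
# affiliation, rhodopsin motif typing, and a marker-concatenation NJ tree.

# word -> protein inverted index for exact 4-aa seed prefiltering
protein_word_index <- function(peps, k = 4) {
  words <- lapply(peps, function(p) {
    n <- nchar(p)
    if (n < k) character(0) else unique(substring(p, 1:(n - k + 1), k:n))
  })
  data.frame(word = unlist(words, use.names = FALSE),
             target = rep(seq_along(peps), lengths(words)),
             stringsAsFactors = FALSE)
}

# best local BLOSUM62 alignment of each query peptide against one target;
# returns bits/pid/coverage fields. Vectorized over queries.
protein_align_batch <- function(qpeps, target) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(qpeps), Biostrings::AAString(target),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  p <- Biostrings::pattern(pa)
  matches <- Biostrings::nmatch(pa)
  alen <- nchar(as.character(p))
  raw <- Biostrings::score(pa)
  data.frame(q_start = Biostrings::start(p), q_end = Biostrings::end(p),
             matches = matches, aligned_len = alen,
             pct_identity = 100 * matches / pmax(alen, 1),
             raw_score = raw, bit_score = bit_from_raw(raw, "translated"))
}

# all-vs-all protein hits above a bit floor, seed-prefiltered
protein_pair_hits <- function(peps, bit_floor = 50, cov_min = 0.5,
                              min_shared = 2) {
  idx <- protein_word_index(peps)
  m <- merge(idx, idx, by = "word")
  m <- m[m$target.x < m$target.y, c("target.x", "target.y")]
  key <- paste(m$target.x, m$target.y)
  cnt <- table(key)
  keep <- names(cnt)[cnt >= min_shared]
  if (!length(keep)) {
    return(data.frame(a = integer(), b = integer(), bit_score = numeric(),
                      coverage = numeric()))
  }
  ab <- do.call(rbind, strsplit(keep, " "))
  pairs <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]))
  out <- lapply(split(pairs, pairs$b), function(g) {
    al <- protein_align_batch(peps[g$a], peps[[g$b[1]]])
    shorter <- pmin(nchar(peps[g$a]), nchar(peps[[g$b[1]]]))
    data.frame(a = g$a, b = g$b, bit_score = al$bit_score,
               coverage = al$aligned_len / shorter)
  })
  out <- do.call(rbind, out)
  out[out$bit_score >= bit_floor & out$coverage >= cov_min, , drop = FALSE]
}

#' Infer orthogroups across proteomes
#'
#' All-vs-all protein similarity (exact 4-aa word prefilter followed by
#' local BLOSUM62 alignment); edges kept at bit score >= `bit_min` with
#' alignment covering >= `cov_min` of the shorter protein; orthogroups
#' are connected components of the edge graph. Proteins in no multi-genome
#' component are the genome's private proteins.
#'
#' @param proteomes named list of named peptide character vectors (one
#'   element per genome).
#' @param bit_min edge bit-score threshold (default 50).
#' @param cov_min shorter-sequence coverage threshold (default 0.5).
#' @return An `ortho_matrix`: list with `presence` (genomes x orthogroups
#'   binary matrix), `groups` (list of protein ids per orthogroup),
#'   `private` (named count of genome-private proteins), `membership`
#'   (data frame protein, genome, orthogroup).
#' @export
infer_orthogroups <- function(proteomes, bit_min = 50, cov_min = 0.5) {
  if (length(proteomes) < 2) stop("need >= 2 proteomes")
  empty <- vapply(proteomes, length, 0L) == 0L
  if (any(empty)) warning("empty proteome(s): ",
                          paste(names(proteomes)[empty], collapse = ", "))
  genome <- rep(names(proteomes), vapply(proteomes, length, 0L))
  peps <- unlist(proteomes, use.names = FALSE)
  pid <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (is.null(pid)) pid <- sprintf("p%05d", seq_along(peps))
  pid <- paste(genome, pid, sep = "|")
  edges <- protein_pair_hits(peps, bit_floor = bit_min, cov_min = cov_min)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pid[edges$a], to = pid[edges$b]),
    directed = FALSE, vertices = data.frame(name = pid))
  comp <- igraph::components(g)
  og <- comp$membership[pid]
  membership <- data.frame(protein = pid, genome = genome,
                           orthogroup = sprintf("OG%04d", og),
                           stringsAsFactors = FALSE)
  sizes <- table(membership$orthogroup)
  genomes_per_og <- tapply(membership$genome, membership$orthogroup,
                           function(x) length(unique(x)))
  shared <- names(genomes_per_og)[genomes_per_og >= 2]
  presence <- table(membership$genome, membership$orthogroup)
  presence <- (presence[, shared, drop = FALSE] > 0) * 1L
  presence <- presence[names(proteomes)[!empty], , drop = FALSE]
  if (any(empty)) {
    zero <- matrix(0L, sum(empty), ncol(presence),
                   dimnames = list(names(proteomes)[empty], colnames(presence)))
    presence <- rbind(presence, zero)[names(proteomes), , drop = FALSE]
  }
  priv <- tapply(!membership$orthogroup %in% shared, membership$genome, sum)
  private <- stats::setNames(rep(0L, length(proteomes)), names(proteomes))
  private[names(priv)] <- as.integer(priv)
  structure(list(presence = unclass(as.matrix(presence)),
                 groups = split(membership$protein, membership$orthogroup),
                 private = private, membership = membership),
            class = "ortho_matrix")
}

# leaf bipartitions of an hclust tree as a list of sorted label vectors
hclust_clades <- function(hc, labels) {
  n <- length(labels)
  sets <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    kids <- hc$merge[m, ]
    grab <- function(kid) if (kid < 0) labels[-kid] else sets[[kid]]
    sets[[m]] <- sort(c(grab(kids[1]), grab(kids[2])))
  }
  sets
}

jaccard_hclust <- function(mat, method = "average") {
  d <- stats::dist(mat, method = "binary")
  stats::hclust(d, method = method)
}

#' Cluster genomes on orthogroup presence-absence with BP and AU support
#'
#' Average-linkage hierarchical clustering on binary (Jaccard) distance.
#' Node support comes from multiscale bootstrap over orthogroup columns:
#' BP is the fraction of same-size resamples containing the node's leaf
#' set; AU (approximately unbiased) p-values are obtained by resampling
#' at scales `r` in 0.5-1.4 and fitting the signed-distance regression
#' `z(r) = d * sqrt(r) + c / sqrt(r)`, with `AU = 1 - pnorm(d - c)`.
#'
#' @param mat binary genomes x orthogroups matrix (e.g.
#'   `infer_orthogroups()$presence`).
#' @param n_boot bootstrap replicates per scale (default 500).
#' @param seed RNG seed.
#' @param scales multiscale resampling ratios.
#' @return A `supported_dendrogram`: list with `hclust`, `nodes` (data
#'   frame `node`, `members`, `bp`, `au`), and `newick` (BP as node
#'   labels).
#' @export
cluster_presence_absence <- function(mat, n_boot = 500, seed = 1,
                                     scales = seq(0.5, 1.4, by = 0.1)) {
  if (nrow(mat) < 3) stop("need >= 3 genomes")
  if (all(mat == mat[1, 1])) warning("constant matrix: degenerate tree")
  set.seed(seed)
  labels <- rownames(mat)
  hc <- jaccard_hclust(mat)
  obs <- hclust_clades(hc, labels)
  p <- ncol(mat)
  counts <- matrix(0, length(obs), length(scales))
  for (si in seq_along(scales)) {
    ps <- max(2L, round(p * scales[si]))
    for (b in seq_len(n_boot)) {
      bm <- mat[, sample.int(p, ps, replace = TRUE), drop = FALSE]
      bhc <- jaccard_hclust(bm)
      bset <- hclust_clades(bhc, labels)
      bkeys <- vapply(bset, paste, "", collapse = "\r")
      okeys <- vapply(obs, paste, "", collapse = "\r")
      counts[, si] <- counts[, si] + (okeys %in% bkeys)
    }
  }
  bp_mat <- counts / n_boot
  one_idx <- which.min(abs(scales - 1))
  au <- vapply(seq_along(obs), function(i) {
    # the signed-distance regression needs scales where the bipartition is
    # neither always present nor always absent; with fewer than three such
    # scales the fit is degenerate and the saturated limit is reported
    inf <- which(bp_mat[i, ] > 0 & bp_mat[i, ] < 1)
    if (length(inf) < 5) return(as.numeric(bp_mat[i, one_idx] >= 0.5))
    bpv <- pmin(pmax(bp_mat[i, inf], 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
    z <- stats::qnorm(1 - bpv)
    sc <- scales[inf]
    X <- cbind(sqrt(sc), 1 / sqrt(sc))
    w <- n_boot * stats::dnorm(z)^2 / (bpv * (1 - bpv))
    fit <- stats::lm.wfit(X, z, w)
    dd <- fit$coefficients[1]; cc <- fit$coefficients[2]
    unname(1 - stats::pnorm(dd - cc))
  }, 0)
  nodes <- data.frame(node = seq_along(obs),
                      members = vapply(obs, paste, "", collapse = ","),
                      bp = bp_mat[, one_idx], au = au,
                      stringsAsFactors = FALSE)
  phy <- ape::as.phylo(hc)
  phy$node.label <- node_support_labels(hc, phy, nodes$bp)
  structure(list(hclust = hc, nodes = nodes,
                 newick = ape::write.tree(phy)),
            class = "supported_dendrogram")
}

node_support_labels <- function(hc, phy, bp) {
  obs <- hclust_clades(hc, hc$labels)
  okeys <- vapply(obs, paste, "", collapse = "\r")
  pp <- ape::prop.part(phy)
  vapply(seq_along(pp), function(ni) {
    key <- paste(sort(phy$tip.label[pp[[ni]]]), collapse = "\r")
    hit <- match(key, okeys)
    if (!is.na(hit)) sprintf("%.2f", bp[hit]) else ""
  }, "")
}

#' Taxonomy affiliation from top-ten protein hits
#'
#' Each query protein is searched against a lineage-labeled reference;
#' the top ten hits with e-value below `evalue_max` are collected and the
#' affiliation is the set of lineages they represent (`no-hit` when
#' nothing passes). Archaea and bacteria are conventionally pooled as
#' `Prokaryote` in the reference labels.
#'
#' @param proteins named character vector of query peptides.
#' @param reference named character vector of reference peptides.
#' @param ref_lineage character vector of lineage labels parallel to
#'   `reference` (e.g. `"NCLDV"`, `"Eukaryote"`, `"Prokaryote"`).
#' @param evalue_max hit threshold (default 1e-5).
#' @param top_n hits considered (default 10).
#' @return list with `per_protein` (data frame `protein`, `category`) and
#'   `fractions` (named fractions per category).
#' @export
taxonomy_affiliation <- function(proteins, reference, ref_lineage,
                                 evalue_max = 1e-5, top_n = 10) {
  stopifnot(length(reference) == length(ref_lineage))
  db_size <- sum(nchar(reference))
  idx <- protein_word_index(reference)
  cats <- vapply(seq_along(proteins), function(i) {
    q <- proteins[[i]]
    qw <- protein_word_index(list(q))
    cand <- unique(idx$target[idx$word %in% qw$word])
    if (!length(cand)) return("no-hit")
    hits <- do.call(rbind, lapply(cand, function(tj) {
      al <- protein_align_batch(q, reference[[tj]])
      al$target <- tj
      al
    }))
    hits$evalue <- nchar(q) * db_size * 2^(-hits$bit_score)
    hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
    if (!nrow(hits)) return("no-hit")
    hits <- hits[order(-hits$bit_score), , drop = FALSE]
    top <- utils::head(hits, top_n)
    paste(sort(unique(ref_lineage[top$target])), collapse = "+")
  }, "")
  per <- data.frame(protein = names(proteins), category = cats,
                    stringsAsFactors = FALSE)
  fr <- table(per$category) / nrow(per)
  list(per_protein = per, fractions = stats::setNames(as.numeric(fr), names(fr)))
}

#' Type a rhodopsin by its functional motif and spectral-tuning residue
#'
#' The query is locally aligned to the (ungapped) reference sequence of a
#' rhodopsin alignment; the residues at the three motif columns and the
#' tuning column are read off through the alignment. The tuning call is
#' `green` if and only if the tuning-site residue is methionine -- the
#' only spectral rule anchored here; other residues are reported without
#' a spectral claim.
#'
#' @param query query peptide.
#' @param ref_alignment named character vector of aligned reference
#'   rhodopsins; the first sequence anchors the column map.
#' @param motif_columns three alignment-column indices of the functional
#'   motif.
#' @param tuning_column alignment-column index of the spectral tuning
#'   site (site 105 in the standard numbering).
#' @param min_bits no-call floor on the query/reference alignment score
#'   (default 50).
#' @return list `motif` (3-letter string), `tuning_residue`,
#'   `tuning_call` (`green`/`unknown`), `aligned` (logical).
#' @export
rhodopsin_motif <- function(query, ref_alignment, motif_columns,
                            tuning_column, min_bits = 50) {
  ref_aln <- ref_alignment[[1]]
  ref_chars <- strsplit(ref_aln, "")[[1]]
  keep <- ref_chars != "-"
  ref_seq <- paste(ref_chars[keep], collapse = "")
  col2pos <- cumsum(keep) # alignment column -> ungapped ref position
  pa <- Biostrings::pairwiseAlignment(query, ref_seq, type = "local",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1)
  bits <- bit_from_raw(Biostrings::score(pa), "translated")
  no_call <- list(motif = NA_character_, tuning_residue = NA_character_,
                  tuning_call = "no-call", aligned = FALSE)
  if (bits < min_bits) return(no_call)
  qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  s_pos <- Biostrings::start(Biostrings::subject(pa)) - 1L + cumsum(sa != "-")
  residue_at <- function(col) {
    if (!keep[col]) return(NA_character_)
    tp <- col2pos[col]
    i <- which(s_pos == tp & sa != "-")
    if (!length(i)) return(NA_character_)
    r <- qa[i[1]]
    if (r == "-") NA_character_ else r
  }
  motif <- vapply(motif_columns, residue_at, "")
  tun <- residue_at(tuning_column)
  if (anyNA(motif)) return(no_call)
  list(motif = paste(motif, collapse = ""),
       tuning_residue = tun,
       tuning_call = if (identical(tun, "M")) "green" else "unknown",
       aligned = TRUE)
}

#' Neighbor-joining tree from concatenated marker alignments
#'
#' Markers are concatenated per genome (missing markers contribute gaps);
#' p-distances use pairwise deletion; the tree is canonical
#' neighbor-joining via [ape::nj()].
#'
#' @param marker_alignments list of alignments; each is a named character
#'   vector (names = genome labels, equal within-alignment lengths).
#' @return an [ape] `phylo` tree.
#' @export
marker_concat_tree <- function(marker_alignments) {
  genomes <- sort(unique(unlist(lapply(marker_alignments, names))))
  if (length(genomes) < 4) stop("need >= 4 genomes")
  concat <- vapply(genomes, function(g) {
    paste(vapply(marker_alignments, function(aln) {
      if (g %in% names(aln)) aln[[g]] else strrep("-", nchar(aln[[1]]))
    }, ""), collapse = "")
  }, "")
  m <- do.call(rbind, strsplit(concat, ""))
  rownames(m) <- genomes
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
  }
  ape::nj(stats::as.dist(d))
}
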