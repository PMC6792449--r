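# Post-binning genome operations: exact-overlap secondary assembly,
# assembly statistics, fragment-based ANI, and 99%-identity read mapping
# with coverage/SNV pileup.

# Longest suffix(A) == prefix(B) overlap strictly greater than
# min_overlap, found by anchoring A's terminal `anchor` bases inside B.
exact_overlap_len <- function(a, b, min_overlap = 100, anchor = 50) {
  na <- nchar(a); nb <- nchar(b)
  if (na <= anchor || nb <= min_overlap) return(0L)
  tail_a <- substr(a, na - anchor + 1L, na)
  hits <- gregexpr(tail_a, substr(b, 1, min(nb, na)), fixed = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  lens <- as.integer(hits) + anchor - 1L
  lens <- sort(lens[lens > min_overlap & lens <= min(na, nb)], decreasing = TRUE)
  for (L in lens) {
    if (substr(a, na - L + 1L, na) == substr(b, 1L, L)) return(L)
  }
  0L
}

#' Merge contigs sharing exact terminal overlaps
#'
#' Suffix-prefix overlaps longer than `min_overlap` bp at 100% identity
#' are merged, both orientations considered, iterating to a fixpoint. A
#' contig end with two distinct qualifying partners is left unmerged and
#' logged (never create chimeras silently). Deterministic under input
#' order: candidates are examined in id order.
#'
#' @param contigs a [nuc_set()].
#' @param min_overlap overlaps must exceed this length (default 100, i.e.
#'   "more than 100 bp").
#' @return list with `contigs` (merged [nuc_set()], merged ids joined by
#'   `+`), `merges` (data frame `left`, `right`, `overlap`, `orientation`)
#'   and `ambiguous` (character vector of contig ends left alone).
#' @export
merge_exact_overlaps <- function(contigs, min_overlap = 100) {
  seqs <- stats::setNames(contigs$seq, contigs$id)
  seqs <- seqs[order(names(seqs))]
  merges <- list(); ambiguous <- character(0)
  repeat {
    ids <- names(seqs)
    n <- length(ids)
    if (n < 2) break
    cand <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      L <- exact_overlap_len(seqs[i], seqs[j], min_overlap)
      if (L > 0) cand[[length(cand) + 1]] <- list(i = i, j = j, L = L, orient = "ff")
      Lr <- exact_overlap_len(seqs[i], revcomp(seqs[j]), min_overlap)
      if (Lr > 0) cand[[length(cand) + 1]] <- list(i = i, j = j, L = Lr, orient = "fr")
      Lq <- exact_overlap_len(revcomp(seqs[i]), seqs[j], min_overlap)
      if (Lq > 0) cand[[length(cand) + 1]] <- list(i = i, j = j, L = Lq, orient = "rf")
    }
    if (!length(cand)) break
    tails <- vapply(cand, function(x) x$i, 0L)
    heads <- vapply(cand, function(x) x$j, 0L)
    ok <- !(tails %in% tails[duplicated(tails)]) &
      !(heads %in% heads[duplicated(heads)])
    if (!any(ok)) {
      amb <- unique(c(ids[tails[!ok]], ids[heads[!ok]]))
      ambiguous <- unique(c(ambiguous, amb))
      break
    }
    x <- cand[ok][[1]]
    left <- if (x$orient == "rf") revcomp(seqs[x$i]) else seqs[x$i]
    right <- if (x$orient == "fr") revcomp(seqs[x$j]) else seqs[x$j]
    merged <- paste0(left, substr(right, x$L + 1L, nchar(right)))
    merges[[length(merges) + 1]] <- data.frame(
      left = ids[x$i], right = ids[x$j], overlap = x$L,
      orientation = x$orient, stringsAsFactors = FALSE)
    new_id <- paste(ids[x$i], ids[x$j], sep = "+")
    seqs <- seqs[-c(x$i, x$j)]
    seqs[new_id] <- merged
    seqs <- seqs[order(names(seqs))]
  }
  list(contigs = nuc_set(names(seqs), unname(seqs)),
       merges = if (length(merges)) do.call(rbind, merges) else
         data.frame(left = character(), right = character(),
                    overlap = integer(), orientation = character()),
       ambiguous = ambiguous)
}

#' Assembly statistics
#'
#' N50 is the length of the contig at which the descending cumulative
#' length first reaches half the total.
#'
#' @param contigs a [nuc_set()] or numeric vector of contig lengths.
#' @return list `total_bp`, `n_contigs`, `largest`, `n50`, `gc` (NA when
#'   only lengths are given).
#' @export
assembly_stats <- function(contigs) {
  if (inherits(contigs, "nuc_set")) {
    lens <- nchar(contigs$seq)
    gc <- stats::weighted.mean(gc_content(contigs$seq), lens)
  } else {
    lens <- as.numeric(contigs)
    gc <- NA_real_
  }
  if (!length(lens)) stop("empty assembly")
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  list(total_bp = total, n_contigs = length(lens), largest = lens[1],
       n50 = n50, gc = gc)
}

# first match position of any seed k-mer of `frag` in the target k-mer
# index; returns candidate target start positions for the whole fragment.
seed_candidates <- function(frag, index_kmers, k, offsets) {
  offsets <- offsets[offsets + k - 1L <= nchar(frag)]
  seeds <- substring(frag, offsets, offsets + k - 1L)
  pos <- match(seeds, index_kmers)
  ok <- !is.na(pos)
  unique(pos[ok] - offsets[ok] + 1L)
}

#' Fragment-based average nucleotide identity
#'
#' `a` is cut into `fragment`-bp pieces, each locally aligned to `b`
#' (seed-guided); fragments reaching `min_identity` percent identity over
#' at least `min_cov` of their length contribute, and ANI is the mean
#' identity of contributing fragments. Both directions are reported with
#' their mean.
#'
#' @param a,b assemblies ([nuc_set()]s or character vectors of contig
#'   sequences).
#' @param fragment fragment size in bp (default 1000).
#' @param min_identity qualifying identity floor in percent (default 70).
#' @param min_cov qualifying fraction of fragment length aligned (default
#'   0.5).
#' @return list `ani` (mean of both directions), `ab`, `ba`,
#'   `n_fragments_ab`, `n_fragments_ba`; values are NA when no fragment
#'   qualifies.
#' @export
compute_ani <- function(a, b, fragment = 1000, min_identity = 70,
                        min_cov = 0.5) {
  seq_of <- function(x) if (inherits(x, "nuc_set")) x$seq else as.character(x)
  ab <- ani_one_way(seq_of(a), seq_of(b), fragment, min_identity, min_cov)
  ba <- ani_one_way(seq_of(b), seq_of(a), fragment, min_identity, min_cov)
  ani <- mean(c(ab$ani, ba$ani), na.rm = TRUE)
  list(ani = if (is.nan(ani)) NA_real_ else ani, ab = ab$ani, ba = ba$ani,
       n_fragments_ab = ab$n, n_fragments_ba = ba$n)
}

ani_one_way <- function(aseqs, bseqs, fragment, min_identity, min_cov,
                        seed_k = 15L) {
  if (!length(aseqs) || !length(bseqs)) return(list(ani = NA_real_, n = 0L))
  bcat <- paste(bseqs, collapse = strrep("N", seed_k))
  bidx <- substring(bcat, seq_len(nchar(bcat) - seed_k + 1L),
                    seq_len(nchar(bcat) - seed_k + 1L) + seed_k - 1L)
  ids <- numeric(0)
  for (aseq in aseqs) {
    n <- nchar(aseq)
    starts <- seq(1L, n, by = fragment)
    starts <- starts[starts + fragment - 1L <= n | starts == 1L]
    for (s in starts) {
      frag <- substr(aseq, s, min(n, s + fragment - 1L))
      if (nchar(frag) < fragment * min_cov) next
      offs <- seq(1L, max(1L, nchar(frag) - seed_k + 1L), by = 100L)
      cands <- seed_candidates(frag, bidx, seed_k, offs)
      rc <- FALSE
      if (!length(cands)) {
        cands <- seed_candidates(revcomp(frag), bidx, seed_k, offs)
        rc <- TRUE
      }
      if (!length(cands)) next
      best <- NULL
      for (p in utils::head(cands, 4)) {
        w0 <- max(1L, p - 200L)
        w1 <- min(nchar(bcat), p + nchar(frag) + 200L)
        h <- local_align(if (rc) revcomp(frag) else frag,
                         substr(bcat, w0, w1), "nucleotide",
                         both_strands = FALSE)
        if (nrow(h) && (is.null(best) || h$bit_score > best$bit_score)) best <- h
      }
      if (is.null(best)) next
      if (best$pct_identity >= min_identity &&
          best$aligned_len >= min_cov * nchar(frag)) {
        ids <- c(ids, best$pct_identity)
      }
    }
  }
  list(ani = if (length(ids)) mean(ids) else NA_real_, n = length(ids))
}

#' Map reads to an assembly at a strict identity gate
#'
#' Seed-and-extend nucleotide mapping (exact 31-mer seeds at three read
#' offsets, both strands, ungapped verification): alignments below
#' `min_identity` percent identity are discarded, and a read mapping
#' equally well to multiple sites is assigned to the first best site in
#' scan order. The pileup yields per-contig depth, breadth, mean depth,
#' and SNV density (positions with alternate-allele fraction >=
#' `snv_alt_frac` at depth >= `snv_min_depth`, per kb).
#'
#' @param reads a [nuc_set()].
#' @param assembly a [nuc_set()] of contigs.
#' @param min_identity percent-identity gate (default 99).
#' @param snv_min_depth,snv_alt_frac SNV-calling thresholds (defaults 5
#'   and 0.2).
#' @return list with `depth` (named list of per-base integer vectors),
#'   `breadth`, `mean_depth`, `n_mapped`, `n_reads`, `snv` (data frame
#'   `contig_id`, `pos`, `depth`, `alt`), `snv_per_kb`, and `hits`
#'   (per-read placements).
#' @export
map_reads <- function(reads, assembly, min_identity = 99, snv_min_depth = 5,
                      snv_alt_frac = 0.2) {
  k <- 31L
  ctg_len <- nchar(assembly$seq)
  sep <- strrep("N", k)
  cat_ref <- paste(assembly$seq, collapse = sep)
  ctg_off <- cumsum(c(0L, utils::head(ctg_len + k, -1L)))
  ref_kmers <- substring(cat_ref, seq_len(nchar(cat_ref) - k + 1L),
                         seq_len(nchar(cat_ref) - k + 1L) + k - 1L)
  n_reads <- nrow(reads)
  n_ref <- nchar(cat_ref)
  L <- nchar(reads$seq)
  rc_seq <- revcomp(reads$seq)
  # three seed offsets per read and strand, one hash lookup for the lot
  cand <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") reads$seq else rc_seq
    for (which_off in 1:3) {
      off <- switch(which_off, rep(1L, n_reads),
                    pmax(1L, (L - k) %/% 2L + 1L), pmax(1L, L - k + 1L))
      ok <- off + k - 1L <= L
      seeds <- substring(q[ok], off[ok], off[ok] + k - 1L)
      pos <- match(seeds, ref_kmers)
      hit <- !is.na(pos)
      cand[[length(cand) + 1]] <- data.frame(
        read = which(ok)[hit], strand = rep(strand, sum(hit)),
        start = pos[hit] - off[ok][hit] + 1L, stringsAsFactors = FALSE)
    }
  }
  cand <- unique(do.call(rbind, cand))
  cand <- cand[cand$start >= 1L & cand$start + L[cand$read] - 1L <= n_ref, ,
               drop = FALSE]
  # scan order: forward strand first, then position
  cand <- cand[order(cand$read, cand$strand, cand$start), , drop = FALSE]
  pos_out <- integer(n_reads); strand_out <- character(n_reads)
  mm_list <- vector("list", n_reads)
  if (nrow(cand)) {
    q <- ifelse(cand$strand == "+", reads$seq[cand$read], rc_seq[cand$read])
    refsub <- substr(rep(cat_ref, nrow(cand)), cand$start,
                     cand$start + L[cand$read] - 1L)
    mms <- cpp_mismatch_offsets(q, refsub)
    n_mm <- lengths(mms)
    max_mm <- floor(L[cand$read] * (1 - min_identity / 100))
    pass <- n_mm <= max_mm
    for (i in which(pass)) {
      rd <- cand$read[i]
      if (pos_out[rd] == 0L || n_mm[i] < length(mm_list[[rd]])) {
        pos_out[rd] <- cand$start[i]
        strand_out[rd] <- cand$strand[i]
        mm_list[[rd]] <- cand$start[i] + mms[[i]] - 1L
      }
    }
  }
  mapped <- which(pos_out > 0L)
  depth_cat <- integer(nchar(cat_ref))
  if (length(mapped)) {
    lens <- nchar(reads$seq[mapped])
    dd <- integer(nchar(cat_ref) + 1L)
    starts <- pos_out[mapped]
    ends <- pmin(starts + lens - 1L, nchar(cat_ref))
    add <- tabulate(starts, nbins = length(dd))
    sub <- tabulate(ends + 1L, nbins = length(dd))
    depth_cat <- cumsum(add - sub)[seq_len(nchar(cat_ref))]
  }
  mmpos <- unlist(mm_list[mapped])
  mm_tab <- if (length(mmpos)) table(mmpos) else table(integer(0))
  snv_pos <- as.integer(names(mm_tab))
  snv_alt <- as.integer(mm_tab)
  ok <- snv_pos > 0 & depth_cat[pmax(snv_pos, 1L)] >= snv_min_depth &
    snv_alt / pmax(depth_cat[pmax(snv_pos, 1L)], 1L) >= snv_alt_frac
  snv_pos <- snv_pos[ok]; snv_alt <- snv_alt[ok]
  to_ctg <- function(p) findInterval(p, ctg_off + 1L)
  depth <- lapply(seq_along(ctg_len), function(ci)
    depth_cat[(ctg_off[ci] + 1L):(ctg_off[ci] + ctg_len[ci])])
  names(depth) <- assembly$id
  total_len <- sum(ctg_len)
  covered <- sum(vapply(depth, function(d) sum(d >= 1L), 0L))
  snv_ctg <- to_ctg(snv_pos)
  snv <- data.frame(contig_id = assembly$id[snv_ctg],
                    pos = snv_pos - ctg_off[snv_ctg],
                    depth = depth_cat[snv_pos], alt = snv_alt,
                    stringsAsFactors = FALSE)
  hits <- data.frame(read_id = reads$id[mapped],
                     contig_id = assembly$id[to_ctg(pos_out[mapped])],
                     pos = pos_out[mapped] - ctg_off[to_ctg(pos_out[mapped])],
                     strand = strand_out[mapped],
                     n_mismatch = vapply(mm_list[mapped], length, 0L),
                     stringsAsFactors = FALSE)
  list(depth = depth,
       breadth = covered / total_len,
       mean_depth = sum(as.numeric(depth_cat)) / total_len,
       n_mapped = length(mapped), n_reads = n_reads,
       snv = snv, snv_per_kb = nrow(snv) / (total_len / 1000),
       hits = hits)
}
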