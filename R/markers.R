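# Ancestral-marker screen: PSSM construction from protein alignments,
# six-frame ORF prediction, profile scanning with an empirical null, rRNA
# detection, and the viral/cellular bin verdict.

#' Build a position-specific scoring matrix from a protein alignment
#'
#' Columns with more than 50% gaps are dropped; log-odds are
#' `log2(((c_ia + alpha * b_a) / (n_i + alpha)) / b_a)` with pseudocount
#' weight `alpha` and background `b` (default uniform over the 20
#' residues). Scores are therefore in bits.
#'
#' @param alignment named character vector of aligned protein sequences
#'   (equal lengths, `-` for gaps).
#' @param name profile label.
#' @param alpha pseudocount weight (default 1).
#' @param background named numeric vector of background frequencies over
#'   the 20 residues (default uniform).
#' @return A `marker_profile`: list with `name`, `matrix` (columns x 20,
#'   bits), `length`, `background`, `alpha`.
#' @export
build_profile <- function(alignment, name = "profile", alpha = 1,
                          background = NULL) {
  if (length(alignment) < 2) stop("need >= 2 aligned sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("ragged alignment")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_RESIDUES)
  }
  m <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(m == "-" | m == ".")
  m <- m[, gap_frac <= 0.5, drop = FALSE]
  L <- ncol(m)
  mat <- matrix(0, L, 20, dimnames = list(NULL, AA_RESIDUES))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% AA_RESIDUES]
    cnt <- table(factor(col, levels = AA_RESIDUES))
    n <- sum(cnt)
    p <- (as.numeric(cnt) + alpha * background) / (n + alpha)
    mat[j, ] <- log2(p / background)
  }
  structure(list(name = name, matrix = mat, length = L,
                 background = background, alpha = alpha),
            class = "marker_profile")
}

#' Predict ORFs in all six frames
#'
#' Maximal stop-to-stop stretches of at least `min_aa` residues; a start
#' codon is not required (marker detection tolerates N-terminal
#' overhang). Coordinates are 1-based nucleotide positions on the forward
#' strand; reverse-strand ORFs carry strand `-`.
#'
#' @param contig a single nucleotide sequence, or a [nuc_set()].
#' @param min_aa minimum ORF length in residues (default 60).
#' @param contig_id label used when `contig` is a bare sequence.
#' @return data frame `contig_id`, `start`, `end`, `strand`, `frame`
#'   (0-5), `peptide`.
#' @export
predict_orfs <- function(contig, min_aa = 60, contig_id = "contig") {
  if (inherits(contig, "nuc_set")) {
    out <- lapply(seq_len(nrow(contig)), function(i)
      predict_orfs(contig$seq[i], min_aa, contig$id[i]))
    return(do.call(rbind, out))
  }
  n <- nchar(contig)
  frames <- six_frame_translate(contig)
  res <- list()
  for (f in 0:5) {
    pep <- frames[f + 1]
    if (!nchar(pep)) next
    segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
    pos <- 1L
    off <- f %% 3L
    for (s in segs) {
      la <- nchar(s)
      if (la >= min_aa) {
        # aa interval [pos, pos+la-1] in this frame's translation
        nt1 <- off + 3L * (pos - 1L) + 1L
        nt2 <- off + 3L * (pos + la - 1L)
        if (f < 3) {
          res[[length(res) + 1]] <- data.frame(
            contig_id = contig_id, start = nt1, end = nt2, strand = "+",
            frame = f, peptide = s, stringsAsFactors = FALSE)
        } else {
          res[[length(res) + 1]] <- data.frame(
            contig_id = contig_id, start = n - nt2 + 1L, end = n - nt1 + 1L,
            strand = "-", frame = f, peptide = s, stringsAsFactors = FALSE)
        }
      }
      pos <- pos + la + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

encode_peptide <- function(pep) {
  match(strsplit(pep, "")[[1]], AA_RESIDUES) - 1L
}

pssm_score <- function(code, mat, band = 6, gap_open = 4, gap_ext = 1) {
  code[is.na(code)] <- -1L
  ug <- cpp_pssm_ungapped(code, mat)
  score <- ug[1]
  if (score > 10) {
    d0 <- as.integer(ug[2] - ug[4]) # query_start - profile_start
    bg <- cpp_pssm_banded(code, mat, d0, band, gap_open, gap_ext)
    score <- max(score, bg)
  }
  c(score, ug[2], ug[3])
}

# Empirical null per profile: scores of shuffled peptides drawn to match
# the ORF length distribution and pooled residue composition, summarized
# by a moment-fit Gumbel.
profile_null <- function(profiles, orfs, n_null = 200) {
  comp <- table(factor(strsplit(paste(orfs$peptide, collapse = ""), "")[[1]],
                       levels = AA_RESIDUES))
  comp <- as.numeric(comp) + 1
  lens <- sample(nchar(orfs$peptide), n_null, replace = TRUE)
  nulls <- lapply(lens, function(L)
    sample.int(20L, L, replace = TRUE, prob = comp) - 1L)
  lapply(profiles, function(pf) {
    sc <- vapply(nulls, function(cd) pssm_score(cd, pf$matrix)[1], 0)
    beta <- stats::sd(sc) * sqrt(6) / pi
    mu <- mean(sc) - 0.57722 * beta
    c(mu = mu, beta = max(beta, 1e-6))
  })
}

gumbel_p <- function(x, mu, beta) {
  -expm1(-exp(-(x - mu) / beta))
}

#' Scan ORFs against marker profiles
#'
#' Each ORF is scored against each profile by a best-ungapped-segment
#' anchor refined with a banded gapped alignment; significance comes from
#' an empirical null (Gumbel fitted to scores of shuffled peptides with
#' the same length and composition distribution). A hit requires
#' `p_null < p_max` and at least `min_bits` bits; the best marker per ORF
#' is retained.
#'
#' @param orfs data frame from [predict_orfs()].
#' @param profiles list of `marker_profile`s (or a named list of
#'   alignments, which are built on the fly).
#' @param p_max null-exceedance threshold (default 1e-4).
#' @param min_bits score floor in bits (default 25).
#' @param n_null shuffled peptides per null fit (default 200).
#' @return data frame `contig_id`, `orf_start`, `orf_end`, `strand`,
#'   `frame`, `marker`, `bits`, `p_null`.
#' @export
scan_markers <- function(orfs, profiles, p_max = 1e-4, min_bits = 25,
                         n_null = 200) {
  if (!length(profiles)) stop("no profiles")
  if (!inherits(profiles[[1]], "marker_profile")) {
    profiles <- lapply(names(profiles), function(nm)
      build_profile(profiles[[nm]], name = nm))
    names(profiles) <- vapply(profiles, `[[`, "", "name")
  }
  empty <- data.frame(contig_id = character(), orf_start = integer(),
                      orf_end = integer(), strand = character(),
                      frame = integer(), marker = character(), bits = numeric(),
                      p_null = numeric(), stringsAsFactors = FALSE)
  if (!nrow(orfs)) return(empty)
  nulls <- profile_null(profiles, orfs, n_null)
  codes <- lapply(orfs$peptide, encode_peptide)
  hits <- vector("list", nrow(orfs))
  pnames <- names(profiles)
  for (i in seq_len(nrow(orfs))) {
    best <- NULL
    for (k in seq_along(profiles)) {
      sc <- pssm_score(codes[[i]], profiles[[k]]$matrix)
      if (sc[1] < min_bits) next
      p <- gumbel_p(sc[1], nulls[[k]]["mu"], nulls[[k]]["beta"])
      if (p >= p_max) next
      if (is.null(best) || sc[1] > best$bits) {
        best <- list(marker = pnames[k], bits = sc[1], p = p)
      }
    }
    if (!is.null(best)) {
      hits[[i]] <- data.frame(contig_id = orfs$contig_id[i],
                              orf_start = orfs$start[i], orf_end = orfs$end[i],
                              strand = orfs$strand[i], frame = orfs$frame[i],
                              marker = best$marker, bits = best$bits,
                              p_null = best$p, stringsAsFactors = FALSE)
    }
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Detect rRNA genes on contigs
#'
#' Nucleotide local alignment against an SSU/LSU reference set with an
#' exact 15-mer seed prefilter; hits with at least `min_identity` percent
#' identity over at least `min_len` aligned bases are reported.
#'
#' @param contigs a [nuc_set()].
#' @param rrna_refs a [nuc_set()] of reference rRNA genes.
#' @param min_identity percent-identity floor (default 75).
#' @param min_len minimum aligned length in bp (default 300).
#' @return data frame `contig_id`, `start`, `end`, `strand`, `ref_id`,
#'   `pct_identity`, `aligned_len`.
#' @export
detect_rrna <- function(contigs, rrna_refs, min_identity = 75, min_len = 300) {
  ref_codes <- sort(unique(unlist(lapply(rrna_refs$seq, cpp_kmer_codes, k = 15L))))
  max_ref <- max(nchar(rrna_refs$seq))
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    cs <- contigs$seq[i]
    n <- nchar(cs)
    # localize candidate loci by shared-15-mer counts in 2 kb windows so
    # only a small region of a long contig is ever aligned
    wstart <- seq(1L, max(1L, n - 999L), by = 1000L)
    shared <- vapply(wstart, function(s) {
      w <- substr(cs, s, min(n, s + 1999L))
      sum(cpp_kmer_codes(w, 15L) %in% ref_codes) +
        sum(cpp_kmer_codes(revcomp(w), 15L) %in% ref_codes)
    }, 0)
    hot <- wstart[shared >= 5]
    if (!length(hot)) next
    grp <- cumsum(c(1, diff(hot) > 2000L))
    for (g in split(hot, grp)) {
      r0 <- max(1L, min(g) - max_ref)
      r1 <- min(n, max(g) + 2000L + max_ref)
      region <- substr(cs, r0, r1)
      best <- NULL
      for (j in seq_len(nrow(rrna_refs))) {
        h <- local_align(rrna_refs$seq[j], region, "nucleotide",
                         query_id = rrna_refs$id[j], target_id = contigs$id[i])
        if (!nrow(h)) next
        if (h$pct_identity >= min_identity && h$aligned_len >= min_len) {
          if (is.null(best) || h$bit_score > best$bit_score) best <- h
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1]] <- data.frame(
          contig_id = contigs$id[i], start = best$t_start + r0 - 1L,
          end = best$t_end + r0 - 1L,
          strand = best$strand, ref_id = best$query_id,
          pct_identity = best$pct_identity, aligned_len = best$aligned_len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      ref_id = character(), pct_identity = numeric(),
                      aligned_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call bins viral or cellular
#'
#' A bin is called NCLDV when it carries at least `min_markers` distinct
#' ancestral markers and no rRNA gene; a bin with rRNA is cellular (rRNA
#' takes precedence over stray marker hits); anything else is ambiguous.
#'
#' @param bins a `bin_assignment` from [bin_contigs()].
#' @param marker_hits data frame from [scan_markers()].
#' @param rrna_hits data frame from [detect_rrna()].
#' @param min_markers distinct-marker threshold for the NCLDV verdict
#'   (default 5).
#' @return data frame `bin`, `n_distinct_markers`, `rrna_found`,
#'   `verdict`.
#' @export
classify_bins <- function(bins, marker_hits, rrna_hits, min_markers = 5) {
  a <- bins$assignment
  out <- lapply(split(a, a$bin), function(g) {
    mk <- unique(marker_hits$marker[marker_hits$contig_id %in% g$contig_id])
    rr <- any(rrna_hits$contig_id %in% g$contig_id)
    verdict <- if (rr) "cellular"
    else if (length(mk) >= min_markers) "NCLDV"
    else "ambiguous"
    data.frame(bin = g$bin[1], n_distinct_markers = length(mk),
               rrna_found = rr, verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
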