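# Local alignment wrappers around Biostrings::pairwiseAlignment, reported
# in a BLAST-like record with fixed Karlin-Altschul constants per scoring
# scheme (bit scores and e-values serve as thresholds, not as calibrated
# significance).

KA_CONST <- list(
  nucleotide = c(lambda = 1.28, K = 0.46),
  translated = c(lambda = 0.267, K = 0.041)
)

nt_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
    }
    m
  }
})

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

bit_from_raw <- function(raw, mode) {
  k <- KA_CONST[[mode]]
  (k[["lambda"]] * raw - log(k[["K"]])) / log(2)
}

align_record <- function(pa, query_id, target_id, mode, strand = "+",
                         frame = NA_integer_, m = NA_real_, n = NA_real_) {
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  matches <- Biostrings::nmatch(pa)
  alen <- nchar(as.character(p))
  raw <- Biostrings::score(pa)
  bit <- bit_from_raw(raw, mode)
  data.frame(
    query_id = query_id, target_id = target_id,
    q_start = Biostrings::start(p), q_end = Biostrings::end(p),
    t_start = Biostrings::start(s), t_end = Biostrings::end(s),
    strand = strand, frame = frame,
    matches = matches, aligned_len = alen,
    pct_identity = 100 * matches / alen,
    raw_score = raw, bit_score = bit,
    evalue = if (is.na(m)) NA_real_ else m * n * 2^(-bit),
    stringsAsFactors = FALSE
  )
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman local alignment via [Biostrings::pairwiseAlignment()].
#' Nucleotide mode scores +1/-2 with affine gaps (open 5, extend 2, as
#' costs) and searches both strands of the query; translated mode aligns
#' all six reading frames of a nucleotide query against a protein target
#' under BLOSUM62 with affine gaps (open 11, extend 1). Bit scores use
#' fixed Karlin-Altschul constants per scheme and
#' `evalue = m * n * 2^-bit`.
#'
#' Reverse-strand (and reverse-frame) query intervals are reported on the
#' forward coordinate system with the `strand` flag set; intervals are
#' 1-based and inclusive throughout the package. Translated-mode query
#' intervals are in peptide coordinates of the reported frame.
#'
#' @param query,target sequences (character scalars); in translated mode
#'   `query` is nucleotide and `target` is protein.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param query_id,target_id labels carried into the result.
#' @param both_strands search the reverse complement too (nucleotide mode).
#' @return one-row data frame (`query_id`, `target_id`, `q_start`, `q_end`,
#'   `t_start`, `t_end`, `strand`, `frame`, `matches`, `aligned_len`,
#'   `pct_identity`, `raw_score`, `bit_score`, `evalue`), or a zero-row
#'   frame when either sequence is empty.
#' @export
local_align <- function(query, target, mode = c("nucleotide", "translated"),
                        query_id = "query", target_id = "target",
                        both_strands = TRUE) {
  mode <- match.arg(mode)
  empty <- align_record_empty()
  if (!nchar(query) || !nchar(target)) return(empty)
  if (mode == "nucleotide") {
    pa <- Biostrings::pairwiseAlignment(query, target, type = "local",
                                        substitutionMatrix = nt_submat(),
                                        gapOpening = 5, gapExtension = 2)
    best <- align_record(pa, query_id, target_id, mode,
                         m = nchar(query), n = nchar(target))
    if (both_strands) {
      rc <- revcomp(query)
      par <- Biostrings::pairwiseAlignment(rc, target, type = "local",
                                           substitutionMatrix = nt_submat(),
                                           gapOpening = 5, gapExtension = 2)
      if (Biostrings::score(par) > Biostrings::score(pa)) {
        best <- align_record(par, query_id, target_id, mode, strand = "-",
                             m = nchar(query), n = nchar(target))
        qn <- nchar(query)
        qs <- best$q_start; qe <- best$q_end
        best$q_start <- qn - qe + 1L
        best$q_end <- qn - qs + 1L
      }
    }
    return(best)
  }
  peps <- six_frame_translate(query)
  best <- NULL
  for (f in seq_along(peps)) {
    pep <- gsub("\\*", "X", peps[[f]])
    if (nchar(pep) < 1) next
    pa <- Biostrings::pairwiseAlignment(pep, target, type = "local",
                                        substitutionMatrix = blosum62(),
                                        gapOpening = 11, gapExtension = 1)
    if (is.null(best) || Biostrings::score(pa) > best$raw_score) {
      best <- align_record(pa, query_id, target_id, mode,
                           strand = if (f <= 3) "+" else "-",
                           frame = f - 1L,
                           m = nchar(pep), n = nchar(target))
    }
  }
  if (is.null(best)) empty else best
}

align_record_empty <- function() {
  data.frame(query_id = character(), target_id = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             strand = character(), frame = integer(),
             matches = integer(), aligned_len = integer(),
             pct_identity = numeric(), raw_score = numeric(),
             bit_score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Format alignment records as BLAST outfmt-6 TSV lines
#'
#' @param hits data frame of alignment records from [local_align()].
#' @return character vector of tab-separated lines
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore).
#' @export
format_blast6 <- function(hits) {
  sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
          hits$query_id, hits$target_id, hits$pct_identity, hits$aligned_len,
          hits$aligned_len - hits$matches, 0L,
          hits$q_start, hits$q_end, hits$t_start, hits$t_end,
          hits$evalue, hits$bit_score)
}

# Exact-match seed prefilter: positions in `index` (named by k-mer) hit by
# any k-mer of `seq` taken at `offsets`.
seed_kmers <- function(seq, k, offsets = NULL) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  if (is.null(offsets)) offsets <- seq(1L, n - k + 1L)
  offsets <- offsets[offsets + k - 1L <= n]
  unique(substring(seq, offsets, offsets + k - 1L))
}
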