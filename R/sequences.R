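#' @useDynLib sortvir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a set of nucleotide sequence records
#'
#' The universal sequence container of the package: a data frame with one
#' row per record and columns `id`, `seq` and (optionally) `qual`, where
#' `qual` holds Sanger (phred+33) quality strings of the same length as
#' `seq`. Residues are upper-cased; IUPAC ambiguity codes other than
#' A/C/G/T are converted to N; anything else is an error.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of residues over A/C/G/T/N.
#' @param qual optional character vector of phred+33 quality strings.
#' @return A `nuc_set` data frame.
#' @export
nuc_set <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  seq <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid residues in record(s): ", paste(utils::head(id[bad], 3), collapse = ", "))
  }
  x <- data.frame(id = as.character(id), seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != length(seq)) stop("qual length mismatch")
    if (any(nchar(qual) != nchar(seq))) {
      i <- which(nchar(qual) != nchar(seq))[1]
      stop("quality string length differs from sequence for record '", id[i], "'")
    }
    x$qual <- as.character(qual)
  }
  class(x) <- c("nuc_set", "data.frame")
  x
}

#' @export
print.nuc_set <- function(x, ...) {
  cat(sprintf("nuc_set with %d record(s), %s qualities\n", nrow(x),
              if ("qual" %in% names(x)) "with" else "no"))
  if (nrow(x)) {
    show <- utils::head(x, 5)
    for (i in seq_len(nrow(show))) {
      s <- show$seq[i]
      cat(sprintf("  %s [%d bp] %s%s\n", show$id[i], nchar(s),
                  substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
    }
    if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  }
  invisible(x)
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_phred <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(pmin(pmax(s, 0L), 41L) + 33L)), "")
}

#' Read FASTA or FASTQ records
#'
#' FASTA parsing (multi-line records allowed) goes through
#' [Biostrings::readDNAStringSet()]; FASTQ is read as strict 4-line Sanger
#' (phred+33) records so that malformed records can be reported with their
#' line number.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (sniff the first byte).
#' @return A [nuc_set()] (with `qual` for FASTQ input).
#' @export
parse_fastx <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1, 1)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    return(nuc_set(ids, as.character(ss)))
  }
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", 4L * (length(lines) %/% 4L) + 1L)
  }
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad)) stop("malformed FASTQ header at line ", i[bad[1]])
  plus <- lines[i + 2L]
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad)) stop("malformed FASTQ separator at line ", i[bad[1]] + 2L)
  seqs <- lines[i + 1L]
  quals <- lines[i + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ", i[bad[1]] + 3L)
  }
  nuc_set(sub("^@", "", sub("\\s.*$", "", hdr)), seqs, quals)
}

#' Write FASTA or FASTQ records
#'
#' @param x a [nuc_set()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires qualities).
#' @return `path`, invisibly.
#' @export
serialize_fastx <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(x$seq)
    names(ss) <- x$id
    Biostrings::writeXStringSet(ss, path)
  } else {
    if (is.null(x$qual)) stop("FASTQ output requires qualities")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", x$id), x$seq, "+", x$qual)), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Quality-trim reads (LEADING / TRAILING / SLIDINGWINDOW / MINLEN)
#'
#' Reproduces the classic read-trimming recipe used on sorted-cell MDA
#' libraries: leading and trailing bases below a phred score of
#' `leading_q`/`trailing_q` are removed, the read is then truncated at the
#' start of the first `window`-base window whose mean quality falls below
#' `window_q`, and reads shorter than `min_len` after trimming are dropped.
#'
#' @param reads a [nuc_set()] with qualities.
#' @param leading_q,trailing_q single-base phred cutoffs (default 3).
#' @param window,window_q sliding-window size and mean-quality cutoff
#'   (defaults 25 and 30).
#' @param min_len minimum surviving length (default 50).
#' @return A [nuc_set()] of surviving trimmed reads; the ids of dropped
#'   reads are in `attr(, "dropped")`.
#' @export
quality_trim <- function(reads, leading_q = 3, trailing_q = 3, window = 25,
                         window_q = 30, min_len = 50) {
  if (is.null(reads$qual)) stop("quality_trim requires qualities")
  b <- cpp_trim_bounds(reads$qual, leading_q, trailing_q, window, window_q)
  len <- b[, 2] - b[, 1] + 1L
  keep <- len >= min_len
  out <- nuc_set(reads$id[keep],
                 substring(reads$seq[keep], b[keep, 1], b[keep, 2]),
                 substring(reads$qual[keep], b[keep, 1], b[keep, 2]))
  attr(out, "dropped") <- reads$id[!keep]
  out
}

#' Six-frame translation
#'
#' Standard genetic code; stops rendered `*`, codons containing N rendered
#' `X`; frames 1-3 on the forward strand, 4-6 on the reverse complement;
#' trailing partial codons are dropped.
#'
#' @param seq a single nucleotide sequence.
#' @return character vector of 6 peptides, named `F1`..`F3`, `R1`..`R3`.
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(seq)
  rc <- revcomp(seq)
  n <- nchar(seq)
  frames <- character(6)
  for (f in 0:2) {
    len <- ((n - f) %/% 3L) * 3L
    fs <- if (len > 0) substr(seq, f + 1L, f + len) else ""
    rs <- if (len > 0) substr(rc, f + 1L, f + len) else ""
    frames[f + 1L] <- translate_dna(fs)
    frames[f + 4L] <- translate_dna(rs)
  }
  names(frames) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  frames
}

# all six frame translations of a vector of sequences, returned read-major
# (6 consecutive entries per input: F1 F2 F3 R1 R2 R3)
six_frames_batch <- function(seqs) {
  n <- nchar(seqs)
  rc <- revcomp(seqs)
  frames <- vector("list", 6)
  for (f in 0:2) {
    len <- pmax(((n - f) %/% 3L) * 3L, 0L)
    tr <- function(x) as.character(
      Biostrings::translate(Biostrings::DNAStringSet(x),
                            if.fuzzy.codon = "X", no.init.codon = TRUE))
    frames[[f + 1L]] <- tr(substr(seqs, f + 1L, f + len))
    frames[[f + 4L]] <- tr(substr(rc, f + 1L, f + len))
  }
  as.vector(do.call(rbind, frames))
}

translate_dna <- function(seq) {
  if (!nchar(seq)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

canonical_4mer_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      kmers <- apply(expand.grid(rep(list(DNA_BASES), 4))[, 4:1], 1, paste0, collapse = "")
      rc <- revcomp(kmers)
      map <<- stats::setNames(pmin(kmers, rc), kmers)
    }
    map
  }
})

#' Canonical k-mer frequency vector
#'
#' Counts k-mers pooled with their reverse complements (the
#' lexicographically smaller member names the class; 136 classes for
#' k = 4). Windows containing N are skipped. The vector is normalized to
#' sum to 1 when anything was counted.
#'
#' @param seq a single nucleotide sequence.
#' @param k word size (default 4, the tetranucleotide signature).
#' @return named numeric vector over canonical k-mer classes; attribute
#'   `empty` is TRUE when no k-mer could be counted.
#' @export
canonical_kmer_counts <- function(seq, k = 4) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(toupper(seq)), k)
  kmers <- names(counts)
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  classes <- sort(unique(canon))
  pooled <- vapply(split(counts, canon), sum, 0)[classes]
  tot <- sum(pooled)
  out <- if (tot > 0) pooled / tot else pooled
  attr(out, "empty") <- tot == 0
  out
}

#' GC content
#'
#' @param seq character vector of sequences.
#' @return (G+C)/(A+C+G+T) per sequence; N excluded from the denominator;
#'   NA for sequences with no A/C/G/T.
#' @export
gc_content <- function(seq) {
  ss <- Biostrings::DNAStringSet(toupper(seq))
  f <- Biostrings::letterFrequency(ss, DNA_BASES)
  denom <- rowSums(f)
  out <- ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
  names(out) <- names(seq)
  unname(out)
}

#' Moving-window GC content
#'
#' One value per window of `window` bp taken every `step` bp (default
#' half-window overlap), as used for genome-map GC tracks.
#'
#' @param seq a single nucleotide sequence.
#' @param window window size in bp (default 1000).
#' @param step step between window starts (default `window / 2`).
#' @return data frame with columns `start`, `end` (1-based, inclusive) and
#'   `gc`.
#' @export
moving_gc <- function(seq, window = 1000, step = window / 2) {
  n <- nchar(seq)
  if (n < window) {
    return(data.frame(start = 1L, end = n, gc = gc_content(seq)))
  }
  starts <- unique(c(seq(1L, n - window + 1L, by = as.integer(step))))
  data.frame(start = starts, end = starts + window - 1L,
             gc = gc_content(substring(seq, starts, starts + window - 1L)))
}

#' Pair forward and reverse read sets
#'
#' @param fwd,rev [nuc_set()]s in matching order; ids must agree after
#'   stripping a trailing `/1`, `/2`, `.1` or `.2`.
#' @return list with elements `fwd`, `rev`, `pair_id`.
#' @export
pair_reads <- function(fwd, rev) {
  strip <- function(x) sub("[/.][12]$", "", x)
  pf <- strip(fwd$id); pr <- strip(rev$id)
  if (!identical(pf, pr)) stop("forward/reverse ids do not pair")
  list(fwd = fwd, rev = rev, pair_id = pf)
}
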