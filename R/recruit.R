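# Competitive recruitment of (meta)transcriptome reads to viral
# proteomes: translated search, decoy re-search keeping only reads whose
# single best overall hit is viral, per-gene counts/RPKM, and recruited
# identity profiles.

# Translated hits of nucleotide reads against a protein database:
# exact 4-aa seed prefilter over all six frames, then batched local
# BLOSUM62 alignment; best hit per (read, target) retained.
translated_search <- function(reads, db, bit_floor = 25, min_shared = 2,
                              seed_k = 4) {
  seqs <- if (inherits(reads, "nuc_set")) reads$seq else reads
  ids <- if (inherits(reads, "nuc_set")) reads$id else names(reads)
  no_hits <- data.frame(read_id = character(), target = character(),
                        bits = numeric(), pct_identity = numeric(),
                        frame = integer(), stringsAsFactors = FALSE)
  if (!length(seqs)) return(no_hits)
  fpep <- six_frames_batch(seqs)
  fpep <- gsub("*", "X", fpep, fixed = TRUE)
  fread <- rep(seq_along(seqs), each = 6)
  nonempty <- nchar(fpep) >= seed_k
  idx <- protein_word_index(db, k = seed_k)
  qwords <- lapply(which(nonempty), function(i) {
    n <- nchar(fpep[i])
    unique(substring(fpep[i], 1:(n - seed_k + 1), seed_k:n))
  })
  qw <- data.frame(word = unlist(qwords),
                   fidx = rep(which(nonempty), lengths(qwords)),
                   stringsAsFactors = FALSE)
  mm <- merge(qw, idx, by = "word")
  if (!nrow(mm)) {
    return(data.frame(read_id = character(), target = character(),
                      bits = numeric(), pct_identity = numeric(),
                      frame = integer(), stringsAsFactors = FALSE))
  }
  key <- mm$fidx * (length(db) + 1) + mm$target
  r <- rle(sort(key))
  good <- r$values[r$lengths >= min_shared]
  cand <- data.frame(fidx = good %/% (length(db) + 1),
                     target = good %% (length(db) + 1))
  hits <- lapply(split(cand, cand$target), function(g) {
    tj <- g$target[1]
    al <- protein_align_batch(fpep[g$fidx], db[[tj]])
    data.frame(read = fread[g$fidx], frame = (g$fidx - 1) %% 6,
               target = tj, bits = al$bit_score,
               pct_identity = al$pct_identity, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$bits >= bit_floor, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(read_id = character(), target = character(),
                      bits = numeric(), pct_identity = numeric(),
                      frame = integer(), stringsAsFactors = FALSE))
  }
  # best frame per (read, target)
  hits <- hits[order(hits$read, hits$target, -hits$bits), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("read", "target")]), , drop = FALSE]
  data.frame(read_id = ids[hits$read], target = names(db)[hits$target],
             bits = hits$bits, pct_identity = hits$pct_identity,
             frame = hits$frame, stringsAsFactors = FALSE)
}

#' Competitive recruitment with decoy re-search
#'
#' Stage 1: translated search of every read against the viral proteomes;
#' reads with a bit score of at least `bit_min` to any viral protein
#' survive. Stage 2: surviving reads are re-searched against the viral
#' proteins plus the decoy database, and a read is retained only when its
#' single best overall hit is viral; ties among equally best hits are
#' broken by a seeded uniform draw.
#'
#' @param reads a [nuc_set()] of nucleotide reads.
#' @param viral_proteomes named list of named peptide vectors (one per
#'   viral genome), or a single named peptide vector.
#' @param decoy_db named peptide vector (labeled non-viral stand-in for a
#'   comprehensive database).
#' @param bit_min stage-1 bit-score threshold (default 50).
#' @param seed RNG seed for tie breaking.
#' @return A `recruitment_table`: list with `assignments` (read, gene,
#'   genome, bits, pct_identity), `genes` (gene, genome, length_aa,
#'   count, rpkm), `n_stage1`, `n_retained`, `seed`.
#' @export
competitive_recruit <- function(reads, viral_proteomes, decoy_db,
                                bit_min = 50, seed = 1) {
  if (!is.list(viral_proteomes)) viral_proteomes <- list(viral = viral_proteomes)
  genome_of <- rep(names(viral_proteomes),
                   vapply(viral_proteomes, length, 0L))
  viral <- unlist(viral_proteomes)
  names(viral) <- unlist(lapply(viral_proteomes, names))
  if (!length(decoy_db)) warning("empty decoy database: stage 2 is degenerate")
  set.seed(seed)
  s1 <- translated_search(reads, viral, bit_floor = bit_min)
  keep_ids <- unique(s1$read_id)
  n_stage1 <- length(keep_ids)
  combined <- c(viral, decoy_db)
  is_viral <- c(rep(TRUE, length(viral)), rep(FALSE, length(decoy_db)))
  names(is_viral) <- names(combined)
  sub <- reads[reads$id %in% keep_ids, , drop = FALSE]
  s2 <- translated_search(sub, combined, bit_floor = 25)
  assigns <- lapply(split(s2, s2$read_id), function(h) {
    best <- h[h$bits == max(h$bits), , drop = FALSE]
    pick <- best[sample.int(nrow(best), 1), , drop = FALSE]
    if (!is_viral[pick$target]) return(NULL)
    pick
  })
  assigns <- do.call(rbind, assigns[!vapply(assigns, is.null, TRUE)])
  gene_len <- nchar(viral)
  if (is.null(assigns) || !nrow(assigns)) {
    counts <- stats::setNames(rep(0L, length(viral)), names(viral))
    assigns <- data.frame(read_id = character(), target = character(),
                          bits = numeric(), pct_identity = numeric(),
                          frame = integer(), stringsAsFactors = FALSE)
  } else {
    counts <- table(factor(assigns$target, levels = names(viral)))
  }
  total_m <- max(sum(counts), 1) / 1e6
  genes <- data.frame(gene = names(viral),
                      genome = genome_of,
                      length_aa = as.integer(gene_len),
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
  genes$rpkm <- genes$count / ((3 * genes$length_aa / 1000) * total_m)
  assigns$genome <- genome_of[match(assigns$target, names(viral))]
  structure(list(assignments = assigns, genes = genes,
                 n_stage1 = n_stage1, n_retained = nrow(assigns),
                 n_reads = nrow(reads), seed = seed),
            class = "recruitment_table")
}

#' Expression summary from a recruitment table
#'
#' A gene counts as expressed when it recruited at least `min_reads`
#' reads. When a second table is given, the cross-sample comparison
#' reports the Pearson correlation of `log10(RPKM + 1)` over genes
#' expressed in either sample.
#'
#' @param table a `recruitment_table`.
#' @param other optional second `recruitment_table` for the pairwise
#'   comparison.
#' @param min_reads expression threshold in reads (default 1).
#' @return list with `fraction_expressed`, `n_genes`, `n_expressed`,
#'   `ranked` (genes by count), and (with `other`) `cor_log_rpkm`.
#' @export
expression_summary <- function(table, other = NULL, min_reads = 1) {
  g <- table$genes
  expressed <- g$count >= min_reads
  out <- list(fraction_expressed = mean(expressed),
              n_genes = nrow(g), n_expressed = sum(expressed),
              ranked = g[order(-g$count), ])
  if (!is.null(other)) {
    m <- merge(g[, c("gene", "rpkm", "count")],
               other$genes[, c("gene", "rpkm", "count")], by = "gene")
    use <- m$count.x >= min_reads | m$count.y >= min_reads
    out$cor_log_rpkm <- if (sum(use) >= 2) {
      stats::cor(log10(m$rpkm.x[use] + 1), log10(m$rpkm.y[use] + 1))
    } else NA_real_
  }
  out
}

#' Amino-acid identity profile of recruited reads
#'
#' Histogram (1% bins by default) and mean of per-read amino-acid
#' identities, per reference genome; flags an endemic-like pattern when
#' the mass above 90% identity falls below `high_id_frac`.
#'
#' @param table a `recruitment_table`.
#' @param bin_width histogram bin width in percent (default 1).
#' @param high_id_frac endemic-flag threshold on the fraction of reads
#'   above 90% identity (default 0.1).
#' @return list per genome: `histogram` (data frame `bin_lo`, `bin_hi`,
#'   `count`), `mean_identity`, `frac_high_identity`, `endemic_like`.
#' @export
identity_profile <- function(table, bin_width = 1, high_id_frac = 0.1) {
  a <- table$assignments
  lapply(split(a, a$genome), function(g) {
    br <- seq(0, 100 + bin_width, by = bin_width)
    h <- hist(pmin(g$pct_identity, 100), breaks = br, plot = FALSE)
    frac_high <- mean(g$pct_identity > 90)
    list(histogram = data.frame(bin_lo = utils::head(br, -1),
                                bin_hi = br[-1], count = h$counts),
         mean_identity = mean(g$pct_identity),
         frac_high_identity = frac_high,
         endemic_like = frac_high < high_id_frac)
  })
}
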