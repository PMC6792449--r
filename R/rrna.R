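# Sort characterization from unassembled read pairs: rRNA pair
# extraction (both-mates rule), N-joining, and an RDP-style bootstrap
# naive-Bayes k-mer classifier over a ranked-lineage reference.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read a SILVA-style ranked-lineage FASTA
#'
#' Headers of the form `>id domain;phylum;class;order;family;genus`.
#'
#' @param path FASTA file.
#' @return A [nuc_set()] with a `lineage` column.
#' @export
read_lineage_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  ids <- sub("\\s.*$", "", hdr)
  lin <- sub("^\\S+\\s+", "", hdr)
  out <- nuc_set(ids, as.character(ss))
  out$lineage <- ifelse(lin == hdr, NA_character_, lin)
  out
}

read_is_rrna <- function(seqs, ref_code_list, refs, min_bits = 80,
                         seed_k = 12L) {
  n <- length(seqs)
  rc <- revcomp(seqs)
  best_ref <- integer(n); use_rc <- logical(n)
  for (i in seq_len(n)) {
    cf <- cpp_kmer_codes(seqs[i], seed_k)
    cr <- cpp_kmer_codes(rc[i], seed_k)
    sf <- vapply(ref_code_list, function(x) sum(cf %in% x), 0L)
    sr <- vapply(ref_code_list, function(x) sum(cr %in% x), 0L)
    if (max(sf, sr) == 0L) next
    if (max(sr) > max(sf)) {
      best_ref[i] <- which.max(sr); use_rc[i] <- TRUE
    } else {
      best_ref[i] <- which.max(sf)
    }
  }
  ok <- logical(n)
  for (j in unique(best_ref[best_ref > 0])) {
    idx <- which(best_ref == j)
    q <- ifelse(use_rc[idx], rc[idx], seqs[idx])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(q), Biostrings::DNAString(refs$seq[j]),
      type = "local", substitutionMatrix = nt_submat(),
      gapOpening = 5, gapExtension = 2)
    bits <- bit_from_raw(Biostrings::score(pa), "nucleotide")
    ok[idx] <- bits >= min_bits
  }
  ok
}

#' Extract read pairs of rRNA origin
#'
#' A pair is kept only when BOTH mates independently align to the rRNA
#' reference set above `min_bits` bits (the strict both-mates confirmation
#' that precedes classification).
#'
#' @param pairs list with `fwd` and `rev` [nuc_set()]s in matching order.
#' @param rrna_refs reference [nuc_set()].
#' @param min_bits per-mate bit-score threshold (default 80).
#' @return `pairs` subset to qualifying pairs, with a `pair_id` element.
#' @export
extract_rrna_pairs <- function(pairs, rrna_refs, min_bits = 80) {
  ref_code_list <- lapply(rrna_refs$seq, cpp_kmer_codes, k = 12L)
  okf <- read_is_rrna(pairs$fwd$seq, ref_code_list, rrna_refs, min_bits)
  okr <- read_is_rrna(pairs$rev$seq, ref_code_list, rrna_refs, min_bits)
  keep <- okf & okr
  list(fwd = pairs$fwd[keep, , drop = FALSE],
       rev = pairs$rev[keep, , drop = FALSE],
       pair_id = sub("[/.][12]$", "", pairs$fwd$id[keep]))
}

#' Join mates with an N
#'
#' `fwd + "N" + revcomp(rev)`; the classifier's k-mer walk skips any word
#' containing the degenerate base, so the joint read carries both mates'
#' signal without inventing sequence between them.
#'
#' @param pairs list with `fwd`, `rev` [nuc_set()]s (and optional
#'   `pair_id`).
#' @return A [nuc_set()] of joined sequences named by pair id.
#' @export
join_pair_with_N <- function(pairs) {
  pid <- if (!is.null(pairs$pair_id)) pairs$pair_id
  else sub("[/.][12]$", "", pairs$fwd$id)
  nuc_set(pid, paste0(pairs$fwd$seq, "N", revcomp(pairs$rev$seq)))
}

#' Train the RDP-style naive-Bayes k-mer model
#'
#' Per-genus 8-mer presence probabilities with add-half smoothing:
#' `P(w|g) = (n_gw + 0.5) / (N_g + 1)` where `n_gw` counts reference
#' sequences of genus g containing word w. Genus priors are uniform.
#'
#' @param refs a [nuc_set()] with a `lineage` column
#'   (domain;...;genus).
#' @param k word size (default 8).
#' @return An `rdp_model`: list with `logp` (4^k x genera matrix of log
#'   probabilities), `lineages` (per-genus rank table), `k`.
#' @export
train_rdp <- function(refs, k = 8) {
  if (is.null(refs$lineage)) stop("reference set lacks lineages")
  lin <- strsplit(refs$lineage, ";")
  genus <- vapply(lin, function(x) x[length(x)], "")
  genera <- sort(unique(genus))
  nk <- 4L^k
  counts <- matrix(0, nk, length(genera), dimnames = list(NULL, genera))
  nseq <- stats::setNames(numeric(length(genera)), genera)
  for (i in seq_len(nrow(refs))) {
    codes <- cpp_kmer_codes(refs$seq[i], as.integer(k))
    counts[codes + 1L, genus[i]] <- counts[codes + 1L, genus[i]] + 1
    nseq[genus[i]] <- nseq[genus[i]] + 1
  }
  logp <- log(sweep(counts + 0.5, 2, nseq + 1, "/"))
  lt <- do.call(rbind, lapply(genera, function(g) {
    x <- lin[[match(g, genus)]]
    if (length(x) < length(RANKS)) x <- c(x, rep(NA, length(RANKS) - length(x)))
    x[seq_along(RANKS)]
  }))
  lt <- as.data.frame(lt, stringsAsFactors = FALSE)
  names(lt) <- RANKS
  structure(list(logp = logp, lineages = lt, genera = genera,
                 k = as.integer(k)),
            class = "rdp_model")
}

#' Classify sequences with the bootstrap naive-Bayes classifier
#'
#' Score(genus) sums `log P(w|genus)` over the query's distinct k-mers
#' (words containing N are skipped). Bootstrap support resamples
#' `ceiling(W/8)` of the W distinct words `n_boot` times; per-rank
#' confidence is the fraction of resamples agreeing with the full-query
#' call at that rank, and the assignment is truncated at the deepest rank
#' with confidence >= `conf_cutoff`.
#'
#' @param queries a [nuc_set()] or character vector.
#' @param model an `rdp_model` from [train_rdp()].
#' @param n_boot bootstrap resamples (default 100).
#' @param conf_cutoff per-rank confidence cutoff (default 0.8).
#' @return data frame: `id`, one column per rank (NA beyond the truncation
#'   depth), `genus_raw`, per-rank confidences (`conf_domain` ...),
#'   `lineage` (truncated, semicolon-joined).
#' @export
rdp_classify <- function(queries, model, n_boot = 100, conf_cutoff = 0.8) {
  seqs <- if (inherits(queries, "nuc_set")) queries$seq else queries
  ids <- if (inherits(queries, "nuc_set")) queries$id else
    if (!is.null(names(queries))) names(queries) else
      sprintf("q%d", seq_along(queries))
  res <- vector("list", length(seqs))
  lt <- model$lineages
  for (i in seq_along(seqs)) {
    codes <- cpp_kmer_codes(seqs[i], model$k)
    W <- length(codes)
    row <- stats::setNames(as.list(rep(NA_character_, length(RANKS))), RANKS)
    conf <- stats::setNames(rep(NA_real_, length(RANKS)),
                            paste0("conf_", RANKS))
    if (W < 1) {
      res[[i]] <- c(list(id = ids[i]), row, list(genus_raw = NA_character_),
                    as.list(conf), list(lineage = NA_character_))
      next
    }
    sub <- model$logp[codes + 1L, , drop = FALSE]
    full <- colSums(sub)
    g_full <- model$genera[which.max(full)]
    nsub <- ceiling(W / 8)
    picks <- matrix(sample.int(W, nsub * n_boot, replace = TRUE), nsub, n_boot)
    wins <- apply(picks, 2, function(ix)
      which.max(colSums(sub[ix, , drop = FALSE])))
    win_lin <- lt[wins, , drop = FALSE]
    full_lin <- lt[match(g_full, model$genera), , drop = FALSE]
    depth_ok <- TRUE
    for (r in RANKS) {
      agree <- mean(!is.na(win_lin[[r]]) & win_lin[[r]] == full_lin[[r]][1])
      conf[paste0("conf_", r)] <- agree
      if (depth_ok && agree >= conf_cutoff && !is.na(full_lin[[r]][1])) {
        row[[r]] <- as.character(full_lin[[r]][1])
      } else {
        depth_ok <- FALSE
      }
    }
    lineage <- paste(unlist(row[!is.na(unlist(row))]), collapse = ";")
    res[[i]] <- c(list(id = ids[i]), row, list(genus_raw = g_full),
                  as.list(conf), list(lineage = if (nzchar(lineage)) lineage else NA))
  }
  out <- do.call(rbind, lapply(res, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Hierarchical composition summary
#'
#' Per-rank counts and percentages of classified lineages; at every level
#' the children's counts sum to their parent's.
#'
#' @param classifications data frame from [rdp_classify()].
#' @return list with `table` (data frame `rank`, `taxon`, `parent`,
#'   `count`, `pct`), `total` (classified input count), and `json`
#'   (nested JSON string).
#' @export
summarize_composition <- function(classifications) {
  n_total <- nrow(classifications)
  if (n_total == 0 || all(is.na(classifications$lineage))) {
    return(list(table = data.frame(rank = character(), taxon = character(),
                                   parent = character(), count = integer(),
                                   pct = numeric()),
                total = 0L, json = "{}"))
  }
  rows <- list()
  for (d in seq_along(RANKS)) {
    r <- RANKS[d]
    vals <- classifications[[r]]
    parents <- if (d == 1) rep("root", n_total) else classifications[[RANKS[d - 1]]]
    ok <- !is.na(vals)
    if (!any(ok)) break
    key <- paste(parents[ok], vals[ok], sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    rows[[d]] <- data.frame(
      rank = r,
      taxon = vapply(parts, `[`, "", 2),
      parent = vapply(parts, `[`, "", 1),
      count = as.integer(cnt),
      pct = 100 * as.integer(cnt) / n_total,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  build <- function(rank_i, parent) {
    if (rank_i > length(RANKS)) return(NULL)
    kids <- tab[tab$rank == RANKS[rank_i] & tab$parent == parent, , drop = FALSE]
    if (!nrow(kids)) return(NULL)
    lapply(seq_len(nrow(kids)), function(i) {
      node <- list(taxon = kids$taxon[i], rank = kids$rank[i],
                   count = kids$count[i], pct = kids$pct[i])
      ch <- build(rank_i + 1, kids$taxon[i])
      if (!is.null(ch)) node$children <- ch
      node
    })
  }
  json <- jsonlite::toJSON(list(total = n_total, children = build(1, "root")),
                           auto_unbox = TRUE, digits = 4)
  list(table = tab, total = n_total, json = as.character(json))
}
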