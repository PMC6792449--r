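# Composition binning: canonical tetranucleotide frequency + GC features,
# agglomerative clustering, truth-based evaluation.

canonical_pool_matrix <- local({
  pm <- NULL
  function() {
    if (is.null(pm)) {
      map <- canonical_4mer_map()
      classes <- sort(unique(map))
      pm <<- vapply(classes, function(cl) as.numeric(map == cl),
                    numeric(length(map)))
      rownames(pm) <- names(map)
    }
    pm
  }
})

# n x 136 canonical tetranucleotide frequency matrix for a set of contigs.
tnf_matrix <- function(seqs) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs), 4)
  pooled <- counts %*% canonical_pool_matrix()
  tot <- rowSums(pooled)
  pooled / ifelse(tot > 0, tot, 1)
}

#' Profile contigs for composition binning
#'
#' Computes, for every contig passing the 1 kb size filter, its canonical
#' tetranucleotide frequency vector (136 classes), GC content and length;
#' attaches mean per-base depth when a read mapping is supplied.
#'
#' @param contigs a [nuc_set()].
#' @param mapping optional result of [map_reads()] (depth source).
#' @param min_len size filter in bp (default 1000).
#' @return A `contig_profiles` object: list with `table` (data frame
#'   `contig_id`, `length`, `gc`, `depth`), `tnf` (matrix), and
#'   `excluded` (ids below the size filter).
#' @export
profile_contigs <- function(contigs, mapping = NULL, min_len = 1000) {
  len <- nchar(contigs$seq)
  keep <- len >= min_len
  if (!any(keep)) {
    message("no contigs pass the ", min_len, " bp size filter")
    return(structure(list(table = data.frame(contig_id = character(),
                                             length = integer(), gc = numeric(),
                                             depth = numeric()),
                          tnf = matrix(0, 0, 136),
                          excluded = contigs$id),
                     class = "contig_profiles"))
  }
  x <- contigs[keep, , drop = FALSE]
  tab <- data.frame(contig_id = x$id, length = nchar(x$seq),
                    gc = gc_content(x$seq), depth = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    md <- vapply(tab$contig_id, function(cid) {
      d <- mapping$depth[[cid]]
      if (is.null(d)) NA_real_ else mean(d)
    }, 0)
    tab$depth <- unname(md)
  }
  tnf <- tnf_matrix(x$seq)
  rownames(tnf) <- x$id
  structure(list(table = tab, tnf = tnf, excluded = contigs$id[!keep]),
            class = "contig_profiles")
}

#' Cluster contig profiles into bins
#'
#' Agglomerative (average-linkage) clustering on the composition feature
#' vector: per-column z-scored canonical tetranucleotide frequencies with
#' z-scored GC appended at weight `gc_weight`. When `n_bins` is not given
#' the tree is cut at the largest gap in merge heights (relative to the
#' tree's total height) - an automatic stand-in for interactive curation.
#' Contigs are ordered by id before clustering so the result does not
#' depend on input order.
#'
#' @param profiles a `contig_profiles` object from [profile_contigs()].
#' @param n_bins optional fixed number of bins.
#' @param linkage hclust agglomeration method (default `"average"`).
#' @param gc_weight weight of the GC feature (default 0.1; composition
#'   dominates, as in interactive tetranucleotide binning).
#' @return A `bin_assignment` object: list with `assignment` (data frame
#'   `contig_id`, `bin`), `summary` (per-bin total bp, mean GC, mean
#'   depth), and the `hclust` tree.
#' @export
bin_contigs <- function(profiles, n_bins = NULL, linkage = "average",
                        gc_weight = 0.1) {
  tab <- profiles$table
  if (nrow(tab) == 0) stop("no profiles to bin")
  ord <- order(tab$contig_id)
  tab <- tab[ord, , drop = FALSE]
  tnf <- profiles$tnf[ord, , drop = FALSE]
  if (nrow(tab) == 1) {
    warning("single contig: one bin")
    assign <- data.frame(contig_id = tab$contig_id, bin = "bin_1",
                         length = tab$length, gc = tab$gc,
                         stringsAsFactors = FALSE)
    return(structure(list(assignment = assign,
                          summary = bin_summary(assign, tab), tree = NULL),
                     class = "bin_assignment"))
  }
  zs <- function(m) {
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sdv, "/")
  }
  feats <- cbind(zs(tnf), gc_weight * zs(matrix(tab$gc, ncol = 1)))
  d <- stats::dist(feats)
  hc <- stats::hclust(d, method = linkage)
  k <- if (!is.null(n_bins)) n_bins else cut_by_height_gap(hc$height, nrow(tab))
  cl <- stats::cutree(hc, k = k)
  # stable bin labels: bin_1 is the largest by total bp
  bp <- tapply(tab$length, cl, sum)
  relab <- stats::setNames(seq_along(bp), names(sort(bp, decreasing = TRUE)))
  assign <- data.frame(contig_id = tab$contig_id,
                       bin = sprintf("bin_%d", relab[as.character(cl)]),
                       length = tab$length, gc = tab$gc,
                       stringsAsFactors = FALSE)
  structure(list(assignment = assign, summary = bin_summary(assign, tab),
                 tree = hc),
            class = "bin_assignment")
}

cut_by_height_gap <- function(h, n) {
  if (length(h) < 2) return(if (max(h) > 0) 2L else 1L)
  gaps <- diff(h) / max(h)
  i <- which.max(gaps)
  if (gaps[i] < 0.05) return(1L)
  n - i
}

bin_summary <- function(assign, tab) {
  m <- merge(assign[, c("contig_id", "bin")], tab, by = "contig_id")
  do.call(rbind, lapply(split(m, m$bin), function(g) {
    data.frame(bin = g$bin[1], n_contigs = nrow(g), total_bp = sum(g$length),
               mean_gc = stats::weighted.mean(g$gc, g$length),
               mean_depth = if (all(is.na(g$depth))) NA_real_ else
                 stats::weighted.mean(g$depth, g$length, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Score bins against the simulator truth table
#'
#' @param bins a `bin_assignment` from [bin_contigs()].
#' @param truth data frame with `contig_id` and `entity` (e.g. the
#'   simulator's contig truth table).
#' @return list with `per_bin` (bin, dominant entity, purity = bp fraction
#'   of the dominant entity) and `per_entity` (entity, completeness = bp
#'   fraction recovered in its majority bin).
#' @export
evaluate_bins <- function(bins, truth) {
  a <- bins$assignment
  miss <- setdiff(a$contig_id, truth$contig_id)
  if (length(miss)) stop("truth table missing contig(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  m <- merge(a, truth[, c("contig_id", "entity")], by = "contig_id")
  m$bp <- m$length
  per_bin <- do.call(rbind, lapply(split(m, m$bin), function(g) {
    ebp <- tapply(g$bp, g$entity, sum)
    data.frame(bin = g$bin[1], entity = names(which.max(ebp)),
               purity = max(ebp) / sum(ebp), total_bp = sum(ebp),
               stringsAsFactors = FALSE)
  }))
  per_entity <- do.call(rbind, lapply(split(m, m$entity), function(g) {
    bbp <- tapply(g$bp, g$bin, sum)
    data.frame(entity = g$entity[1], majority_bin = names(which.max(bbp)),
               completeness = max(bbp) / sum(bbp), stringsAsFactors = FALSE)
  }))
  rownames(per_bin) <- rownames(per_entity) <- NULL
  list(per_bin = per_bin, per_entity = per_entity)
}
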