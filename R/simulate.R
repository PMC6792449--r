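# Synthetic sorted-cell communities with known ground truth: a low-GC
# giant virus, a higher-GC eukaryote host, optional bacterial contaminant
# and phage; planted marker genes and rRNA operons; MDA-style uneven
# paired-end read coverage with quality decay.

AA_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Describe one community member
#'
#' @param name entity label.
#' @param role one of `giant_virus`, `host_eukaryote`, `bacterium`, `phage`.
#' @param genome_len genome length in bp.
#' @param gc_target target GC fraction. Giant-virus genomes default to the
#'   low-GC range (0.25-0.31) typical of the group; hosts should sit at
#'   least 0.08 above the virus so composition binning has signal.
#' @param markov_order order of the composition Markov chain (0-3).
#' @param n_markers_planted number of ancestral-marker genes (<= 47) to
#'   plant as ORFs.
#' @param has_rrna plant an rRNA operon.
#' @param abundance relative read-sampling weight.
#' @param n_genes number of additional protein-coding genes to plant (for
#'   recruitment/expression fixtures); 0 for none.
#' @param rrna_taxon genus label in the rRNA reference set to plant from
#'   (default: first genus).
#' @return An `entity_spec` list.
#' @export
entity_spec <- function(name, role = c("giant_virus", "host_eukaryote",
                                       "bacterium", "phage"),
                        genome_len = 3e5,
                        gc_target = NULL,
                        markov_order = 3, n_markers_planted = 0,
                        has_rrna = FALSE, abundance = 1,
                        n_genes = 0, rrna_taxon = NULL) {
  role <- match.arg(role)
  if (is.null(gc_target)) {
    gc_target <- if (role == "giant_virus") 0.28 else 0.45
  }
  stopifnot(gc_target > 0, gc_target < 1, n_markers_planted <= 47)
  structure(list(name = name, role = role, genome_len = as.integer(genome_len),
                 gc_target = gc_target, markov_order = as.integer(markov_order),
                 n_markers_planted = as.integer(n_markers_planted),
                 has_rrna = isTRUE(has_rrna), abundance = abundance,
                 n_genes = as.integer(n_genes), rrna_taxon = rrna_taxon),
            class = "entity_spec")
}

#' Community/simulation configuration
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param entities list of [entity_spec()]s.
#' @param contig_len_meanlog,contig_len_sdlog lognormal contig-length
#'   parameters (truncated at 1 kb).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size distribution in bp.
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution probability.
#' @param qual_start,qual_end mean phred score at read start/end (linear
#'   decay between them).
#' @param mda_sigma lognormal sdlog of per-window coverage weights (MDA
#'   amplification bias); 0 gives uniform coverage.
#' @param marker_divergence amino-acid substitution rate applied to planted
#'   marker genes relative to their family consensus.
#' @param rrna_divergence nucleotide substitution rate applied to planted
#'   rRNA operons relative to the reference.
#' @param n_overlap_pairs contig pairs emitted with an exact terminal
#'   overlap (to exercise secondary assembly).
#' @param overlap_len length of that exact overlap (> 100 bp).
#' @param n_sub1kb sub-1 kb fragments emitted per entity (to exercise the
#'   size filter).
#' @return A `community_config` list.
#' @export
community_config <- function(seed, entities,
                             contig_len_meanlog = log(4e4),
                             contig_len_sdlog = 0.8,
                             read_len = 150, insert_mean = 350, insert_sd = 40,
                             n_pairs = 2e5, error_rate = 0.005,
                             qual_start = 38, qual_end = 30, mda_sigma = 1.2,
                             marker_divergence = 0.30, rrna_divergence = 0.02,
                             n_overlap_pairs = 1, overlap_len = 150,
                             n_sub1kb = 2) {
  stopifnot(is.numeric(seed), length(entities) >= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(seed = as.integer(seed), entities = entities,
                 contig_len_meanlog = contig_len_meanlog,
                 contig_len_sdlog = contig_len_sdlog,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_pairs = as.integer(n_pairs), error_rate = error_rate,
                 qual_start = qual_start, qual_end = qual_end,
                 mda_sigma = mda_sigma,
                 marker_divergence = marker_divergence,
                 rrna_divergence = rrna_divergence,
                 n_overlap_pairs = as.integer(n_overlap_pairs),
                 overlap_len = as.integer(overlap_len),
                 n_sub1kb = as.integer(n_sub1kb)),
            class = "community_config")
}

#' The default sorted-cell scenario
#'
#' One sorted "cell": a 1 Mb GC-0.45 eukaryote host carrying an 18S rRNA
#' operon, plus a 300 kb GC-0.28 giant virus carrying 30 planted ancestral
#' marker genes; 200,000 read pairs with MDA-style coverage bias.
#'
#' @param seed integer RNG seed.
#' @param n_pairs number of read pairs (default 2e5).
#' @return A [community_config()].
#' @export
community_sorted_cell <- function(seed, n_pairs = 2e5) {
  community_config(seed, list(
    entity_spec("host", "host_eukaryote", genome_len = 1e6, gc_target = 0.45,
                has_rrna = TRUE, abundance = 3),
    entity_spec("virus", "giant_virus", genome_len = 3e5, gc_target = 0.28,
                n_markers_planted = 30, abundance = 1)
  ), n_pairs = n_pairs)
}

# ---- synthetic references -------------------------------------------------

#' Synthetic ancestral-marker protein families
#'
#' A stand-in for the 47 ancestral NCLDV (NCVOG) marker alignments: each
#' family is a random consensus of 150-300 residues with `n_seqs` members
#' at ~20% divergence, plus occasional gap runs so profile construction
#' sees realistic columns.
#'
#' @param n_families number of families (default 47).
#' @param n_seqs members per family.
#' @param seed RNG seed.
#' @return named list of aligned protein character vectors (equal lengths,
#'   `-` for gaps); names are `ncvog_01` ...
#' @export
synthetic_marker_families <- function(n_families = 47, n_seqs = 8, seed = 4207) {
  set.seed(seed)
  fams <- vector("list", n_families)
  names(fams) <- sprintf("ncvog_%02d", seq_len(n_families))
  for (i in seq_len(n_families)) {
    len <- sample(150:300, 1)
    cons <- paste(sample(AA_RESIDUES, len, replace = TRUE), collapse = "")
    members <- vapply(seq_len(n_seqs), function(j) {
      s <- mutate_protein(cons, 0.20)
      if (j > 1 && stats::runif(1) < 0.3) {
        glen <- sample(3:10, 1)
        gs <- sample(len - glen - 1L, 1)
        substr(s, gs, gs + glen - 1L) <- strrep("-", glen)
      }
      s
    }, "")
    names(members) <- sprintf("%s_seq%d", names(fams)[i], seq_len(n_seqs))
    attr(members, "consensus") <- cons
    fams[[i]] <- members
  }
  fams
}

mutate_protein <- function(pep, rate) {
  r <- strsplit(pep, "")[[1]]
  hit <- which(stats::runif(length(r)) < rate & r != "-")
  if (length(hit)) {
    r[hit] <- vapply(r[hit], function(a) sample(setdiff(AA_RESIDUES, a), 1), "")
  }
  paste(r, collapse = "")
}

mutate_dna <- function(seq, rate) {
  as.character(cpp_add_errors(seq, rate))
}

#' Synthetic ranked-lineage rRNA reference set
#'
#' A small SILVA-style SSU reference: `n_genera` genera, each a distinct
#' random 1600 bp gene, with `n_per_genus` reference copies at ~2%
#' within-genus divergence. Headers carry semicolon-delimited lineages
#' (domain;phylum;class;order;family;genus).
#'
#' @param n_genera number of genera (default 4; two eukaryote, two
#'   bacterial).
#' @param n_per_genus reference sequences per genus.
#' @param seed RNG seed.
#' @return A [nuc_set()] with an extra `lineage` column.
#' @export
synthetic_rrna_refs <- function(n_genera = 4, n_per_genus = 3, seed = 1804) {
  set.seed(seed)
  doms <- rep(c("Eukaryota", "Bacteria"), length.out = n_genera)
  phyla <- c("Dinoflagellata", "Choanozoa", "Proteobacteria", "Bacteroidetes",
             "Ciliophora", "Firmicutes")[seq_len(n_genera)]
  genera <- c("Syndinium", "Bicosta", "Pelagibacter", "Flavobacterium",
              "Strombidium", "Bacillus")[seq_len(n_genera)]
  ids <- character(0); seqs <- character(0); lins <- character(0)
  for (g in seq_len(n_genera)) {
    base <- paste(sample(DNA_BASES, 1600, replace = TRUE,
                         prob = c(0.24, 0.26, 0.26, 0.24)), collapse = "")
    for (j in seq_len(n_per_genus)) {
      ids <- c(ids, sprintf("%s_ref%d", genera[g], j))
      seqs <- c(seqs, mutate_dna(base, 0.02))
      lins <- c(lins, paste(doms[g], phyla[g], paste0(phyla[g], "_cl"),
                            paste0(phyla[g], "_or"), paste0(genera[g], "aceae"),
                            genera[g], sep = ";"))
    }
  }
  out <- nuc_set(ids, seqs)
  out$lineage <- lins
  out
}

# ---- genome simulation ----------------------------------------------------

# Order-m transition matrix whose every row carries exactly `gc` mass on
# G+C: a blend between the GC-matched order-0 model and a random order-m
# signature, re-scaled so GC stays on target while the within-GC
# allocation gives each entity a distinct tetranucleotide fingerprint.
entity_transition <- function(gc, order, signature_weight = 0.7) {
  n_ctx <- max(1L, 4L^order)
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(stats::rgamma(n_ctx * 4, shape = 1.2), n_ctx, 4)
  m <- m / rowSums(m)
  m <- (1 - signature_weight) * matrix(p0, n_ctx, 4, byrow = TRUE) +
    signature_weight * m
  at <- m[, c(1, 4), drop = FALSE]; gcc <- m[, c(2, 3), drop = FALSE]
  m[, c(1, 4)] <- at * (1 - gc) / rowSums(at)
  m[, c(2, 3)] <- gcc * gc / rowSums(gcc)
  m
}

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

back_translate <- function(pep, gc_target) {
  tab <- codon_table()
  aa <- strsplit(pep, "")[[1]]
  aa <- aa[aa != "-"]
  codons <- vapply(aa, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) cods <- tab[["L"]]
    w <- vapply(cods, function(cd) {
      gcn <- sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
      gc_target^gcn * (1 - gc_target)^(3 - gcn)
    }, 0)
    sample(cods, 1, prob = w)
  }, "")
  paste(codons, collapse = "")
}

# Splice a gene cassette into the genome, replacing an equal-length slice;
# returns the updated genome and the 1-based insert interval.
plant_feature <- function(genome, cassette, occupied) {
  n <- nchar(genome); m <- nchar(cassette)
  if (m >= n) stop("genome too short to host requested features")
  for (try in 1:200) {
    s <- sample(n - m, 1)
    iv <- c(s, s + m - 1L)
    if (!any(occupied[, 1] <= iv[2] & occupied[, 2] >= iv[1])) {
      substr(genome, iv[1], iv[2]) <- cassette
      return(list(genome = genome, interval = iv))
    }
  }
  stop("genome too short to host requested features")
}

#' Simulate community genomes with planted features
#'
#' Each genome is drawn from an order-m Markov chain tuned to its GC
#' target; marker genes are planted as stop-free ORFs back-translated from
#' diverged copies of the synthetic marker-family consensi; rRNA operons
#' are planted from the ranked-lineage reference set; additional
#' protein-coding genes (with true expression weights) can be planted for
#' recruitment fixtures. All planted features are recorded in the truth
#' table.
#'
#' @param config a [community_config()].
#' @param marker_families output of [synthetic_marker_families()].
#' @param rrna_refs output of [synthetic_rrna_refs()].
#' @return list with `genomes` (named character), `truth` (list with
#'   `features`, `gene_weights`), `proteomes` (named list of planted
#'   peptides per entity).
#' @export
simulate_genomes <- function(config,
                             marker_families = synthetic_marker_families(),
                             rrna_refs = synthetic_rrna_refs()) {
  set.seed(config$seed)
  genomes <- character(0)
  feats <- list(); weights <- list(); proteomes <- list()
  for (ent in config$entities) {
    tm <- entity_transition(ent$gc_target, ent$markov_order)
    g <- as.character(cpp_markov_generate(ent$genome_len, ent$markov_order, tm))
    occupied <- matrix(numeric(0), 0, 2)
    efeat <- list()
    if (ent$n_markers_planted > 0) {
      fam_idx <- sample(length(marker_families), ent$n_markers_planted)
      for (fi in fam_idx) {
        cons <- attr(marker_families[[fi]], "consensus")
        pep <- mutate_protein(cons, config$marker_divergence)
        cds <- paste0("ATG", back_translate(pep, ent$gc_target), "TAA")
        strand <- sample(c("+", "-"), 1)
        cassette <- if (strand == "+") cds else revcomp(cds)
        pl <- plant_feature(g, cassette, occupied)
        g <- pl$genome
        occupied <- rbind(occupied, pl$interval)
        efeat[[length(efeat) + 1]] <- data.frame(
          entity = ent$name, name = names(marker_families)[fi],
          type = "marker", start = pl$interval[1], end = pl$interval[2],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    if (ent$has_rrna) {
      taxon <- ent$rrna_taxon
      if (is.null(taxon)) taxon <- sub("_ref.*$", "", rrna_refs$id[1])
      ref <- rrna_refs$seq[grep(paste0("^", taxon, "_"), rrna_refs$id)[1]]
      op <- mutate_dna(ref, config$rrna_divergence)
      strand <- sample(c("+", "-"), 1)
      pl <- plant_feature(g, if (strand == "+") op else revcomp(op), occupied)
      g <- pl$genome
      occupied <- rbind(occupied, pl$interval)
      efeat[[length(efeat) + 1]] <- data.frame(
        entity = ent$name, name = paste0(taxon, "_rrna"), type = "rrna",
        start = pl$interval[1], end = pl$interval[2], strand = strand,
        stringsAsFactors = FALSE)
    }
    if (ent$n_genes > 0) {
      w <- stats::rlnorm(ent$n_genes, 0, 1)
      peps <- character(ent$n_genes)
      for (k in seq_len(ent$n_genes)) {
        pep <- paste(sample(AA_RESIDUES, sample(120:350, 1), replace = TRUE),
                     collapse = "")
        peps[k] <- pep
        cds <- paste0("ATG", back_translate(pep, ent$gc_target), "TAA")
        pl <- plant_feature(g, cds, occupied)
        g <- pl$genome
        occupied <- rbind(occupied, pl$interval)
        efeat[[length(efeat) + 1]] <- data.frame(
          entity = ent$name, name = sprintf("%s_g%03d", ent$name, k),
          type = "gene", start = pl$interval[1], end = pl$interval[2],
          strand = "+", stringsAsFactors = FALSE)
      }
      names(peps) <- sprintf("%s_g%03d", ent$name, seq_len(ent$n_genes))
      proteomes[[ent$name]] <- peps
      weights[[ent$name]] <- data.frame(entity = ent$name, gene = names(peps),
                                        weight = w / sum(w),
                                        stringsAsFactors = FALSE)
    }
    genomes[ent$name] <- g
    feats[[ent$name]] <- if (length(efeat)) do.call(rbind, efeat) else NULL
  }
  list(genomes = genomes,
       truth = list(features = do.call(rbind, feats),
                    gene_weights = if (length(weights)) do.call(rbind, weights) else NULL),
       proteomes = proteomes)
}

# ---- contigs --------------------------------------------------------------

#' Fragment genomes into contigs
#'
#' Genomes are cut at random breakpoints into contigs with lognormal
#' lengths (minimum 1 kb); optional sub-1 kb fragments exercise the size
#' filter; `n_overlap_pairs` contigs are emitted as overlapping pairs
#' sharing an exact terminal overlap of `overlap_len` bp to exercise
#' secondary assembly.
#'
#' @param genomes named character vector from [simulate_genomes()].
#' @param config a [community_config()].
#' @return list with `contigs` (a [nuc_set()]) and `truth` (data frame
#'   `contig_id`, `entity`, `class` in `assembly`/`sub1kb`, and
#'   `overlap_mate` for planted overlap pairs).
#' @export
make_contigs <- function(genomes, config) {
  set.seed(config$seed + 2L)
  ids <- character(0); seqs <- character(0)
  entity <- character(0); class <- character(0); mate <- character(0)
  ov_budget <- config$n_overlap_pairs
  for (en in names(genomes)) {
    g <- genomes[[en]]; n <- nchar(g); pos <- 1L; k <- 0L
    while (pos <= n - 999L) {
      len <- max(1000L, round(stats::rlnorm(1, config$contig_len_meanlog,
                                            config$contig_len_sdlog)))
      len <- min(len, n - pos + 1L)
      if (n - (pos + len) < 1000L) len <- n - pos + 1L
      k <- k + 1L
      frag <- substr(g, pos, pos + len - 1L)
      if (ov_budget > 0 && len >= 2100L + config$overlap_len) {
        cut <- len %/% 2L
        a <- substr(frag, 1L, cut + config$overlap_len)
        b <- substr(frag, cut + 1L, len)
        ida <- sprintf("%s_c%03d", en, k)
        k <- k + 1L
        idb <- sprintf("%s_c%03d", en, k)
        ids <- c(ids, ida, idb); seqs <- c(seqs, a, b)
        entity <- c(entity, en, en); class <- c(class, "assembly", "assembly")
        mate <- c(mate, idb, ida)
        ov_budget <- ov_budget - 1L
      } else {
        ids <- c(ids, sprintf("%s_c%03d", en, k)); seqs <- c(seqs, frag)
        entity <- c(entity, en); class <- c(class, "assembly"); mate <- c(mate, NA)
      }
      pos <- pos + len
    }
    if (config$n_sub1kb > 0) {
      for (j in seq_len(config$n_sub1kb)) {
        len <- sample(300:900, 1); s <- sample(n - len, 1)
        k <- k + 1L
        ids <- c(ids, sprintf("%s_c%03d", en, k))
        seqs <- c(seqs, substr(g, s, s + len - 1L))
        entity <- c(entity, en); class <- c(class, "sub1kb"); mate <- c(mate, NA)
      }
    }
  }
  list(contigs = nuc_set(ids, seqs),
       truth = data.frame(contig_id = ids, entity = entity, class = class,
                          overlap_mate = mate, stringsAsFactors = FALSE))
}

# ---- reads ----------------------------------------------------------------

#' Simulate MDA-biased paired-end reads
#'
#' Fragment starts are drawn with per-window lognormal weights (window
#' 5 kb, sdlog `mda_sigma`) emulating multiple-displacement-amplification
#' coverage skew; substitution errors at `error_rate`; qualities decay
#' linearly from `qual_start` to `qual_end` with per-base noise; mate 2 is
#' reverse-complemented.
#'
#' @param genomes named character vector from [simulate_genomes()].
#' @param config a [community_config()].
#' @return list with `fwd`, `rev` ([nuc_set()]s with qualities) and
#'   `truth` (data frame `pair_id`, `entity`, `start`, `insert`).
#' @export
simulate_reads <- function(genomes, config) {
  set.seed(config$seed + 1L)
  stopifnot(config$n_pairs > 0)
  ab <- vapply(config$entities, function(e) e$abundance, 0)
  ent_names <- vapply(config$entities, function(e) e$name, "")
  n_ent <- as.vector(stats::rmultinom(1, config$n_pairs, ab / sum(ab)))
  rl <- config$read_len
  fid <- rid <- fseq <- rseq <- character(0)
  origin <- character(0); starts <- integer(0); inserts <- integer(0)
  for (i in seq_along(ent_names)) {
    np <- n_ent[i]
    if (np == 0) next
    g <- genomes[[ent_names[i]]]; n <- nchar(g)
    win <- 5000L
    nwin <- max(1L, n %/% win)
    w <- if (config$mda_sigma > 0) stats::rlnorm(nwin, 0, config$mda_sigma) else rep(1, nwin)
    wsel <- sample.int(nwin, np, replace = TRUE, prob = w)
    ins <- pmax(rl, round(stats::rnorm(np, config$insert_mean, config$insert_sd)))
    s <- (wsel - 1L) * win + 1L +
      floor(stats::runif(np) * pmin(win, n - (wsel - 1L) * win))
    s <- pmin(pmax(1L, as.integer(s)), pmax(1L, n - ins))
    ins <- pmin(ins, n - s + 1L)
    f <- substring(g, s, pmin(s + rl - 1L, n))
    r <- revcomp(substring(g, pmax(s, s + ins - rl), s + ins - 1L))
    pid <- sprintf("%s_p%06d", ent_names[i], seq_len(np))
    fid <- c(fid, pid); fseq <- c(fseq, f); rseq <- c(rseq, r)
    origin <- c(origin, rep(ent_names[i], np))
    starts <- c(starts, s); inserts <- c(inserts, as.integer(ins))
  }
  if (config$error_rate > 0) {
    fseq <- as.character(cpp_add_errors(fseq, config$error_rate))
    rseq <- as.character(cpp_add_errors(rseq, config$error_rate))
  }
  fq <- sim_quals(nchar(fseq), config$qual_start, config$qual_end)
  rq <- sim_quals(nchar(rseq), config$qual_start, config$qual_end)
  list(fwd = nuc_set(paste0(fid, "/1"), fseq, fq),
       rev = nuc_set(paste0(fid, "/2"), rseq, rq),
       truth = data.frame(pair_id = fid, entity = origin, start = starts,
                          insert = inserts, stringsAsFactors = FALSE))
}

sim_quals <- function(lens, q_start, q_end) {
  out <- character(length(lens))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    ramp <- q_start + (q_end - q_start) * (seq_len(L) - 1) / max(1L, L - 1L)
    for (chunk in split(idx, ceiling(seq_along(idx) / 5e4))) {
      noise <- matrix(stats::rnorm(length(chunk) * L, 0, 2), length(chunk), L)
      q <- pmin(pmax(round(sweep(noise, 2, ramp, "+")), 2), 41)
      out[chunk] <- apply(q, 1, function(z) rawToChar(as.raw(z + 33L)))
    }
  }
  out
}

#' Run the whole simulator
#'
#' @param config a [community_config()].
#' @param marker_families,rrna_refs synthetic references (defaults
#'   regenerated deterministically).
#' @return list with `genomes`, `contigs`, `reads`, `truth` (features,
#'   contigs, read origins, gene weights), `proteomes`, `config`.
#' @export
simulate_community <- function(config,
                               marker_families = synthetic_marker_families(),
                               rrna_refs = synthetic_rrna_refs()) {
  gen <- simulate_genomes(config, marker_families, rrna_refs)
  ctg <- make_contigs(gen$genomes, config)
  rds <- simulate_reads(gen$genomes, config)
  list(genomes = gen$genomes, contigs = ctg$contigs, reads = rds,
       truth = list(features = gen$truth$features, contigs = ctg$truth,
                    read_origin = rds$truth,
                    gene_weights = gen$truth$gene_weights),
       proteomes = gen$proteomes, config = config)
}

#' Write simulator outputs to a directory
#'
#' Emits `contigs.fasta`, `reads_R1.fastq`, `reads_R2.fastq`, `truth.tsv`
#' (contig assignments) and `features.tsv` (planted genes/rRNA).
#'
#' @param sim output of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  serialize_fastx(sim$contigs, file.path(dir, "contigs.fasta"), "fasta")
  serialize_fastx(sim$reads$fwd, file.path(dir, "reads_R1.fastq"), "fastq")
  serialize_fastx(sim$reads$rev, file.path(dir, "reads_R2.fastq"), "fastq")
  utils::write.table(sim$truth$contigs, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$features)) {
    utils::write.table(sim$truth$features, file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
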