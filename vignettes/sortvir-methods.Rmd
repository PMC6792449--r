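---
title: "Recovering giant-virus genomes from sorted-cell metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering giant-virus genomes from sorted-cell metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Flow-cytometric sorting of individual predatory eukaryotes (or small pools
of ~300 cells) followed by multiple displacement amplification (MDA) and
Illumina sequencing yields "targeted metagenomes": mixtures of a host
cell's genome, any nucleocytoplasmic large DNA virus (NCLDV, "giant
virus") infecting or attached to it, and low-level bacterial
contamination. `sortvir` implements the computational arc that turns such
a mixture into a characterized viral genome:

1. **Quality trimming** of paired reads (leading/trailing phred cutoff 3,
   truncation at the first 25-bp window with mean quality below 30,
   minimum surviving length 50 bp — the classic Trimmomatic recipe used
   for these libraries).
2. **Composition binning** of assembled contigs longer than 1 kb on
   canonical tetranucleotide frequency (TNF) and GC content.
3. **An ancestral-marker screen**: bins carrying several of the 47
   putatively ancestral NCLDV gene families and no rRNA gene are called
   viral; bins with rRNA are cellular.
4. **Sort characterization** from unassembled reads: rRNA read pairs are
   extracted (both mates must be rRNA), joined with an `N`, and
   classified with an RDP-style bootstrap naive-Bayes classifier.
5. **Genome finishing**: exact-overlap secondary assembly (> 100 bp at
   100% identity), assembly statistics (N50 etc.), fragment-based average
   nucleotide identity (ANI), and strict 99%-identity read mapping with
   coverage breadth and SNV pileup.
6. **Comparative content analysis**: orthogroup presence–absence
   clustering with bootstrap (BP) and approximately unbiased (AU) node
   support, top-ten-hit taxonomy affiliation, rhodopsin motif typing, and
   a neighbor-joining tree over concatenated markers.
7. **Competitive recruitment** of metatranscriptome reads: translated
   search against viral proteomes (bit score > 50), re-search against a
   large decoy database, retention only of reads whose single best hit is
   viral, with seeded randomization of ties.

Giant-virus genomes in this setting are low-GC (25–31%), while their
eukaryotic hosts sit substantially higher; that separation, together with
distinct tetranucleotide signatures, is what makes step 2 work.

## The synthetic community

Real sort read sets are not redistributable at desk scale, so validation
runs on a generator (`simulate_community()`) whose defaults are the study
conditions: a 1 Mb host at GC 0.45 carrying an 18S rRNA operon, a 300 kb
giant virus at GC 0.28 carrying 30 planted marker genes, and 200,000
read pairs with MDA-style coverage bias (`community_sorted_cell()`).

* **Genome composition.** Each genome is drawn from an order-3 Markov
  chain. Every transition row is a blend of a GC-matched order-0 model
  and a random per-entity signature, then rescaled so each row places
  exactly the target mass on G+C. This guarantees both axes the binning
  uses: realized GC within about ±0.01 of target, and a tetranucleotide
  fingerprint that differs between entities by more than a genome's own
  window-to-window spread.
* **Planted features.** Marker genes are drawn from synthetic stand-in
  families for the 47 ancestral NCVOG alignments (consensus plus members
  at ~20% divergence), mutated at 30% amino-acid distance, back-translated
  with GC-biased codon choice, and spliced in as stop-free ORFs on either
  strand. rRNA operons come from a synthetic ranked-lineage SSU reference
  (SILVA-style headers) at 2% divergence. All coordinates land in a truth
  table.
* **Reads.** Fragment starts are drawn with per-5-kb lognormal weights
  (sdlog `mda_sigma`, default 1.2) emulating MDA unevenness — a smooth
  weight model, not a branching-process simulation of the chemistry.
  Substitution errors at 0.5% per base; qualities decay linearly (38 to
  30) with Gaussian jitter; mate 2 is reverse complemented. Indels,
  chimeras and platform-specific error profiles are deliberately absent,
  so passing tests say nothing about indel robustness on real data.

Everything is deterministic under the configured seed.

## Design choices where the procedure was open

* **Coordinates.** All intervals are 1-based and inclusive, the R and
  Bioconductor convention, with reverse-strand features reported on
  forward coordinates plus a strand flag.
* **Binning features and cut.** TNF columns and GC are z-scored
  separately and GC enters with weight 0.1 — composition dominates, GC
  assists. The published procedure binned interactively; an automatic
  stopping rule replaces the human: the tree is cut at the largest merge-
  height gap relative to the tree height (below 5% of the range, one bin).
  `n_bins` overrides it. Contigs are sorted by id first, so binning is
  input-order invariant; depth is reported but not clustered on.
* **Marker screen.** Profile HMMs are replaced by per-family PSSMs
  (log-odds in bits, pseudocount 1, uniform background, >50%-gap columns
  dropped) scanned by a best-ungapped-segment anchor plus a banded
  (±6) affine-gap refinement. Tool-specific e-value cutoffs do not
  transfer, so significance uses an empirical null: Gumbel
  moment-fit to scores of shuffled peptides matched to the ORF length and
  composition distribution, with hits requiring null-exceedance
  probability < 1e-4 *and* ≥ 25 bits. At ~50k ORF×profile tests per
  genome this admits a handful of isolated false marker hits, which is
  why the bin verdict demands ≥ 5 *distinct* markers (the real screens
  carried ≥ 28) and why an rRNA gene always outranks markers.
* **ORF calling** is stop-to-stop (≥ 60 aa) without a start-codon model;
  marker detection tolerates N-terminal overhang.
* **rRNA detection** aligns references only against 2-kb windows that
  share ≥ 5 exact 15-mers with the reference set, then reports hits at
  ≥ 75% identity over ≥ 300 bp.
* **rRNA classifier.** Word size 8, 100 bootstraps, 0.8 confidence
  cutoff (the QIIME-era defaults). The strict per-mate confirmation
  filter is a ≥ 80-bit local alignment to the reference set, standing in
  for a database-specific e-value threshold. Words containing `N` carry
  no signal, which is what makes N-joined pairs equivalent to plain
  concatenation.
* **Secondary assembly** merges only suffix–prefix overlaps *strictly*
  longer than 100 bp at 100% identity, in either orientation, iterated to
  a fixpoint; any contig end with two qualifying partners is left alone
  and logged. The guard is deliberately conservative — never create a
  chimera silently.
* **ANI** follows the common fragment convention (1 kb fragments, ≥ 70%
  identity over ≥ 50% of the fragment, mean of both directions), since
  the original analysis does not name its ANI recipe. On a 0.7%
  i.i.d.-substituted copy of a 200 kb genome the estimator returns
  99.3 ± 0.1.
* **Read mapping** is seed-and-verify (exact 31-mer seeds at three read
  offsets, both strands, ungapped mismatch verification) with the 99%
  identity gate and the first-best-site rule for ambiguous reads. It is
  purpose-built rather than delegated to an external aligner because the
  module's contract — the exact identity gate, the ambiguity rule, and
  SNV thresholds (alternate-allele fraction ≥ 0.2 at depth ≥ 5) — must be
  controlled precisely; with substitution-only simulated reads, gapped
  alignment adds nothing. The SNV thresholds make a "less than 1 variant
  per kb" regime reproducible on 50:50 strain mixtures.
* **Orthogroups** are connected components of the ≥ 50-bit,
  ≥ 50%-coverage protein similarity graph (4-aa exact-word prefilter,
  BLOSUM62 local alignments). Components replace MCL plus reciprocal-best
  normalization because presence/absence, not fine-grained orthology, is
  what the clustering consumes.
* **AU support.** pvclust-style multiscale bootstrap is implemented
  in-package: column resampling at scales 0.5–1.4, the signed-distance
  regression `z(r) = d·sqrt(r) + c/sqrt(r)`, `AU = 1 − Φ(d − c)`. The
  distance on binary rows is Jaccard (the original's metric is unstated).
  When a bipartition is saturated (present or absent in essentially every
  replicate at nearly all scales) the regression has no signal and the
  saturated limit is reported; BP is always reported alongside AU so
  conclusions never hinge on AU numerics alone.
* **Rhodopsin typing** reads the three motif residues and the spectral
  tuning site through a local alignment to the reference alignment's
  anchor sequence. The only spectral rule asserted is methionine at the
  tuning site ⇒ green; every other residue is reported without a claim.
* **Recruitment.** The comprehensive decoy database is a labeled
  synthetic proteome — the computation under test is the competitive
  best-hit retention, not the database. A gene counts as expressed at
  ≥ 1 retained read (configurable); cross-sample comparisons correlate
  `log10(RPKM + 1)` over genes expressed in either sample.

## Numerical and degenerate-input behavior

Bit scores use fixed Karlin–Altschul constants per scoring scheme
(nucleotide +1/−2: λ = 1.28, K = 0.46; BLOSUM62 gapped 11/1: λ = 0.267,
K = 0.041); e-values are thresholds, not calibrated significance.
All-N sequences give `NA` GC; sequences shorter than k give an empty,
flagged k-mer vector; an empty assembly is an error while a single contig
is its own N50; a constant presence–absence matrix warns of a degenerate
tree; queries with fewer than 8 informative bases are unclassified; ties
everywhere break deterministically (contig id order, scan order, or a
seeded draw where the procedure specifies randomization).

## Problem sizes

The test suite and the acceptance script run the full scenario at its
stated size (1 Mb + 300 kb, 200k pairs) once, and the remaining suites on
smaller communities (60–200 kb genomes, a few thousand reads or pairs),
sizes at which every statistical check above has comfortable power.

## Known limitations

The simulator omits indels, chimeric MDA artifacts and real taxonomic
breadth, so the pipeline's behavior on diverged real references is
characterized only down to the divergences tested (markers at 30%
amino-acid distance, rRNA at a few percent, recruitment at 20% amino-acid
divergence). The marker screen is a PSSM approximation of profile HMMs
and inherits no Plan7 insert-state model. The NJ marker tree is a
topology check, not a substitute for model-based phylogenomics, which is
out of scope here.
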