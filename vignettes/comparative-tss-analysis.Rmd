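---
title: "Comparative TSS analysis between two bacterial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative TSS analysis between two bacterial genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsscompare)
library(dplyr)
```

# The analysis

`tsscompare` compares the primary transcriptomes of two related bacterial
species starting from strand-specific counts of read 5′ ends, the raw signal
of 5′-enriched RNA sequencing. The pipeline has five stages:

1. **TSS calling.** Positions carrying signal in *both* biological replicates
   become transcription start site (TSS) candidates; replicate counts are
   combined; a greedy non-maximum suppression removes weaker candidates
   within a 10-bp window of a stronger one; surviving TSSs are assigned to
   the nearest downstream gene start on the same strand, capped at 700 bp;
   within each gene, TSSs below 50% of the gene's strongest signal are
   flagged sub-threshold.
2. **Orthology.** All-vs-all global protein alignment between the two
   proteomes; pairs with at least 50% identity and 50% aligned length are
   homolog candidates, and a reciprocal-best-hit (RBH) rule reduces them to
   a one-to-one ortholog set.
3. **Promoter categorization.** Every gene-assigned TSS defines a 50-bp
   promoter immediately upstream. The promoter is locally aligned onto the
   800-bp region upstream of the orthologous gene in the other species. The
   position one base downstream of the alignment's 3′ end is the *implied*
   TSS in the partner. Depending on whether the alignment passes a
   conservation test, whether a partner TSS sits within 2 bp of the implied
   position, and whether the reciprocal alignment points back at the
   original TSS, the promoter is classified CPT (conserved, with matching
   TSS), CPNT (conserved, no matching TSS), OP (orphan: TSS but no conserved
   sequence), or SSP (species-specific gene).
4. **5′ UTR and sequence statistics.** CPT pairs define comparable 5′ UTR
   pairs (TSS to start codon), from which length correlation (R²), the
   equal-length fraction, and mean percent identity are computed; ortholog
   CDS pairs yield an anchored conservation profile across ±100 nt of the
   translation start and per-codon-position conservation; the TSS set yields
   base preferences at offsets −5..+5 (purine enrichment at +1, pyrimidine
   at −1).
5. **sRNA discovery.** Each annotated sRNA of species A is searched for in
   species B inside the interval bounded by the orthologs of its nearest
   ortholog-bearing neighbours (synteny), on both strands; hits passing
   identity and coverage thresholds are *expressed* when a B TSS lies within
   2 nt of the hit's 5′ end.

# Key parameters

All thresholds live in `pipeline_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `noise_window` | 10 | nt | suppression radius between retained TSSs |
| `multi_tss_frac` | 0.5 | fraction | per-gene multiple-TSS retention cutoff |
| `max_tss_gene_dist` | 700 | nt | TSS-to-start assignment cap |
| `promoter_len` | 50 | nt | promoter region length |
| `upstream_search_len` | 800 | nt | partner upstream search window |
| `tss_match_tol` | 2 | nt | implied-position-to-TSS tolerance |
| `dataset_match_tol` | 3 | nt | whole-dataset comparison tolerance |
| `ortholog_min_identity` / `ortholog_min_aligned` | 50 / 50 | % | orthology cutoffs |
| `promoter_conserved_min_identity` | 0.60 | fraction | conservation test identity |
| `promoter_conserved_min_cols` | 0.5 | of `promoter_len` | conservation test span |
| `srna_min_identity` / `srna_min_coverage` | 0.60 / 0.60 | fraction | sRNA hit acceptance |
| `srna_tss_tol` | 2 | nt | sRNA 5′-end-to-TSS tolerance |

The window, fraction, distance and tolerance values above are the analysis
conventions for replicated bacterial 5′-end tag data. The promoter
conservation threshold (≥ 60% identity over at least half the promoter
length) and the sRNA acceptance thresholds are this package's own defaults:
no published value exists for these steps, and 60%/25 columns cleanly
separates genuinely copied 50-mers from the best chance local alignment
between unrelated sequences under the default scoring (match +2, mismatch
−3, gap −5/−2). Both are configurable.

# Design choices where the procedure was open

* **Combined counts.** Replicate counts are summed (configurable to mean);
  summing preserves integer read evidence and keeps the multiple-TSS
  fraction interpretable.
* **Suppression semantics.** "Strongest signal within a 10-bp window" is
  implemented as greedy non-maximum suppression: candidates are visited in
  decreasing combined count (ties: lower coordinate) and kept only if every
  already-kept TSS on that strand is at least `noise_window` away; a spacing
  of exactly 10 survives. Reconciliation runs before suppression, so a
  position must replicate before it can suppress anything.
* **Internal TSSs.** A TSS downstream of a gene's start is never assigned to
  that gene (distance must be ≥ 0); assignment ignores intervening genes, so
  a TSS inside an upstream gene's coding region can still serve the next
  gene — as real operon-internal promoters do.
* **Percent aligned.** The denominator of the percent-aligned score is the
  longer of the two sequences (configurable to the query); the numerator is
  the number of gap-free alignment columns. Percent identity divides
  identical columns by all alignment columns, internal gaps included, and
  `N` never counts as identical.
* **Implied TSS position.** The promoter's 3′ terminus abuts its TSS by
  construction, so the implied partner position is one base downstream
  (in the gene's direction) of the local alignment's 3′ end in the upstream
  window.
* **CPT reciprocity failure** falls through to the CPNT test using the
  matched upstream segment, rather than terminating at OP: a conserved
  sequence whose partner TSS fails the back-check is still a conserved
  promoter without a (confirmed) matching TSS.
* **Multiple partner TSSs.** The candidate nearest the implied position is
  tested first; at equal distance the stronger TSS wins. One partner TSS may
  be the CPT partner of several promoters (logged as multiplicity, not an
  error).
* **Clipped windows.** An upstream window shorter than `promoter_len`
  (contig edge) disqualifies the TSS from categorization with an explicit
  flag rather than producing a category from insufficient sequence.
* **Conservation profile.** The ±100-nt profile around the translation start
  is compared ungapped and anchored at the start codon, over ortholog pairs
  whose global CDS alignment has no gap in the first three codons
  ("clearly aligned" starts). Anchoring is exact at the anchor and avoids
  projecting positions through alignments whose gaps would blur the
  Shine–Dalgarno region.
* **R²** is the squared Pearson correlation of the paired UTR lengths; it is
  undefined (flagged `NA`) below two pairs or at zero length variance.
* **Orthology pairing.** All threshold-passing pairs are reported, but
  promoter categorization and UTR pairing use the one-to-one
  reciprocal-best subset (ties broken by percent aligned, then partner id):
  categorization needs an unambiguous partner gene. sRNAs are never
  orthology nodes; they are paired by the synteny search.
* **Missing synteny flank.** When an sRNA has an ortholog-bearing neighbour
  on only one side, the search interval extends 10 kb from the present
  ortholog (clipped to the contig) — bounded search instead of a
  genome-wide scan.
* **Alignment engine.** Global (Needleman–Wunsch) and local
  (Smith–Waterman) affine-gap dynamic programming via Biostrings, with
  deterministic traceback. Gap convention: a gap of length L costs
  `gap_open + L × gap_extend`. Protein scoring is BLOSUM62 (−11/−1);
  "identity" means exact residue match throughout.

# What the simulator emulates — and what it does not

`simulate_genome_pair()` builds both genomes on a fixed slot grid (one gene
or sRNA per ~1.4-kb slot) so that features never overlap and every gene
keeps a free 800-nt upstream window. Orthologous CDS pairs derive from a
common ancestor by codon-aware mutation: non-synonymous replacement at
`protein_divergence` (default 0.05) plus synonymous third-position swaps at
`syn_rate` (0.3), which makes third codon positions the least conserved, as
in real coding sequence. Species-specific genes come in "decoy" pairs at
`decoy_divergence` 0.7 — near-miss homologs that must not pass the 50/50
orthology cutoffs. Promoter categories are planted literally: CPT copies the
50-bp promoter (mutated at `promoter_divergence`, default 0.1) immediately
upstream of a planted partner TSS, and also copies the start-codon-proximal
part of the 5′ UTR at the same divergence — partner UTRs are conserved where
they overlap, with extra length appearing as an unrelated 5′ extension, the
way comparable UTRs of different lengths behave between related strains;
CPNT copies the promoter to a phantom position
150–400 nt upstream of the partner's start with no TSS there; OP leaves the
partner upstream random; SSP plants TSSs on species-specific genes. Planted
TSS counts are negative binomial (mean 20, size 5, truncated at 1) in both
replicates; noise positions are Poisson-placed (0.5/kb) *independently per
replicate* with geometric counts, so the both-replicates rule is the
operative noise filter exactly as intended. sRNAs (120 nt, 10% divergence)
sit between ortholog-bearing genes with TSSs planted at both 5′ ends, and
are annotated only in species A. UTR lengths are drawn from 20–120 nt with a
small leaderless fraction (0.05) and correlated partner lengths; 10% of gene
TSSs get a secondary TSS 15–40 nt further upstream to exercise the
multiple-TSS rule.

The simulator deliberately does **not** emulate: operon structure and
internal/antisense TSSs, sequencing-error or fragment-length models,
compositional bias (backgrounds are i.i.d. uniform), overlapping genes,
genome rearrangements (orthologs stay collinear, so the synteny search is
always well-posed), or condition-dependent expression. Passing the planted-
truth tests therefore demonstrates the correctness of the algorithms under
the stated statistical conditions, not performance on real libraries, where
mapping artefacts, processed 5′ ends and antisense transcription add error
modes the simulation excludes.

# Numerical and degenerate-input behaviour

Ties in suppression break toward the lower coordinate; ties in RBH selection
break by percent aligned then lexicographic id; the primary TSS of a gene is
the strongest retained one, ties toward the lower coordinate. Empty
candidate sets, empty ortholog sets (everything becomes SSP, with a
warning), leaderless UTR pairs (identity flagged `NA`), sub-2-pair R²
(`NA` with a warning), CDS lengths not divisible by three (trailing bases
ignored, warning), and local alignments with no positive-scoring cell
(`NULL`) are all defined rather than accidental. Coordinates are 1-based
inclusive everywhere inside the package; BED/bedGraph conversion happens at
the file boundary, and fractional or negative track counts are rejected.

# Problem sizes

The reference simulation used by the acceptance checks is two species × 200
genes on 300 kb with category mix {CPT 40, CPNT 20, OP 20, SSP 20}, eight
planted sRNAs, and two replicates — large enough that every stage runs on
hundreds of features, small enough to run end to end in a few minutes on one
CPU. Unit tests use 10–40-gene simulations and hand-built micro-fixtures.
The alignment engine is validated against exhaustive enumeration of the
alignment space on random pairs up to length 8, and the estimator
calibrations (dinucleotide preference, codon-position conservation) run at
n = 1000 against three-binomial-standard-error bands.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 42)
truth <- simulate_genome_pair(cfg)
tracks <- simulate_count_tracks(truth)

tss_a <- call_tss(tracks$a[[1]], tracks$a[[2]], truth$genes_a)
tss_b <- call_tss(tracks$b[[1]], tracks$b[[2]], truth$genes_b)

cmp <- compare_species(tss_a, tss_b, truth$genes_a, truth$genes_b,
                       truth$genome_a, truth$genome_b,
                       truth$proteome_a, truth$proteome_b)
glance(cmp)
plot_category_summary(cmp$category_summary)
plot_utr_lengths(cmp$utr_pairs)
```

# Known limitations

Categorization accuracy degrades gracefully with promoter divergence: local
alignment trims mismatched promoter ends, which can shift the implied
position past the 2-bp tolerance for a few percent of planted conserved
promoters at 10% divergence (they fall to CPNT or OP). The sRNA search
assumes flanking synteny; a translocated sRNA is invisible to it. The
orthology stage is purely pairwise — no phylogeny, no paralog resolution
beyond RBH. And because the acceptance checks run on synthetic data, they
bound algorithmic correctness, not biological recall on real strains.
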