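---
title: "Mining prostaglandin-pathway enzymes from annotated transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prostaglandin-pathway enzymes from annotated transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmine)
```

## The mining model

`pgmine` screens assembled, Swiss-Prot-annotated transcriptomes for the
enzymes of prostaglandin (Pg) metabolism. The method deliberately trusts
the precomputed annotation tables — there is no BLAST or HMM search in the
pipeline — and rests on three assumptions:

* a transcript's Swiss-Prot hit *description* is informative enough to
  recognize a pathway enzyme by name;
* redundant transcripts of one gene (assembly isoforms, strain variants)
  are near-identical at the amino-acid level and can be collapsed by an
  identity threshold;
* relative expression is adequately summarized by FPKM computed from the
  per-contig mapped read-pair counts shipped with each assembly.

The unit of input is the *bundle*: one transcriptome's directory holding a
peptide FASTA (`pep.fa`), an annotation table (`swissprot.gff3` or
`annotations.tsv`), a read-count table (`contig.dat`) and a YAML metadata
sidecar, optionally a nucleotide FASTA and `stats.txt`. A `cds.dat` file,
when present, is accepted and ignored — nothing downstream consumes it.

**A note on `contig.dat`.** There is no public schema for this file's
columns, so the package defines its own explicit layout and documents it
prominently: tab-separated `transcript_id`, `length_bp`,
`mapped_read_pairs`, preceded by a `#total_read_pairs<TAB>N` sidecar line
carrying the library size. `write_bundle()` emits exactly this layout and
`read_bundle()` validates it line by line (negative or non-integer counts
are fatal, with the offending line number).

## The vocabulary gate

The search is a two-stage filter. First, a case-insensitive substring
query (default term `"prostaglandin"`) of the annotation descriptions;
second, canonicalization of each hit against the nine-function controlled
vocabulary (six synthesis enzymes: COX2, HPGDS, PTGES2, PGE2-9-OR, PTGFS1,
PTGFS2; three catabolic: 15-PGDH, PTGR1, PTGR2). Canonicalization tries
synonyms longest-first so that e.g. "Prostaglandin F synthase 1" can never
be claimed by a shorter, more generic synonym, and a synonym claimed by
two codes is rejected at load time.

The term query alone is *not* sufficient: Swiss-Prot also contains
prostaglandin transporters and receptors. Such hits match the term but no
synonym; they are retained in an unmapped report (`unmapped_hits()`)
rather than silently dropped, so the vocabulary itself stays auditable.
Matching uses only the description field — not accessions, not
coordinates. Coordinates are carried through verbatim (1-based inclusive,
as in GFF3) but unused by the mining logic. A transcript annotated with
two *different* pathway functions keeps both assignments; duplicate
(transcript, function) pairs collapse to one.

## Identity and clustering

Redundancy is removed by greedy incremental clustering in the CD-Hit
style. Sequences (peptides — clustering operates on `pep.fa` content) are
processed by decreasing length, ties broken by ascending id, which makes
the algorithm fully deterministic; each sequence joins the first existing
cluster whose *representative* it matches at or above the threshold, else
founds a new cluster. Representatives ("heads") are therefore always a
longest member of their cluster.

Identity between two sequences is defined as the maximal number of
identical aligned residues under a global alignment scored match = 1,
mismatch = 0 and zero linear gap penalty, divided by the length of the
**shorter** sequence. With that scoring the optimum equals the longest
common subsequence, which a small C++ dynamic program computes exactly; no
heuristic prefilter is applied, so the incremental path and the
brute-force all-pairs oracle (`brute_force_cluster()`, the independent
validation route used throughout the tests) must agree identically. The
shorter-length denominator is stated explicitly because it changes cluster
counts: a perfect fragment of a longer sequence has identity 1. The
default threshold is 0.90 amino-acid identity, CD-Hit's default,
configurable in every entry point.

Clustering is grouped two ways, for two purposes:

* **per (species, function)** — pooling a species' replicate
  transcriptomes — for the before/after cluster report (`sp_count`,
  `cdhit_count`), i.e. "how many independent genes carry this function in
  this species";
* **per (transcriptome, function)** for head selection in expression
  summation. Heads chosen at species level live in a single
  transcriptome's id space, so head-mode FPKM sums for the sibling
  replicates would silently vanish; per-transcriptome grouping keeps one
  head per replicate.

A pooled, ungrouped run feeds `cross_species_purity()`, which reports per
cluster whether all members share one species and one function.

## Expression

FPKM is evaluated exactly as
`mapped_read_pairs / (length/1000) / (total_read_pairs/1e6)`; zero-length
transcripts or empty libraries are errors, not NaNs. Read counts are
treated as fragment (pair) counts throughout; single-end data is an input
property, not a computation change. Per function and transcriptome the
FPKM values of the contributing transcripts are summed, on the view that
the expression of a *function* is the sum over all genes expressing it.
Which transcripts contribute is genuinely ambiguous — heads only, or every
assigned transcript — so both modes are implemented and tested
(`mode = "heads"`, the default since downstream analysis works on heads,
and `mode = "all"`); no claim is made about which mode matches any
particular published heatmap.

Absence is not zero: a function with no assigned transcript yields *no*
expression record, and the expression matrix encodes it as a missing cell.
Heatmaps render missing cells in a reserved grey (`#BFBFBF`) outside the
expression color ramp, and an optional `log10(x + 1)` transform keeps
zeros finite. Presence matrices follow the same discipline; their columns
are always the nine vocabulary codes in fixed canonical order, and rows
with no annotated function are dropped (the explicit
`species_with_any()` count is kept for matrices built without dropping).

Assembly statistics use the classical N50: sort lengths descending and
take the length at which the cumulative sum first reaches half the total
assembly length. Species are counted as distinct (genus, species) pairs,
so a basionym pair recorded under two genera — *G. foliaceum* /
*K. foliaceum* in the bundled survey — counts as two species rows, as the
source tables do.

## What the synthetic generator emulates

`generate_bundles()` builds a study with known truth. Its default
configuration is the package's reference condition: 3 species × 2
replicate transcriptomes, 4 planted functions per species (rotating
through the nine codes so species differ), one gene per function with 3
transcript copies at 0.95 identity to the original, 50 decoy transcripts
per transcriptome of which 10% carry near-miss term-matching descriptions,
planted expression mean 200 mapped pairs (decoys 50), dispersion 0.3,
library size 10^6 pairs, 300-aa peptides.

Choices worth stating:

* **Count model.** Counts are gamma-mixed Poisson with variance
  `m + dispersion * m^2`, so replicate-to-replicate irreproducibility —
  a prominent feature of real multi-replicate transcriptome sets — can be
  emulated and dialed. `dispersion = 0` is deliberately *fully
  deterministic* (`count = round(mean)`), not Poisson, so that degenerate
  replicates are exactly equal — the property the expression-matrix tests
  rely on.
* **Fixed library size.** `total_read_pairs` is held at its configured
  value rather than resampled, so the expected FPKM of a planted
  transcript is exactly analytic (`m / (L/1000) / (T/1e6)`) and
  expression-recovery tests can use real standard errors around a closed
  form.
* **Copy structure.** The original peptide of each gene is drawn once per
  species and shared across replicates; copies substitute exactly
  `round((1 - identity) * length)` positions (no indels), so two sibling
  copies at identity 0.95 sit at mutual identity ≥ 0.90 — right at the
  default threshold, by construction on the conservative side.
  Transcript ids are assigned so the unmutated original sorts first and
  becomes the head under the deterministic tie-break.
* **Annotations.** Planted transcripts draw their description from the
  term-containing synonyms of their function (as real Swiss-Prot protein
  names would); abbreviations like "COX2" are excluded because a term
  query of a real annotation table would not retrieve them. Decoys draw
  from ribosomal/photosystem-style background names; near-miss decoys from
  transporter/receptor names that must *not* canonicalize.
* **No biological realism in sequence content.** Peptides are uniform
  random strings: only the identity structure matters downstream. The
  generator does not simulate reads, sequencing error, assembly artifacts,
  chimeras, or annotation error (a planted transcript is always annotated
  with its own function). Passing the recovery suites therefore
  demonstrates the correctness of the mining logic under its stated
  assumptions — not robustness to mis-annotation or mis-assembly in real
  data.

## Test and validation scale

The suites run at desk scale, sized for a single CPU: the clustering
oracle equivalence uses 200 random instances of ≤ 30 sequences (20–60 aa)
at thresholds {0.7, 0.8, 0.9, 0.95}; end-to-end recovery runs the default
configuration over 20 seeds and requires the planted presence matrices and
per-gene cluster counts exactly; expression recovery uses 200 replicate
transcriptomes and accepts the empirical mean within 3 standard errors of
the analytic expectation; N50 is checked against an independent
formulation on 300 random length lists. The bundled survey tables
(42 transcriptomes / 15 genera / 19 species; 14 species with at least one
annotated function) are asserted exactly.

## Known limitations

* The pipeline inherits every limitation of the upstream annotation: an
  enzyme absent from the annotation table is invisible, however highly it
  may be expressed (low expression, small assemblies and missing
  replicates all translate into absent annotations).
* The vocabulary is intentionally strict; true pathway enzymes annotated
  under names outside the synonym lists would land in the unmapped report
  rather than the presence matrix. The report is the audit trail for
  extending the vocabulary.
* Greedy clustering is order-dependent by nature; the deterministic
  length/id ordering makes results reproducible but, as with CD-Hit, they
  are not guaranteed to be optimal partitions.
* FPKM is a within-transcriptome summary; no cross-library normalization
  or differential-expression statistics are attempted, and none should be
  read into the heatmaps.
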