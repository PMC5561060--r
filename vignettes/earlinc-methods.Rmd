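---
title: "Methods: lncRNA discovery and prioritization in the inner ear"
author: "earlinc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and prioritization in the inner ear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlinc)
```

# Scope

`earlinc` implements the computational stages of a long non-coding RNA
(lncRNA) catalogue study of the mouse inner ear sensory epithelium: the
cochlea (organ of Corti) and vestibule sampled at embryonic day 16.5 and at
birth, 2 tissues x 2 stages x 3 replicates. Starting from an assembled
transcriptome, the package filters and classifies candidate transcripts,
flags novel loci, profiles expression and tissue specificity, screens for
differential expression, links mouse lncRNAs to human counterparts by
sequence similarity and synteny, and prioritizes candidates near deafness
genes. Read alignment, transcript assembly and isoform quantification are
upstream of this package and out of scope; the package consumes their
outputs (a GTF, a count matrix, a precomputed coding-potential table).

Because the raw study data and the exact annotation releases are not
required here, every input can instead be produced by the synthetic-data
generator with planted ground truth, and the whole analysis is validated
end to end against that truth.

# Coordinates and containers

All internal coordinates are 0-based half-open; GTF input/output converts
from/to the 1-based inclusive convention and BED is consumed natively. This
removes any off-by-one ambiguity from overlap and distance arithmetic. The
central containers are the `transcript_set` (validated exon table plus a
per-transcript summary: span, exon count, mature length, biotype) and the
`gene_set` (genes as groups of transcripts). Interval joins are performed
with `GenomicRanges`/`IRanges`; the test suite checks them against an
independent per-base brute-force oracle written in base R.

# Transcript classification

A candidate transcript receives exactly one category, decided in a fixed
order:

1. mature length <= 200 nt: `excluded_short` (a lncRNA must exceed 200 nt);
2. maximum FPKM across the twelve samples below the expression floor
   (default 0.1 FPKM): `excluded_low_expression`;
3. exonic overlap with a protein-coding gene on the *same* strand:
   `excluded_coding` (keeps the lincRNA class strictly intergenic);
4. exonic overlap with a coding gene on the *opposite* strand: `antisense`;
5. containment within a coding gene's span on the same strand without
   exonic overlap (i.e. inside an intron): `excluded_intronic_same_strand`
   — such transcripts are notoriously hard to annotate reliably;
6. an annotated small RNA inside the transcript's span (exon or intron):
   `small_rna_host`;
7. otherwise `lincRNA` (long intervening non-coding RNA).

Before classification, the coding-potential filter drops transcripts whose
precomputed assessment shows a long open reading frame (default >= 100
codons), a protein/domain homology hit, or a codon-substitution-style score
at or above the cutoff (default 0, i.e. positive scores are coding-like).
The assessment is consumed as a table because the underlying evidence
(protein homology searches, cross-species codon substitution patterns)
comes from external tools; the ORF length itself can be recomputed from a
transcript sequence with `find_orfs()`, which scans all three frames of the
sense strand for complete ATG-to-stop frames. Transcripts with no usable
assessment are routed to a `needs_assessment` report rather than silently
kept. These thresholds are deliberately configuration-exposed: upstream
pipelines differ in their exact cutoffs, so the defaults are declared
rather than hard-coded assumptions.

Genes are the transitive closure of same-strand exonic overlap between
transcripts (`any_overlap`, a span-based strand-blind relation, is
available for conservative comparisons). Gene-level categories use the
precedence `small_rna_host > antisense > lincRNA`; genes whose transcripts
are all excluded are excluded. A gene is *novel* when none of its exons
overlaps a reference lncRNA transcript; the default compares either strand,
a conservative reading of "does not overlap the reference annotation", with
a strand-restricted mode available.

Two classification subtleties deserve a note. First, step 3 (same-strand
exonic overlap with coding) is not always listed as part of this taxonomy's
decision order, but without it a transcript sharing exons with an mRNA on
its own strand would fall through to `lincRNA`; routing it to
`excluded_coding` keeps the intergenic class honest. Second, strand `"."`
is accepted on input but treated as incomparable in strand-aware tests
(overlap 0, with a warning) rather than as a wildcard.

# Expression

Counts convert to FPKM by the closed form
`fpkm = counts * 1e9 / (library_size * gene_length)` with the library size
taken as the column sum. Tissue specificity against a multi-tissue panel is
the number of samples with FPKM >= 1 (inclusive; panel figures use
"FPKM >= 1" while a strict ">" also circulates — the inclusive reading is
used and the difference is negligible away from the exact boundary).

The differential-expression screen is a documented stand-in for a
negative-binomial GLM fit: median-of-ratios size factors, a two-sided test
on `log2(normalized + 1)`, Benjamini–Hochberg adjustment, and the
significance rule `adjusted p < 0.05` with at least a two-fold change. The
default test moderates per-gene variances toward the mean–variance trend
(limma's empirical-Bayes machinery applied to the log-normalized values).
The plain Welch t-test (`method = "welch"`) is retained, but at the study's
group size (n = 3) its 2–4 residual degrees of freedom leave planted
four-fold changes with p-values right at the BH threshold, and sensitivity
collapses to ~0.2; variance moderation is the field's standard remedy for
exactly this regime and restores sensitivity above 0.9 while keeping the
empirical FDR under the nominal level (both are measured by the acceptance
suite rather than asserted). The fold change is computed from normalized
group means with a pseudocount of 1 and is not shrunken.

Pearson correlation (with the standard two-sided t test) backs both the
cis-candidate screen and ad-hoc comparisons; the screen correlates
`log2(FPKM + 1)` by default, since raw FPKM correlations are dominated by
the heavy right tail. Constant profiles are flagged, not reported as zero
correlation. Sample-structure diagnostics use Euclidean distances on
`log2(FPKM + 1)`, average-linkage hierarchical clustering, and PCA on
centered (unscaled) log values; qRT-PCR validation data are reduced with
the 2^-ddCt method against a reference gene and a calibrator sample (the
newborn cochlea in the study design).

# Orthology

Sequence evidence comes from a BLASTN-style tabular hit table filtered at
>= 60% identity and e-value <= 1e-5 (declared defaults; the thresholds are
configuration-exposed), deduplicated to the best bit score per gene pair.

Synteny evidence uses 1:1 orthologous coding genes as anchors. For a mouse
lncRNA, the nearest anchored genes upstream and downstream are located; a
human lncRNA is a candidate when it lies between the human orthologs of
those two anchors *and* the two orthologs are adjacent anchors on their
human chromosome. The adjacency requirement is this package's
operationalization of conserved gene order: without it, any two orthologs
— however far apart after a rearrangement — would still define a candidate
window, and randomly shuffled anchors would keep producing spurious
"syntenic" pairs. The synteny score is `1/(1 + k)` with `k` the number of
competing human lncRNAs in the same window.

Candidates merge per pair (evidence union, best scores) and are resolved to
a 1:1 matching greedily under a total order: both evidence types beat
sequence-only beats synteny-only, then higher similarity score, then higher
synteny score, then lexicographic ids. Greedy resolution with a total
deterministic order is simple, reproducible, and adequate at the scale of
this screen; the test suite verifies on exhaustive small instances that the
output is a maximal matching consistent with that order.

Resolved pairs are clustered into three expression groups. Each pair's
feature vector concatenates its mouse and human `log2(FPKM + 1)` profiles
after standardizing each sample column *across pairs*. Column
standardization (rather than z-scoring each profile) is deliberate: the
three groups of interest differ primarily in expression *level*
(high-in-both, high-in-mouse-only, low-in-both), and per-profile z-scoring
would erase exactly that signal. Average-linkage hierarchical clustering on
Euclidean distance is cut at k = 3 and groups are renumbered by descending
mean human expression, so group 1 is the highest-in-human group.

# Candidate prioritization

Every lncRNA gene within 4 Mb (span-to-span, 0 for any overlap) of a
disease gene — genes annotated to impaired hearing (MP:0006325) or deafness
(MP:0001967) — becomes a candidate record, labelled by the first matching
relationship: the disease feature inside an intron of the lncRNA
(`host_in_intron`, e.g. a microRNA hosted in a lincRNA intron); span
containment (`within`/`contains`); opposite-strand exonic overlap
(`antisense`); head-to-head 5' ends within 1 kb pointing apart
(`overlapping_divergent` — the window is configurable since "divergent" has
no universal definition); otherwise `proximal` with the distance. The
host-in-intron test is restricted to *introns* (not the whole span) so that
containment within exons remains distinguishable as `contains`. Distances
are measured between gene spans, matching how such distances are usually
tabulated; whether a TSS-to-TSS convention was intended is unknowable from
a distance column alone, and the span convention is the more conservative
(never larger) of the two.

The correlation screen fills each record with Pearson R and p across the
twelve samples and calls `positive` (R > 0.3, p < 0.05), `negative`
(R < -0.3, p < 0.05) or `none`; records with a gene missing from the
matrix are flagged `no_expression`, never dropped, so the four calls
partition the records.

Human deafness loci (hg19-style intervals) map to mouse coordinates by
linear interpolation inside anchor blocks, with the fraction reversed for
inverted blocks; endpoints outside every block snap to the nearest block
edge with a flag, and endpoints landing on different mouse chromosomes
yield a split report instead of an interval. Interpolation inside anchor
blocks is a deterministic, dependency-free alternative to chain-file
liftover, and is exact (round-trip identity) when paired blocks have equal
lengths — which the generator guarantees; for real unequal-length blocks
the round-trip error is bounded by the block length ratio. Mapped loci are
intersected with lncRNA gene spans.

# The synthetic study generator

`sim_config()` fixes the emulated conditions; `generate_annotation()` lays
out a mouse genome of protein-coding genes (4–5 exons each) separated by
80–200 kb intergenic gaps, and plants one feature per gap: lincRNAs and
antisense transcripts with 2–3 exons, small-RNA hosts with 4–5 exons and
the small RNA centered in a long intron, divergent head-to-head lincRNAs
100–800 bp from a coding 5' end, plus the planted exclusion classes
(short, intronic-same-strand, coding-like, low-expression). Placement
keeps >= 1 kb margins so every planted label is geometrically unambiguous —
that is what makes "zero confusion" a meaningful acceptance property. The
deliberately margin-free counterpart, `simulate_adversarial_transcripts()`,
exists only to stress the classifier against the per-base oracle.

A mirrored human genome provides equal-length anchor blocks (a quarter
inverted), human lncRNA orthologs placed syntenically between the anchors
flanking their mouse counterpart, sequence-only orthologs placed in
windows that mirror empty mouse gaps, and decoy human lncRNAs likewise
confined to empty windows. The default geometry therefore plants at most
one candidate per window; competing candidates are exercised separately in
unit tests. `shuffle_human_anchors()` permutes the human anchor positions,
rejecting permutations that conserve any mouse adjacency, so shuffling
provably destroys all synteny evidence.

Counts are negative-binomial (dispersion 0.1) around log-normal baseline
FPKM with class medians 0.3 (lncRNA) and 5.9 (coding) — the order-of-
magnitude gap characteristic of lncRNAs. Expressed-class baselines are
floored at 0.2 FPKM; since the floor sits below the median, the median is
untouched, while planted expressed genes stay clearly above the 0.1 FPKM
classification floor (planted low-expression genes sit at 5e-4 FPKM).
A background transcriptome of 20,000 unannotated genes (log-normal FPKM,
median 12; log-normal lengths, median 2.5 kb) carries the bulk of the
library so that recomputed FPKM lands on the same scale as the planted
baselines — without it, a ~100-gene matrix would concentrate the whole
library mass and inflate FPKM a thousand-fold. Planted differential genes
get a 2^2 multiplier in the cochlea (random sign); planted cis pairs share
a per-sample latent log2 factor (sd 2) that induces a log-scale
correlation near 0.9; ~30% of the transcriptome receives structured
condition effects (a dominant tissue axis, a weaker stage axis, mirroring
the study's PCA structure); library sizes jitter by ±30%. The specificity
panel spans 66 samples with 46% of lncRNAs silent everywhere and 15%
ubiquitous. Ortholog pairs follow three expression archetypes
(high/high, high-mouse/intermediate-human, low/low) across the 12 mouse
and 6 human samples.

Everything is deterministic given the seed; derived stages consume fixed
offsets of it, so equal seeds give byte-identical files.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: realistic splice-isoform complexity and
ambiguous gene models, mapping/assembly artifacts, GC and length biases in
quantification, batch effects, overdispersion heterogeneity across genes,
sequence evolution (similarity hits are drawn, not aligned), and genuinely
ambiguous synteny (overlapping or nested anchor blocks). Results on real
data will degrade in proportion to those factors.

# Numerical and engineering choices

* Degenerate inputs: zero-variance genes under the Welch test get p = 1
  (equal means) or 0; all-zero genes are reported untested (p = NA), never
  dropped; constant correlation inputs are flagged.
* All id-based orderings use radix (C-locale) sorting, so outputs are
  byte-identical across platforms and locale settings.
* Greedy tie-breaks everywhere are total (ids as the final key), making
  reruns reproducible; the pipeline writes a manifest with row counts and
  MD5 checksums and two runs on the same inputs are byte-identical.
* Validation sizes: the classifier oracle runs on 2,000 adversarial
  transcripts; the DE calibration uses 50 replicates of 200 genes (20
  planted at |log2FC| = 2, dispersion 0.1, n = 3 vs 3) plus 100 null
  replicates; the correlation calibration 100 replicates of planted
  r = 0.9 pairs at n = 12; orthology recovery 57 syntenic + 6
  sequence-only planted pairs; liftover 1,000 random intervals; structure
  recovery 12 samples from 4 centroids. These sizes give stable pass/fail
  behaviour at the stated tolerances while keeping the full suite around a
  minute on one core.

# Known limitations

* The DE stand-in is not a negative-binomial GLM: no dispersion shrinkage
  on the count scale, no shrunken fold changes; genes with very low counts
  rely on the log-scale moderation behaving sensibly.
* The synteny rule (flanking-anchor containment with conserved adjacency)
  is one operationalization among several; real rearrangement landscapes
  (nested inversions, anchor loss) will need the `require_adjacent` and
  window parameters revisited.
* Interpolation liftover is only as good as the anchor blocks; it is not a
  substitute for chain-based liftover on real genomes.
* Relationship labels depend on annotated gene spans; unannotated
  alternative promoters can turn a `proximal` pair into a truly divergent
  one without the label changing.
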