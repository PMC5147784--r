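---
title: "Methods: comparative alternative-splicing analysis in splicecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative alternative-splicing analysis in splicecomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecomp)
```

# Scope and data model

`splicecomp` implements the analysis layer of a multi-species,
multi-tissue splicing study: given per-species transcript annotations,
per-sample count tables (splice-junction, exon-body and gene counts)
and pairwise alignment-overlap orthology tables, it quantifies
expression and percent-spliced-in (Ψ), resolves 1:1 orthologs, and
computes the comparative statistics (correlation clustering, PCA,
Jensen–Shannon divergence, sex-bias ΔΨ, maternal/zygotic contrasts).
Read processing, alignment, transcript assembly and whole-genome
alignment are upstream of this package and are consumed only through
their tabular products.

All internal coordinates are 0-based half-open, so lengths and junction
arithmetic need no ±1 corrections; GTF I/O converts to and from the
1-based inclusive convention, and the conversion is an exact bijection
(round-trip tested on generator output). Strand is stored but event
enumeration works on genomic coordinates; the 5′/3′ labels of
alternative splice sites are resolved from strand at classification
time, which keeps all strand logic in one place.

# Event enumeration

Events are coordinate patterns over a gene's transcripts, deduplicated
gene-wide:

* **SE** — exons A–B–C consecutive in one transcript while the junction
  A→C (identical donor and acceptor) exists in another; the target is
  B.
* **A5SS/A3SS** — two junctions sharing one splice site and differing
  at the other, *provided* the differing sites are alternative
  boundaries of overlapping exons. Without the overlap requirement any
  skipping pattern would double-report as an alternative splice site;
  with it, the pattern is the classic extension segment, which is also
  the event's target.
* **MXE** — exons B1 < B2 spliced A→B1→C in one transcript and A→B2→C
  in another, with the same outer sites, non-overlapping middles, and
  no transcript of the gene containing the A→B1→B2→C path. The
  both-path check runs against *all* transcripts, not just the pair,
  which prevents double-counting SE pairs.
* **RI** — an exon exactly spanning exon A, the intervening intron and
  exon B of another transcript; the target is the intron. RI events
  overlapping other events' splice sites are retained.

When several flank choices exist, the shortest enclosing flanks are
reported (deterministic, and the most local description of the event).
Output is sorted by (type, coordinates); single-transcript genes yield
no events. Enumeration is verified against an independent exhaustive
pairwise-transcript oracle on hundreds of random genes (≤ 5
transcripts, ≤ 10 exons) in the test suite.

**Ψ orientation.** Ψ is the fraction of transcripts carrying the
*inclusion* form: the longer (more exonic) form for SE, A5SS, A3SS and
RI, and the form containing the genomically first exclusive exon for
MXE. A fixed orientation makes ΔΨ comparable across samples and
species.

# Expression and Ψ quantification

For a feature with count $c$, length $l$ and library size $N$ (the sum
of the sample's gene-level counts; junction and body rows re-count the
same fragments and are excluded):

$$\mathrm{FPKM} = \frac{10^9\,c}{N\,l}, \qquad
  \mathrm{TPM} = 10^6\,\frac{c/l}{\sum_f c_f/l_f}.$$

A feature is *expressed* iff FPKM strictly exceeds 1 — the conventional
inclusion threshold; the boundary value 1 satisfies neither the
expressed test nor the imputation rules below, which is harmless
because it has measure zero in practice.

**Effective lengths.** With read length $r$ (nt) and anchor $a$ (nt,
default 8 — at least $a$ nucleotides must map on each side of a
junction), a junction offers $r - 2a + 1$ distinct read start
positions and a body interval of length $L$ offers
$\max(L - r + 1, 0)$. The inclusion and exclusion effective lengths
$\ell_I, \ell_S$ sum those contributions over each form's support: two
junctions (plus the target body when body reads are used) for SE; one
junction plus the extension segment for A5SS/A3SS; two junctions plus
the first exclusive exon for MXE; and for RI two exon–intron boundary
segments plus the intron interior (RI inclusion support is
intrinsically body-based, so it is counted regardless of the body-read
setting). These formulas are validated in the tests against a
brute-force enumeration of every read placement on the toy isoforms.

$$\Psi = \frac{I/\ell_I}{I/\ell_I + S/\ell_S},$$

undefined when $I = S = 0$. An event is *classified alternatively
spliced in a sample* when both forms are observed ($I \ge$ `min_each`
and $S \ge$ `min_each`, default 1); condition-level Ψ is the arithmetic
mean over a condition's classified samples. For samples in which an
event was not classified but was classified elsewhere, Ψ is imputed
from expression: exon FPKM > 1 → Ψ = 1; exon FPKM < 1 with an
expressed flanking exon → Ψ = 0; exon and both flanks below 1 → no
value. Within-species Ψ is computed per sample directly rather than by
averaging all-pairs runs; because a pairwise run's Ψ for a sample
depends only on that sample's counts, the two procedures coincide, and
the direct form is the simpler one.

# Orthology

Candidate pairs carry an opaque overlap score in [0, 1] (the alignment
pipeline's convention is the caller's responsibility; the generator
draws true pairs from Uniform(0.6, 1) and decoys from
Uniform(0.2, 0.7) so both the filter and the tie-break branches are
exercised). Resolution keeps pairs with overlap strictly > 0.5, then
resolves many-to-one relations hub-side first and other-side second —
the order matters on adversarial inputs and is fixed here — keeping the
unique best-overlap pair and discarding a feature entirely when its
best score is tied. The result is always a partial bijection (asserted
on every run) and equals a brute-force implementation of the two rules
on random instances. The hub species is configurable and need not be
among the analyzed species; pairwise analyses use the same machinery
with a two-species list.

# Comparative statistics

* Correlations between condition profiles use pairwise-complete rows
  (Ψ matrices are missing where no sample defined a value); pairs with
  fewer than 3 complete rows are NA with a warning.
* Clustering is complete-linkage `hclust` on Euclidean distances
  between correlation-matrix rows — the behaviour of the standard
  heatmap tools; dendrograms export as Newick.
* PCA treats conditions as observations with complete-case feature
  rows, centered and unscaled (`prcomp` defaults), reporting variance
  fractions that sum to 1.
* Jensen–Shannon divergence uses base-2 logarithms on
  sum-normalized profiles; the reported distance is $\sqrt{JSD}$,
  a metric bounded in [0, 1].
* **Label dominance** quantifies the qualitative "clusters by species
  vs by tissue" statement: the fraction of conditions whose nearest
  neighbour (highest off-diagonal correlation, ties to the lowest
  index) shares a label. On random matrices it fluctuates around the
  label-share baseline; block structure drives it toward 1.

# Sex-biased splicing and the maternal-to-zygotic transition

ΔΨ = |Ψ_female − Ψ_male| per exon and context, with gonad pooling
ovary (female) against testis (male). Thresholds are strict:
ΔΨ > 0.10 is sex-biased, ΔΨ > 0.7 strongly so; both the all-exon and
the ΔΨ > 0 denominators are obtainable from the summary because the
published style of percentage is ambiguous between them. Exons with Ψ
defined in only one sex after imputation are excluded from ΔΨ and
counted separately. Histograms bin ΔΨ at 0.05 signed by direction.

A gene is *maternal* iff expressed (FPKM > 1 in ≥ 1 replicate) at the
earliest, pre-zygotic stage; *zygotic* iff silent there but expressed
at any later sampled stage — "later" includes every stage after the
first even though the second sampled stage is still largely maternal,
because the operational definition depends only on stage-2 silence;
otherwise unexpressed in the embryo. The classes are mutually
exclusive and exhaustive. Complexity comparisons (log₂ length, exon
count) use two-sided Wilcoxon rank-sum tests via `wilcox.test`: exact
enumeration for small untied groups, normal approximation with tie
correction otherwise.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with truth tables for every planted feature:

* **Gene models.** Genes occupy fixed genomic slots so orthologous
  features share coordinates up to a per-species offset. Exon counts
  are 2 + Poisson(4) (multi-exon genes), exon lengths log-normal
  around 250 nt, introns ≥ 150 nt; zygotic-designated genes deflate
  exon length and count by a factor 0.5 each, emulating the short,
  intron-poor character of early zygotic transcripts. One AS event per
  AS gene is realized as a second transcript implementing the chosen
  type.
* **Profiles.** log₂-TPM = baseline N(4, 1.5) + tissue effect
  N(0, σ_tissue_GE = 1.5) + species effect N(0, σ_species_GE = 0.3) +
  noise N(0, 0.2); logit-Ψ = baseline N(0, 1) + species effect
  N(0, σ_species_AS = 1.5) + tissue effect N(0, σ_tissue_AS = 0.3) +
  noise N(0, 0.2), truncated to [0.001, 0.999] to avoid degenerate
  logits. The defaults encode the study-level contrast — expression
  varies mostly by tissue, splicing mostly by species. A planted 10%
  of shared events are strongly gonad sex-biased: in gonads, per-sex Ψ
  is set to 0.5 ± δ/2 (default δ = 0.8) with random direction, so the
  planted ΔΨ is exact. In embryo designs, zygotic genes have zero TPM
  at the two pre-zygotic stages and switch on at the third stage
  (the maternal-to-zygotic transition); maternal genes carry AS events
  at `maternal_as_excess` (default 4×) the zygotic probability.
* **Counts.** Reads per gene are $N\cdot$TPM·L/Σ(TPM·L) with library
  size $N$ = coverage × Σ L / r; per-feature counts are Poisson (an
  overdispersion parameter switches to negative binomial) with mean
  λ_gene × isoform weight × effective positions, where the isoform
  weight of an interval or junction is the mass of isoforms fully
  containing it (ψ, 1 − ψ, or 1). This makes the Ψ estimator's
  expectation correct by construction, so calibration tests probe the
  estimator, not a generator idiosyncrasy.
* **Orthologs.** True pairs, decoys against synthetic non-features,
  and exact-tie pairs are planted at configurable rates; the truth
  table records analytically which hub features must survive
  resolution, so recovery tests are exact.

What the generator does **not** emulate: mappability and alignment
artifacts, positional read biases, overlapping genes, complex events
(multi-skip, alternative first/last exons), annotation errors, and
correlated biological replicates. Passing tests therefore demonstrate
correctness of the analysis given its inputs, not robustness to
upstream noise in real data.

# Numerical and design choices

* Strict inequalities everywhere a threshold appears (overlap > 0.5,
  FPKM > 1, ΔΨ > 0.10 / 0.7), matching the conventions above;
  threshold-boundary values deliberately fall through.
* Effective lengths are floored at 1 to avoid division by zero for
  degenerate events (e.g. an RI intron shorter than a read in
  junction-free mode).
* Missing-value policy: pairwise-complete rows for correlations,
  complete-case rows for PCA and JSD; both surfaced in the outputs.
* Dendrogram and nearest-neighbour ties resolve to the lowest column
  index for determinism; repeated runs are identical, and the pipeline
  is byte-deterministic given the seed.
* Zero-variance rows in Z-scoring become zeros with a warning rather
  than NaN, keeping heatmap inputs finite.
* FPKM exactly 1 assigns no imputed Ψ and does not count as expressed.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to keep Monte-Carlo error comfortably inside the tolerances they
assert: ~200 random genes for the event oracle, ~200 events × 3
replicates at 100× and 500× for Ψ recovery (mean |error| and bias),
50 random bipartite instances for orthology, the default 4-species ×
4-tissue × 2-sex × 2-replicate design (200 genes) for the clustering
contrast, ~500 gonad exons at 200× for sex-bias recovery, and 300
genes over four embryonic stages for the maternal/zygotic analyses.

# Known limitations

* Ψ estimation is a point estimate; no posterior intervals or
  differential-splicing tests are provided.
* Exon body reads are attributed to the single feature key matching
  the read's containing interval; nested exon intervals are counted
  per key, not probabilistically deconvolved.
* The overlap score's denominator (reciprocality) is the upstream
  aligner's business; the package treats it as opaque, so users must
  ensure a consistent convention across species pairs.
* Annotation-supported events only: junctions absent from the
  annotation are never discovered.
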