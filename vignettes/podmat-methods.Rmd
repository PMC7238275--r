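---
title: "podmat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{podmat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podmat)
```

## The problem

Common bean (*Phaseolus vulgaris*) pods pass through well-separated
developmental stages, conventionally labelled by days after anthesis:
ANT5 and ANT10 (immature, green, elongating) versus ANT20, ANT30 and
ANT45 (mature, seed filling through desiccation onset).  Given stage-wise
bulk RNA-seq of two contrasting accessions (a cultivated breeding line
and a weedy form), the goal is the set of genes whose expression change
is a property of pod maturation itself rather than of either genotype:
genes consistently up- or down-regulated from the immature to the mature
class, in both accessions, and concordant with maturation genes reported
in a reference species (Arabidopsis silique studies).

`podmat` implements that inference as a reusable, tested pipeline:

1. **Replicate QC** — hierarchical clustering (maximum distance, average
   linkage) of the common top-expressed genes; replicates that cluster
   with the wrong stage are discarded.
2. **DEG calling** — signed fold change between every (mature, immature)
   stage pair of FPKM stage means; a gene is `up` iff the signed FC
   exceeds +2 in *all* pairs (default 3 mature × 2 immature = 6 pairs),
   `down` iff below −2 in all pairs; strict inequalities.
3. **Cross-genotype intersection** — shared, genotype-exclusive and
   direction-conflicting sets.
4. **Cross-species concordance** — a shared DEG survives iff at least one
   of its reference-species homologs appears in the same-direction
   reference maturation list.
5. **Enrichment** — hypergeometric (one-sided Fisher) tests for term
   over-representation (BH-adjusted, α = 0.01) and for
   transcription-factor binding sites in promoters (raw *P* ≤ 0.05, the
   convention of the TFBS analysis this reproduces), with target
   assignment for significant TFs.
6. **Ordination** — classical correspondence analysis of the
   sample × gene table; axis 1 is expected to separate maturity classes.
7. **qPCR utility** — the 2^(−ΔΔCt) relative-expression transform.

## Statistical and numerical choices

**Signed fold change.**  For means `a` (mature) and `b` (immature), both
augmented by a pseudocount, the statistic is `a/b` when `a ≥ b` and
`−b/a` otherwise — magnitudes are symmetric around ±1 and the value is
antisymmetric under swapping.  Stage means are arithmetic means of
surviving replicates' FPKM; the source procedure does not state its
replicate handling, so the mean is declared (not inferred) and recorded
here.  The pseudocount default is 0.01 FPKM, small enough not to blunt
genuine signal yet keeping zero-expression genes finite; genes absent
everywhere get FC = +1 and are never called.

**Strictness.**  The threshold is exclusive (`> 2`, `< −2`): a gene with
one pair exactly at ±2 is `not_de`.  Direction consistency is built into
the all-pairs rule; a gene cannot be called with mixed signs.

**FPKM.**  `fpkm = counts · 10⁹ / (length_bp · column_sum)`, with gene
length the union of exon intervals (interval length for BED input) and
the per-sample denominator the column sum of the supplied count matrix —
totals from the original alignment step are not recoverable from a count
matrix.  A consequence worth knowing: FPKM ratios between stages absorb
the ratio of column sums, so background genes can drift slightly beyond
their generative ratio bound.  All coordinates are 0-based half-open
internally; GFF3 is converted at the boundary.

**Replicate QC.**  The "common top k" gene set is operationalized as the
smallest rank depth R whose per-sample top-R intersection holds at least
k genes, then the k of those with the highest mean; ties break
lexicographically, making the selection deterministic.  Ranking uses
log(FPKM+1), the same transform as the clustering input (whether the
original ranking used raw or log FPKM is unstated; the orders only
differ through the replicate-mean step, and log1p is declared the
default).  UPGMA is implemented directly so that its tie-break (smallest
pair of cluster representatives) is specified; the implementation is
validated against a flat-average brute-force reference.  The
discordance rule — cut into G = #(genotype, stage) clusters, flag a
replicate whose cluster contains foreign but no own-group members — is a
declared operationalization of the observed symptom ("clustered with
other samples than its own"); reasons are recorded so users can
override, and a group whose replicates are all flagged is reported as
"not separable" rather than pretending a single culprit exists.

**PWM scanning.**  Promoters are TSS − 500 bp to TSS + 100 bp,
strand-aware and clipped at contig ends.  Scores are log₂ odds against a
0-order background (uniform by default) with pseudo-probability
smoothing `p' = p(1 − 4ε) + ε`, ε = 10⁻³, so zero entries stay finite.
P-values come from exact dynamic programming over per-position scores
floored onto an integer lattice of 1000 steps across the total score
range; flooring makes lattice scores conservative, and the DP is exact
for the lattice score function.  The accepted tolerance against
exhaustive word enumeration is one word-level lattice step
(`W · range / bins`); tests assert exactly that.  Both strands are
scanned; a site's offset is the leftmost base on the forward promoter
sequence.  Evidence classes beyond the raw match (`motif_CE`: > 50% of
the site covered by a conserved element, strict; `FunTFBS`: functional
labels) are filters over supplied input tracks, never computed here.

**Enrichment.**  Gene-level presence (≥ 1 site) defines a TF–target
interaction; site multiplicity is deliberately ignored.  Tests are
one-sided (enrichment only).  The hypergeometric tail is accumulated in
log space and matches exhaustive combinatorial sums to 10⁻¹² for
N ≤ 60.  Benjamini–Hochberg is the declared default wherever "adjusted
p-value" is required (the source names no procedure); TFBS enrichment
follows its source in using raw *P* ≤ 0.05, with BH available.

**Correspondence analysis.**  Standardized residuals of the relative
table are decomposed by SVD; principal inertias are squared singular
values and their sum equals Pearson's χ²/n (asserted to 10⁻⁹ against
`chisq.test`).  Axis signs are unidentifiable, so all separation tests
are written sign-invariantly.  CA runs per genotype by default,
matching the per-accession ordination panels of the original analysis.

## The synthetic world

`generate_dataset()` emulates the study design: 2 genotypes × 5 stages
× 3 replicates, negative-binomial counts around lognormal base means
(meanlog = log 100, sdlog = 1.5), dispersion 0.05, per-sample depth
factors (lognormal, sdlog 0.1), and a per-gene accession-divergence
factor (sdlog 0.4 — the two accessions are deliberately contrasting
germplasm).  Planted signals, all recorded in a ground-truth manifest:

- maturation DEGs up and down (4% / 5% of genes; mature/immature mean
  ratio `effect_ratio` = 4 in both genotypes),
- genotype-exclusive DEGs (3% per genotype, random direction),
- background genes whose pairwise stage-mean ratios stay within
  `background_ratio` = 1.3,
- **stage markers** (10% of genes, single-stage peak at ×4, drawn from
  the abundant quartile): every developmental stage in real data has a
  distinct transcriptome, and replicate QC depends on stages being
  mutually distinguishable.  Without markers the three mature stages
  would be statistically identical — a world in which no clustering
  method could assign replicates to stages.  Markers never become DEGs:
  a single-stage peak cannot clear the threshold in *all*
  mature-vs-immature pairs,
- one **discordant replicate**, regenerated from the mean vector of a
  stage in the opposite maturity class — the failure mode actually
  observed (a replicate clustering with another stage's samples),
- a homolog map routing 60% of planted DEGs to same-direction reference
  entries and 10% to opposite-direction entries, plus background
  homologs outside both lists,
- promoter motif insertions (exact consensus of width-10 PWMs) at rate
  0.9 in the planted TFs' target promoters and 0.05 elsewhere,
- one annotation term enriched in the planted up set.

Two deliberate detectability rules shape the world.  Planted signal
genes are sampled from the expressed fraction (base mean ≥ 5): a
fold-change criterion can only recover detectably expressed genes, so
planting signal on near-zero genes would misstate the ground truth.
Background and marker genes below a detection limit (genotype-level
mean < 2 expected counts) are emitted as absent in that genotype: real
matrices do not contain flat genes trickling fractional counts, and
integer rounding at that boundary would otherwise fabricate
presence/absence patterns that are, by any reasonable reading, genuine
on/off differential expression mislabelled as background.

With `dispersion = 0` (and depth variation off) counts are deterministic
rounded means — the noise-free regime in which the pipeline must recover
every planted set *exactly*.  All randomness flows from a single
`set.seed(seed)`, so bundles are byte-identical across runs.

**What the generator does not emulate:** read-level artifacts, isoform
structure, batch effects, GC/length biases, correlated gene modules,
and annotation-term hierarchies.  A green end-to-end test therefore
establishes the *logic* of the pipeline against a controlled truth, not
its behaviour on the full messiness of real libraries.

## Known limitations

- The DEG criterion is the source procedure's thresholded fold change —
  no dispersion modelling, no DE p-values.  That is fidelity, not an
  endorsement; count-based testing is explicitly out of scope.
- FPKM normalization by column sums couples genes through the
  denominator (compositional drift); the generator keeps planted
  fractions small enough that this stays inside the calling margin.
- The DP p-value is exact only for the lattice score function; extremely
  fine thresholds near the decision boundary can differ from the
  continuous-score tail by up to one word-level lattice step.
- Homolog concordance uses the existential (any-homolog) rule with an
  ambiguity flag; many-to-many homology resolution is declared, not
  derived.
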