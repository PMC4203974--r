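---
title: "Entropy-weighted prioritization of noncoding somatic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted prioritization of noncoding somatic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-genome sequencing of a tumor yields thousands of somatic alterations,
almost all of them passengers. In protein-coding regions the candidate
drivers can be triaged by their consequence on the protein; in the
noncoding genome there is no comparably crisp signal. `regvar` ranks
noncoding SNVs and small indels (net length change at most 20 bp) by
combining regulatory annotation, nucleotide-level motif effects,
conservation, element-to-gene linkage, gene-network topology and
cross-sample recurrence into a single weighted score, with every weight
learned from the variation patterns of natural polymorphisms.

The guiding idea is selectionist: a genomic feature frequently overlapped
by common polymorphisms is tolerant of variation, so carrying that feature
says little about a somatic variant's impact. Feature weights are therefore
one minus the Shannon entropy of the feature's occurrence probability in a
polymorphism panel,

$$ w_d \;=\; 1 + p_d \log_2 p_d + (1 - p_d)\log_2(1 - p_d), $$

where $p_d$ is the fraction of panel polymorphisms carrying discrete
feature $d$ (with $0\log_2 0 := 0$). The weight is 1 for features never or
always observed, 0 at $p_d = 0.5$, and decreases monotonically over
$(0, 0.5]$ — rarer features weigh more. A continuous feature $c$ with value
$v_c$ uses the tail probability $p_c^{\ge v_c}$ (fraction of polymorphisms
with a value at least $v_c$) in the same formula, evaluated on a smooth
monotone curve fitted over the observed grid. A variant's score is the sum
of the weighted values of its observed features; unobserved features
contribute nothing.

Two refinements matter in practice:

* **Dependency suppression.** Features nest (a polymorphism-depleted
  "sensitive" region is also a "functional annotation"). To avoid double
  counting, features form an acyclic dependency graph and a parent's weight
  is dropped from the sum whenever any of its children is observed. The
  default graph hangs the specific annotation classes (TFP, DHS, enhancer,
  HOT, sensitive, ultra-sensitive, ultra-conserved, and the two motif
  features) under the generic `in_functional_annotation` root, with
  `in_ultra_sensitive` additionally refining `in_sensitive`. The graph is
  configuration, not code, and can be replaced wholesale.
* **Core versus final score.** Recurrence depends on how many samples the
  user uploaded and whether the recurrence database is consulted, so the
  recurrence weight is added only to the *final* score. The *core* score is
  invariant to cohort size and database settings, which the test suite
  checks explicitly.

Coding variants are ranked on a separate 0–6 tally (nonsynonymous;
premature stop; gene under strong selection; gene a network hub; recurrent;
GERP > 2), with stop gains counting only as premature stops. The two scales
are deliberately not merged: they are reported as separate ranked tables,
because a sum of entropy weights and a criterion count are not
commensurable.

## Nucleotide-level motif analysis

PWM frequencies $f_{i,b}$ are transformed to log-likelihoods
$\log_2\!\big((f_{i,b} + \kappa\,\pi_b)\,/\,((1+\kappa)\,\pi_b)\big)$ with
background $\pi$ (default uniform) and pseudocount $\kappa$ (default 0.01).
Published motif conventions vary, so base, background and pseudocount are
all parameters of `to_log_likelihood()`; with a given motif library a
different convention can be matched by configuration.

**Motif breaking.** For a variant inside a motif instance (the motif-hit
track), the break score is the germline-minus-mutant log-likelihood
difference at the affected matrix position, strand-adjusted. Only score
*decreases* are breaking events; increases and no-ops are conserving and
are not emitted. For indels we report the maximum per-position score range
over the disrupted positions, flagged distinctly — this is a pragmatic
extension, since an indel's footprint has no single-column delta.

**Motif gaining.** For each variant in a promoter (2.5 kb upstream of a
TSS) or in an element significantly associated with a gene, the reference
allele plus 29 bp of flank on each side is concatenated (59 bp windows for
SNVs; indels change the window length), the alternate window is built by
substitution, and every matrix is slid over every offset covering the
altered base(s), on both strands. A gain event requires the mutant window's
match-score tail probability to reach `alpha_gain` (default 4e-8) while the
germline-aligned window's does not, together with a score increase. Both
strands are scanned; reports are stranded.

**Exact tail p-values.** $P(\mathrm{score} \ge s)$ under an i.i.d.
background sequence is computed by dynamic programming over the discretized
score distribution: matrix entries are floored onto a grid of width
`granularity` (default $10^{-3}$ in log2 units) and the per-position mass
functions are convolved. Floor rounding makes the discretized score at most
$L \cdot \mathrm{granularity}$ below the true score, so the returned value
is bracketed between the exact $P(\mathrm{score} \ge s)$ and
$P(\mathrm{score} \ge s - L\,g)$; the test suite verifies this bracket
against exhaustive $4^L$ enumeration for matrices up to length 6. The full
distribution is cached per matrix, so repeated p-value lookups (the common
case when scanning) are a binary search.

## Element-to-gene linkage

Distal regulatory modules (DRMs) are regulatory regions (TFP, DHS, enhancer
tracks) at least 1 kb from the nearest annotated gene body. For each
element, every TSS expression unit within 1 Mb (closed boundary) is a
candidate target. Across tissues we correlate the element's activity
signals — H3K4me1 and H3K27ac read counts per million — and its inactivity
signal — the methylation level $\sum_i m_i / \sum_i n_i$ over the element's
CpG sites — with the target's expression (reads per million in the TSS ± 50
bp window, averaged over replicates). Activity signals are tested on the
right tail (looking for positive correlation), methylation on the left
(anti-correlation).

Pearson p-values come from the one-tailed $t$ statistic
$r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom; a Fisher-Z variant
is available as an option since the two disagree slightly at small $n$, and
the $t$ form is the primary definition here. Spearman p-values are exact by
full permutation enumeration for $n \le 7$ and use the large-sample $t$
approximation on the rank correlation above that. Tissues with missing
cells are dropped pairwise, with a minimum of 3 complete pairs per test;
zero-variance inputs return $p = 1$ and are flagged degenerate rather than
propagating NaNs. All raw p-values are adjusted jointly (Bonferroni, Holm,
BH or BY; BH at $\alpha = 0.05$ by default), and the per-pair association
confidence passed downstream is the best adjusted p over signals and
methods.

## Network and recurrence features

Gene networks are loaded from edge lists (self-loops and duplicate edges
dropped). Centrality is degree by default — hubs are the intended signal
and degree is robust on sparse user networks — with betweenness and
closeness selectable per network. A gene's scaled centrality is its
empirical-CDF position with the $\le$ convention (the minimum gene gets
$1/N$, the maximum 1, ties share a value); a variant linked to several
genes or networks takes the maximum.

Recurrence is counted over *distinct samples*, never variants: a site
(identical chromosome, position and alternate allele), an element of the
configured tracks, or a coding gene mutated in at least two samples is
recurrent. An optional sample-alias map collapses duplicate sample ids
across studies before counting. The same logic builds the recurrence
database from per-cancer-type variant sets and matches user cohorts against
it, reporting per-type counts such as `5/88 Liver samples`.

## What the synthetic data context emulates

Everything is testable offline because the `fixture_spec()` /
`make_context()` / `make_cohort()` / `make_tissue_panel()` generators build
a complete toy data context deterministically from a seed: a 2 × 200 kb
genome, 12 genes (6 coding), sharp 14-bp PWMs whose consensus occurrences
are physically written into the genome (so the motif-hit track is the
result of really scanning the sequence), disjoint annotation zones, a
polymorphism panel that plants the enhancer/DHS/sensitive features at rates
0.5 / 0.1 / 0.01 (chosen to span common-to-rare, giving closed-form
expected weights of 0, 0.53 and 0.92), a hub-and-spoke gene network, and a
20-tissue panel with planted element–gene correlations of 0.9 — roughly the
tissue count of real epigenome compendia and a correlation strong enough to
survive multiple-testing correction at that panel size. The planted driver
is the field's archetype: a promoter SNV completing a one-mismatch ETS-like
consensus next to a hub cancer gene.

These toy conditions exercise every code path, but passing them does not
show that the method separates drivers from passengers in real tumors: the
toy genome has no mutation signatures, no linkage structure, no celltype
heterogeneity, and its annotation tracks are disjoint by construction
where real tracks overlap heavily. What the tests do establish is that each
component computes exactly the quantity its definition states (enumeration
oracles for p-values and permutation tests, closed forms for weights and
levels), and that the pipeline recovers structure it provably contains.

## Numerical choices and edge cases

* DP discretization: floor rounding at $10^{-3}$ log2 units; the
  error bracket is documented above and tested.
* Weight curves: isotonic regression over the grid where the tail
  probability is ≤ 0.5, then a shape-preserving monotone (Hyman) spline;
  queries outside the observed range clamp to the boundary weights. A
  parametric nonlinear fit would need a chosen functional form; isotonic +
  monotone interpolation keeps the same intent (smooth, monotone) without
  that choice. Features observed fewer than 10 times fall back to a
  constant low-confidence weight at the observation rate.
* GERP enters as a sigmoid $w_d/(1+e^{-k(g-2)})$ sharp at the conventional
  conservation cutoff 2 ($k = 10$ per GERP unit by default), scaled by the
  entropy weight of the discrete GERP > 2 feature, preserving the cutoff
  while keeping the contribution continuous.
* If a variant carries several values of one continuous feature (several
  broken motifs, several networks), the largest value is used.
* Ranking ties are broken by genomic coordinate so repeated runs are
  byte-identical; multi-allelic VCF records are split and alleles
  left-normalized on input; indels with net change over 20 bp are dropped
  with a logged count.
* The training sample fraction defaults to 0.1 of the panel with an
  explicit seed; the trained model serializes to versioned JSON and reloads
  bit-identically.

## Problem sizes

The shipped tests and the acceptance script run at toy scale by design: a
400 kb genome, cohorts of ~2,200 variants across 3 samples, a 5,000-variant
panel for the shared fixtures and a 50,000-variant panel for the
weight-recovery check, 50 random matrices of length ≤ 6 against exhaustive
enumeration, and 2,000 null simulations for the correlation engine's size.
These sizes give binomial/enumeration error bars comfortably inside the
asserted tolerances while keeping a full run in the low minutes.

## Known limitations

* The minimal coding annotator handles SNV consequences and flags indels
  frameshift/inframe; it is not a full transcript-aware consequence caller
  (no splice sites, no multi-transcript reconciliation).
* Gain-of-motif germline alignment for indels anchors windows at the same
  left genomic coordinate and remaps offsets through the allele-length
  change; other alignment conventions are defensible.
* Coding and noncoding ranks are reported separately and intentionally not
  merged.
* The recurrence weight is trained like any other discrete feature; in a
  polymorphism panel recurrence is never observed, so it defaults to the
  maximum weight 1 and is flagged low-confidence.

## A worked run

```{r}
library(regvar)

dir <- tempfile("toy-context-")
spec <- fixture_spec(seed = 7)
res <- make_context(spec, dir)
ctx <- build_context(res$config)
cohort <- make_cohort(spec, ctx, res$truth)

model <- train_weights(ctx$polymorphisms, ctx, sample_fraction = 1, seed = 3)
summary(model)

pr <- run_pipeline(cohort$variants, ctx, model)
print(pr)
head(pr$noncoding)

write_report(pr$noncoding, file.path(dir, "ranked.bed"), fmt = "bed")
```
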