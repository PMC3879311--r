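---
title: "Inferring lncRNA-disease associations from expression profiles: methods and design"
author: "lncDA maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-disease associations from expression profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncDA)
```

# The problem

Thousands of human long noncoding RNAs (lncRNAs) are catalogued, but only a
small fraction have any experimentally established disease association.
Because so few lncRNA-disease pairs are known, supervised approaches that
learn from known associations have little to train on. lncDA implements an
unsupervised, guilt-by-association framework that needs only three inputs,
all of which exist at scale: an lncRNA expression matrix over tissue or
cell-type conditions, a gene expression matrix over a condition set that
shares labels with the first, and a curated gene-disease association table.
Known lncRNA-disease pairs are used exclusively for *evaluation*, never for
prediction.

# The model

The framework forks on tissue specificity.

**Step 1 — partition by the tau index.** For an expression profile
$x_1,\dots,x_N$ over $N \ge 2$ conditions, the tissue specificity score is

$$\tau \;=\; \frac{\sum_{i=1}^{N} (1 - \hat x_i)}{N - 1},
\qquad \hat x_i = \frac{x_i}{\max_j x_j}.$$

$\tau = 0$ for a flat nonzero profile and $\tau = 1$ when exactly one
condition is expressed; it is invariant to positive rescaling, so raw score
tracks need no normalisation first. lncRNAs with $\tau \ge 0.8$ are called
tissue-specific; the boundary is *inclusive* (the score 0.8 itself is
specific), a choice the partition documents because the cutoff convention is
otherwise ambiguous. All-zero rows make $\tau$ undefined and must be removed
first (`filterDegenerate()`); treating them here as an error rather than a
silent skip keeps the count trail exact.

**Step 2 — tissue-specific branch.** A tissue-specific lncRNA is linked to
the disease class of the tissue(s) in which it peaks: one prediction per
peak tissue, with exact-equality peak detection (source scores are integers
on 0-1000 UCSC-style tracks; a relative tolerance flag exists for float
inputs and defaults to off). Ties are informative — an lncRNA peaking in
$k$ tissues yields $k$ class predictions. The default label is
`"<tissue>-related diseases"`; a user mapping table can substitute curated
class names, falling back (with a warning) to the default for unmapped
tissues. This branch deliberately stops at disease *classes*: the expression
signal alone cannot resolve a specific disorder, and pretending otherwise
would overstate the method.

**Step 3 — co-expression neighbourhood.** For each non-tissue-specific
lncRNA, Spearman's rank correlation is computed against every gene over the
conditions the two matrices share (matched by trimmed, case-folded label —
the two atlases are produced independently, and name matching is the
package's convention). Pairs with $\rho \ge 0.7$ form the lncRNA's
co-expressed gene set. Ties get average (fractional) ranks, the standard
Spearman definition. Each retained edge also carries a two-sided p-value
from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; it is reported for the record but never
used for filtering — the edge rule is the coefficient itself. Profiles that
are constant over the shared conditions have undefined correlation; such
pairs are skipped and counted rather than failing the run, because the
degenerate filter only removes all-zero/all-saturation rows and other
constant rows can legitimately survive. Fewer than `minCommon` (default 5)
shared conditions is a hard error: a rank correlation over a handful of
points carries almost no information.

**Step 4 — hypergeometric disease enrichment.** With a universe of $M$
genes (the genes with expression profiles), a disease with $x$ genes in the
universe, a co-expressed set of size $n$, and an overlap of $y$ genes, the
enrichment p-value is the upper tail

$$P(Y \ge y) \;=\; \sum_{k=y}^{\min(n,x)}
\frac{\binom{x}{k}\binom{M-x}{n-k}}{\binom{M}{n}},$$

evaluated through the hypergeometric survival function for numerical
stability. Disease gene sets are intersected with the universe before $x$
is counted (genes without expression profiles cannot appear in any
co-expressed set, so leaving them in $x$ would deflate p-values); diseases
with no gene in the universe are dropped with a logged count. $M$ is always
computed from the supplied gene universe, never hardcoded, with an override
for replication against a stated universe size.

**Multiple testing.** Bonferroni and Benjamini-Hochberg corrections are both
computed *independently from the raw p-values* and reported as separate
columns; significance is decided on the BH FDR at 0.05. Composing the two
corrections sequentially would be statistically nonstandard, so the package
does not do it. The correction family defaults to per-lncRNA — all diseases
tested against one lncRNA's gene set — because the multiplicity being
corrected is exactly the many disease gene sets confronted with the same
co-expressed set; a global family over all (lncRNA, disease) tests is
available by flag. Zero-overlap tests ($y = 0$, $p = 1$ identically) are
not reported, but they still belong to the family: they enter the
corrections as implicit $p = 1$ members (`p.adjust(..., n = m)`), so hiding
them from the output does not make the survivors look more significant.
Output is filtered at FDR $\le$ 0.05 and sorted ascending by FDR, with
deterministic tie-breaks (raw p, then lncRNA ID, then disease ID).

# Evaluation harness

Predictions and a known association set are first *harmonized*: both are
restricted to the lncRNAs and diseases present on both sides, so positives
and negatives live in one candidate space (the full lncRNA × disease grid
over the common IDs). Each known pair is scored by its rank in the fixed,
FDR-sorted prediction list; candidates absent from the list share the worst
rank (list length + 1) — excluding them would leave the false positive rate
undefined beyond the list. Sweeping the rank threshold $t$ (rank $\le t$
counts as a positive call) yields the ROC curve; its trapezoidal area
equals the tie-corrected Mann-Whitney statistic, and the suite cross-checks
the two routes against each other on random instances.

Because the method never consumes known lncRNA-disease pairs, the
prediction list is identical in every leave-one-out fold, and LOOCV reduces
exactly to ranking each known pair once. `loocv(..., literal = TRUE)` runs
the explicit per-fold loop anyway and returns identical output; it exists
to demonstrate that equivalence, not to be used. Negatives are all
harmonized candidate pairs not in the known set — the known set records
only positives, and this is the standard convention for this style of
validation; it does mean some "negatives" may be merely undiscovered
associations, which biases AUC downward, not upward.

`overlapAccuracy()` reports the simpler headline: of the predicted pairs
whose lncRNA has any known association (the *verifiable* ones), what
fraction is itself a known pair.

# The synthetic world

`generateSynthetic()` produces the package's standing benchmark — the
framework's assumptions made literal, with planted ground truth:

- **Shapes.** 50 lncRNAs × 12 conditions and 300 genes × 20 conditions,
  sharing 8 condition labels — a desk-scale analogue of the real-data
  shapes (an lncRNA track matrix and a larger gene atlas with a common
  tissue subset).
- **Blocks.** 5 co-expression blocks. Each block draws a latent positive
  signal per shared condition (log-normal, log-sd 0.6). Every gene, and
  every non-tissue-specific lncRNA, takes a per-entity monotone transform
  of its block's latent signal (power in [1.0, 1.4], scale in [0.5, 2])
  times log-normal noise (sd 0.2), with independent noise on its private
  conditions. The per-entity power map makes the block relation nonlinear
  but monotone — detectable by Spearman, not reliably by Pearson — which is
  precisely the design choice the co-expression step embodies.
- **Signal strength, chosen once.** The latent spread, power range and
  noise sd were fixed by a detectability argument, not by tuning on test
  output: the block population models *non*-tissue-specific lncRNAs, so its
  dynamic range must keep typical $\tau$ well below 0.8 (here ≈ 0.6, with
  a small tail above the cutoff — as in real data, where the partition also
  routes some block-correlated lncRNAs to the tissue branch); and true
  same-block rank correlation must sit near 0.9 so that the paper's own
  0.7 cutoff on 8 shared conditions can see the structure through sampling
  noise. With 8 points, a sample Spearman coefficient is a noisy estimate,
  so same-block pairs *usually*, not always, pass — the benchmark is
  informative rather than trivial.
- **Tissue-specific minority.** 20% of lncRNAs instead get near-zero
  expression with one saturated peak condition ($\tau \approx 0.99$).
- **Diseases.** 10 diseases, assigned to blocks round-robin; each draws 15
  genes from its block and 5 uniformly. Setting the block component to 0
  yields the null world for calibration checks.
- **Truth.** Each non-tissue-specific lncRNA is paired with the diseases of
  its block. Two all-zero and two all-saturation rows are appended so
  filter tests can assert exact removal counts. Values are scaled to
  [0, 1000] and rounded to integers, mimicking UCSC score tracks and
  exercising the exact-equality degenerate filter realistically.
- **Determinism.** All randomness flows from the single config seed; the
  caller's RNG state is saved and restored.

What a green benchmark run does establish: the full pipeline, run end to
end, separates planted signal from background (LOOCV AUC > 0.9, > 80% of
planted pairs at FDR ≤ 0.05) and stays near-silent on the null world. What
it does not establish: performance on real transcriptomes. The generator
does not model realistic expression distributions, correlated disease
ontologies, shared genes between diseases of different blocks, or the
severe incompleteness of curated association databases; real-data AUC will
be far below the benchmark's.

# Numerical and degenerate-input choices

- The hypergeometric tail, BH adjustment and Spearman coefficient are
  delegated to R's standard numerics (`phyper`, `p.adjust`, rank +
  `cor`); the test suite verifies each against an independent oracle
  (exhaustive enumeration, a hand-rolled step-up, a counting-based
  rank-then-Pearson formula) so the delegation is checked, not assumed.
- p-values are clamped into (0, 1]: underflow to exactly 0 is replaced by
  the smallest positive double so downstream log-scale consumers never see
  zero.
- The co-expression cutoff comparison allows a 1e-12 absolute slack so an
  exactly-rational coefficient (e.g. 7/10 on five ranks) is retained at the
  boundary regardless of floating-point representation.
- An expression matrix whose rows are *all* degenerate filters to `NULL`
  rather than an (invalid) empty matrix; the pipeline reports this as a
  stage error.
- An empty prediction list makes every candidate rank 1 in the evaluation
  harness; this degenerate case is logged and only reachable when the
  enrichment step produced nothing.

# Known limitations

- Condition matching across the two matrices is by normalized label only;
  no ontology mapping is attempted, and tissue labels are used verbatim as
  disease-class stems (raw track labels will surface in class names).
- The tissue-specific branch predicts disease *classes*, not disease terms.
- Redundant lncRNAs (near-identical profiles) are not collapsed; each is
  scored independently.
- The per-lncRNA correction family is a documented interpretation; the
  global family is one flag away, and on the benchmark both recover the
  planted truth.
- Reported Spearman p-values use the t approximation, adequate at the
  condition counts the method requires but approximate at the minimum of 5.
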