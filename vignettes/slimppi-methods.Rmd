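---
title: "slimppi: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slimppi: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimppi)
```

# Overview

`slimppi` predicts protein–protein interactions mediated by peptide
recognition modules (the SH3 domain being the motivating case): a position
weight matrix per domain proposes candidate binding sites in a proteome,
four peptide-level and five protein-level evidence scores assess each
candidate, and two naive Bayes classifiers plus a Bayes-theorem
combination turn the evidence into a single interaction probability with
binding-site resolution. This vignette records the models, their
assumptions, every tunable that matters, and the design decisions taken
where more than one reasonable construction existed.

# The PWM model and exact p-values

A PWM is built from the fixed-length binding peptides of one domain.
Counts receive a background-weighted pseudocount: cell $(a, j)$ gets
$\kappa\, m\, b_a$ extra mass, where $m$ is the alphabet size, $b_a$ the
background frequency and $\kappa$ the `pseudocount` argument. Two useful
identities follow: each column's total pseudo-mass is $m\kappa$ whatever
the background, and at uniform background each cell receives exactly
$\kappa$. The default $\kappa = 0.05$ therefore adds one pseudo-observation
per column on the 20-letter alphabet — ordinary Laplace-style
regularisation. Weights are $\log_2$ odds against the background, in bits.
With `pseudocount = 0`, empty cells would be $-\infty$; they are floored
at $-30$ bits so arithmetic stays bounded (a single floored position is
already far below any plausible acceptance threshold).

Two backgrounds are built in: `"uniform"` and `"from-proteome"` (residue
frequencies of the scanned sequences, recomputed per run). The proteome
background is the pipeline default because it absorbs composition bias —
proline-rich motifs would otherwise look artificially surprising in a
proline-rich proteome. Peptides must be equal length; phage-display
libraries are fixed-length and no internal alignment is attempted.

Window score significance is computed exactly: weights are rounded to a
`granularity` grid (default $10^{-3}$ bits) and the null score
distribution under the background is obtained by column-wise convolution.
Tail probabilities at every grid point give the p-value of any score, and
`threshold_for_pvalue()` inverts the map. Numerical details worth knowing:

* the cumulative tail is clamped to $[0, 1]$ (floating-point summation can
  overshoot 1 by a few ulp, which would otherwise make "p $\le$ 1" filters
  drop windows);
* an unrounded window score can land up to half a grid step per column
  beyond the distribution's extremes; scores within that slack are clamped
  onto the nearest extreme. Outside the slack, p-values are exactly 1
  (below the minimum) or 0 (above the maximum);
* the whole construction is deterministic, and for motifs of length
  $\le 4$ the suite verifies it against brute-force enumeration of all
  $20^n$ windows.

*Significant positions.* Per-column relative entropy against the
background, $IC_j = \sum_a f_{aj}\log_2(f_{aj}/b_a)$, with a default
cutoff of 1.0 bit, selects the columns that carry the motif's specificity.
Only these residues enter the disorder/accessibility/conservation
averages. The cutoff is deliberately configurable: the notion of
"specificity-carrying position" has no canonical definition, and 1 bit
(a 2-fold concentration of the column distribution) is a conservative
middle ground. If no column passes, the scores are undefined and a classed
error forces the caller to decide.

# Scanning

Every window of every protein is scored (no heuristic skipping), N- to
C-terminal; coordinates are 1-based inclusive. Windows containing residues
outside the 20-letter alphabet (X, U, B, ...) are skipped and counted, so
ambiguity invalidates the smallest possible amount of sequence.
Overlapping hits of the same PWM are all reported — binding sites are
counted individually, not merged. The binding-site overlap measure used to
compare predicted and known sites divides the intersection length by the
*shorter* hit (configurable to union), so a short site fully inside a long
one counts as complete overlap.

# Peptide evidence

`DR`, `SA` and `PC` are means over the hit's significant residues: the
fraction called disordered (probabilistic tracks binarised at 0.5,
inclusive; 0/1 tracks pass through), the fraction with relative solvent
accessibility at or above 25% (the conventional exposure call, boundary
inclusive), and the mean conservation value. Conservation tracks can be
derived in-package from an ortholog multiple alignment by the unweighted
sum-of-pairs rule: per column, the average substitution score over all
unordered row pairs, gap-containing pairs scoring 0 but still counted;
columns where the reference sequence has a gap are dropped and the profile
is z-normalised across the protein. The default scoring matrix for this
step is identity (fraction of agreeing pairs) — the scale is then
normalised away — with any substitution matrix accepted.

`SC` transfers contacts from co-complex base models. The query domain is
aligned to each model's domain chain and the query peptide to the model's
peptide chain, independently, because contacts are defined *between* the
chains. For model $j$ with contact strengths $c_{ij}$ (raw contact areas
max-normalised within the model so the strongest pair is 1), the score is

$$SC = \max_j \frac{1}{N_j}\sum_i c_{ij}\,[\text{both residues aligned}]$$

with $N_j$ the model's *total* number of contact pairs. Keeping $N_j$
fixed is the load-bearing choice: a gap at a contact residue then reduces
the average in proportion to the contact's strength, which is exactly the
intended behaviour — losing a large-area contact should hurt more than
losing a marginal one. Ties between models resolve to the first in input
order.

Alignment is affine-gap Needleman–Wunsch (Gotoh's three-state DP) with
BLOSUM62, gap open $-10$ and extend $-1$: the first residue of a gap costs
the open penalty, each further residue the extend penalty. Tie-breaking is
fixed — diagonal over up over left, in both cell filling and traceback —
so identical inputs always give the identical alignment and the contact
transfer is reproducible. The suite cross-checks scores against exhaustive
enumeration of all global alignments on short pairs and against an
independent implementation under the equivalent gap parameterisation.

# Protein evidence

*GO semantic similarity with topological clustering.* The ontology's
structure-only information content, $ICT(t) = -\ln(|\mathrm{desc}(t)|/n)$,
partitions each namespace: terms whose $ICT$ reaches the cutoff and whose
parents all fall below it become sub-graph roots (sub-graph = root plus
descendants, so a term may belong to several), and the below-cutoff terms
plus the roots form a meta-graph. Within every graph, annotation-frequency
IC ($-\ln$ of the propagated protein count over the graph root's count,
true-path propagated) is normalised by the graph's maximum, putting each
graph on a common $[0, 1]$ scale — the point of the clustering, since
shallow and deep ontology regions otherwise have incomparable IC ranges.
A term pair is scored by the normalised IC of its most informative common
ancestor, evaluated in a shared sub-graph when one exists and in the
meta-graph otherwise; a protein pair aggregates over its annotated term
pairs by maximum (best-match average available). Default cutoffs follow
the published per-ontology calibration: 2.4 (cellular component), 3.5
(biological process), 3.3 (molecular function), natural logarithms.
Electronic annotations (IEA) are excluded by default, as is standard for
interaction benchmarks; the exclusion list is configurable. Degenerate
cases: a graph whose root has no annotations, or whose annotated terms all
tie the root count, is uninformative and scores 0; proteins without
annotations in a namespace raise a classed error that the pipeline
converts to a missing feature.

*Expression.* One Pearson correlation per profile in which both genes
have at least 3 shared non-missing conditions and non-zero variance;
disqualifying profiles are skipped and counted, never imputed. The
combined value is $EX = \tanh(\bar z)$ with $\bar z$ the mean of
$\mathrm{atanh}(r_i)$ — Fisher's z transform makes correlations from
profiles with different condition counts commensurable before averaging.
Correlations at $|r| = 1$ (a gene paired with itself or a perfect linear
copy) are clipped to $0.999999$ with a warning since the transform
diverges. If *no* profile qualifies the feature is missing, never a
fabricated 0 — a zero correlation is evidence of independence, which
absence of data is not.

*Signatures.* From a reference interaction set, every cross combination
of one signature from each side of a pair is one observation of the
unordered signature pair; marginals count per-side occurrences. With
Jeffreys smoothing (0.5 per cell) the score is
$SS = \sum_{ij}\log_2(p_{ij}/p_ip_j)$, positive when the signature pair
is enriched on interacting proteins. The sign convention is `association`
(enrichment positive); a `printed` switch negates the sum for
compatibility with sources that report the negated quantity. Signatures
unknown to the model are skipped; a protein with none known yields a
missing feature.

# Naive Bayes integration

Features are discretised: equal-width bins on the natural range for
bounded features ($[0,1]$; $[-1,1]$ for EX), quantile bins estimated on
training data for the unbounded PC and SS. Ten bins with Laplace
smoothing 1.0 per bin are the defaults — enough resolution to capture the
class-conditional shapes at the training sizes used here, smooth enough
that empty bins stay harmless. Missing values are excluded from the
affected feature's table (missing-at-random), which buys the key
deployment property: scoring a vector with feature $f$ missing is
*identical* to scoring under a model trained without $f$ (the suite
asserts this to $10^{-12}$). The class prior defaults to 0.5, matching
balanced training with equal-sized random negatives; it is a parameter,
not an estimate, so deployment-time imbalance can be dialled in.

The two posteriors combine by Bayes' theorem under classifier
independence:
$$P = \frac{p_1 p_2/\pi}{p_1 p_2/\pi + (1-p_1)(1-p_2)/(1-\pi)}.$$
The identities that make this the right form — symmetry, monotonicity in
each argument, $P(p, \pi, \pi) = p$ (a classifier sitting at the prior is
uninformative) — are asserted in the suite. Posteriors at 0 or 1 are
clipped to $[10^{-12}, 1-10^{-12}]$ with a warning. A candidate with no
usable evidence in one scope uses the prior for that scope (equivalently,
the combination returns the other scope's posterior unchanged); a
candidate with no evidence in either scope is excluded and counted.
Per-pair aggregation over binding sites is the maximum — one real site
suffices for an interaction — with noisy-or available where several weak
sites should reinforce. The default decision threshold is a combined
probability of 0.9, the conventional high-confidence cutoff for this kind
of predictor.

Evaluation uses the standard six metrics: AUROC as the Mann–Whitney rank
statistic with mid-rank ties, AUPRC as average precision over a
deterministic (score-descending, index-stable) ordering, Brier score, and
F1 / MCC / accuracy at the stated threshold, with the usual conventions
for degenerate confusion matrices (F1 = 0 without true positives, MCC = 0
on an empty margin).

# What the synthetic generator emulates — and what it does not

`fixture_spec()` fixes the study conditions; every generator is a pure
function of the spec and its seed. The defaults: 30 target proteins of
150–400 residues plus one carrier protein per domain; three 10-residue
proline-rich consensus motifs with 25 phage-style peptides each
(per-position noise 0.1) and 6 planted instances per motif (plant noise
0.05), each target carrying at most one motif so interaction clusters are
disjoint carrier stars; disorder/accessibility tracks Beta(8,2)/Beta(6,2)
inside planted sites against Beta(2,6)/Beta(2,5) background and
conservation N(1.2, 0.5) against N(0, 1); a three-namespace ontology of
depth 4 and branching 2 with interacting pairs annotated to shared or
sibling leaves and non-interacting pairs to different top-level subtrees;
an 8-profile, 20-condition expression panel in which interacting partners
share a latent factor tuned to correlation 0.7; a 30-signature vocabulary
with 5 enriched signature pairs planted on interactions at rate 0.8; and
labelled classifier vectors (2000 per class for training and for testing)
drawn from Beta class-conditionals for bounded features and Gaussians
(tanh-Gaussian for EX) for unbounded ones. These sizes keep a full bundle
generation plus pipeline run in the tens of seconds on a single core
while leaving every recovery margin comfortably non-trivial.

The generator validates *mechanics and recoverability*, not biology: real
disorder and accessibility are strongly autocorrelated along the chain
where the fixtures draw residues independently; real GO annotation depth
is highly skewed; real expression compendia share batch structure across
profiles; real negatives are unverifiable non-interactions rather than
known negatives. Passing the suite therefore demonstrates that the
implementation computes what it claims and that the integration recovers
planted signal under controlled separation — it does not certify
performance on biological data, which depends on upstream predictors and
curated training sets outside this package's scope.

# Known limitations

* The significant-position rule (relative entropy, 1-bit cutoff) is a
  reasonable stand-in for a quantity with no canonical definition;
  downstream features depend on it, so it is exposed for recalibration.
* Contact-area normalisation is per-model max-normalisation; if raw areas
  are comparable across models a global normalisation could preserve
  absolute contact strength, at the cost of coupling models.
* The naive Bayes likelihoods are binned, not parametric; with very small
  training sets quantile bins for PC/SS can collapse (the code then
  reduces the bin count).
* The Bayes combination assumes the two classifiers err independently;
  correlated features across scopes (e.g. disorder and cellular
  compartment both tracking membrane proteins) would make the combined
  posterior overconfident.
* The pipeline treats domain carriers as single-domain proteins; paralogous
  domains within one protein need distinct carrier entries in the domain
  map.
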