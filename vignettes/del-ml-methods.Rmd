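---
title: "Methods: synthetic DEL selections and machine-learning hit finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic DEL selections and machine-learning hit finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`delscreen` re-implements, end to end and on fully synthetic data, the
computational workflow used to find small-molecule hits from DNA-encoded
chemical library (DEL) selections: selection sequencing output is
decoded to building-block counts, aggregated to disynthons, labeled by
enrichment, used to train fingerprint-based classifiers, and the trained
ensemble ranks a commercial-style catalog from which a diverse purchase
list is drawn; candidate hits are then "confirmed" against simulated
titration data with the standard 1:1 binding-model fits. No real DEL
deck, catalog or assay trace ships with the package — the raw data
behind real campaigns of this kind are proprietary — so every claim the
package makes is a property of the algorithms measured on generated data
with known ground truth.

# The selection simulator

A library is a 2- or 3-cycle combinatorial enumeration. Building-block
fragments come from a fixed pool of ~107 substituent SMILES; members are
assembled on an amide (2-cycle) or peptoid-like (3-cycle) backbone
template, and each block carries an 8-nt DNA tag; the member's tag is
the concatenation. Reads have the layout
`[12-nt UMI][cycle tags][10-nt constant region]`.

Capture follows a one-site occupancy model. Per selection cycle a member
survives with probability

$$ p = \min\!\left(\frac{[T]}{[T]+K_D^{\mathrm{eff}}} + m,\; 1\right), $$

where $m$ is the matrix-capture probability (0.01 by default for
ordinary members, 0.5 for planted matrix binders) and
$K_D^{\mathrm{eff}} = K_D\,(1+[C]/K_{D,\mathrm{comp}})$ for competitive
binders in the competitor condition ($K_D^{\mathrm{eff}} = K_D$
otherwise). Cycles are treated as independent, so the weight of a member
after the default two cycles is $p^2$. This is the simplest physical
model consistent with two rounds of capture-wash-elute selection; no
wash kinetics, bead chemistry or DNA damage is modeled. Pre-PCR
molecules are drawn multinomially at those weights, each gets a distinct
UMI, PCR emits $1+\mathrm{Geom}(q)$ reads per molecule (truncated so the
read count equals the requested depth exactly), and each base is
substituted independently at the sequencing error rate.

**Study conditions.** The screen the validation suite runs everywhere
is: a 2-cycle 50×50 library; planted truth of 5 competitive motifs, 3
noncompetitive motifs (a motif fixes the cycle-1 block, so 50 members
share it and the signal aggregates at the disynthon level) and 25
individual matrix binders; $K_D = 1\,\mu M$ for all planted binders;
target at $[T]=1\,\mu M$ so the per-cycle occupancy is 0.5 — a ~50×
capture advantage over the 0.01 background; competitor at
$[C]=100\,\mu M$ with $K_{D,\mathrm{comp}}=1\,\mu M$, i.e. a properly
saturating dose (100× its own $K_D$) that pushes competitive binders to
within ~2× of background; depth $10^5$ reads per condition. Real
screens sequence $\ge 10^6$ reads per library and condition over decks
of 19–65 libraries; the depth here is scaled down by one order so ten
replicate screens run in about twenty seconds each, and the
single-library deck keeps the bookkeeping readable. None of these
values were fitted to anything: occupancy 0.5 and background 0.01 were
chosen once as a round "strong binder vs weak matrix background"
contrast, and the affinity range (default
$10^{-8}$–$10^{-6}$ M log-uniform) spans typical DEL hit potencies.

What the simulator deliberately does not emulate: sequence-dependent PCR
bias, tag synthesis errors, chimeric reads, library synthesis yield
differences, or truncation products. Passing tests therefore show the
analysis is correct *given* the occupancy model, not that it would be
robust to every artifact of a real sequencing run.

# Decoding and counting

Decoding is strict by default: a read is kept only if its length, its
constant region and every cycle tag match the schema exactly — in real
pipelines of this kind error-containing sequences are disregarded
rather than corrected. Rejections are tallied by reason
(`length`, `bad_constant`, `unknown_tag`) and `decoded + rejected =
input` always. A rescue mode matching tags at Hamming distance 1 exists
but refuses schemas whose minimum inter-tag distance is below 3; it is
off everywhere in the package's own analyses. Deduplication keys on
`(UMI, block tuple, condition)`; with error-free reads this reproduces
the simulator's internal pre-PCR molecule ledger exactly, which the
tests assert at depth $10^5$. Counts are normalized to reads-per-million
within each (library, condition); the normalization unit is a package
convention (the original platforms normalize, but do not state the
unit).

# Enrichment and the five classes

Members aggregate into disynthons — block pairs from two cycles; for a
2-cycle library the member is its own disynthon, and a 3-cycle member
contributes to its three cycle-pair views. The enrichment statistic is
a pseudocounted two-proportion z:

$$ z = \frac{p_s - p_r}{\sqrt{\bar p(1-\bar p)(1/N_s + 1/N_r)}},
\qquad p_i = \frac{k_i + c}{N_i + c}, $$

with $c = 0.5$. The platform that inspired this workflow computes a
proprietary enrichment score; the two-proportion z was chosen as a
robust, low-count-safe stand-in, and no parity with proprietary numbers
is attempted. A disynthon counts as *enriched* when $z \ge z^\* = 6$
and its selected-side count is at least $k_{\min} = 5$ (the count floor
guards against singleton artifacts).

Classes are assigned with top-down precedence:

1. `matrix_binder` — enriched in no-target vs the input pool (a uniform
   pool is assumed when no input-pool condition was sequenced);
2. `promiscuous_binder` — enriched against more than half of a panel of
   at least 3 targets (with a single target the class is unreachable,
   and the validation screen leaves it empty);
3. `competitive_hit` — enriched in target vs no-target *and* quiet in
   the competitor condition, operationalized as $z_{comp} < z^\*/2$
   (published DEL-ML workflows state no quantitative competition
   criterion);
4. `noncompetitive_hit` — enriched in both;
5. `non_hit` otherwise.

Without a competitor condition the two hit classes merge into
`target_hit`. Positive training examples (PTEs) are the
competitive-hit members when a competitor was present, else the
target-hit members.

# Models

Features are folded circular fingerprints: Morgan radius 2 at 1024 bits
for the forests, radius 3 ("ECFP6") at 2048 bits for the neural network
and at 1024 bits for similarity analyses. Fingerprints are computed by
OpenBabel's ECFP implementation; bit positions are backend-specific, so
the package promises (and tests) determinism and canonical-molecule
invariance, never particular bits.

**Forests.** The training protocol resamples per model: 90% of the
positives (duplicated ×2 in the training partition) plus `n_negatives`
sampled non-hits, 10% of the negatives held out, holdout accuracy at a
0.5 threshold; the highest-accuracy model is chosen for single-model
inference and the full set is ensembled for ranking. Reference-scale
values are 30 models × 2000 trees × $10^6$ negatives; the package's
study runs 5 × 100 × $10^4$, which preserves every structural feature
of the protocol at desk scale. `ranger` provides the probability
forest (`min.node.size = 5` as the analog of a minimum-split size); a
compound's score is the fraction of trees voting positive — the score
definition is not part of the published protocols and is declared here
as a choice.

**The graph network is not re-implemented.** The production-scale
message-passing model behind this workflow is TPU-trained prior work;
re-implementing it is out of scope. Its *role* is preserved through a
pluggable scorer interface (`plugin_scorer()`), and the
fingerprint network — two fully connected ReLU layers, reference sizes
(2000, 100), logistic output — stands in for it throughout. Training
uses minibatch SGD on log-loss (batch 128, configurable learning rate);
optimizer and loss are not part of the published recipe, so these defaults are
flagged as this package's own. Checkpoints are taken on a fixed cadence
and the checkpoint maximizing `top_100_actives` (true actives among the
100 top-ranked tuning predictions, boundary ties resolved by stable
input order) is kept.

**Ensembling** is a median of replica medians (replicas within runs,
then runs), which is permutation-invariant and bounded by the member
score range; the two-model filter takes the top $k$ by the primary
score, drops the half with the lowest secondary scores, and re-ranks
the survivors by primary score.

# Selection and hit expansion

The purchase list applies property rules, then directed sphere
exclusion (DISE). Default rules — MW 250–550 Da, 17–40 heavy atoms,
elements {C,H,N,O,S,F,Cl,Br} — are conventional drug-likeness windows
(published campaigns name none); the synthetic screen's own analyses widen the
MW window to 150–550 because the two-fragment assemblies are smaller
than commercial leads. DISE scans candidates in descending score order
and keeps a candidate iff its Tanimoto *distance* to every kept
compound exceeds the radius (0.2 default). Whether the original "0.2
radius" is a distance or similarity cutoff is not stated; distance is
the standard sphere-exclusion convention and is declared as the
package's interpretation. Ties in score break by input order, making
selection deterministic. Hit expansion filters the catalog at ECFP6
Tanimoto similarity ≥ 0.35 to the hit, ranks survivors with a scorer,
and applies DISE.

# Binding-model fits

Four closed-form models, all fitted by Levenberg–Marquardt
(`minpack.lm`), with simulators for recovery studies:

* steady state $R = R_{max} C/(C+K_D)$, positive-bounded; a fit whose
  $K_D$ exceeds 50× the top concentration — or data a line through the
  origin explains with $R^2 > 0.999$ — is flagged `no_curvature`;
* 1:1 kinetics, global across concentrations with shared
  $(k_a, k_d, R_{max})$ (rates fitted on the log scale) and per-curve
  dissociation amplitude; $K_D = k_d/k_a$; dissociation windows with
  $k_d t < 0.01$ are flagged unobservable;
* Boltzmann melt $F = F_{min} + (F_{max}-F_{min})/(1+e^{(T_m-T)/s})$;
* FP displacement as a 4-parameter logistic whose inflection (IC50) is
  reported as $K_{disp}$ — displacement assays report $K_{disp}$ without a
  formula; a Cheng–Prusoff transform is available but off by default
  since it needs the probe's $K_D$ and concentration. Curves with less
  than 20% dynamic range are flagged non-displacing.

Recovery at the study's noise levels (100 seeds each; 2% CV for SPR, 1%
for DSF): noiseless residuals below $10^{-8}$ relative, median
steady-state $K_D$ error within 10%, kinetic rate errors within 5%,
$T_m$ within 0.2 °C. The selectivity matrix reports
$100 \cdot R_{obs}/R_{max}^{theo}$ averaged over replicates, where
$R_{max}^{theo}$ scales the immobilized surface capacity by the
analyte/protein mass ratio; values clamp to [0, 120] with an over-range
flag. The exact normalization behind published "normalized percent
binding" tables is not stated, so this convention is isolated in one
function (`selectivity_matrix()` + `theoretical_rmax()`).

# Reproducibility and numerics

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds from one root seed, and `run_pipeline()` writes a
manifest of row counts and file digests that reruns reproduce
byte-for-byte. RNG state is always restored after seeded sections, so
library code never perturbs a caller's stream. Numerical tie-breaks are
deterministic throughout: stable ordering in ranking and DISE, lowest
index on equal forest accuracies, earliest checkpoint on equal tuning
metrics.

Known limitations: single-target screens cannot produce
promiscuous-binder labels; the fingerprint backend's bit assignments
are not portable across chemistry toolkits (only invariants are
promised); the occupancy simulator's independence-across-cycles
assumption ignores carry-over effects; and the synthetic catalog's
chemical diversity is bounded by the ~107-fragment pool, which is far
narrower than any commercial library it stands in for.
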