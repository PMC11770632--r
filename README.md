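# delscreen

Hit finding from DNA-encoded chemical library (DEL) selections, as a
fully synthetic, fully reproducible R workflow. DEL screening couples
affinity selection of billions of DNA-tagged compounds with deep
sequencing; machine-learning models trained on the enriched chemotypes
then predict likely binders in commercial catalogs, so that hits can be
purchased instead of resynthesized. The raw data behind real campaigns
(the library decks, selection reads, and assay traces) are proprietary,
so `delscreen` implements the *computational* pipeline end to end and
validates every stage against simulated screens with planted ground
truth.

The pipeline:

1. **simulate** — split-and-pool combinatorial libraries with per-cycle
   DNA tags; three parallel selection conditions (no target / target /
   target + competitor); two selection cycles under a one-site occupancy
   model θ = [T]/([T]+K_D) + matrix capture, reads emitted with UMIs,
   PCR duplicates and per-base sequencing error;
2. **decode** — strict tag decoding (error-containing reads are
   disregarded), UMI deduplication, reads-per-million count tables;
3. **enrich** — disynthon aggregation and a pseudocounted two-proportion
   z statistic; each disynthon assigned one of five classes
   (competitive hit, noncompetitive hit, promiscuous binder, matrix
   binder, non-hit); competitive hits become the positive training
   examples (PTEs);
4. **train / predict** — resampled random-forest scorers over 1024-bit
   Morgan (radius 2) fingerprints and a two-layer ReLU fingerprint
   network over 2048-bit ECFP6 features, selected by the
   top-100-actives metric; median-of-medians ensembling; a two-model
   filter halves the top slice by the secondary model's scores;
5. **select / expand** — drug-likeness property rules, directed sphere
   exclusion (DISE, Tanimoto-distance radius 0.2) for a diverse
   purchase list, and similarity-threshold (ECFP6 ≥ 0.35) hit
   expansion;
6. **confirm** — 1:1 binding-model fits for SPR steady state and
   kinetics (K_D = k_d/k_a), Boltzmann DSF melts (T_m), FP displacement
   (K_disp as the logistic inflection), and a selectivity matrix of
   normalized percent binding against theoretical R_max.

Fingerprinting and molecular properties go through OpenBabel (`obabel`
on PATH); forests through `ranger`; nonlinear fits through
`minpack.lm`.

## Worked example

The numbered scripts under `analysis/` run the whole study; each writes
its tables under `results/`. Stage 1–3 simulate and label a 2-cycle
50×50 screen (5 competitive + 3 noncompetitive planted motifs, 25
matrix binders, 10^5 reads per condition):

```
$ Rscript analysis/01_simulate_screen.R
no_target              100000 reads, 89942 pre-PCR molecules
target                 100000 reads, 90014 pre-PCR molecules
target_plus_competitor 100000 reads, 90125 pre-PCR molecules
library: 2500 members; planted truth: 396 binders, 25 matrix binders

$ Rscript analysis/02_decode_counts.R
no_target  100000 reads: 97334 decoded, 2666 rejected (length=0, bad_constant=1029, unknown_tag=1637), 88000 unique molecules
...
$ Rscript analysis/03_enrichment_labels.R
classes: competitive_hit=248, matrix_binder=25, non_hit=1649, noncompetitive_hit=148
competitive sensitivity 1.000 | matrix sensitivity 1.000 | non-hit specificity 1.0000
```

Every planted competitive motif is recovered as a `competitive_hit`
(the competitor condition abolishes its enrichment, separating it from
the noncompetitive motifs), matrix binders are flagged from the
no-target condition, and no null member is mislabeled. Stages 4–5 train
the models and rank a 5000-compound synthetic catalog containing 100
planted analogs of the PTEs:

```
$ Rscript analysis/05_virtual_screen.R
planted analogs in ensemble top 100: 87 (random expectation 2)
two-model filter: 5000 -> 500 candidates
purchase list: 50 diverse compounds; 40 are planted analogs
purchase-list novelty: median max-similarity to PTEs 0.59, median top-10 mean 0.47
```

The ensemble concentrates planted analogs ~43× over chance in its top
100, and the DISE-selected purchase list stays structurally diverse
(pairwise Tanimoto distance > 0.2). Stage 6 fits the confirmation
assays on simulated titrations with known parameters:

```
$ Rscript analysis/06_binding_confirmation.R
steady state: KD = 1.94e-05 M (true 1.8e-05), Rmax = 51.5 RU
kinetics: ka = 9.92e+04 1/(M s), kd = 0.01 1/s, KD = 1.01e-07 M
DSF: apo Tm = 51.98 C, +compound Tm = 55.46 C (delta 3.48 C)
FP displacement: Kdisp = 3.2e-05 M (true 3.6e-05)
       T1   T2   T3  T4
hitA 83.1  5.1  5.1 5.1
hitB  5.2 82.5  5.2 5.0
hitC  5.0  5.0 87.7 4.9
```

The selectivity matrix shows each simulated hit binding only its
intended target (~85% normalized binding on-target, ~5% off-target).

The same machinery is available programmatically:

```r
library(delscreen)
cfg <- run_config("toy", seed = 1)     # minutes-scale smoke profile
manifest <- run_pipeline(cfg, "my_run/")
```

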