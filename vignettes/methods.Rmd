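---
title: "Methods: structural feature landscapes of cytoplasmic and exported proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural feature landscapes of cytoplasmic and exported proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoland)
```

## The scientific question

Bacterial proteomes are split between proteins that stay in the cytoplasm
(the *cytoplasmome*) and proteins that leave it (the *exportome*: inner-
membrane-embedded proteins plus the *secretome* of periplasmic, lipoprotein,
outer-membrane and extracellular proteins).  Exported proteins must avoid
folding prematurely in the cytoplasm, cross the inner membrane in an
unfolded state, and only then acquire their native structure.  `topoland`
implements a proteome-wide comparison of the intrinsic structural
properties that distinguish these groups — residue composition, hydropathy,
isoelectric point, biosynthetic cost, hydrophobic patches, intrinsic
disorder, early folding, aggregation propensity, relative contact order,
fold repertoire and abundance variability — together with the
group-comparison statistics and a cross-validated cytoplasmome-vs-secretome
classifier with feature-family ablations.

All analyses operate on **mature sequences**: the signal peptide (whose
length is an annotation input, never predicted) is removed first, and every
coordinate downstream is 1-based inclusive on the mature sequence.
Residues read as `X` are excluded from the numerator and denominator of
every composition statistic, while per-residue tracks still cover them
positionally.

## Sequence features

* **Composition profiles** count the fraction of residues in named sets.
  The polar (D,E,K,H,R,Q,N,S,C,T,Y,W), hydrophobic
  (I,L,V,F,Y,W,H,T,C,G,A,M,K) and small (G,S,A,C) sets follow the
  composition conventions of this analysis tradition; note they are
  composition sets, not physical classes (glycine sits in both the small
  and the hydrophobic set).  Charged {D,E,H,K,R}, aromatic {F,W,Y},
  aliphatic {A,I,L,V} and a TOP-IDP-style disorder-promoting set
  {A,R,G,Q,S,P,E,K} complete the default list; all sets are overridable
  because reasonable variants exist in the literature.
* **GRAVY** is the arithmetic mean of Kyte–Doolittle constants.
* **Isoelectric point** solves the Henderson–Hasselbalch net-charge
  equation (N-terminus, C-terminus, D/E/C/Y/K/R/H side chains, EMBOSS pKa
  set) by bisection on pH ∈ [0, 14] to |charge| < 10⁻⁴.  Bisection is
  appropriate because the net charge is strictly decreasing in pH; the
  test suite confirms agreement within 0.01 pH units with a dense-grid
  search.
* **Biosynthetic cost** is the mean Akashi–Gojobori opportunity cost (ATP
  equivalents) per residue.
* **Hydrophobic patches** are maximal runs (≥ 5 residues by default) of a
  *stricter* patch set {A,C,F,I,L,M,V,W} — the Kyte–Doolittle-positive
  core plus tryptophan.  Using the composition "hydrophobic" set here
  would be wrong (it contains lysine and glycine); the patch set is
  config-overridable because the field also uses windowed-hydropathy
  definitions.

## Track segmentation

Per-residue predictor tracks (disorder, backbone dynamics, early folding,
aggregation, secondary-structure propensities) are consumed as inputs; the
package never re-implements the predictors.  Segmentation is a single
primitive — maximal runs of positions with score ≥ threshold, kept at a
minimum length — applied with per-kind conventions:

* **IDRs**: threshold 0.5 (the IUPred2 convention), minimum length 5;
  short IDRs are 5–19 residues, long ones ≥ 20.  Coverage is computed on
  the *merged* IDR cover, and a protein is an **IDP** when coverage
  reaches 30%.  Position classes: N-terminal when the segment starts in
  the first 30 residues, C-terminal when it extends into the last 30,
  middle otherwise; for short proteins where both apply, N wins (an
  explicit tie-break, so heat-map rows are reproducible).
* **Early foldons**: threshold 0.163 (the published EFoldMine operating
  point), minimum length 5.
* **APRs**: threshold 5.0 on the 0–100 TANGO-style scale, minimum length 5.
  **Gatekeepers** are the up-to-3 residues flanking each APR on each side,
  deduplicated across APRs and excluded when they fall inside another APR.
  The 3-residue flank width is a package default (the convention the
  aggregation literature uses); it is configurable because no single
  width is canonical.

Per-100-residue frequencies always use the mature length as denominator.

## Structure features

Relative contact order is computed from coordinates alone:
contacts are residue pairs with any heavy-atom pair closer than 6 Å at
sequence separation ≥ 1 (the original contact-order convention; a CA-only
mode exists for backbone-trace models), absolute contact order is the mean
sequence separation over contacts, and rCO divides by the modeled chain
length L measured from first to last resolved residue *including*
unresolved interior gaps (which contribute no contacts).  This makes rCO
reproducible from any deposited coordinate set without external sequence
look-ups.  rCO is invariant under rigid motion and residue renumbering,
equals 1/L for an ideal extended chain, and never exceeds 1 — all enforced
as tests.  PDB reading keeps the first model and first alternate location
and treats missing residue numbers as unresolved.

## Fold repertoire and abundance variability

The census joins a SCOP-style domain table to topology groups.  A fold is
*rare* when it occurs 1–3 times in the whole proteome and *frequent* at
≥ 4; *unique* when all its occurrences fall in one group; *popular* within
a group when it carries ≥ 3% of the group's fold instances.  Class
composition (α, β, α/β, α+β) counts each distinct fold once per group — a
repertoire view, not an instance census — because the question is which
structural solutions a compartment has at its disposal; an
instance-weighted view is available through the per-fold counts.  Class f
(membrane) folds can be excluded to restrict the census to soluble folds.

The abundance **variability score** is the standard deviation of log2
abundance across growth conditions.  This choice (over, say, a linear-scale
CV) is scale-free under multiplicative noise, exactly zero for constant
rows and invariant under global rescaling of the matrix; a CV mode is
provided.  Classes very-low/low/moderate/high are assigned by quartiles by
default, with an explicit-cutoff mode for calibrated class boundaries; ties
at a boundary go to the lower class so degenerate inputs behave
predictably.

## Group statistics and classification

Numeric features are compared with Kruskal–Wallis (midranks, tie
correction), boolean features with Fisher's exact test, reported with the
star scheme \*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05, # p ≥ 0.05 on
**raw** p-values — no multiplicity correction by default, matching the
star-scheme reporting convention common in proteome-wide feature surveys;
a correction flag exists.  Positional N-terminal profiles average each track position over
the proteins still long enough to contribute, for the first 90
(ribosome-exposed) mature residues.

The classifier is an L1-penalized logistic regression evaluated by
repeated stratified cross-validation (10 folds × 10 repeats by default).
The penalty doubles as embedded feature selection.  Median imputation of
masked cells, zero-variance filtering and penalty tuning all happen
*inside* each training fold — a leakage canary test (a feature equal to
the labels, evaluated under permuted labels) confirms the test folds stay
clean.  Metrics (AUC, accuracy, per-class precision) are averaged over
folds with percentile-bootstrap 95% confidence intervals.  The ablation
suite runs three paired rows: all features,
non-disorder features, disorder features only, on *identical* CV splits so
the comparison is paired.  Analyses of this kind are often run through
automated machine-learning services; this package deliberately uses a
standard, seeded, fully reproducible procedure instead — the contract is
the report shape and the ablation design, not the algorithm identity.

## The synthetic study

Because the real analysis depends on a full reference proteome and several
external predictor runs, the package ships a generator that produces
proteomes with the same *statistical structure*, with known ground truth:

* per-group residue composition targets tilted so that the secretome is
  higher in polar/small/disorder-promoting fractions and the cytoplasmome
  in hydrophobic/charged/aromatic/aliphatic fractions, GRAVY and
  biosynthetic cost;
* log-normal lengths (cytoplasmic proteins longer), signal peptides only
  on secretome records;
* tracks built as moving-average-smoothed Gaussian noise (window 5,
  mimicking predictor autocorrelation) with plateaus planted at known
  coordinates, raised a configurable number of noise standard deviations
  (SNR, default 3) above the calling threshold.  Planted IDR rates default
  to 1.1 vs 0.7 per 100 residues (secretome higher), APRs 1.0 vs 0.7 and
  early foldons 1.4 vs 0.9 (cytoplasmome higher);
* ideal-geometry CA traces — helices for cytoplasmic, hairpins for
  secreted proteins — planting the higher-rCO-in-secretome contrast;
* a fold pool with shared folds, many unique cytoplasmome folds (α/α-β
  heavy) and few unique secretome folds (β-dominated);
* an abundance matrix over 13 conditions with planted variability classes
  (class proportions 10.4%/41%/40%/8.6%, very-low rows exactly constant)
  and a higher cytoplasmome abundance mean; and
* gatekeeper residues written into the sequence flanks of planted APRs
  with group-specific residue bias (cytoplasmome E/R-rich, secretome
  D-rich).

Where a realistic magnitude is known for E. coli at desk scale (IDR
rates, variability class proportions, essentiality rates), the generator
defaults to it.  Where only a direction is programmed, magnitudes were fixed
once by a normal-approximation power calculation so that every programmed
direction is detectable (target z ≥ 5) at the default study size of 400
proteins per group, and they are configuration, not constants.  The
default acceptance study therefore recovers 21/21 programmed directions at
p < 0.01, and the ablation suite orders AUC(all) ≥ AUC(disorder-only).

What passing these tests shows — and what it does not: the synthetic
proteome has independent residues within a Dirichlet-multinomial
composition model, idealized geometry, uncorrelated feature noise and a
clean two-group structure.  Real proteomes have domain architecture,
phylogenetic correlation, annotation noise and overlapping topology
classes, so synthetic recovery demonstrates the *correctness of the
machinery*, not the effect sizes to expect on real data.  In particular
the near-perfect synthetic AUC simply reflects the programmed separation,
not what a real proteome would yield.

## Numerical choices and degenerate inputs

* Segment calling uses ≥ semantics at the threshold and at the minimum
  length; boundary cases (coverage 0.29 vs 0.30, fold totals 3 vs 4,
  popularity exactly 3%) are pinned by tests.
* The redundancy filter clusters greedily, longest sequence first (the
  CD-HIT convention), with identity defined as identical columns divided
  by alignment length of a deterministic Needleman–Wunsch global alignment
  (match +1, mismatch −1, gap −1, diagonal-preferring traceback).  The
  exact parameters of the original clustering are not published; this
  greedy policy is deterministic and oracle-checkable at test scale.
* Bisection for pI runs at most 100 iterations; convergence is guaranteed
  by monotonicity of the charge curve.
* rCO is undefined (an error, not NA) for structures with no contacts;
  the feature-table assembler converts such errors to masked cells.
* Empty and all-X sequences, non-contiguous track positions, overlapping
  planted segments, non-positive abundances and unsorted class cutoffs
  are all rejected with named errors.

## Problem sizes

The shipped tests and the acceptance script run the synthetic study at 400
proteins per group, oracle-equivalence sweeps at 1000 random tracks and
sequences, the Fisher enumeration over all 2×2 tables with grand total
≤ 30, and 1000 simulated Kruskal–Wallis nulls — sizes chosen so the whole
suite completes in a few minutes on a single core while every property is
exercised at meaningful scale.

## Known limitations

* External predictor tracks are inputs; nothing here validates their
  accuracy.
* The classifier is one standard embedded-selection method; it will not
  reproduce the exact selected-feature list of an AutoML system.
* The fold census consumes a domain table; no HMM scanning is performed.
* Structure handling is single-chain, first-model, ATOM-record PDB only.
* No canonical variability-score formula exists in the literature; the
  log-SD definition here is one principled choice (zero for constant
  rows, scale-free), with CV as the shipped alternative.
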