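# topoland

Structural feature landscapes of cytoplasmic and exported bacterial
proteomes.

## The problem

More than a third of a bacterial proteome leaves the cytoplasm after
synthesis.  Exported proteins ("exportome": inner-membrane proteins plus
the **secretome** of periplasmic, lipoprotein, outer-membrane and
extracellular proteins) must avoid premature folding in the cytoplasm,
cross the inner membrane unfolded, and only then acquire native structure.
This package implements a proteome-wide comparison of the intrinsic
structural properties that distinguish the **cytoplasmome** from the
secretome, for structural bioinformaticians who want those comparisons —
and the classifier built on them — as tested, reusable, seeded code.

## What it computes

Per mature protein (signal peptide removed; coordinates 1-based on the
mature sequence):

* **Sequence features** — residue-set fractions (polar, hydrophobic,
  small, charged, aromatic, aliphatic, disorder-promoting),
  GRAVY = mean Kyte–Doolittle hydropathy, isoelectric point (bisection on
  the Henderson–Hasselbalch net charge, EMBOSS pKa set), mean
  Akashi–Gojobori biosynthetic cost, continuous hydrophobic patches and
  their flanking quintapeptides.
* **Track segmentation** — from per-residue predictor tracks:
  intrinsically disordered regions (IDRs, runs of score ≥ 0.5 of length
  ≥ 5; short 5–19, long ≥ 20; IDP when merged coverage ≥ 30%), early
  foldons (score ≥ 0.163, length ≥ 5), aggregation-prone regions (APRs,
  score ≥ 5 on a 0–100 scale) with flanking gatekeeper residues and their
  composition, and N/middle/C positional classes (30-residue windows).
* **Structure features** — residue contact pairs (heavy atoms < 6 Å,
  separation ≥ 1), absolute and **relative contact order**
  `rCO = (1/N) Σ (j − i) / L`, termini distance, secondary-structure
  content.
* **Fold repertoire census** — per-fold counts across topology groups,
  unique/shared status, rare (1–3 occurrences) vs frequent (≥ 4), class
  composition over SCOP classes a/b/c/d, popular folds (≥ 3% of a group's
  instances), domains per protein.
* **Abundance variability** — per-protein variability score
  `VS = sd(log2 abundance)` across growth conditions, binned into
  very-low/low/moderate/high classes.
* **Group statistics** — Kruskal–Wallis (numeric) / Fisher's exact
  (boolean) per feature with the `***/**/*/#` star scheme on raw
  p-values; positional N-terminal profiles over the first 90 residues.
* **Classification** — seeded repeated stratified cross-validation of an
  L1-penalized logistic regression (embedded feature selection,
  fold-internal imputation), reporting AUC / accuracy / per-class
  precision with bootstrap 95% CIs, and a three-way ablation (all
  features / non-disorder / disorder-only) on paired CV splits.
* **Synthetic data** — a seeded generator producing proteomes, tracks with
  planted segments, toy structures, fold pools and abundance matrices
  with known ground truth, so every stage has a recovery test without
  external downloads.

## Worked example

```r
library(topoland)

study    <- generate_synthetic_study(n_per_group = 100, seed = 20)
features <- compute_feature_table(study$bundle, study$groups,
                                  config = list(ca_only = TRUE))
cmp <- compare_feature_table(features, groups = c("cytoplasmome", "secretome"))
head(cmp[order(cmp$p), c("feature", "test", "p", "stars", "direction")], 8)
#>                 feature           test            p stars    direction
#>                     rco kruskal_wallis 3.451890e-45   ***    secretome
#>                  co_abs kruskal_wallis 3.451890e-45   ***    secretome
#>              n_contacts kruskal_wallis 3.451890e-45   *** cytoplasmome
#>            termini_dist kruskal_wallis 3.451890e-45   *** cytoplasmome
#>          abundance_mean kruskal_wallis 2.469905e-34   *** cytoplasmome
#>  backbone_dynamics_mean kruskal_wallis 2.523939e-34   ***    secretome
#>                    cost kruskal_wallis 2.994575e-33   *** cytoplasmome
#>                   small kruskal_wallis 1.657101e-30   ***    secretome
```

The comparison table is the analysis' feature ledger: each row is
one feature, the test used, the raw p-value with its stars, and which
group sits higher — here relative contact order, backbone dynamics and
small-residue content are higher in the secretome, while abundance,
biosynthetic cost and contact counts are higher in the cytoplasmome,
exactly as programmed into the generator.

```r
suite <- ablation_suite(features, n_folds = 10, n_repeats = 2, seed = 20)
suite$all_features
#> <classifier_report 'all_features'>
#>   auc                      1.000 (1.000, 1.000)
#>   accuracy                 1.000 (1.000, 1.000)
#>   precision_cytoplasmome   1.000 (1.000, 1.000)
#>   precision_secretome      1.000 (1.000, 1.000)
#>   selected features: 5
suite$disorder_only
#> <classifier_report 'disorder_only'>
#>   auc                      0.633 (0.577, 0.688)
#>   accuracy                 0.583 (0.535, 0.633)
#>   precision_cytoplasmome   0.577 (0.533, 0.624)
#>   precision_secretome      0.597 (0.549, 0.653)
#>   selected features: 9
```

With the full feature set the synthetic groups separate perfectly (the
generator plants wide margins); restricted to the disorder family alone
the AUC drops — the paired ablation design quantifies how much the other
feature families add.  On real proteome data the same code produces the
analysis-grade version of these tables.

See `vignettes/methods.Rmd` for the model, thresholds, default choices and
their rationale.

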