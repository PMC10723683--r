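# edjshape

Geometric-morphometric classification of lower-molar **enamel-dentine
junction (EDJ)** shapes, with companion tools for post-processing ancient
enamel proteomes. The package is aimed at dental paleoanthropologists
working with isolated hominid (here: orangutan) molars, where the outer
crown is worn or taphonomically damaged and the EDJ — the internal
interface between enamel cap and dentine core — carries the taxonomic
signal.

## What it computes

Each tooth is a configuration of K = 147 ordered 3D points: 5 fixed
landmarks on the dentine-horn apices (protoconid → metaconid → entoconid
→ hypoconulid → hypoconid) and 142 semilandmarks along the marginal
ridges connecting them. The morphometric pipeline is:

1. **Mirroring** — left molars are reflected (x → −x) so all teeth are
   right antimeres.
2. **Generalized Procrustes analysis** — iterative removal of position,
   centroid size CS = √Σᵢ‖xᵢ − x̄‖² and orientation (least-squares
   rotation via SVD, reflections suppressed), giving Procrustes shape
   coordinates and a consensus shape.
3. **PCA** of the vectorized shape coordinates.
4. **Canonical variate analysis** on the first *k* PC scores, with *k*
   chosen as the minimum number of PCs reaching the optimum of
   cross-validated correct classification. Canonical vectors **a** solve
   **W**⁻¹**B a** = λ**a** (pooled within-group covariance **W**, divisor
   n − G; size-weighted between-group covariance **B**, divisor G − 1),
   scaled so **a**ᵀ**W a** = 1 — Euclidean distance in canonical space is
   then Mahalanobis distance.
5. **Jackknife classification** — leave-one-out refits of the CVA with
   nearest-centroid (Mahalanobis) assignment, tabulated as the familiar
   group × predicted frequency/percentage tables.
6. **A posteriori projection** of specimens excluded from the fit (small
   sites, sampled teeth), and **typicality probabilities**
   P(χ²_df ≥ D²) of each specimen against each group centroid.
7. **Allometry tests** — Pearson correlation (and r²) of each canonical
   axis with centroid size.
8. **Extreme shape reconstruction** along any canonical axis, for
   visualizing what the axes mean anatomically.

The proteomics side post-processes peptide evidence tables from a
database search of ancient enamel: intensity-weighted **deamidation**
rates (N/Q) and **arginine→ornithine** conversion ratios (damage-based
authentication), per-sample **consensus sequences** from aligned peptide
fragments, per-protein **amino-acid coverage**, the parsimony rule that
collapses the isobaric **isoleucine/leucine** ambiguity against modern
reference individuals, **concatenation** of per-protein alignments into a
phylogeny-ready supermatrix (FASTA / relaxed PHYLIP / NEXUS + RAxML-style
partitions), and **single amino acid polymorphism (SAP)** reports.

Synthetic-data generators (`simulate_dataset()`, `simulate_evidence()`)
provide datasets with known ground truth for every stage.

## Worked example

The numbered scripts under `analysis/` run the whole study design on
synthetic data and write their tables under `results/` (regenerate with
`Rscript analysis/01_simulate.R` … `04_proteomics.R`). In brief:

```r
library(edjshape)
sim <- simulate_dataset(simulation_spec(n_posteriori = 5, seed = 1))
res <- run_pipeline(sim$dataset, k_max = 15)
res
#> <edj_pipeline> subset=all, 112 specimens, 2 PCs, 5 groups
#>   CV% variance: 95.98/4.02 | overall jackknife accuracy 100.0%
```

112 specimens in five groups (China, Vietnam, Indonesia, *P. abelii*,
*P. pygmaeus*; sizes 9/35/25/20/23, five held out a posteriori) are
superimposed; the screening selects 2 PCs — the planted group effect
(δ = 0.2) dwarfs the landmark noise (σ = 0.005), so two canonical axes
carrying 95.98% and 4.02% of the among-group variance separate the
groups completely (overall jackknife accuracy 100%). Each a posteriori
specimen is most typical of its own group (e.g. the held-out Vietnam
tooth: P = 0.099 for Vietnam, ≤ 3×10⁻⁴⁴ elsewhere), and no canonical
axis correlates with centroid size (allometry p = 0.80 and 0.41) —
the generator plants shape, not size, differences.

```r
ev <- simulate_evidence(n_samples = 5, peptides_per_sample = 300,
                        deamidation_prob = 0.9, orn_prob = 0.1, seed = 2)
damage_statistics(ev$records)
#>   sample_id n_peptides deamidation_pct arg_orn
#> 1 sample_01        300            86.4  0.0750
#> ...
```

Per-sample deamidation comes back in the 86–93% band around the planted
90% — the range that authenticates ancient proteins — and the ornithine
ratios scatter around the planted 0.1.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analysis from scratch at the given seed —
synthetic five-group dataset → mirroring → GPA → PCA → CVA (12 PCs) →
jackknife → a posteriori typicalities → allometry, then the proteomic
damage statistics on simulated evidence — printing all summary tables
and writing the JSON report to `--out`.
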