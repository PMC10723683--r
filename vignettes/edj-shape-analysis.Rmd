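---
title: "Methods: EDJ shape classification and enamel-proteome post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDJ shape classification and enamel-proteome post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edjshape)
```

This vignette documents the statistical model behind the package, the
choices made where the procedure admitted more than one reasonable
convention, what the synthetic generators do and do not emulate, and the
known limitations. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The data and the question

Isolated fossil orangutan molars are hard to assign to species: outer
crown morphology overlaps heavily across taxa and is degraded by wear.
The enamel-dentine junction (EDJ), protected under the enamel cap,
retains a ridge-and-horn geometry that is taxonomically informative. A
tooth is represented by K = 147 ordered 3D points — 5 fixed landmarks on
the dentine-horn apices in the cyclic homology order protoconid →
metaconid → entoconid → hypoconulid → hypoconid, plus 142 semilandmarks
along the marginal ridges connecting them. The question is whether
groups of teeth (geographic fossil samples, extant species) occupy
distinct regions of shape space, how reliably an individual tooth can be
assigned, and whether apparent shape differences are secretly size
(allometry).

## 2. Superimposition

Left molars are reflected through the first coordinate axis so all teeth
are analyzed as right antimeres; after Procrustes alignment the choice
of reflection plane is immaterial, which is why a single-axis negation
suffices. Generalized Procrustes analysis then removes position (each
configuration centered), size (scaled to unit centroid size; "full"
Procrustes) and orientation (least-squares rotation, computed from the
SVD of the cross-product matrix with the smallest singular value
sign-corrected so a reflection can never sneak into the fit).

Numerical conventions, all deterministic:

* the consensus is initialized from the first configuration, so results
  are reproducible given input order;
* each iteration rotates all configurations to the current consensus,
  then re-averages and renormalizes the consensus to unit centroid
  size; the convergence metric is the RMS change of the consensus
  (default tolerance 1e-10, cap 100 iterations; non-convergence returns
  a flagged result with a warning rather than an error);
* semilandmarks are treated as fixed points. No sliding (bending-energy
  or minimum-distance) is performed; if the coordinates being analyzed
  were sampled by a consistent curve protocol this mainly costs a little
  within-group noise. This is a documented limitation.
* no tangent-space projection is applied by default: analyses run on the
  Procrustes shape coordinates themselves. At the shape distances
  involved here the curvature effect is far below the group signal.

Size is not discarded: centroid sizes in original units are kept for the
allometry tests.

## 3. Ordination and classification

**PCA.** The n × 3K matrix of aligned coordinates is decomposed via the
SVD of the centered data (equivalent to the covariance
eigendecomposition, divisor n − 1, but stable when 3K ≫ n). Eigenvector
signs follow the largest-magnitude-loading-positive convention so that
plots and stored scores are platform-reproducible.

**PC-subset selection.** CVA needs many fewer variables than specimens.
The package screens k = k_min … k_max, running the full jackknife
classification on the first k PCs, and returns the smallest k attaining
the maximum overall accuracy — the minimum number of PCs reaching the
optimum of correct classification. The tie rule (smallest such k)
matters: accuracy plateaus are common and the smaller model is the
defensible one. For reproducing the published analyses the subset can be
fixed (12 PCs for M1–M2, 15 for M3).

**CVA.** With groups g of sizes n_g, pooled within-group covariance
**W** (divisor n − G) and between-group covariance **B** built from
group means weighted by n_g (divisor G − 1), the canonical vectors solve
the generalized eigenproblem **B a** = λ **W a**, computed by Cholesky
whitening of **W** followed by a symmetric eigendecomposition (never the
non-symmetric `solve(W) %*% B`, which is kept in the tests as the
independent oracle). Vectors are scaled so **a**ᵀ**W a** = 1; the pooled
within-group covariance of canonical scores is then the identity and
Euclidean distance in canonical space *is* Mahalanobis distance. There
are c = min(G − 1, n_pcs) axes; percent variance is 100·λ_k/Σλ.
Size-weighted **B** and the unbiased-style divisors were chosen for
comparability with standard discriminant implementations; with the
package's data flow the alternative (unweighted means) shifts percent
variance by well under a point.

**Classification and jackknife.** A specimen is assigned to the nearest
group centroid in canonical space; ties (measure-zero, but constructible)
go to the earlier group in the model's group order. The jackknife
removes one specimen, refits the CVA — group means, **W**, canonical
vectors — on the remaining n − 1 *on the same fixed PC scores*, and
classifies the held-out specimen. Not recomputing the PCA per fold is
the convention that keeps the PC-screening well defined and matches
common morphometric practice; the PCA is a rotation fitted without group
labels, so the optimism it could leak is negligible. A fold whose
removal would empty a group or make **W** singular is skipped with a
warning and recorded.

**A posteriori projection.** Specimens from sites with too few teeth to
support a group (and teeth destructively sampled for proteomics) are
kept out of the CVA fit entirely — they enter the GPA and PCA (so they
live in the same coordinate system) but never touch **W**, **B** or the
grand mean. Their PC scores are truncated to n_pcs, centered by the
*training* grand mean, and projected on the canonical vectors.

**Typicality.** For specimen score **z** and group centroid **m**,
D² = ‖**z** − **m**‖² in canonical space, and typicality is the
chi-square upper tail P(χ²_df ≥ D²). The reference df is genuinely
ambiguous in the literature; the package defaults to df = c (the
dimension the distance is actually measured in) and offers
df = n_pcs as an option. A specimen at a centroid has typicality
exactly 1; typicality is strictly decreasing in D².

**Allometry.** Pearson r between centroid size and each canonical axis,
two-sided p from the t distribution on n − 2 df, and r². Raw centroid
size is the default (log size is an option) — the tested hypothesis is
"does this axis encode size", not a growth model.

**Extreme shapes.** A canonical axis is visualized by composing the two
linear maps back to landmark space: mean shape + s · E₁:ₚ **a**, with E
the PC eigenvectors. Score s = 0 returns the consensus exactly, and the
reconstruction is linear in s.

## 4. The synthetic shape world

`simulate_dataset()` emulates the structure of the study collection, and
its defaults are fixed at that stated world: 5 groups (China, Vietnam,
Indonesia, *P. abelii*, *P. pygmaeus*) with sizes 9/35/25/20/23
(the study's morphometric sample), 147-point configurations from an
idealized EDJ template (elliptical crown outline, five elevated horn
apices, ridge arcs dipping between horns), group mean shapes displaced
by δ = 0.2 (units of template centroid size) along a fixed, documented
deformation basis — per-horn height offsets plus mesiodistal
elongation, the contrasts the real canonical axes express — landmark
noise σ = 0.005 per coordinate, lognormal size spread 0.15, half the
teeth stored as left antimeres, uniform random rotations and
translations. δ/σ = 40 makes the default world strongly separated, which
is deliberate: it is the regime in which the pipeline's bookkeeping
(mirroring, projection, typicality) can be verified sharply. The
calibration tests instead set δ = 0 or permute labels.

What the generator does **not** emulate: molar-position metamery (M1 vs
M3 shape trends), wear, observer landmarking error structure
(correlated along ridges rather than iid), unequal within-group
covariances, and any size–shape coupling. Consequently a green test
establishes the estimators and their calibration under the stated
world — not that real *Pongo* groups are separable; that claim belongs
to the real data, which the test suite's replication criterion runs
whenever the supplementary coordinate table is supplied (it is not
redistributable with the package, so that one criterion reports as
failing in its absence).

## 5. Proteomic post-processing choices

* **Damage statistics.** The deamidation computation behind the
  published figures is cited to a script, not printed; the package
  therefore exposes both estimators: the intensity-weighted occurrence
  fraction 100·Σw·d / Σw·n_NQ (default; records with missing intensity
  fall back to weight 1) and the unweighted count fraction. They agree
  under equal weights and are both invariant to rescaling all
  intensities. Arg→Orn is the same statistic over arginines, reported
  as a proportion. Parameter-recovery tests use the unweighted
  estimator, whose error is binomial.
* **Consensus reconstruction** is positional: fragments carry 1-based
  start offsets on the reference (the MAFFT `--addfragments` step that
  produces such placements is out of scope). Per column: majority
  residue; ties break toward the highest-intensity covering fragment,
  then lexicographically — determinism over elegance. Uncovered columns
  are `X`; covered count excludes `X` and gaps.
* **I/L collapsing** follows the quoted parsimony rule exactly, applied
  per column restricted to columns where at least one fossil shows I or
  L: modern unanimous in one of the two → fossils switched to it;
  modern carrying both → every I/L residue in the column set to L. When
  the modern samples show neither I nor L at such a column the rule is
  silent; the package leaves the column unchanged (no parsimony call is
  possible). Only I/L residues are ever rewritten, which is what makes
  the operation idempotent.
* **SAP detection** reports columns with ≥ 2 distinct non-gap, non-`X`
  residues within the focal clade, with per-group frequency tables;
  variation expressed only through gaps/unknowns is not a polymorphism.
  Collapsing I/L first is recommended so isobaric noise is not reported.
* **Concatenation** appends proteins in the given order, gap-fills
  missing samples, and emits FASTA (Biostrings), NEXUS with a charset
  block (ape) and relaxed PHYLIP (written directly — no installed
  package writes relaxed amino-acid PHYLIP), plus a RAxML-style
  partition file. Tree inference itself is out of scope.
* The evidence simulator's toy proteome is four short synthetic
  sequences (labelled as stand-ins, not biological sequences) chosen to
  be N/Q/R-rich so damage statistics have events to count.

## 6. Degenerate inputs and numerical guards

Rank-0 configurations abort the rotation solve; zero-size configurations
abort GPA; singular **W** produces an instructive error (reduce n_pcs)
rather than a pseudo-inverse, because a silently regularized CVA changes
the reported percentages; `pmax(d2, 0)` guards the typicality distances
against negative round-off; eigenvalues below 1e-12 of the leading one
are dropped from the PCA rather than carried as numerical noise.

## 7. Known limitations

No semilandmark sliding; no tangent projection by default; jackknife
refits share the training PCA; typicality df convention is a choice, not
a derivation; the synthetic world is iid-Gaussian in shape space. Where
these could move published-style numbers (tangent projection, **B**
weighting), the effect is sub-point; where they could not be resolved
from the available description, both options are exposed as arguments.
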