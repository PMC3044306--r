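---
title: "Learned similarity and deviation measures for active-site template matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned similarity and deviation measures for active-site template matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enzyme function is carried by a handful of precisely arranged atoms — a
catalytic triad, a metal-binding cluster — rather than by the global fold.
Template-based active-site prediction therefore compares a small *template*
(an ordered set of atoms taken from an annotated active site) against
*local sites*: candidate atom sets in a target structure placed in
one-to-one correspondence with the template by a composition-constrained
search. Two practical settings are supported:

* **single template analysis** — one template is the query; every structure
  in a collection is searched and the candidate sites are ranked;
* **multiple template analysis** — one protein is the query; a library of
  templates is searched against it and the per-template scores are merged
  into a single ranked list of putative active sites.

The classical score for such comparisons is the RMSD after optimal
rigid-body superposition. `sitematch` implements that baseline and three
refinements, two of which are *learned* from labeled examples.

## The four measurements

Write $t_i$ for the template's atom coordinates, $s_i$ for the site's
($i = 1, \dots, m$), and let $(A, b)$ range over proper rotations and
translations.

**UMD** (unweighted mean deviation) is the squared RMSD:
$$\mathrm{UMD} = \min_{A,b} \frac{1}{m} \sum_{i=1}^m \lVert A s_i + b - t_i \rVert^2 .$$

**WMD** (weighted mean deviation) generalizes it with per-atom importance
weights $\beta$ on the simplex ($\beta_i \ge 0$, $\sum_i \beta_i = 1$):
$$\mathrm{WMD} = \min_{A,b} \sum_{i=1}^m \beta_i \lVert A s_i + b - t_i \rVert^2 .$$
Catalytically constrained atoms are positionally conserved while peripheral
atoms wobble; a learned $\beta$ concentrates the deviation measure on the
informative atoms. With uniform weights WMD equals UMD exactly, a reduction
the test suite asserts to $10^{-10}$.

**MDS** (mean DALI score) avoids superposition altogether by comparing
intra-structure distances. For atom pair $p = (i_1, i_2)$ with template
distance $d^T_p$ and site distance $d^S_p$, the DALI elastic pair score is
$$\varphi(d^T_p, d^S_p) = \left(0.20 - \frac{|d^T_p - d^S_p|}{d^*_p}\right)
  \exp\!\left[-\left(\frac{d^*_p}{20\,\text{Å}}\right)^2\right],
  \qquad d^*_p = \tfrac{1}{2}(d^T_p + d^S_p),$$
and MDS is the mean of $\varphi$ over all $m(m-1)/2$ pairs. The constants
(similarity threshold 0.20, envelope width 20 Å) are the published DALI
values and are exposed as arguments; the $d^* = 0$ singularity is resolved
by its continuity limit, $\varphi = 0.20$.

**DSDS** (DALI-score-based discriminative similarity) replaces the uniform
average with a learned linear combination $w^\top x$ of the pair-score
feature vector $x$. MDS is recovered at uniform coefficients, which the
tests assert as an identity.

Both distance-matrix measures are invariant to rigid transforms of either
structure by construction; both deviation measures are invariant to rigid
transforms of the site.

## Learning the parameters

### WMD: alternating linear program and weighted Procrustes

Given labeled sites (positives carry the template's function, negatives do
not), the quality of $(\beta, \theta)$ is a cost-weighted hinge loss with
margin $\varepsilon$: a positive site pays
$\max(0, \delta_j - (\theta - \varepsilon))$ and a negative pays
$\max(0, (\theta + \varepsilon) - \delta_j)$, where $\delta_j$ is the
site's WMD. Because $\delta_j$ itself minimizes over transforms, the full
problem is bi-level and intractable globally. `train_wmd()` alternates:

1. **LP stage** — with per-site transforms frozen, $\delta_j$ is linear in
   $\beta$; minimizing the total loss over $(\beta, \theta)$ with the
   simplex constraint and the over-fitting bound $\beta_i \le 2/m$ is a
   linear program, solved exactly (pure-R simplex method).
2. **Transform stage** — with $\beta$ frozen, each site's optimal transform
   is a weighted Kabsch/Procrustes fit in closed form (weight-scaled
   centroids and SVD of the weighted cross-covariance, reflection corrected
   to $\det A = +1$).

Transforms are initialized by the unweighted (UMD) superpositions — the
natural $\beta$-uniform starting point, since the first LP needs transforms
to exist — and two rounds are run by default. Site costs are $1/n_+$ for
positives and $1/n_-$ for negatives, so each class contributes equally
regardless of the heavy skew toward negatives. The scheme is a surrogate:
each LP is globally optimal given its transforms, but the total loss is not
guaranteed to decrease across rounds (re-fitting transforms can lower
negative-site deviations too), and the tests therefore check per-stage
optimality and constraint satisfaction rather than monotone descent.

The margin default is $\varepsilon = 0.01\,\text{Å}^2$ — small against the
$\text{Å}^2$-scale deviations the hinge compares, and affecting only margin
sharpness; it is configurable.

### DSDS: cost-weighted support vector classifier

The DSDS coefficients minimize
$\tfrac{1}{2}\lVert w \rVert^2 + \sum_j C_j \ell_j$ with the analogous
hinge $\ell_j$ around a threshold $\theta$ and unit margin; this is
precisely the soft-margin linear SVC with per-sample costs and bias
$-\theta$, and is solved with libsvm (via e1071). Costs are $1000/n_+$ and
$1000/n_-$. A non-unit margin $\varepsilon$ is supported through the exact
rescaling $w = \varepsilon v$, $\theta = \varepsilon \eta$ with costs
$C_j/\varepsilon$. No feature scaling is applied — DALI scores are already
bounded — though the constants of the score itself can be changed. The test
suite cross-checks the trainer against a grid-search minimizer of the
written objective on one- and two-feature problems.

## Local site search

`lss_search()` enumerates candidate sites whose residues match the
template's residue names and contain all required atom names, prunes
partial assignments by inter-atom distance compatibility, superposes the
survivors and keeps those with RMSD ≤ 4.0 Å (the conventional template-hit
cutoff, configurable). Design choices worth knowing:

* The published searches use geometric hashing as an index; at package
  scale a constrained depth-first enumeration returns the identical site
  set, so the index structure is treated as an optimization, not a
  contract.
* The pruning slack is $2 \cdot \text{cutoff} \cdot \sqrt{m}$, a provably
  sound (loose) bound: superposition moves no corresponding distance pair
  by more than twice the per-atom displacement budget, so no site passing
  the cutoff is ever pruned. Tests validate this against exhaustive
  enumeration.
* Chemically indistinguishable sidechain atoms (ASP OD1/OD2, GLU OE1/OE2,
  ARG NH1/NH2, LEU/VAL methyls, PHE/TYR ring flips) may stand in for each
  other; all admissible mappings are generated and the lowest-RMSD one
  kept. Residue identity itself is matched exactly — no SER↔THR style
  substitution groups.
* Alternate locations other than blank/'A' are dropped on reading;
  insertion codes are part of residue identity; only the first model of a
  multi-model file is read. Hydrogens are ignored throughout.

Template construction from annotated residues follows the four role types:
catalytic-site and modified residues contribute sidechain atoms (heavy
atoms minus N, CA, C, O, OXT), cofactor-binding-site residues contribute
all atoms, mainchain catalytic residues contribute N, CA, C, O only.
Glycine annotated as catalytic has no sidechain and falls back to its
mainchain atoms with a warning — the pattern seen in real serine-protease
templates that include a backbone glycine. Atom order (residue spec order,
then canonical PDB v3 order within a residue) is fixed and serialized,
because it defines the feature correspondence everywhere downstream.

## Post-processing for cross-template ranking

Raw WMD values (or DSDS scores) are not comparable across templates of
different sizes and compositions, so the multiple-template analysis
calibrates them:

* **LR** — a logistic posterior $P(+1 \mid \text{score})$ fitted per
  template on training scores. Under complete separation the MLE diverges;
  the fit then falls back to a ridge penalty ($\lambda = 10^{-6}$) solved
  by Newton iteration, keeping coefficients bounded and deterministic, and
  warns.
* **PINTS-style significance** — converts $\sqrt{\mathrm{WMD}}$ into a log
  expected frequency of random matches at least that good. The published
  significance scheme's exact fitted form is not reproduced here; this
  package substitutes a documented empirical-null variant: a Gumbel
  (minimum-type) location–scale model fitted by the method of moments to
  the negative-site $\sqrt{\mathrm{WMD}}$ distribution, reported as
  $\log F(r) = \log(n_- \cdot P_\text{null}(\text{dev} \le r)) -
  \text{penalty}(m)$. The default size penalty, $(m-1)\log 10$, encodes
  that each additional matched atom makes a random match roughly an order
  of magnitude rarer; it is a pluggable function argument. The Gumbel
  family is the natural choice for the left tail of a best-match
  distribution; moment fitting keeps the estimate deterministic and
  closed-form. Significance is only defined for the RMSD-type deviations —
  requesting it for MDS/DSDS is a configuration error.
* **Direct** — no calibration; only legal when all templates are scored
  with a single measurement family.

Merged rankings keep one row per (site, template) pair — a site matched by
two templates appears twice — and break ties deterministically by
structure, residue key, then template.

## Evaluation protocol

`roc_score()` uses the rank/Mann–Whitney identity with half-credit ties;
`roc5_score()` truncates the curve at the fifth false positive and
normalizes by $5 n_+$ (ties contribute fractionally through diagonal
segments; with fewer than five negatives, all are used);
`sensitivity_at_specificity()` takes the conservative convention — TPR at
the largest achievable FPR not exceeding $1 - \text{specificity}$, reading
the 95 % requirement as a floor. `make_splits()` draws repeated 50/50
structure-level splits and repairs each by swapping structures until every
template retains at least one positive training site, erroring (naming the
template) when a template has fewer than two positive-bearing structures.
`run_experiment()` trains on the training half only and records the
structure ids touched during training so the test-set firewall is
auditable, not just asserted.

## What the synthetic generator does and does not emulate

Real annotated corpora at the scale the method was designed for (hundreds
of structures, dozens of curated templates) cannot ship with a package, so
`sitematch` generates its own study conditions. `make_template()` draws
$m$ catalytic-pool atoms with pairwise distances in $[2, \text{span}]$ Å;
`make_sites()` plants rigid-transformed copies with per-atom Gaussian
displacement for positives and a larger isotropic displacement for decoys;
`make_protein_fixture()` writes valid PDB files containing a planted site
plus composition-matched decoy residues, so decoys are reachable by the
search — mirroring the hard negatives that a real template search returns.

The default **heterogeneous-noise benchmark** is $m = 6$ atoms, two
conserved at $\sigma = 0.05$ Å and four variable at $\sigma = 0.8$ Å in
positives, decoys at $\sigma = 1.5$ Å, 50 positives against 500 negatives.
The 1:10 skew keeps the class-balanced costs meaningful; the two-tier noise
gives the learned measures genuine headroom over their unlearned controls
while keeping the unweighted baseline informative but imperfect. Problem
sizes throughout the tests (tens of positives, hundreds of negatives, five
to ten seeds per stochastic property) were chosen as the smallest at which
the Monte-Carlo properties are stable.

What passing tests on this generator do **not** show: robustness to real
crystallographic artifacts (alternate conformations beyond altloc 'A',
missing atoms, non-standard residues), to correlated backbone motion
(noise here is isotropic and independent per atom), or to the biased
composition of real decoy sites, which share evolutionary context rather
than being Gaussian clouds. Conclusions about relative method performance
on real corpora require real data.

## Numerical choices and degenerate inputs

* Superposition uses the SVD closed form; orthogonality and determinant
  are maintained to $10^{-8}$. Two-atom sites leave a rotation about the
  pair axis free; the transform is flagged `non_unique` but the residual —
  the quantity under contract — is unique. Collinear configurations are
  detected by a vanishing second singular value and flagged likewise.
* The weight LP relaxes its phase-1 feasibility tolerance stepwise
  ($10^{-10} \to 10^{-8} \to 10^{-6}$) if the simplex stalls on degenerate
  vertices; solutions are accepted at any optimal vertex, and tests compare
  objective values rather than argmin vectors.
* LP degeneracy also means learned $\beta$ often saturates the $2/m$ bound
  on the conserved atoms — that is the intended over-fitting guard at work,
  not an artifact.
* Gumbel CDF evaluations are floored at $10^{-300}$ before the log so that
  extremely good deviations report a large negative, finite significance.

## Limitations

* The bi-level WMD program is solved heuristically (two alternating
  rounds); a different initialization can reach a different local surrogate
  optimum.
* The PINTS-style significance is an empirical-null stand-in, suitable for
  ranking; its absolute values are not comparable to the published server's.
* The search is exact but exhaustive; scanning full PDB mirrors would need
  the geometric-hashing index this package deliberately omits.
* Templates with several residues of the same type multiply the candidate
  assignments; the search handles this correctly but at combinatorial cost.
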