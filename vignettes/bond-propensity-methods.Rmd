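---
title: "Bond-to-bond propensity analysis: model, scoring and site statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-to-bond propensity analysis: model, scoring and site statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondprop)
```

## The problem

Allosteric sites are pockets distant from a protein's orthosteric
(active) site whose occupation modulates activity. They are prime drug
targets but hard to find computationally, because what defines them is
not local geometry but *functional coupling* across the structure.
`bondprop` scores that coupling on an energy-weighted atomistic graph:
atoms are nodes, covalent and non-covalent bonds are edges weighted by
interaction energy, and a perturbation applied at the orthosteric
bonds is propagated to every other bond through the graph Laplacian.
No interaction cutoff is applied beyond the geometric detection
criteria, so weak long-range coupling is retained, and the atomistic
resolution keeps side-chain detail that residue-level elastic network
models coarse-grain away.

## The model

### Atomistic graph

For a protonated structure, covalent bonds come from residue templates
for the twenty standard amino acids (plus distance criteria for
peptide links, disulfides and non-template groups) and are weighted by
standard bond enthalpies in kJ/mol. Four non-covalent interaction
types are detected geometrically and weighted by the absolute value of
a physical potential evaluated at the observed geometry:

| type | detection | potential | key defaults |
|------|-----------|-----------|--------------|
| hydrogen bond | donor–acceptor ≤ 3.5 Å, D-H...A ≥ 120° | 12-10 well × cos²(angle) | depth 33.5 kJ/mol, R₀ = 2.75 Å |
| hydrophobic | apolar C/S pairs ≤ 4.5 Å | 12-6 Lennard-Jones | depth 0.65 kJ/mol, σ = 3.8 Å |
| electrostatic | opposite formal charges ≤ 4.0 Å | Coulomb / ε(r), ε(r) = 4r | k = 1389.35 kJ·Å/mol |
| ring stacking | centroids ≤ 6 Å, normals within 30° | 12-6 in centroid distance | depth 8 kJ/mol, d₀ = 3.8 Å |

The exact constants of these potentials are a reproduction detail: the
analysis downstream consumes only positive edge weights in which
covalent bonds (hundreds of kJ/mol) dominate non-covalent ones (a few
kJ/mol). All constants and cutoffs live in
`default_energy_parameters()` and can be overridden per run;
attractive (negative) energies become positive weights by absolute
value because the Laplacian machinery requires nonnegative weights.

### Propensities

With incidence matrix $B$ ($n \times m$), weight matrix
$W = \mathrm{diag}(w_{ij})$ and weighted Laplacian $L = B W B^\top$,
the edge-to-edge transfer matrix is

$$M = \tfrac12\, W B^\top L^\dagger B ,$$

whose element $M_{bb'}$ measures the effect of a fluctuation at edge
$b'$ on edge $b$. The raw propensity of bond $b$ given a perturbation
source (the orthosteric ligand's protein contacts, or all bonds of the
orthosteric residues) is $\Pi_b^{\text{raw}} = \sum_{b' \in
\text{source}} |M_{bb'}|$, normalised to $\Pi_b$ summing to one;
residue propensities sum $\Pi_b$ over each residue's bonds. Rather
than forming the pseudoinverse, `raw_propensities()` performs one
sparse Cholesky solve of the grounded Laplacian per source edge
(incidence columns are orthogonal to the constant vector, so grounding
is exact up to an irrelevant constant), which scales near-linearly
with the edge count. Tests pin this against the dense pseudoinverse
construction on dozens of random graphs.

Two normalisation choices were genuinely open:

* **Source bonds are excluded** from the normalised field used for
  scoring (config-switchable). They are the perturbation, not the
  response, and their near-field values would distort the
  distance-decay fit at $d \approx 0$.
* **Residue membership**: a bond belongs to every residue that
  contributes an endpoint atom (so a bridging bond counts twice); an
  `"exclusive"` mode assigns each bond to one residue, making the
  residue field sum to exactly one — used by the conservation tests.

### Quantile scoring

Propensities decay roughly exponentially with distance from the
source, so raw values cannot be compared across the protein. For each
level $p$ of a grid (0.01–0.99 in 0.01 steps, refined to 0.001 steps
in [0.95, 0.999] because the 0.95 threshold below needs top-end
resolution), a linear quantile regression of $\log \Pi$ on distance is
fitted by minimising the tilted absolute (pinball) loss. A bond's
quantile score is the grid level whose fitted line at its distance is
nearest to its log propensity — i.e. where it sits among bonds at
comparable distance. Ties break to the lower level and extremes clamp
to the grid ends, so scores live in [0, 1] and are approximately
uniform when a dataset is scored against its own fit.

Numerical choices:

* No quantile-regression solver is available in the dependency
  stack, so the package implements one: a majorise-minimise /
  iteratively-reweighted-least-squares iteration with annealed
  smoothing, polished onto the exact solution by enumerating lines
  through pairs of small-residual points (the pinball minimiser passes
  through two data points). Fits agree with an external QR
  implementation to ~1e-5 on frozen test data.
* Finite-sample quantile crossing is removed by monotone rearrangement
  of the fitted values at each distance before score lookup.
* Zero or underflowing propensities are floored at (smallest positive
  value) × 1e-3 before taking logs; the count is logged.

*Reference* (absolute) scores use the same machinery with the model
fitted on pooled (log propensity, distance) pairs from a user-supplied
ensemble of reference proteins, each analysed with its own source.
Every pair carries equal weight in the pool. The composition of the
reference ensemble is the user's choice; the tests use synthetic
ensembles of random graphs, clearly labelled as stand-ins.

### Site statistics and verdicts

A candidate site (a residue list; bonds are those with an endpoint in
the site, ligand atoms excluded) is summarised by six measures: mean
bond score (m1), mean residue score (m2), the proportions of bond and
residue scores strictly above 0.95 (m3, m5), and the mean reference
bond/residue scores (m4, m6). Verdicts are strict comparisons: m1/m2
must exceed the upper bound of a 95% percentile bootstrap confidence
interval (10,000 resamples) for the mean of 1,000 surrogate-site
scores; m3/m5 must exceed 0.05 (the expected tail mass of a uniform
score); m4/m6 must exceed 0.5. A protein with several annotated sites
averages each measure (and the CI bounds) across sites before the
verdicts. With no reference ensemble, m4/m6 are skipped and the
report says "detected by k of 4 measures".

Surrogate sites obey two structural rules: same residue count as the
candidate, and strictly smaller diameter (maximum atom–atom distance).
The sampling algorithm — the rules do not prescribe one — grows a site
from a uniformly random seed residue, repeatedly adding a uniformly
chosen residue that keeps the running diameter below the bound,
restarting on dead ends (capped at 10,000). Surrogates may overlap the
candidate or each other; contiguity is not enforced beyond the
diameter rule. Percentile bootstrap (not BCa) is used, and the
surrogate and bootstrap seeds default to 2021 and are always logged.

**A statistical caveat worth knowing.** The m1/m2 criterion compares
one draw (the candidate's mean score) against a confidence interval
for the *mean* of the surrogate distribution, whose width shrinks like
$\sigma/\sqrt{1000}$. It is therefore not a 5% false-positive test: a
random site exceeds the bound with probability closer to one half
(empirically 0.2–0.3 on the synthetic fixtures, because candidates are
unconstrained while surrogates are diameter-constrained). The package
implements the criterion exactly as published; the test suite checks
that the null rate is non-degenerate rather than asserting a 5% rate
the construction cannot deliver. Interpretation should lean on the
ensemble of all six measures, as the original analysis does.

## Synthetic data

Three seeded generators make the whole pipeline testable offline:

* `make_mini_pdb()` — an idealised extended peptide (ALA/GLY/SER/CYS)
  with hydrogens at template geometry and an optional two-atom
  pseudo-ligand placed to accept one hydrogen bond at ideal geometry
  (donor–acceptor 2.91 Å, collinear). Adjacent apolar side chains sit
  4.32 Å apart, planting hydrophobic contacts. The generator emits a
  truth table (atom and bond counts, planted interactions) computed
  from its own bookkeeping, so graph construction is checked against
  an independent ledger. With `jitter = 0` the geometry is exact and
  the planted potentials hand-evaluable; a small jitter (~0.08 Å)
  breaks the chain's translational symmetry, which is necessary when
  surrogate sampling must find sites of strictly smaller diameter
  (all residue windows of a perfectly periodic chain tie in diameter).
* `make_random_graph()` — a connected random weighted graph with
  coordinates and block residues, shaped like an atomistic graph, for
  propensity/scoring/surrogate tests and dense-oracle comparisons.
* `make_planted_decay()` — (propensity, distance) samples with
  $\log \Pi = a + b\,d + \mathcal N(0, \sigma^2)$; defaults $b = -0.3$,
  $\sigma = 1$, $d \le 30$ Å, matching the decay scale the scoring
  stage assumes.

What a green test does **not** establish: the fixtures have no
realistic secondary structure, no crystallographic noise, no missing
atoms or alternate conformations beyond the synthetic altloc cases,
and the reference "ensemble" is synthetic. Agreement with the
published benchmark numbers requires the real PDB structures and site
annotations, which need downloads and hours of compute; the published
verdict logic itself is reproduced exactly from the printed values in
the test suite.

## Known limitations

* mmCIF, NMR ensembles and assembly generation are out of scope; only
  MODEL 1 of multi-model files is read.
* Protonation is checked (≥ 25% hydrogens among protein atoms), not
  performed; an external command hook can be configured.
* Ligand atoms are typed by element for non-covalent detection, which
  is cruder than a cheminformatics perception of donors/acceptors.
* Structural waters are removed by default; their mediation of
  interaction networks is not modelled.
* Nucleic-acid residue templates are not provided (such groups fall
  back to distance-based covalent detection).
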