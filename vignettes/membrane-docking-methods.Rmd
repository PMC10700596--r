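---
title: "Membrane-aware virtual screening and hit triage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-aware virtual screening and hit triage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscreen)
```

## The problem

Lipid-activated G-protein-coupled receptors such as the prostanoid
receptors bind their ligands in pockets that are partially exposed to the
membrane. Docking screens against such targets face a specific failure
mode: generic hydrophobic complementarity swamps the few specific polar
interactions — typically an ion pair between a ligand carboxylate and a
pocket arginine, plus hydrogen bonds to threonine/serine hydroxyls — that
actually distinguish binders. Two modelling counter-measures help: treating
the surrounding lipid as a low-dielectric medium, which strengthens every
electrostatic interaction inside the pocket, and increasing the local
dipoles of selected pocket residues so that anions are recognised
preferentially.

`memscreen` implements this campaign end to end at desk scale: scoring-grid
generation over a membrane-aware dielectric, rigid-conformer docking by
matching-sphere superposition, anion-library construction by substructure
harvesting, the hit-triage cascade (ranking, fingerprint clustering,
novelty and strain filters, required-interaction checks), decoy-based
enrichment controls, and the downstream pharmacology arithmetic used to
quantify confirmed hits.

## Scoring model

A pose is scored as

$$E = E_{\mathrm{elec}} + E_{\mathrm{vdw}} + E_{\mathrm{desolv}},$$

with all three terms read off precomputed lattices by trilinear
interpolation at the ligand atom positions.

**Electrostatics.** The receptor potential $\phi$ solves the
variable-dielectric Poisson equation $\nabla\cdot(\varepsilon\nabla\phi) =
-4\pi k\rho$ at zero ionic strength, with $k = 332.063$ kcal Å/(mol e²) so
that $\phi$ is in kcal/(mol e). The dielectric lattice takes only two
values: $\varepsilon_r = 2$ inside any receptor atom inflated by the
pocket surface extension (1.9 Å) or inside any retained lipid atom, and
$\varepsilon_r = 78$ elsewhere. Lipid atoms farther than 17 Å from every
receptor atom are discarded, producing the low-dielectric ring around the
embedded receptor; lipid atoms carry no charge. A ligand atom then
contributes $q_i\,\phi(x_i)$ — the probe-charge model.

**Anion recognition.** Before grid generation, the partial charge of
selected side-chain hydroxyl hydrogens is increased by $\delta q = 0.4$ e
and the same residue's backbone carbonyl oxygen decreased by $\delta q$,
leaving residue and receptor net charge unchanged to $10^{-9}$ e while
strengthening the local dipole. On the bundled toy complex this
perturbation improves the docked monoanion's best score while leaving its
charge-inverted twin behind — the directional property the perturbation
exists to produce, asserted in the test suite.

**van der Waals.** Two lattices store $\sum_j \sqrt{A_j}/r^{12}$ and
$\sum_j \sqrt{B_j}/r^{6}$ over receptor atoms (lipid atoms excluded), so an
atom with coefficients $(\sqrt{A_i}, \sqrt{B_i})$ scores the AMBER-style
6-12 energy by two interpolations. Distances are floored at 0.8 Å and the
per-atom repulsion capped at +100 kcal/mol: clashed poses stay finite but
keep their ordering.

**Ligand desolvation.** Each ligand atom carries a desolvation penalty
magnitude (an input, normally from a continuum-solvation calculation); the
grid stores the *occlusion* — the fraction of a ball of sample points
around each node that falls inside the receptor-plus-lipid volume, the
receptor surface extended by 0.5 Å — and the pose pays
$\sum_i d_i\,\mathrm{occ}(x_i)$. Fully solvated atoms pay nothing; buried
atoms pay in full.

## Orientation sampling

Hot spots ("matching spheres", at most 45, deduplicated and kept in order
of centroid proximity) are the heavy-atom positions of a reference ligand.
Orientations enumerate ligand heavy-atom triplets against ordered sphere
triplets; when the three pairwise distances agree within a tolerance
(default 0.5 Å) the triplet is superposed by a least-squares rigid fit
(proper rotation enforced) and the full conformer transformed. Enumeration
order is lexicographic and deterministic, truncated at a configurable
maximum. This triplet matcher is deliberately simpler than a docking
engine's internal bipartite matcher: every accepted orientation is
verifiable against a brute-force $O(n^3 m^3)$ oracle, which the test suite
does. Conformers are inputs — there is no internal conformer generator —
and ligand internal strain is handled as a post-docking filter, not in the
pose score.

## Triage cascade

Ranked output passes through: top-$N$ selection; greedy leader clustering
on 2048-bit radius-2 circular fingerprints at Tanimoto $\ge 0.5$ (walking
down the ranking, so each cluster head is its cluster's best scorer);
novelty removal at Tanimoto $\ge 0.35$ (inclusive) to any known ligand;
a torsion-strain filter keeping poses whose single most strained dihedral
is $\le 1.5$ TEU (inclusive); and a codified required-interaction check
(hydrogen bond: donor-acceptor heavy atoms $\le 3.5$ Å and donor angle
$\ge 120^\circ$; ionic: opposite charges within 4.0 Å). Every stage logs
in/out counts and rejected identifiers; the counts telescope and re-running
the cascade on its own survivors is a fixed point.

The strain model is a small built-in rule table (biaryl, amide, ester,
alpha-to-carbonyl rotors) mapping each matched dihedral to a
piecewise-linear TEU profile over the folded angle $[0^\circ, 180^\circ]$,
first-match precedence, overridable from TSV. It reproduces the
*thresholding behaviour* of a full torsion-library method, not its
energies; dihedrals matched by no rule score 0 and are logged as
uncovered. Note the distinction between the conventional rotatable-bond
count (amide C–N excluded), used as a property descriptor, and the strain
dihedral set (amide included — cis/trans amide strain is precisely what
the rule table penalises).

The stated interaction criteria replace visual inspection of poses; the
geometric thresholds are conventions, exposed as arguments.

## Library construction

Anions are harvested by SMARTS patterns: the carboxylic acid itself plus a
curated bioisostere table (tetrazole, acylsulfonamide, hydroxamic,
sulfonic, sulfinic, phosphonic acids), shipped as a stand-in for the full
32-pattern collection and overridable from file. pH-7 protonation is
rule-based at the graph level — carboxylic/sulfonic/sulfinic/phosphonic
OH and tetrazole NH lose a proton, aliphatic amines and amidines and
guanidines gain one — idempotent by construction (a centre that has
already reacted never fires again), with one proton per polyprotic centre.
Properties are molecular weight, atom-contribution clogP, net formal
charge, heavy atoms, rotatable bonds and donor/acceptor counts; the
lead-like filter applies inclusive windows (anion screen: 250–400 amu,
clogP 1–5, net charge in {$\le -2$, $-1$, 0} — the $-2$ entry is the
open-ended dianion bucket, and cations are excluded).

Analog libraries decompose a hit into its building blocks along its
make-on-demand coupling (the amide scheme is built in: retro-cut the
unique C(=O)–N bond, cap with OH) and re-enumerate the cross-product of
reagent pools, canonicalising and deduplicating; re-coupling a product's
own fragments regenerates its canonical SMILES.

## Benchmark controls

Property-matched decoys are drawn per ligand from an annotated pool inside
windows of ±25 amu, ±1.0 clogP, equal net charge, ±2 rotatable
bonds/donors/acceptors, below a Tanimoto cap of 0.35, most-dissimilar
first. A charge-stratified "extrema" set probes whether the model actually
prefers monoanions. Enrichment is quantified by the tie-averaged ROC AUC
(equal to the Mann–Whitney statistic, which the tests verify) and by the
adjusted logAUC: the integral of TPR over $\log_{10}$ FPR from $10^{-3}$
to 1, normalised by 3, minus the same integral of the diagonal — exactly 0
for random ranking and $\approx 0.8554$ at complete separation, both
reproduced as closed forms in the tests. The 0.1% floor is the convention
of the enrichment literature and is configurable.

## Pharmacology

* 4PL fits: $y = b + (t - b)/(1 + 10^{(\log_{10}x - \log_{10}\mathrm{XC}_{50})h})$,
  Levenberg–Marquardt with five log-spaced XC50 starts; returned as a
  classed object with `coef`/`predict`/`plot`/`residuals` methods.
* Cheng–Prusoff: $K_i = \mathrm{IC}_{50} / (S/K_m + 1)$.
* Ligand efficiency: $-RT\ln K_i / N_\mathrm{heavy}$ at $T = 298$ K,
  $R = 1.987\times10^{-3}$ kcal/(mol K).
* NCA: censored concentrations count as zero in the linear-trapezoid AUC
  over the observed span (AUC$_{0\text{-}t}$, no terminal extrapolation);
  the terminal half-life is $\ln 2 / k$ from a log-linear regression over
  the longest terminal run of at least three strictly quantifiable,
  strictly declining points — censored points are discarded, never
  run-breaking — and is reported as absent otherwise.
* Oral bioavailability: $F = 100\,(\mathrm{AUC}_{po}/D_{po}) /
  (\mathrm{AUC}_{iv}/D_{iv})$.
* Schild: regression of $\log_{10}(\mathrm{DR}-1)$ on $\log_{10}[B]$;
  $K_B$ is reported only when the slope lies in $[0.8, 1.2]$, the
  competitive range.

## What the synthetic generators emulate — and what they do not

The generators make every stage runnable and property-testable with known
ground truth:

* `make_toy_complex`: a rigid cluster of united-atom pseudo-atoms (charges
  in {−0.4, 0, +0.4, +1} e, radii 1.5/1.9 Å) forming a concave pocket with
  a cationic bottom and three hydroxyl/backbone-oxygen pairs, flanked by a
  lipid slab of two apolar planes at ±slab/2 on an 8 Å raster with the
  pocket mouth left open. It spans the charge-perturbation and
  anion-recognition test space without any force field — it is *not* an
  equilibrated bilayer, has no lipid chemistry and no receptor
  flexibility.
* `make_compound_library`: curated decorated SMILES templates per class
  (carboxylates, tetrazole/acylsulfonamide/hydroxamate bioisosteres,
  non-ionisable neutrals, aliphatic amines), composition by deterministic
  largest-remainder rounding, molecular weight constrained to the
  requested window. Pattern-match ground truth is exact by construction;
  chemical diversity is far below a make-on-demand library's.
* `make_planted_benchmark`: ligand scores displaced below decoy scores by
  a chosen gap — the shape (21 ligands, 658 decoys) mirrors the control
  calculation; an infinite gap gives the closed-form enrichment limits.
* `make_dose_response` / `make_pk_profile`: exact 4PL and one-compartment
  kinetics (Bateman absorption for oral/intraperitoneal routes) with
  optional Gaussian noise and below-LLOQ censoring. Dose-response data are
  generated in triplicate by default, the usual plate format. The sampling
  grid of nine timepoints over 1440 min matches the in-vivo design.

Passing tests therefore demonstrate the *algorithms* — classification,
solvers, enumeration, filters, estimators — against independent oracles on
fixtures with known truth. They do not demonstrate accuracy on real
receptors, real libraries or real assay data, and absolute docking scores
are not comparable to any production docking energy; only orderings and
invariants carry over.

## Numerical choices

* Aqueous dielectric 78 (the low value 2 is the modelled quantity; 78 is
  the standard solvent constant). Zero ionic strength; Dirichlet boundary
  from the high-dielectric Coulomb sum; face dielectrics by arithmetic
  average; red-black SOR iterated to a relative residual below $10^{-6}$
  (an explicit error reports non-convergence). Charges spread to the eight
  surrounding nodes with trilinear weights.
* Test lattices use 0.4–0.6 Å spacing in boxes of 38³–45³ nodes and a
  0.1 Å lattice for the pair-minimum interpolation check; the Poisson
  fixtures are 41³. The occlusion ball is sampled on a deterministic cubic
  subgrid (step = radius/6, ~900 points), checked against a 10⁵-sample
  Monte-Carlo oracle to 0.02.
* Tie-breaks are deterministic everywhere: enumeration order in the
  matcher, input order in ranking and clustering, pool order in decoy
  selection.
* Degenerate inputs are errors with named culprits: empty receptors,
  lattices not covering the charged atoms, atoms outside the scoring box,
  missing vdW parameters, absent required residues, all-censored PK
  profiles, flat dose-response data, oral profiles with $k_a = k_e$.

## Open design points, resolved

* How the 45 hot spots were derived from the reference ligand is not
  specified anywhere; we take all heavy atoms, deduplicate at 0.25 Å and
  keep the 45 closest to the centroid, on the view that the pocket core
  matters most. The count and the truncation rule are arguments.
* The dielectric boundary uses inflated atomic spheres rather than a
  solvent-excluded surface: it realises the stated "extend outwards by
  1.9 Å" rule directly and is exactly checkable against a per-point
  distance oracle.
* Net-charge classes for the anion screen read "{$\le -2$, −1, 0}" as
  cations excluded and the dianion bucket open-ended.
* The PK AUC is AUC$_{0\text{-}t}$; with trapezoid quadrature the
  oral-bioavailability round trip is exact only in the dense-sampling
  limit, so the recovery test uses a 2-minute grid (within 0.1%) and the
  sparse 9-point clinical design is checked to 10%.
* clogP is the OpenBabel atom-contribution implementation; tautomers are
  not enumerated (single input tautomer); both are dialect differences
  from commercial preparation tools, documented here once.

## Known limitations

Rigid receptor, rigid conformers, no ordered waters, no polarizability, no
salt in the electrostatics, a stand-in bioisostere table and strain rule
set, and a toy membrane. The matcher under-samples orientations relative
to production engines by design — its budget (default 1000 orientations)
is a correctness-first choice, not a throughput one.
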