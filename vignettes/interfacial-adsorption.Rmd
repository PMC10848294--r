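---
title: "Quantifying protein surface activity at water/vapor interfaces"
author: "adsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein surface activity at water/vapor interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsurf)
```

Proteins — monoclonal antibodies in particular — adsorb at the
water/vapor interfaces that agitation and filling processes create, and
the adsorbed, partially dehydrated molecules are a known seed for
aggregation. `adsurf` implements the analysis layer for this problem:
given structures or trajectories of a protein near a solvent slab, it
measures how much accessible surface protrudes into the vapor, which
residues and sequences carry that protrusion, and how exposed
hydrophobicity and conformation co-vary.

This vignette is the package's account of the underlying model, its
conventions and tunable parameters, the synthetic data used to validate
it, and the numerical choices a careful user should know about.

## Accessible surface area

SASA is defined on the probe-expanded spheres: atom $i$ with van der
Waals radius $r_i$ contributes the part of the sphere of radius
$R_i = r_i + p$ (probe radius $p$) not contained in any other expanded
sphere. The engine samples each expanded sphere with a deterministic
Fibonacci lattice of $n$ points; each accessible point carries the area
weight $4\pi R_i^2 / n$. The per-atom area is therefore
(accessible count $/ n) \times 4\pi R_i^2$, and the exported point cloud
sums to the same areas bit-identically — that identity is what lets the
vapor-exposed area below be defined as a sum over classified surface
points rather than a separate geometric computation.

Numerical conventions, chosen for reproducibility:

* **Tie-break toward burial.** A point exactly on another expanded
  sphere counts as buried. Ties have measure zero in generic geometry
  but arise in constructed fixtures; fixing the rule makes results
  bit-stable.
* **Quadrature density.** Default $n = 960$ points/atom; the minimum 92
  is rejected as insufficient. At 960 points an isolated sphere is exact
  to machine precision and overlapping pairs are accurate to a few
  tenths of a percent; the remaining error is concentrated at occlusion
  rims, whose granularity is one point weight
  ($4\pi R^2/n \approx 10^{-3}\,\mathrm{nm}^2$ for carbon).
* **No periodic images.** The protein is assumed whole; `check_unwrapped()`
  flags molecules broken across a periodic box (backbone gaps
  > 0.25 nm, or CA–CA gaps > 0.45 nm for bead models, which carry no
  N/C atoms). It is a read-path validator rather than an engine
  precondition because the package's own coarse-grained fixtures use
  0.38 nm pseudo-bonds by construction.
* **Radii.** Bondi element radii by default (C 0.170, N 0.155, O 0.152,
  H 0.120, S/P 0.180 nm), recorded in output metadata and overridable —
  either by passing a radii table or, on the CLI, a per-atom
  `--radii` file (needed whenever radii are not element-determined, as
  for bead fixtures round-tripped through PDB).

An independent Monte-Carlo estimator (`mc_sasa_oracle`, uniform random
directions from R's RNG) exists purely as a cross-check; the test suite
and acceptance script hold the engine to ≤ 2% per-atom agreement at
$10^5$ samples on 50 seeded clusters. The cluster generator enforces a
0.45 nm minimum separation between atoms: spheres still occlude each
other by up to ~60%, but no atom's accessible fraction falls so low that
a *relative* comparison against a stochastic oracle becomes
ill-conditioned. That choice is about conditioning the comparison, not
about flattering the engine — near-buried atoms are exercised separately
by deterministic full-burial fixtures.

## Locating the interface

A slab's two liquid/vapor planes are taken from the time-averaged
solvent number-density profile along the interface normal (default $z$):
the bulk density is the mean over the central 50% of the occupied
region, and each plane is the outermost crossing of half the bulk
density, linearly interpolated between bin centers — the Gibbs dividing
surface. The `method` string records this convention in every output.

The default bin width is 0.15 nm. For the ~20,000-particle slabs the
generators produce, 0.1 nm bins leave ~500 counts per bin and a plane
jitter of ~0.03 nm, occasionally exceeding 0.05 nm; 0.15 nm bins cut
the jitter below ~0.02 nm while the interpolation bias stays negligible
relative to a 0.3 nm interfacial width. Bins are tied to the box, so
plane positions shift exactly with coordinate shifts that are multiples
of the bin width.

Interfaces can be located per frame (default) or once from the
trajectory-averaged profile (`locate_interfaces_trajectory(per_frame =
FALSE)`); which is appropriate depends on how mobile the slab is
relative to the quantity being averaged.

## Vapor-exposed area

$A_{ads}$ is the accessible area on the vapor side of the planes. Each
accessible surface *point* is classified by its own position —
$z > z_{upper}$ or $z < z_{lower}$ — and the vapor-side weights are
summed. Classifying points rather than atom centers matches the idea
that protrusion is a property of the accessible surface, and makes the
partition identity ($\sum_{\text{residues}} A_{ads} = \text{total}$) and
the bound $A_{ads} \le \mathrm{SASA}$ hold exactly at every frame. A
point exactly on a plane counts as the water side, consistent with the
strict-inequality convention used for all cutoffs. The conventional
probe for vapor-exposure work is 0.2 nm — chosen to match the simulated
roughness of the water surface — versus 0.14 nm for generic SASA; both
live in `run_config()`, not at call sites.

Because each surface point's classification is monotone in a rigid
$z$-translation, the per-frame total is exactly non-decreasing as a
rigid body rises through the interface — the package tests that as a
zero-violation property, not within a tolerance.

Production time series use 960 points/atom; the synthetic adsorption
trajectories carry a 9600-point refined-quadrature oracle computed at
generation time, and agreement is enforced frame by frame at 5% on
frames with non-zero oracle area. The planted protrusion schedules keep
peptides either deeply submerged (exact zeros on both sides) or
substantially protruding; grazing offsets, where a sliver of area makes
*relative* errors meaningless, are deliberately absent from the default
schedule and are covered instead by the analytic single-sphere cap scan.

## Time averaging

Production averages are trailing-window means: `window_fraction = 0.75`
mirrors the convention of averaging the last 150 ns of a 200 ns
trajectory, skipping the initial approach/equilibration. The window is
in *frames*, not time, so irregular sampling should be resampled first.

## SAP

Per atom $j$:

$$\mathrm{SAP}^j = \left\langle \sum_{\text{res}}
\frac{\mathrm{SASA}\left(\text{side-chain atoms of res within } r
\text{ of } j\right)}{\mathrm{SASA}_{exposed}^{res}} \times
R_{h,res} \right\rangle$$

with $r = 0.5$ nm measured center-to-center (inclusive — the tie again
has measure zero but is fixed), the time average over the requested
frames, and a 0.14 nm SASA probe. Residue SAP is the unweighted mean of
constituent atoms; the SAP score sums the strictly positive residue
values. Conventions worth stating:

* $R_h$ is the Black–Mould hydrophobicity scale shifted additively so
  that $R_h(\mathrm{GLY}) = 0$ exactly; the packaged table carries the
  shifted values and its provenance, and is user-replaceable. Positive
  SAP then means locally exposed hydrophobicity; glycine-rich
  surroundings contribute nothing by construction, which the poly-GLY
  $\equiv 0$ identity tests pin down.
* $\mathrm{SASA}_{exposed}^{res}$ is the solvent-exposed side-chain area
  of the residue in an Ala–X–Ala trimer. The packaged defaults are
  published maximum-exposure values (Miller et al. 1987 lineage,
  recorded in the table header); they are *reference denominators*, not
  claims about any particular force field. Glycine is given 0.50 nm²
  via an Hα-proxy convention so the ratio is defined; it never
  contributes because its $R_h$ is zero.
  `reference_exposed_from_structure()` recomputes the table from
  user-supplied trimer structures so the denominator can be made
  self-consistent with any model chemistry.
* Backbone atoms are N, CA, C, O, OXT and their amide/alpha hydrogens;
  everything else is side chain. Glycine's HA2/HA3 count as side-chain
  proxies.

The vectorised implementation is held to $10^{-9}$ agreement against a
plain double-loop evaluation on randomized fixtures, and to the burial
property: surrounding a hydrophobic residue with inert occluders can
only lower SAP values (true whenever all residues present have
$R_h \ge 0$; with hydrophilic neighbours the sign of the change follows
the sign of their $R_h$).

## Adsorption score and sequences

The residue adsorption score $S$ combines per-simulation, time-averaged
$A_{ads}$ values across repeated simulations. A value contributes only
if strictly greater than 0.5 nm² — roughly the exposed area of the
smallest side chain, so "adsorbed" means at least one side chain's worth
of surface. Two denominators are defensible and both are implemented:
the default averages over *contributing* simulations; the alternative
divides the contributing sum by the *total* simulation count
(e.g. `(0.8, 0.6, 0.4, 0×6)` gives 0.7 and 0.156 respectively). The
convention used is recorded in every output; neither is claimed as
uniquely correct.

Adsorbing sequences are maximal runs of length ≥ 2, within one chain, of
residues whose mean $A_{ads}$ strictly exceeds 0.1 nm² — the
mild-adsorption floor that catches cooperative adsorption of weakly
hydrophobic residues. *Every member* must clear the threshold (the
alternative — thresholding the run mean — would let one strong residue
drag neighbours in); qualifying singletons are reported separately
rather than silently dropped. The normalized sequence area is the
per-residue mean of member areas, and sequence hydrophobicity the sum of
member $R_h$ — which is why the GLY shift matters: glycines lengthen a
sequence without changing its hydrophobicity. Correlation analysis
(`hydrophobicity_area_stats`) groups residues sharing an $R_h$ value and
reports group mean/sd plus the Pearson correlation and least-squares
slope.

## Conformation

$R_g$ is mass-weighted by default (flag to disable; the difference
matters only for mixed-element selections). RMSD uses the standard
least-squares superposition: center both selections, rotate by the SVD
solution constrained to a proper rotation (reflections excluded), then
root-mean-square — masses unweighted, which is the common convention for
RMSD even when $R_g$ is mass-weighted. Per-domain RMSD superposes each
domain independently on its reference counterpart, removing interdomain
translation/rotation by construction, so a rigid interdomain
rearrangement yields zero per-domain RMSD while the whole-molecule fit
does not — that separation is exactly what distinguishes hinge motion
from intradomain unfolding.

## Synthetic data: what it does and does not show

Every generator returns its ground truth alongside the data, and no test
re-derives ground truth from the data itself:

* **Spheres** carry the analytic spherical-cap area
  $2\pi R h$, $h = R + z_{offset}$ — the exact oracle for single-atom
  $A_{ads}$.
* **Slabs** sample a tanh-bounded density whose half-density crossings
  sit exactly at the planted planes; recovery is tested at 0.05 nm with
  20,000 particles.
* **Toy peptides** are two-bead-per-residue models (backbone pseudo-CA
  0.17 nm; side-chain bead radius growing with residue heavy-atom count,
  GLY 0.10 → bulky 0.30 nm). They order side-chain exposure correctly
  and give SAP/sequence machinery realistic shapes, but they are *not*
  physical: no dihedrals, no packing, no solvent structure.
* **Adsorption trajectories** rigidly translate a peptide along a
  protrusion schedule; the oracle is quadrature refinement (10× points),
  chosen over Monte-Carlo so per-frame tolerances are deterministic.

Passing tests on these fixtures demonstrates that the *measurement
machinery* is correct — areas, classifications, scores, mining,
conventions. It does not demonstrate anything about real antibody
adsorption: headline experimental-scale numbers (tens of nm² of adsorbed
area for an antibody, SAP scores in the tens) require real structures
and long all-atom trajectories, which are out of scope here. The
problem sizes used throughout (≤ 30-atom clusters, ≤ 8-residue peptides,
50-frame trajectories, 20,000-particle slabs) were chosen so the full
validation suite runs on a laptop-class single core in well under an
hour while still exercising every code path at meaningful tolerances.

## Degenerate inputs and errors

Uniform or empty density profiles raise "no interface detectable";
unknown elements and residues are reported by name with their residue
context; radius-unassigned systems are rejected before any geometry;
mismatched residue tables stop ΔSASA; empty averaging windows, empty
selections and over-long running-average windows all error rather than
return NA. Truncated or malformed trajectory frames are reported with
their frame index.

## Limitations

* Interfaces are planar means; no capillary-wave or intrinsic-surface
  analysis, so $A_{ads}$ near a strongly corrugated surface inherits the
  planar approximation.
* SASA only — no Connolly/SES molecular surface.
* The packaged Black–Mould and reference-exposure tables are documented
  substitutes for simulation-specific tables; recompute the reference
  exposures from your own trimers for force-field-consistent SAP.
* PDB handling goes through bio3d and inherits its tolerance of
  real-world files; severely malformed fixed-width records surface as
  bio3d errors without line numbers.
* No desorption kinetics or free-energy barriers: $\gamma A_{ads}$ is a
  driving-force estimate, not a rate.
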