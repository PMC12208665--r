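---
title: "Multiconformer ligand fitting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiconformer ligand fitting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcligand)
```

## The problem

A crystallographic or cryo-EM density map is a population average. When a
bound ligand adopts more than one conformation in the crystal, a
single-conformer model leaves systematic residual density and misstates
the ligand's pose. `mcligand` detects and models this heterogeneity:
starting from one deposited conformer, it proposes a large constrained
ensemble of alternatives, asks which small subset of them — with which
fractional occupancies — jointly best explains the observed density, and
validates the result in real space.

The fitted object is a *multiconformer model*: one to three conformers
(two for cryo-EM maps) with altloc labels and occupancies summing to at
most one.

## The model

### Occupancy estimation as a quadratic program

Each candidate conformer $i$ contributes a calculated density
$\rho^c_i$ on the voxels of a footprint mask around the ensemble. With
weights (occupancies) $\omega$, the model density is
$\sum_i \omega_i \rho^c_i$, and the fit minimizes the residual sum of
squares

$$\min_\omega \;\lVert \rho^c \omega - \rho^o \rVert^2
\quad \text{s.t.} \quad \omega_i \ge 0,\; \textstyle\sum_i \omega_i \le 1 .$$

Occupancies are physical fractions, hence the simplex-with-slack
constraint set. The solver is an accelerated projected-gradient method
with an exact active-set refinement: the refinement solves the
equality-constrained KKT system on the identified support directly, so
returned solutions satisfy the KKT conditions to near machine precision
(the acceptance tolerance is $10^{-8}$ relative to the data scale).
Because observed maps are on arbitrary scales, calculated rows are first
put on the observed scale with the least-squares factor
$s = \langle \rho^c_{\text{input}}, \rho^o\rangle /
\lVert \rho^c_{\text{input}}\rVert^2$ computed from the input conformer.

### Parsimonious selection as an exact MIQP

The final model must be interpretable: at most `cardinality` conformers
(3 X-ray / 2 cryo-EM), each with occupancy at least $t_{\min} = 0.20$.
This is the mixed-integer constraint $z_i t_{\min} \le \omega_i \le z_i$
with binary $z_i$. Rather than depending on a branch-and-bound MIQP
solver, the package solves the problem *exactly* by enumerating all
supports of size $\le$ cardinality and solving each small
box-and-sum-constrained QP in closed form (KKT active-set enumeration in
compiled code). After QP screening the candidate pool is a few tens of
conformers, so the enumeration is at most a few hundred thousand
3-variable QPs — seconds of work — and is provably optimal. Ties between
equal-objective supports resolve to the lexicographically smallest index
set, making selection deterministic.

### The density model

An atom is a single isotropic Gaussian
$\rho_a(r) = Z\,(4\pi/B_{\text{eff}})^{3/2}
\exp(-4\pi^2 r^2 / B_{\text{eff}})$ integrating exactly to the element's
electron count $Z$, with $B_{\text{eff}} = B_{\text{atom}} + 8\,d_{\min}^2$.
The $8 d_{\min}^2$ blur makes the atom image width track the nominal map
resolution; the constant is a package choice, stated here because no
single-Gaussian model reproduces a full form-factor calculation exactly.
Grids for per-ligand calculations cover the ensemble bounding box padded
by 4 Å at spacing $\min(d_{\min}/4, 0.5)$ Å (Nyquist-safe for this
density model with bounded memory).

## Conformer generation

The generator is a seeded *torsion driver*: rotatable bonds (acyclic
bonds between atoms of heavy-atom degree $\ge 2$) are re-sampled while
bond lengths and angles stay exactly at their input values, and proposals
with non-bonded heavy-atom clashes below 2.0 Å are rejected. The clash
floor guarantees that geometric bond re-perception recovers exactly the
template bond graph, so every emitted conformer passes the SMILES-template
connectivity check by construction. This is a deliberate design choice:
it gives exact, per-atom control for the biased searches below, at the
cost of never altering ring pucker or bond-angle strain (see
*Limitations*).

Every run performs three preliminary searches, with two specialized
searches activated by topology:

* **unconstrained** — all rotatable bonds driven freely;
* **fixed terminal atoms** — every distance between terminal heavy atoms
  (degree 1) must stay within 0.1 Å of the input, preserving the overall
  molecular envelope while the interior moves;
* **blob** — conformers are recentered on the input centroid and must fit
  inside the input's bounding sphere (radius = max centroid-to-atom
  distance), confining the search to the binding-site volume;
* **branch** (side chain of $\ge 4$ heavy atoms present) — core atoms are
  frozen at input coordinates and only side-chain torsions move;
* **long chain** (side chain of $> 30$ atoms) — the converse: the chain
  is frozen and the core explores.

Side chains are maximal acyclic components hanging off a ring system
(or, for acyclic ligands, off the graph-center atom); a macrocycle is any
ring of 12 or more atoms. The default budget is 5000 conformers for
ligands under 25 heavy atoms and 7000 otherwise, split evenly across
active strategies (remainder to the unconstrained search); each strategy
retries up to three times its allocation before reporting a shortfall.
An optional **flip** search rotates the input by 180° about each
principal axis and refines each flip by ±2…±10° in 2° steps about the
same axis (33 conformers); it is off by default because it targets a
specific, user-suspected disorder mode.

Redundant conformers — in-place RMSD below 0.2 Å, no superposition, fixed
atom order — are removed, the surviving member of each pair chosen
uniformly at random under the run seed. In-place RMSD is used throughout
because position in the map is meaningful; superposition would merge
genuinely distinct placements. After QP screening, survivors are enriched
with one-at-a-time rigid perturbations: rotations of ±5/10/15° about each
principal axis and translations of ±0.3 Å along each map axis (25 outputs
per input).

Determinism: every stochastic step derives its seed from the run seed
(per-strategy sub-seeds), so results are identical for any worker count
and bit-stable across runs on one platform.

## Validation metrics

**RSCC** is the Pearson correlation of observed and calculated density
over the footprint mask (default radius 1.5 Å around the ensemble's heavy
atoms, covering the first density shell).

**EDIA** estimates per-atom density support:
$\mathrm{EDIA}(a) = \sum_p w(p,a)\,o(p,a)\,z(p) \,/\,
\sum_{p: w>0} w(p,a)$, where $z(p)$ clamps the map-normalized density
$(\rho(p)-\mu)/\sigma$ to $[0, \zeta]$ with $\zeta = 1.2$. The functional
forms of the distance weight $w$ and the ownership split $o$ are package
choices documented in the code: $w$ is positive inside the atom's support
radius, a smooth negative lobe (depth 0.15) out to twice that radius
penalizes unclaimed excess density; the support radius is where the
Gaussian atom image falls to 5% of peak,
$r(a) = \sqrt{\ln 20 \cdot B_{\text{eff}}}/(2\pi) \cdot (Z/6)^{1/6}$,
hence element- and resolution-dependent. Voxels claimed positively by
several atoms are split evenly; negative-lobe voxels count only when no
atom claims them. Within a multiconformer model, ownership competes only
among atoms of the same conformer — alternates share density by design.
**EDIAm** combines atoms with a power mean of exponent $-2$, which
punishes poorly supported atoms; an arithmetic mean is available via
`combine = "mean"`. EDIA assumes roughly spherical atom images, which
degrades beyond 2 Å resolution; the package warns there rather than
refusing.

**RMSD** is the standard root-mean-square coordinate deviation over
atoms in fixed order with no superposition.

## The synthetic benchmark

`generate_benchmark()` reproduces a two-conformer ground-truth study:
four programmatically constructed ligand archetypes spanning distinct
disorder classes —

1. *ring flip*: methylcyclohexane, chair flipped between A and B;
2. *linear displacement*: octane, B displaced as a near-rigid body;
3. *torsional shift*: propanol, one terminal torsion rotated 120°;
4. *macrocycle*: a 12-membered ring with a 4-atom branch; B rotates the
   branch and its terminal atom

— crossed with occupancy splits 0.50/0.50 … 0.90/0.10 and resolutions
0.8–2.5 Å in 0.1 Å steps: 360 (map, model) pairs, plus the A-only input
model per case. Per-atom B-factors follow
$B = 15 + 20\,(d_{\min} - 0.8)$ Å², emulating growing positional
uncertainty at worse resolution, and i.i.d. Gaussian noise of standard
deviation $0.05 \cdot d_{\min} \cdot \sigma_{\text{clean}}$ emulates
noise escalating with resolution. Both constants are explicit stand-ins
chosen so 0.8 Å maps are crisp and 2.5 Å maps appropriately smeared; they
are recorded in the manifest and configurable. Maps are synthesized
directly in real space from the Gaussian-atom model — there is no
reciprocal-space step and no bulk-solvent term, which is irrelevant for
ligand-local footprints but means absolute map scales are not those of a
full crystallographic calculation.

What passing the benchmark does and does not show: the generator's maps
are made by the same density model the fit uses, so recovery tests probe
the sampling, screening and selection machinery under controlled truth —
not form-factor accuracy, solvent effects, model bias in experimental
maps, or receptor rearrangement. The archetypes capture the *disorder
classes* of real two-conformer ligands, not any particular deposited
geometry.

## Numerical choices and degenerate inputs

* QP weights below $10^{-4}$ are zeroed; conformers below 0.1 occupancy
  are culled after MIQP selection (a lone sub-floor conformer is retained
  with a warning — the model is never empty). Surviving occupancies are
  not renormalized; redistribution belongs to downstream refinement.
* QP screening works in batches of 300 candidates; when the footprint
  mask exceeds 20,000 voxels, screening uses a deterministic stride
  subsample of the mask (the final selection design uses the full mask).
* For event maps, final occupancies are multiplied by $(1-\mathrm{BDC})$,
  the estimated bound-state fraction, just before output.
* Flip sampling on collinear molecules and perturbation of fewer than
  three atoms are rejected (principal axes undefined).
* Maps with permuted axis order are canonicalized on read; modes 0/1/2
  are supported.
* The problem sizes used in the test suite (sampling budgets of a few
  hundred, one archetype and two occupancy splits for the recovery
  checks) were chosen as the smallest sizes at which the studied
  behaviors are stable; the full 360-case benchmark is generated in the
  acceptance run.

## Limitations

* A torsion driver cannot invert ring pucker: the ring-flip archetype's B
  conformer is not reachable by sampling from A (it requires re-embedding
  or a mirror-type move). Recovery tests therefore use the torsion-shift
  archetype; on real ring-flip disorder the flip search or an externally
  supplied alternate seed is needed.
* Bond lengths and angles are frozen at input values; strain introduced
  by the depositor is not relieved (no force-field minimization).
* Structure-factor (MTZ) input is not parsed; supply a real-space
  CCP4/MRC map produced by external tooling.
* Occupancy totals below 1 are reported as-is; deciding whether the
  remainder is solvent or an unmodeled conformer is out of scope.
* Charged or tautomeric SMILES that disagree with the deposited residue's
  heavy-atom composition raise an error rather than being reconciled.
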