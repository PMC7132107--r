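---
title: "Designing two-state C3 helical bundles at CA resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing two-state C3 helical bundles at CA resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixswitch)
library(dplyr)
```

## The model

`helixswitch` works with homotrimeric helical bundles that have two designed
ground states sharing a six-helix base. Each monomer contributes four
segments, in chain order: a `base_inner` helix, a `base_outer` helix, a
short `hinge`, and a `flipping` helix. In the **short** state the flipping
helix folds back through a turn and packs against the inner helices
(~66 Å axial height); in the **long** state the hinge stays helical and the
flipping helix continues the outer helix, with the three flipping helices
packing against each other across the three-fold axis (~100 Å). Everything
is modeled at CA resolution in a fixed frame: the C3 axis is +z, units are
Ångström, residue numbering is 1-based per chain and continuous through the
hinge.

### Crick parameterization

Each helix is a minor α-helix wound on a superhelix. For residue index
$t = 0, 1, \dots$:

$$
\begin{aligned}
x &= r_0\cos\varphi + r_1\cos\varphi\cos\psi - r_1\cos\alpha\sin\varphi\sin\psi\\
y &= r_0\sin\varphi + r_1\sin\varphi\cos\psi + r_1\cos\alpha\cos\varphi\sin\psi\\
z &= \Delta z\, t - r_1\sin\alpha\sin\psi + z_{\mathrm{off}}
\end{aligned}
$$

with superhelical phase $\varphi = \omega_0 t + \varphi_0$, minor-helix
phase $\psi = \omega_1 t + \varphi_1$, and pitch angle
$\alpha = \operatorname{atan2}(r_0\omega_0, \Delta z)$. With $r_0 = 0$ and
$\omega_0 = 0$ this degenerates to a straight ideal α-helix on the z axis.
The ideal-helix constants are the canonical ones: 1.51 Å rise per residue,
100°/residue twist, $r_1 = 2.26$ Å, giving the familiar ~3.8 Å CA–CA
spacing.

`fit_crick()` inverts the parameterization by Levenberg–Marquardt least
squares over all eight parameters. Initialization is moment-based (axial
rise from the z span, superhelical radius from the mean axial distance,
superhelical twist from the unwrapped azimuth drift) with a fixed
multi-start grid over the minor-helix phase and two start families: a
supercoil hypothesis and a straight-helix hypothesis. The second family
matters because a straight helix admits a degenerate representation in
which $r_0$ rotates at $\omega_1$ and absorbs the minor circle; on residual
ties the fit prefers the smaller, more parsimonious $r_0$. Round trips on
generated traces recover every parameter to better than $10^{-3}$ in its
unit, and a rotation of the input about z moves only the phases.

### ABEGO bins

Backbone torsions are classified into the five-letter ABEGO alphabet with
conventional boundaries, kept in one constants table: `O` (cis peptide,
$|\omega| < 90°$) takes precedence; otherwise `A` is $\phi < 0$ with
$\psi \in [-75°, 50°)$, `B` the rest of $\phi < 0$, `G` is $\phi \ge 0$
with $\psi \in [-100°, 100°)$, `E` the rest of $\phi \ge 0$. The bins
partition the torus, so classification is total and deterministic.

## The frozen default architecture

The target heights (~66 Å and ~100 Å) constrain the base geometry; the
exact superhelical parameters of the parent bundles are not part of the
package's inputs, so the defaults here were calibrated once against those
two heights and then frozen, and should be read as approximations to the
real designs rather than reproductions:

| quantity | value | why |
|---|---|---|
| inner helix | 45 res, $r_0$ = 4.8 Å | 44 × 1.51 Å ⇒ 66.4 Å short height |
| outer helix | 43 res, $r_0$ = 9.2 Å, $\varphi_0$ = 60° | base ring; top at 63.4 Å |
| flipping helix | 21 res | the longer second-generation length |
| hinge | 3 res (`GGG`) + backup `T` | glycine hinge with threonine backup |
| long-state packing radius | 5.2 Å | flipping helices 9.0 Å apart across the axis |
| short-state flip placement | r = 12.8 Å, azimuth 20° | packs against the inner helix at ~8.4 Å |
| outer $\varphi_1$ | 48.5° | places the key hinge residue CA ~5.0 Å from the axis in the long state |

Two deliberate abstractions are worth stating plainly. First, the real
monomers are helical hairpins (inner and outer helices antiparallel, joined
by loops); at CA resolution this package leaves the inner–outer connector
unmodeled and runs both base helices N→C along +z, because the set of
geometric contracts on the two states (flipping antiparallel to the inner
helix in the short state, flipping continuing the outer helix in the long
state, hinge at the top of the base) is only jointly satisfiable that way.
Second, the frozen default uses an untwisted bundle ($\omega_0 = 0$): the
generator and the fitter support supercoiling, but a straight idealized
base makes every packing distance and both heights auditable by hand.

### The two state builders

The **long** state assigns helical torsions to the hinge and continues the
outer helix's Crick parameters through hinge and flipping helix, while the
superhelical radius tapers linearly from the outer ring (9.2 Å) to the
packing radius (5.2 Å) across the hinge. This reflects the designed long
state, in which the three contiguous helices leave the base and pack
against one another; it also creates the geometry of the hinge
ion-coordination site (below). The build is exactly C3-symmetric and is
rejected if any inter-chain CA pair comes closer than 2.5 Å.

The **short** state places the flipping helix antiparallel to the inner
helix, folded back from a turn at the top of the outer helix, and closes
the hinge with a fixed library of ABEGO turn templates (`GB`, `GBB`,
`BAB`, … per hinge length). Each template's torsions are converted to an
ideal-geometry backbone by an internal NeRF builder; the template whose
end-to-end CA distance best matches the anchor gap is placed rigidly, with
the roll angle about the gap vector chosen deterministically to push the
turn radially outward (keeping the apex below the inner-helix top, so the
short height is set by the inner helix). Hinge torsions therefore classify
as all-`A` in the long state and contain non-`A` bins in the short state by
construction — mirroring the design logic that a glycine-rich,
torsionally ambiguous hinge is what allows both states. The turn fails
loudly if the anchors are farther apart than `hinge_len × 3.8` Å. The
flipping helix start drops `1.6 + 1.5 × hinge_len` Å below the outer top,
so longer hinges arch further down and the closure stays feasible across
the supported hinge lengths (2–7).

The hinge sequence is stored as the four-letter hinge+backup window
(default `GGGT`): the **key** residue is the last hinge position and the
**backup** residue the first flipping position, so hinge variants are
expressed exactly as the familiar four-letter names (`GVDQ`, `GGHN`, …)
via `mutate_hinge()`.

### The ion-coordination check

`check_ion_site()` approximates the three symmetry-related coordinating
side chains by pseudo-atoms offset 2.4 Å from the CA toward the axis — a
CA-only stand-in for a short polar side chain — and accepts the site if
the triad's centroid lies on the axis and every pseudo-atom is within the
coordination window (default 2.2–3.0 Å, mimicking Ca²⁺–O distances). In
the long state the tapered hinge brings the key residue's CA to ~5.0 Å
from the axis, so the pseudo-atom sits at ~2.6 Å and the site is feasible;
in the short state the same residue rides the turn at ~12 Å radius and the
site cannot form. That asymmetry — a coordination site that exists in the
long state only — is the package's geometric expression of the
hinge-tuning idea.

## Interface layers and the preference score

`assign_layers()` finds the packed inner/flipping interface of the short
state (CA contacts within 10 Å, with the inner residue inside the flipping
helix's axial span) and slices it into three z-slabs of equal thickness,
hinge-proximal first; boundary ties go to the lower-index (more
hinge-proximal) layer. The assignment is defined on the short state and
reused unchanged for the long state. `apply_config()` writes frozen
identity tables into the layers: Asn/Ser/Thr cycling for `A` layers
(asparagine-cored networks), Leu/Ile/Val for `X` layers.

Burial differences use Shrake–Rupley SASA on uniform 3.0 Å CA
pseudo-spheres with a 1.4 Å probe and a deterministic 960-point Fibonacci
quadrature (validated against the analytic sphere area to 2%). For the
default design, every inner-side layer gains solvent exposure in the long
state — the geometric fact that motivates hydrogen-bond layers: polar
networks tolerate that exposure, hydrophobic layers pay for it.

`score_state_preference()` is a transparent linear proxy for the
fold-and-dock ranking, which is out of scope here. Each `A` layer
contributes $+w_A[l]$ (long-favoring), each `X` layer $-w_X[l]$
(short-favoring), with position weights frozen at
$w_A = (0.30, 0.20, 0.15)$ and $w_X = (0.60, 0.35, 0.25)$,
hinge-proximal first. The asymmetry between the two weight vectors is
essential, not cosmetic: a single position-weighted ±1 sum cannot
simultaneously make the score strictly monotone in the number of networks
and put the two-network design `XAA` on the short side of zero — the first
requires $w_1 < w_2 + w_3$ and the second $w_1 > w_2 + w_3$. Separate
A-reward and X-penalty scales satisfy both. The weights were calibrated
once against the four crystallographically observed states (`XXA`, `XAX`,
`XAA` short; `AAA` long) and then frozen; they are constants, not fitted
per call.

## State classification

`symmetric_rmsd()` computes the Kabsch RMSD minimized over the three
cyclic chain permutations only — the chains are oriented N→C, so
anti-cyclic mappings are physically invalid for a C3 trimer — and the
Kabsch step enforces a proper rotation. `classify_state()` labels a
candidate `short` or `long` when the smaller reference RMSD is below the
threshold (default 3.0 Å over CAs; no published cutoff exists for
"resembling" a state, so the threshold is an exposed parameter), and
`other` otherwise, with exact ties resolved to `other`.

## Solution observables

The Debye sum over CA dummy residues (unit form factors, no hydration
layer) is deliberately minimal: the package only needs *relative*
discrimination between two known states, not absolute intensities. The
default grid is q ∈ [0, 0.4] Å⁻¹ with 201 points. Guinier fits use the
window $qR_g \le 0.9$, below the globular 1.3 convention, because the
bundles are mildly elongated and the wider window biases $R_g$ by more
than the 2% self-consistency the package promises on compact models.
Normalized Kratky curves $(qR_g)^2 I(q)/I(0)$ are peak-located by spline
interpolation; the ideal compact reference peaks at
$(\sqrt 3, 3/e)$, and elongation moves the peak right — the short/long
pair lands at ≈2.2 and ≈3.7. `fit_states()` fits each model profile to the
data with a closed-form scale factor and χ² normalized by $N-1$ (missing
σ defaults to 1% of I), calling the smaller χ dominant, with the honest
caveat that a near-1 χ ratio (for example a 50/50 mixture) supports no
confident call. The chemical-shift deviation functions are the exact
nucleus-weighted formulas and nothing more.

## The fixture generator

`generate_fixtures()` emulates the data products such a characterization
campaign yields: reference PDBs
for both states, decoy ensembles (isotropic Gaussian CA noise, default
0.5 Å — comfortably inside the 3 Å classification threshold, as the
fold-and-dock outputs near a well were), synthetic scattering profiles
with 2% multiplicative Gaussian noise (a typical relative error for
well-exposed solution data), and a synthetic shift table in which the
mobile segments (hinge, flipping helix) carry large differences and the
base small ones. Everything derives from one recorded seed and reruns
byte-identically.

What passing the closed-loop tests shows: the classifier, the profile
fitter and the generator are mutually consistent at the stated noise
levels. What it does not show: performance on real fold-and-dock decoys
(which have correlated, structured error, not isotropic noise), real
scattering data (with buffer subtraction artefacts, aggregation and
inter-particle effects), or real chemical shifts. The generator is a model
of the data's shape, not of its pathologies.

## Numerical choices and degenerate inputs

* Angles are wrapped into (−180°, 180°]; all thresholds live in
  `hs_constants()`.
* Coordinates are serialized at PDB precision (3 decimals); internal
  computation is double precision.
* Degenerate inputs fail loudly: fewer than 8 points for a Crick fit,
  rank-deficient Kabsch input, empty decoy lists, disjoint q ranges,
  non-3-chain trimers, hinge anchors beyond closure range.
* Determinism: the only stochastic components are explicitly seeded
  (fixtures, decoys); builders, scores, SASA and classification are pure
  functions of their inputs.

## Problem sizes

The test-suite and acceptance computations run on the default architecture
(112 residues per chain, 336 CA per trimer), 201-point q grids, 100-case
Crick round-trip batches and 10-decoy closed loops — sizes chosen so the
whole suite exercises every contract in well under a minute of CPU while
keeping the Debye double sums (~56k pairs) and SASA quadratures exact
rather than subsampled.

## Known limitations

* CA-only geometry: no side chains, no packing energetics, no
  electrostatics; the ion-site and hydrogen-bond checks are distance
  geometry, not chemistry.
* The default architecture approximates the published designs' dimensions,
  not their sequences or exact superhelical parameters; layer positions are
  slab-derived, not residue-for-residue matched.
* The preference score reproduces a qualitative ordering; it has no energy
  scale and should not be compared across architectures.
* Ion-dependent register shifts, domain swapping and aggregation — all
  observed for the real proteins — are outside the model.
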