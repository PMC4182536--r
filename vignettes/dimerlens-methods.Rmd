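---
title: "Methods: contact, conformation and secondary-structure analysis of dimerization ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, conformation and secondary-structure analysis of dimerization ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlens)
```

## The problem this package addresses

When a globular protein domain self-associates — the motivating case is the
Josephin Domain (JD) of ataxin-3, whose dimerization seeds the aggregation
behind spinocerebellar ataxia type 3 — the questions a simulation ensemble
can answer are statistical: which residues sit in the inter-monomer contact
surface and how often; whether binding shifts the monomer between its
open-hairpin (~1.73 nm radius of gyration) and closed-hairpin (~1.65 nm)
conformations; whether particular helices (here alpha-4, residues
Leu84–Trp87) partially unfold and move toward the solvent; and how
per-residue mobility responds. `dimerlens` implements that post-processing
battery for multi-model coordinate ensembles, together with a synthetic
trajectory generator that plants every one of those signals with known
ground truth so the whole pipeline is testable without any molecular
dynamics.

Internal units are nanometres and picoseconds everywhere; angstroms exist
only inside the PDB reader/writer. Residue numbering is taken verbatim from
the input file and is 1-based.

## Contact probability

The central statistic is the per-residue inter-monomer contact probability.
For residue $i$ of monomer A, frame $t$:

$$ c_i(t) = \mathbf{1}\!\left[\min_{j \in B}\; d_{ij}(t) \le r_c \right],
\qquad p_i = \frac{1}{T}\sum_{t=1}^{T} c_i(t), $$

where $d_{ij}$ is the minimum atom–atom distance between residue $i$ and
residue $j$ of the partner monomer, and the cutoff $r_c$ defaults to
0.28 nm — roughly one water diameter, so a contact means no water fits
between the residues. Three commitments matter:

* **The threshold is inclusive** (`<=`). A pair at exactly 0.28 nm is a
  contact. Minimum distances are recomputed by direct coordinate
  subtraction for the winning atom pair, so the comparison at the threshold
  is exact rather than subject to the rounding of the fast
  squared-distance expansion used for screening.
* **Probabilities are exact rationals** — an integer count of contact
  snapshots divided by the number of snapshots. No floating accumulation.
* **Atom policy**: the default uses every atom present in the file; a
  heavy-atom policy (`atom_policy = "heavy"`) is provided and is the
  recommended setting for hydrogen-containing models, because a 0.28 nm
  criterion reads most naturally as a heavy-atom surface separation.
  Neither policy is asserted to be "the" published setting; the choice is
  the user's and is recorded in the output.

The contact map stores the same minimum-distance event per residue *pair*;
because the profile is the frequency of the union over partners, the
profile entry is always at least the row maximum of the map.

## Solvent-accessible and contact surface

`shrake_rupley_sas()` distributes test points over each atom's
solvent-expanded sphere (van der Waals radius + 0.14 nm probe) and counts
the fraction outside all neighbouring expanded spheres. The point set is a
deterministic golden-section spiral: no random numbers, so areas are
reproducible bit for bit at a fixed `n_points` (default 960, which lands
within 2% of analytic sphere/cap values for two-sphere systems). Radii are
a Bondi-style table keyed by element; an atom whose element has no entry is
an error naming the atom, never a silent default.

The buried contact surface between chains is
$CS = \tfrac{1}{2}\,[SAS(A) + SAS(B) - SAS(AB)]$. The factor one half
assigns half of the buried area to each partner; because conventions differ
across the literature, `halve = FALSE` returns the total buried area
instead.

## Superposition, RMSD, RMSF

Superposition is mass-weighted Kabsch via SVD with the determinant
correction; the test suite checks it against an independently implemented
Horn quaternion solution to 1e-9 nm on random instances. RMSF uses an
iterated-mean reference: frames are fitted to the first frame, averaged,
then refitted to that mean and re-averaged (two passes). The default fit
selection is the C-alpha set of the *globular core* — all residues minus
the hairpin (Val31–Leu62) — because fitting on a mobile region deflates
that region's own fluctuation; the reported atoms default to one C-alpha
per residue with a mass-weighted all-atom variant available. The hairpin
boundary and the alpha-4 extent (84–87, the Leu84–Trp87 landmark) are
configuration, not constants, since published boundaries are approximate.

## Compactness states and the Gaussian mixture

The radius of gyration is mass-weighted by default over all protein atoms.
Its distribution over a bound-state ensemble is decomposed by a
two-component Gaussian mixture fitted with expectation–maximization on the
raw per-frame values — "Gaussian interpolation" of a histogram is read
here as maximum-likelihood fitting, the statistically standard
interpretation; a least-squares fit to binned counts is available as a
comparison mode (`binned =`). EM runs from several k-means initializations,
keeps the best log-likelihood, stops when the log-likelihood improves by
less than 1e-8 (or at 500 iterations), floors standard deviations at
1e-6 nm against variance collapse, and reports components in descending
mean order. The seed is a required argument: stochastic fits are
reproducible or they are not fits. One- and two-component fits are nested,
and the suite asserts both the nesting inequality and per-iteration
monotonicity.

Open/closed/intermediate hairpin states are assigned by two bands around
the state centres (defaults: the fitted mixture means, with one fitted SD
as band half-width): at most `closed + band` is closed, at least
`open - band` is open, strictly between is intermediate. Overlapping bands
are a configuration error, and the partition conserves frame counts by
construction.

## Secondary structure and backbone quality

The assigner is a three-state implementation in the Kabsch–Sander
tradition: the electrostatic hydrogen-bond energy
$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol (distances in angstrom) defines a bond at $E < -0.5$; two
consecutive n-turns give helix (3-10, alpha and pi all fold into "H" for
the three-state view), parallel/antiparallel bridge patterns give sheet,
everything else is coil. Amide hydrogens are taken from the file when
present, otherwise placed 0.1 nm from N opposite the preceding carbonyl;
a chain's first residue cannot donate. One deliberate extension: a peptide
C–N distance beyond 0.25 nm is treated as a chain break — dihedrals across
it are undefined, the following residue gets no reconstructed hydrogen, and
sequential turn patterns may not span it. That is the correct behaviour for
genuinely broken chains and is what makes the generator's segment-placed
folds analysable.

Only one assigner is implemented rather than wrapping several published
tools, because three-state per-residue occupancies are all the ensemble
profile needs; the suite cross-checks it against an independent published
implementation (via `mdtraj`) on ideal helices and sheets, requiring at
least 95% residue agreement with ends allowed to differ.

Ramachandran classification uses a rectangular-polygon approximation of the
classic core/additional-allowed/generous regions, shipped as
`extdata/rama_regions.csv` so exact polygons can be substituted; glycine
and proline carry their own maps, and undefined dihedrals leave the
denominator of the favored-fraction summary.

## The synthetic generator: what it emulates, and what it does not

`generate_dimer_trajectory()` produces a two-chain (or single-chain)
ensemble in which every analysis target is planted:

* **Contacts** are geometric, not labelled: in each scheduled frame the
  partner residue is rigidly moved to 0.9 x cutoff from its target residue,
  with verified clearance (>= 0.35 nm) from every other residue; in
  unscheduled frames the chains rest >= 3 x cutoff apart. Schedules are
  exact-count Bernoulli draws — probability p over n frames means exactly
  `round(p n)` planted frames — so recovered probabilities are exact
  rationals, and the generator re-measures its own plants and fails rather
  than emit wrong ground truth.
* **Compactness states** radially scale the hairpin arm about the chain's
  centre of mass, solving a quadratic for the exact per-frame RG target
  drawn from the state's normal distribution.
* **Helix–coil switching** rebuilds the 84–87 block's dihedrals in place
  with the downstream chain anchored, so the toggle is local.
* **Exposure** displaces the block outward along the region-to-COM axis;
  by default the exposure schedule is coupled to the coil schedule,
  mirroring unfolding-with-exposure.
* **Fluctuation levels** rigidly displace the alpha-4-bearing helix unit
  (82–95) by a per-frame Gaussian vector, planting RMSF = sigma sqrt(3)
  while preserving the unit's internal geometry and hence its
  secondary structure. An atom-wise mode exists for tests that want
  uncorrelated jitter.
* A small global jitter (default 0.002 nm per axis, truncated at
  3 sigma) roughens everything; spec validation guarantees it cannot flip
  a planted contact.

The monomer itself is a 182-residue synthetic stand-in with the JD landmark
numbering (hairpin 31–62 as a protruding two-strand arm, alpha-4 on a
surface helix, Arg101/Arg103, Lys128, Asp145, C-terminal tail) assembled by
rigidly placing ideal secondary-structure units into a compact bundle with
deliberate chain breaks at the turns. The default conditions are the study
conditions: the bound dimer plants the interface at 65/55/50% with a 40%
C-terminal involvement and a 50/50 open/closed mixture at 1.73/1.65 nm
with 35% helix–coil switching; the alanine-mutant dimer plants 25/18/18%
with a 60% C-terminal interface and a 1.71/1.61 nm mixture; the lone
monomer is unimodal at 1.71 nm (sd 0.03 nm) with helix conserved.

What the generator does **not** emulate: physics. There is no force field,
no solvent, no excluded volume between rearranged parts; hairpin scaling
and anchored rebuilds break bond geometry at documented places, and
teleported contacts are not docked poses. Consequently, passing tests
demonstrate that the *measurement* machinery recovers known signals
exactly or within stated tolerances — they say nothing about force-field
accuracy, sampling convergence, or whether real trajectories contain such
signals. One visible consequence: the buried contact surface of a planted
interface (a single residue pair per plan row) is of order 1–2 nm², well
below the 3–11 nm² of genuinely docked interfaces.

## Numerical choices and degenerate inputs

* Frame selection matches target times to nearest frames with tolerance
  stride/2; an empty selection is an error, not an empty object.
* Alternate locations resolve to highest occupancy, ties to the first
  record; parse errors carry the 1-based line number.
* PDB writing refuses residue ids above 9999 and serials above 99999
  rather than corrupting fixed-width fields; round-trips are exact to the
  format's 0.001 angstrom.
* Superposition requires >= 3 non-collinear atoms; single-frame RMSF,
  empty selections, identical chains in a contact call, and all-identical
  samples in a mixture fit are all explicit errors.
* Interface tables rank by descending probability with ties broken by
  residue id.
* States with fewer than two frames are flagged in per-state summaries,
  not fatal.

## Problem sizes

The test suite exercises the generator at 6–500 frames per case and the
acceptance script uses 600-frame dimer conditions, a 400-frame monomer,
300-frame fluctuation plants and five contact-surface frames; these sizes
were chosen so every exact-count schedule realizes its planted probability
exactly (all planted fractions are multiples of 1/200) while each script
stays in the minutes range on one core. Recovery tolerances do not depend
on these sizes except where stated (mixture means, which tighten with
frame count).

## Known limitations

* The fold is a test scaffold; analyses of *real* ensembles should treat
  the generator only as a verification device.
* The assigner implements the hydrogen-bond core of the published
  eight-state algorithm (helices, bridges) but exposes only the
  three-state reduction; bends, turns as output classes, and
  torsion-based assignment are out of scope.
* The Ramachandran map is a rectangular approximation; substitute exact
  polygons through `default_rama_map(path =)` where publication-grade QC
  percentages are needed.
* Binary trajectory formats (XTC/TRR/DCD) and mmCIF are not read; convert
  to multi-model PDB or GRO first.
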