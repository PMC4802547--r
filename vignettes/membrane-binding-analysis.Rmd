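---
title: "Analysing protein-membrane binding, structure and leaflet asymmetry with memsurf"
author: "memsurf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein-membrane binding, structure and leaflet asymmetry with memsurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsurf)
```

# Scope and data model

memsurf quantifies how a peptide — the running example throughout is the
amyloid-beta dimer, two copies of the 42-residue peptide on chains A and B
— binds to and restructures on a lipid bilayer surface.  The package
operates on two S4 containers: an `MDSystem` (atom table, coordinates in
Angstrom, orthorhombic box) and an `MDTrajectory` (one topology, strictly
increasing frame times in nanoseconds).  PDB and GRO files are read and
written at the boundary; GRO's nm/ps conventions are converted on entry so
that every internal computation uses a single unit system (Angstrom, ns,
degrees).  Contact maps are the one deliberate exception on output: they
are reported in nm, the unit in which residue-contact maps are
conventionally drawn.

Residues are numbered globally and continuously across chains (chain A
1..42, chain B 43..84 for the dimer), because every downstream axis —
structure matrices, contact maps, zone directories — uses that convention.
Chain-local numbering is recoverable from the chain column of the atom
table.

# Surface-binding kinetics

The binding observable is the minimum distance between two atom
selections, by default all protein atoms against all atoms of the lipids
in the contact leaflet (not only phosphates: restricting the selection is
a config choice, not the default, since the distance that defines
"attached" is to the lipid as a whole).  Distances use the exact
all-pairs minimum-image computation; there is no cutoff or grid
approximation to second-guess.

The attachment time is defined graphically, the way it is read off a
distance-versus-time plot: a straight decline line and a horizontal
plateau line are fitted, and their intersection is the attachment time.
`detectAttachment()` realises this as an exhaustive breakpoint search:
for every interior breakpoint k it fits a least-squares line to samples
1..k and a horizontal line (the segment mean) to samples k..n, and keeps
the k minimising the total squared error.  Ties go to the earliest k, the
decline must have at least three samples and the plateau at least two,
and a non-negative decline slope at the optimum raises a "no attachment"
error rather than returning a meaningless crossing.  The crossing time is
clamped to the observed time range.  An exhaustive search was chosen over
nonlinear optimisation because it is deterministic, has no starting-value
sensitivity, and matches the two-line graphical procedure exactly.  The
plateau is fitted with zero slope; a free-slope plateau would absorb part
of the decline and bias the crossing late.

The membrane-orientation angle is the angle between a body-fixed vector
(by convention from the C-terminal residue to the lysine at the tip of
the U-shaped fold, residues 42 to 28 in chain A) and the bilayer normal
(+z).  The full [0, 180] degree range is reported rather than folding at
90 degrees: folding discards the information of whether the vector points
into or away from the membrane, and a consumer who wants the folded
convention can apply `pmin(angle, 180 - angle)` without loss.

# Secondary structure

Assignment follows the hydrogen-bond pattern dictionary of Kabsch and
Sander.  The bond energy between a donor amide (N, H) and an acceptor
carbonyl (C, O) is the electrostatic model

E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  kcal/mol,

with a bond declared below -0.5 kcal/mol.  Amide hydrogens are placed
geometrically when absent — 1.0 Angstrom from N along the preceding
residue's C=O direction, none for prolines and chain-initial residues —
which is the standard convention when the input carries no protons.
n-turns (bond from the carbonyl of residue i to the amide of i+n,
n = 3, 4, 5) combine into G/H/I helices when two start consecutively;
parallel and antiparallel bridge patterns give B, ladders of consecutive
bridges give E; unconsumed turn spans give T; a CA-trace direction change
above 70 degrees gives the bend S; everything else is coil C.  Per-residue
priority is H > E/B > G > I > T > S.  Candidate 3-10 and pi spans are
accepted only when free of higher-priority assignments, per the original
rules.  beta-bulge linkage of interrupted ladders is not implemented; on
the idealised fixtures the package is tested against, bulges cannot occur,
and the reference-implementation agreement test would expose any practical
consequence.

The stacked residue-by-time matrix uses a nine-letter alphabet: the eight
structural states plus X, a constant separator row between chains.  The
separator is bookkeeping for plotting and parsing, not a structural state;
it never enters any count.  Reduction pools B+E, G+H+I and T — the three
hydrogen-bonded classes — per domain (N-terminal and C-terminal, pooled
over both chains), with BEGHIT their sum.  Bend and coil are geometric,
not hydrogen-bonded, and are excluded by construction.

Whether the original workflows ran their assignments on engine-placed or
geometric hydrogens is generally unknowable from published figures; the
geometric placement here is a documented choice, validated functionally by
agreement with an independent DSSP implementation on ideal geometries
(at least 90% residue-wise, differences confined to segment termini).

# Contact maps and zones

A contact map entry (i, j) is the minimum inter-atomic distance between
residues i and j, heavy atoms only by default: fixtures may carry no
hydrogens at all, and when hydrogens are present they systematically
shrink minima, so mixing protonated and unprotonated frames would bias
comparisons.  Averaging is two-stage and unweighted: the mean over frames
in the trailing window (50 ns by default) within each replicate, then the
mean across replicates.  Unweighted replicate averaging treats each
independent simulation as one observation regardless of how many frames
it contributed, which is also what makes the SEM over replicates
meaningful.

The zone directory enumerates the ten unordered pairs of the four domains
N_A, C_A, N_B, C_B of a two-chain dimer: three within chain A, three
within chain B, four across chains.  Zone summaries exclude the self-pair
diagonal inside within-domain zones (the structural zeros of d(i,i) = 0
would deflate those means) and use the full rectangle of pairs between
distinct domains.  With fewer than two replicates the SEM is reported as
NA, never as a fake zero.

# Annular sorting

A lipid or water molecule is annular when any of its atoms comes within a
cutoff of any protein atom, whole molecules being assigned as units.  The
default metric is lateral (x-y projection, minimum image in x and y),
which matches the lateral-view reading of surround-style renderings of an
annular shell around a surface-bound protein; a full 3D metric is one
flag away (`mode = "spatial"`).  The default cutoff of 6 Angstrom is
approximately one lipid coordination shell and is documented as a
tunable, not a literature constant.  The sorting is monotone in the
cutoff and partitions the lipid and water population exactly — both
properties are asserted in the test suite.

# Leaflet asymmetry

Leaflets are assigned by headgroup z relative to the midplane, the
midplane being the mean headgroup z rather than the box centre (robust to
bilayers drifting off-centre); a headgroup exactly on the midplane is an
error, not a silent coin flip.  The two asymmetry metrics are

* number mismatch = |n_upper - n_lower| / max(n_upper, n_lower) * 100,
* SAPL mismatch = |apl_upper - apl_lower| / max(apl_upper, apl_lower) * 100,

with apl = area / n per leaflet.  Both are symmetric, bounded in
[0, 100], zero iff their arguments are equal, and invariant under scaling
both arguments — the algebraic form of the observation that these
percentages do not depend on system size.  When both leaflets share one
lateral box area the two mismatches coincide identically (both reduce to
1 - n_min/n_max); they can differ only when per-leaflet areas are
measured independently, which is why `leafletStats()` accepts externally
estimated per-leaflet areas but never computes them itself (Voronoi-style
area estimation is out of scope).

# Synthetic fixtures and what they do and do not show

All tests run on generated inputs with analytically known ground truth;
no simulation data ships with the package.

* `makeBilayer()` builds two leaflets of three-atom pseudo-lipids
  (headgroup P on a laterally jittered square grid at z = +/- 19
  Angstrom, two tail beads stepping toward the midplane) in a shared
  lateral box of area max(n_upper, n_lower) * apl.  Defaults: 64 lipids
  per leaflet, 65 Angstrom^2 per lipid — a typical fluid-phase
  phosphatidylcholine value — and a 38 Angstrom headgroup-plane
  separation.  Only leaflet topology, counts and headgroup planes matter
  to the analyses; lipid conformational realism is explicitly not a goal.
* `makeBindingTrajectory()` translates a rigid dimer toward the upper
  leaflet so that the exact protein-headgroup minimum distance follows
  d(t) = max(plateau, d0 - (d0 - plateau)/t_attach * t).  The dimer's
  lowest atom is aligned vertically over one headgroup, which makes the
  analytic profile and the measured minimum distance agree to machine
  precision at every frame — the property that turns attachment detection
  into an exact parameter-recovery test.  Noise enters as Gaussian jitter
  on the rigid-body z offset, not per atom, so the noiseless target stays
  analytically known.  The default attachment time of 4 ns with a 0.1 ns
  frame spacing and a 60 ns horizon mirrors the fastest binding regime a
  single-component phosphatidylcholine surface shows in this class of
  system; the noisy-recovery tests use 28 ns, the slow regime.
* `makeIdealHelix()` (phi = -57, psi = -47) and `makeBetaPair()`
  (phi = -139, psi = 135, partner strand placed by a fitted two-fold
  rotation that realises the antiparallel hydrogen-bond registry at any
  strand length) provide geometries whose correct codes are known.

Every generator is a pure function of its specification and one integer
seed, drawn from a private RNG stream so the caller's RNG state is never
touched; identical seeds give byte-identical coordinates.

What passing these tests does *not* show: the fixtures have rigid
proteins, caricature lipids, no solvent dynamics and no conformational
noise beyond the injected jitter, so they validate the estimators and
their algebra, not the behaviour of the estimators on rugged real
trajectories (e.g. attachment traces with slow drifts or re-detachment
events, or structures at the margin of the hydrogen-bond cutoff).

# Numerical choices and problem sizes

Degenerate inputs fail loudly: empty selections, zero-length orientation
vectors, fewer than eight kinetics samples, flat traces, non-negative
decline slopes, lipids without headgroups, headgroups exactly on the
midplane, and sub-0.5-Angstrom hydrogen-bond geometries are all errors
with specific messages.  Breakpoint ties resolve to the earliest
candidate; the attachment time is clamped to the observed range; PDB
round-trips are exact to the format's 10^-3 precision in the written
unit.

The shipped test suite sizes its simulations for desk-scale runs: 50
noiseless and 20 noisy attachment recoveries on a 9+9-lipid bilayer with
a 5-residue dimer, 100 random systems for the minimum-image oracle, 50
random 10-residue frames for contact-map brute-force equality, and 1000
random structure columns for the class-sum identity.  These sizes are the
package's own choice of a thorough-but-quick regression net; all
estimators are size-independent in their logic.

# Known limitations

* Only orthorhombic boxes; no triclinic minimum image.
* Text formats only (PDB, GRO, TSV); binary trajectory formats are out of
  scope and should be converted upstream.
* The secondary-structure assigner omits beta-bulge ladder linkage and
  solvent accessibility; it targets the hydrogen-bonded class counts, not
  a byte-identical reimplementation of any particular DSSP binary.
* Per-leaflet surface areas are taken from the shared lateral box unless
  supplied externally; no Voronoi estimation.
* The annular criterion is a documented stand-in (lateral proximity,
  whole-molecule assignment, 6 Angstrom default) for surround-style
  sorting whose original parameters are not published alongside the
  figures it emulates; both the metric and the cutoff are exposed.
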