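---
title: "Building hydrated crystal unit cells for MD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building hydrated crystal unit cells for MD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalmd)
```

## Scope and model

`xtalmd` prepares crystallographic unit cells for constant-pressure MD
and verifies, after the fact, that the chosen solvent content preserves
the experimental cell volume. It deliberately stops at the MD engine's
door: it generates coordinates, parameter files and a run script, and
it consumes the box-vector record of finished runs, but it never
integrates equations of motion. That boundary keeps every quantitative
claim in the package testable without an MD installation.

The pipeline is: read an mmCIF asymmetric unit, clean it, expand it to
the unit cell by space-group symmetry, fill the cell with water over a
grid of overlap scale factors, emit the run recipe, and judge the
resulting mean volumes against the experimental cell.

## Crystal geometry

All crystallographic math happens in Angstrom, in the frame of the
orthogonalization matrix

$$A = \begin{pmatrix} a & b\cos\gamma & c\cos\beta \\
0 & b\sin\gamma & -c\sin\beta\cos\alpha^* \\
0 & 0 & c\sin\beta\sin\alpha^* \end{pmatrix}, \qquad
\cos\alpha^* = \frac{\cos\beta\cos\gamma-\cos\alpha}{\sin\beta\sin\gamma},$$

which maps fractional coordinates to Cartesian. A symmetry operation
$\{R|t\}$ becomes Cartesian as $M = A R A^{-1}$, $V = A t$. Textbooks
differ on the sign of the $(2,3)$ element of $A$; we implement the form
above and pin correctness to a sign-independent invariant, checked for
thousands of random cells in the tests:

$$|\det A| \;=\; V_\text{cell} \;=\; abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+2\cos\alpha\cos\beta\cos\gamma}.$$

A cell is accepted as valid only when all lengths are positive, all
angles lie in $(0^\circ, 180^\circ)$, and the radicand above is
positive.

Space-group operators are parsed from operator-triplet strings
(`"-x,y+1/2,-z"`). The built-in registry covers the triclinic,
monoclinic, orthorhombic and tetragonal groups most common for protein
crystals (P 1, P -1, P 1 2 1, P 1 21 1, C 1 2 1, P 2 2 2, P 2 2 21,
P 21 21 2, P 21 21 21, C 2 2 21, P 41 21 2, P 43 21 2); an operator
list present in the input file always takes precedence, so any group
can be used. Every registered table is property-tested for closure
under composition (mod-1 translations) and distinctness, which together
with the known multiplicity pins the group.

### Building choices

* **Wrapping** is whole-molecule: after applying an operation, each
  molecule (polymer chain, or hetero residue) is translated by whole
  lattice vectors until its geometric center lies in the cell. Per-atom
  wrapping would split molecules across the boundary; MD engines
  re-wrap as they please, but bonds must arrive intact.
* **Chain identifiers** of symmetry mates are reassigned from the PDB
  chain alphabet, and the mapping is written to the build report,
  because merged copies must stay distinguishable for topology
  generation.
* **Special positions**: atoms of different copies closer than 0.1 Å
  (minimum-image) are treated as the same crystallographic site; the
  first occurrence is kept. Proteins rarely sit on special positions,
  but crystallographic waters can.
* A post-build clash scan (0.5 Å heavy-atom threshold, configurable)
  reports inter-copy contacts. Clashes warn, never abort: the audit
  trail matters more than a hard stop, since downstream minimization
  fixes mild contacts.

## Cleaning

* **Altlocs**: default policy keeps the highest-occupancy conformer,
  ties alphabetical; explicit per-residue choices override. The
  operation is idempotent.
* **Gaps** are reported (chain, flanking residues, missing count), not
  filled: loop building is a modelling problem we delegate to external
  tools, and inventing coordinates silently would bias simulations.
  Terminal truncations are warnings, not gaps, because capping and loop
  modelling are different repairs.
* **Protonation** uses a fixed standard-pKa rule (Asp 3.65, Glu 4.25,
  His 6.0, Cys 8.3, Tyr 10.07, Lys 10.53, Arg 12.48): charged if acidic
  and pH ≥ pKa, or basic and pH ≤ pKa (ties resolve charged). This
  replaces empirical pKa predictors on purpose — it is deterministic,
  dependency-free and exactly testable — and a per-residue override
  hook (`pka_override`) lets users inject externally computed pKa
  values when they need environment-aware assignments. Output is the
  residue-renaming table (HIE/HIP/ASH/GLH/...) that topology generators
  consume.
* **Hetero policy**: waters (HOH/WAT/H2O/DOD), monatomic ions
  (Na, Cl, Mg, Ca, K, Zn, Mn, Fe as single-heavy-atom het residues) and
  ligands can each be kept or dropped; retained ions are checked
  against the declared force-field ion list, since the MD engine has no
  parameters for anything else. Occupancies are carried through
  unmodified; partial-occupancy waters receive no special treatment.

## Solvation

Unresolved solvent is the central calibration problem. Candidate waters
come from a cubic template tile replicated across the box; molecules
whose oxygen falls outside the cell parallelepiped (fractional
coordinates outside $[0,1)^3$) are discarded; a candidate is then
removed when **any** of its atoms overlaps a solute heavy atom within
$\mathrm{scale}\times(r_\text{water}+r_\text{atom})$ under
minimum-image periodic distances. Whole-molecule removal, because
fragment waters are unphysical. Kept counts are deterministic and
non-increasing in scale (a property test).

Numerical choices worth recording:

* The template is generated in code, not shipped: a jittered lattice
  (deterministic internal seed, jitter 0.35 of the spacing) at the
  canonical density of the 216-water, 1.862 nm cube. The jitter matters:
  a perfectly regular lattice has rows aligned with the box faces, and
  cutting it at an arbitrary boundary biases the kept density by up to
  ~10 %; with disorder the cut is unbiased, like the equilibrated box
  the MD tool itself uses, and the kept density lands within 5 % of the
  template's for non-commensurate boxes (exact for commensurate ones).
* vdW radii (Å): C 1.7, N 1.55, O 1.52, H 1.2, S 1.8, P 1.8, plus
  common ions; water-oxygen probe 1.4. Standard values, configurable.
* Minimum-image distances search all 27 neighbour images of the
  triclinic box after wrapping the solute into the primary cell; for
  the box shapes of real crystals this is exact, and it makes pruning
  invariant under lattice translation of the solute (tested).
* Crystallographic waters are always kept verbatim and never count
  toward the scale-controlled budget; new waters are pruned against
  them like any other solute atom. The solvation manifest records this.
* Ions: $n_\text{pairs} = \mathrm{round}(c \cdot N_\text{water}/55.5)$
  at concentration $c$, plus bare counter-ions to exact neutrality.
  Placement replaces randomly chosen kept waters; the RNG seed is
  recorded in the manifest, so systems are reproducible.

The default scale grid is 0.53, 0.55, 0.57, 0.59, 0.61 — five values,
step 0.02, centered on 0.57, the value appropriate for solvated
proteins at bulk density. Crystals typically need more water (smaller
scale), which is exactly what the grid-and-check loop discovers.

## Workflow generation

The rendered recipe is a pure function of the configuration: one bash
script with, per scale value, the six-step chain (add hydrogens,
solvate, add ions, minimize, NVT+NPT equilibration, production), plus
four mdp parameter files and a YAML manifest. Bundled parameters encode
the standard crystal setup: PME, 1.0 nm real-space cutoff, 0.16 nm
grid; LJ cutoff 1.0 nm (potential-shift); v-rescale thermostat, 300 K,
τ = 0.5 ps; c-rescale barostat, 1 bar, τ = 5 ps, **anisotropic**
coupling (a unit cell must be free to breathe per axis); LINCS on
H-bonds; 2 fs steps; 100 ps NVT and 100 ps NPT equilibration under
heavy-atom position restraints; 20 ns production (10,000,000 steps)
with nothing restrained. Equilibration restraints are standard practice
we adopt by choice; production is unrestrained because restraining
would suppress exactly the volume response the check stage measures.
User-supplied mdp files override bundled ones, referenced as given.

## Volume check and iteration

Mean volumes are taken over **all** production frames by default
(`discard_initial` exists but defaults to 0). The acceptance tolerance
is 0.5 % relative, configurable. Among passing scales the smallest
deviation wins; exact ties go to the larger scale (fewer waters,
cheaper system) — a tie-break we chose, applied after rounding
deviations to 9 significant digits so verdicts are invariant under
rescaling all volumes.

When nothing passes, the refinement exploits the monotone decrease of
mean volume with scale: if an adjacent pair of probed scales straddles
the experimental volume, three evenly spaced values strictly between
them are proposed (three is our choice — it keeps a second iteration
cheap and, with the default 0.02 step, resolves scale to 0.005); if the
experimental volume lies above all means, the grid extends below the
smallest scale by the original step, and symmetrically above. Noisy,
non-monotone means fall back to the adjacent opposite-sign pair with
deviations nearest zero. Proposals never repeat a probed value. When
iterating, a ready-to-use YAML input for the preparation stage is
written alongside the verdict report.

Box-vector → cell-parameter recovery assumes the lower-triangular MD
convention (first vector on x, second in the xy plane). The adapter
reads multi-frame GRO trajectories and a plain text table
(`a b c alpha beta gamma` per frame); binary trajectory formats have no
reader in the dependency set and are intentionally out of scope — any
trajectory tool can dump the text table.

## Synthetic data: what it emulates, what it does not

The fixture generator emulates the *geometry* of the problem: toy
asymmetric units (random C/N/O atoms, one per residue) placed in a
fractional region chosen so that no registered symmetry operation maps
the region onto itself — symmetry mates of a fixture therefore never
clash, unless a test asks for clashes. Waters, ions, altlocs and
numbering gaps are injected on request. Trajectories are synthesized
with multiplicative volume noise: each frame's volume is the target
times $(1+\varepsilon)$, $\varepsilon$ uniform with standard deviation
equal to the requested relative noise, implemented by scaling the three
lengths by $(1+\varepsilon)^{1/3}$ with angles fixed. Defining the
noise on the volume (rather than on the lengths) makes the sample-mean
bound $3\sigma/\sqrt{n}$ hold by construction, which is the property
the check-stage tests rely on.

None of this is chemistry: fixtures carry no realistic bond geometry,
no force-field validity, and the synthetic trajectories contain no
physics — only the statistical behaviour of a volume series. A green
test suite therefore establishes that the geometry, bookkeeping,
calibration logic and file contracts are correct; it says nothing about
whether a particular force field reproduces a particular crystal. The
three published validation systems are represented by synthetic
stand-ins (`synthetic_reference_crystal()`) that reproduce their space
groups and crystallographic water/ion content (124 waters; 2 Mg + 118
waters; 4 Ca + 1 Na + 256 waters) but not their coordinates; parsing
and classification are exercised fully offline against those published
counts.

## Known limitations

* Single unit cell only; no k×l×m supercells.
* Membrane-protein crystals are unsupported.
* No hydrogen placement and no ligand parameterisation — both are the
  topology generator's or the user's job; first model only for
  multi-model files.
* No autocorrelation analysis of the volume series; the mean is an
  unweighted average.
* PDB output is limited to 99,999 atoms; larger systems must use GRO
  (the writer refuses rather than wrapping serials silently).
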