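---
title: "Mapping binding-cavity water: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding-cavity water: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavsolv)
```

## The problem

When a protein binding cavity is empty, it is filled with water. How well
that water is accommodated — how many hydrogen bonds it makes with the
protein surface, how much of its favorable water–water structure it retains,
and how its total energy compares with bulk water — governs the
thermodynamics of ligand binding and of apo-state cavity conformations.
`cavsolv` maps these properties from simulation frames on a voxel grid and
summarizes them over ligand-defined subvolumes, per hydration site, and per
protein functional group, with a particular focus on comparing *rigid*
ensembles (all heavy atoms restrained near a ligand-bound structure) against
*flexible* ones (side chains free to relax with the ligand absent).

## The grid model

Water-oxygen positions are binned on a regular grid (0.5 Å spacing by
default, i.e. 0.125 Å³ voxels). Voxels use half-open intervals
`[lower, upper)` with boundary points assigned upward, so assignment is
deterministic. For every visit, the voxel accumulates the visiting water's

* solute–water interaction energy `e_sw`,
* water–water interaction energy `e_ww` (each unique pair shared evenly
  between its two partners, `ww_split = 0.5`),
* the referenced total `e_sw + e_ww − e_neat`, where `e_neat` is the mean
  potential energy per molecule of the neat liquid under the same
  conditions, and
* its solute–water and water–water hydrogen-bond counts.

Finalization derives the number density `rho_vox`, the normalized density
`g = rho_vox / rho0`, and two energy fields:

* `e_dens = g × mean(e_ref)` — the density-weighted per-voxel energy, the
  form in which grid energy densities are conventionally printed; and
* `e_per_frame = sum(e_ref) / n_frames` — the additive quantity whose sum
  over any voxel set equals the trajectory-direct total for those waters.

Both are kept because the density-weighted field does not sum to a total
energy over voxels; all subvolume integration uses `e_per_frame`, which
makes integrated totals exactly additive and exactly conserving (this is
asserted to 1e-9 kcal/mol in the test suite). Never-visited voxels carry
zeros in every derived field.

The `ww_split = 0.5` convention makes `E_tot = E_sw + E_ww` hold in every
report, and matches the `U/N` convention in which the neat reference energy
is expressed. Whether the half-share is applied inside the per-water energy
or only at reporting time is a convention choice with no unambiguous
published form; `ww_split` is a model parameter so either can be produced.

## The interaction model

Energies use point-charge Coulomb (332.0636 kcal·Å/mol/e²) plus
Lennard-Jones 12-6 with Lorentz–Berthelot combination, truncated at a
cutoff (10 Å default; the packaged synthetic model uses 9 Å so that the
neat calibration box can hold twice the cutoff). Two gating rules keep
molecules intact at the cutoff sphere:

* water–water: a molecular pair is included all-or-nothing based on the
  oxygen–oxygen minimum-image distance;
* solute–water: each solute atom is included against the whole water
  molecule based on its distance to the water *oxygen*.

Splitting a neutral water at the cutoff leaves a bare monopole, and a
Metropolis sampler will happily orient cutoff-shell waters to exploit that
artifact; with molecule-based gating the artifact cannot arise. The generic
`pair_energy()` operation (two arbitrary atom groups) retains the plain
per-atom-pair cutoff, which is the natural contract for arbitrary groups.

Boxes are orthorhombic and coordinates are Å throughout. Long-range
corrections (Ewald sums, LJ tail corrections) are out of scope: the
analysis and the synthetic sampler share one truncated potential, so every
conservation statement is exact rather than approximate.

## Hydrogen bonds and neighbors

A hydrogen bond requires a donor–acceptor heavy-atom distance strictly
below 3.6 Å and an angle strictly below 30°. The default angle is measured
at the donor heavy atom between the donor→hydrogen and donor→acceptor
vectors (the acceptor–donor–hydrogen angle); the more common
donor–hydrogen–acceptor linearity convention (180° minus the angle at the
hydrogen, same 30° bound) is available as `angle_convention` and the two
cannot silently mix. Polar heavy atoms are N, O and S by default; hydrogens
attach to the nearest polar heavy atom of their own molecule within
1.25 Å. Intramolecular pairs are skipped at the molecule level.

Neighbors are water oxygens within 3.6 Å (inclusive, "within") of any heavy
atom of a group. Published per-group tables sometimes quote 3.5 Å in their
captions while methods sections state 3.6 Å; the cutoff is therefore an
explicit argument rather than a constant, with 3.6 as the default.

## Hydration sites

Sites are found greedily: every observed oxygen position is a candidate
center; the 1 Å sphere holding the most observations becomes a site, its
observations are removed, candidates within 2 Å of an accepted center
become ineligible, and clustering stops when the best remaining sphere
falls below `min_occupancy_ratio` (default 2) times the bulk expectation
`rho0 · (4/3)π·1³` per frame. Ties break to the lowest observation index,
so the procedure is deterministic. Note that the 2 Å center-separation rule
means a few observations lying 1–2 Å from an accepted center can end up
claimed by no site; we keep the separation rule (disjoint spheres are what
make per-site occupancies interpretable) and accept that the sum of site
occupancies is bounded by, rather than equal to, the observation count.

Per site, energetics are averaged over occupying waters
(`e_tot_ref = mean(e_sw) + mean(e_ww) − e_neat`), and a site is classified
*donor* (*acceptor*) when ≥ 60% of its occupants donate (accept) at least
one hydrogen bond to the solute, *both* when both fractions reach 60%
(the published rule says "60% or more" for the single classes and "above
60%" for *both*; we harmonize to ≥ for consistency), *neither* otherwise.

## Subvolumes, integration and errors

A subvolume is the set of voxels whose center lies within a stated distance
(inclusive) of any heavy atom of a reference ligand, typically scanned from
3 to 10 Å in 0.5 Å steps; 3 Å approximates the displacement region and
10 Å the full binding-site solvation region. Integrated quantities are
voxel sums of the additive fields; per-water values divide by the mean
water count. Errors come from block averaging: the trajectory is split into
four contiguous blocks (trailing frames dropped if the count does not
divide evenly), each block is accumulated and integrated separately, and
the SEM is the standard deviation of block means over √4. Comparisons
report `rigid − flexible` for every quantity, so a positive total-energy
delta means the flexible ensemble solvates the cavity more favorably.

## The synthetic-data generator

The generator is the stand-in for production molecular dynamics: it
produces ensembles with *known* statistical structure so that every
analysis stage has an oracle.

* **Ideal gas** — uniform positions, uniform random orientations. Null
  model: `g → 1`, all energies zero, no enriched hydration sites.
* **Lattice** — static cubic arrangement; fully deterministic fixture.
* **Metropolis Monte Carlo** — rigid-water translations (±0.18 Å) and
  rotations (±20°) about the oxygen, with the Metropolis criterion at the
  configured temperature, using *exactly* the analysis potential. Saved
  frames re-evaluate to the sampler's own energies bit-for-bit, which is
  asserted, not assumed. Frames are written every few sweeps after a
  burn-in.

The solvent is a rigid 3-site water (O–H 0.9572 Å, H–O–H 104.52°, charges
−0.834/+0.417 e, LJ on oxygen only: σ 3.15061 Å, ε 0.1521 kcal/mol). Its
neat reference energy was measured once from a 216-water neat run at
0.0334 molecules/Å³ and 298 K with the 9 Å molecule-gated cutoff
(2,000 burn-in sweeps, 500 frames, seed 42; a 1,500-frame check agreed
within its ±0.04 SEM) and frozen at **e_neat = −9.702 kcal/mol**; `rho0 =
0.0334 /Å³` is fixed by construction of that box. These are constants of
the packaged model, exactly as a published water model's neat energy is a
fixed reference.

What the generator does *not* emulate: protein force fields, polarization,
long-range electrostatics, flexible solutes beyond a two-state group, or
the system sizes of production simulations. Passing tests therefore
demonstrate that the analysis stack is correct and self-consistent on
equilibrium ensembles of a simple polar solvent — not that any specific
biological conclusion transfers.

## The rigid/flexible demonstration system

`demo_two_state_system()` is built for the rigid-vs-flexible comparison.
A near-spherical shell of 28 apolar carbons (radius 4 Å) carries a "grate"
of four small soft atoms at its top pole: water cannot pass the grate, but
can hydrogen-bond through it. A single acceptor oxygen (−1 e) either sits
deep inside the shell (cognate state: ≥ 4 Å from any allowed water
position, beyond hydrogen-bond range) or just beneath the grate (alternate
state: nearest allowed water position ≈ 2.9 Å — inside hydrogen-bond
range). Three design points matter:

* Both sites are permanently water-inaccessible, so the two-state swap
  move never collides with solvent in either direction. Swap moves that
  insert atoms into solvent-occupied space are rejected essentially always
  (we measured acceptance ≈ 1e-5 for exposed-site variants), which makes
  equilibration between states unattainable at desk scale.
* The cognate site carries a deliberate mild steric strain (≈ +4.5
  kcal/mol against a small buffer atom), so the first barrier crossing is
  downhill and occurs during burn-in at any seed. The hydration of the
  exposed state — one to two donated hydrogen bonds worth 15–25 kcal/mol
  in the subvolume solute–water energy — then locks the flexible ensemble
  in the exposed state. The strain is a factor of 3–5 smaller than the
  hydration signal it unlocks, so the preference being measured is
  water-driven.
* Water orientations around a charge relax over many sweeps, so a system
  like this is kinetically bistable: state swaps that reverse or displace
  charges across water contact distances almost never equilibrate by
  single moves. The demonstration accepts this (the flexible ensemble is
  expected to *stay* exposed) rather than pretending two-state occupancy
  statistics are converged; the zero-energy-difference calibration case
  (a non-interacting group, occupancy 0.5 ± binomial error) is tested
  separately where true equilibration is trivial.

On this system the flexible ensemble shows, relative to rigid: a
significantly more favorable subvolume total energy, significantly more
solute–water hydrogen bonds, and a less favorable *per-water* water–water
energy — the per-water form is used because the exposed acceptor also draws
extra waters into the subvolume, which makes the raw water–water *total*
reflect population as much as per-molecule sacrifice.

## Numerical choices

* Voxel assignment uses the oxygen position only; virtual sites and
  hydrogens never bin, never count as neighbors, but always carry charge
  in energies.
* Waters outside the grid are counted (`n_outside`) and otherwise ignored;
  the grid never wraps periodically.
* OpenDX output is the "regular positions, regular connections" dialect,
  grid positions at voxel centers, z index fastest; the reader inverts the
  writer exactly.
* The density-derived surface extracts the iso-surface of the (3³
  box-smoothed) `g` field at `g = 0.5` by marching tetrahedra (six
  tetrahedra per cube, linear edge interpolation); a voxel-face count is
  returned alongside as a cross-check. On a 4 Å spherical cavity sampled
  at 1 Å resolution the area lands within ~10–15% of 4π·4², and refining
  the grid on a noise-free field converges toward the analytic value.
* Superposition is available (Kabsch, with a collinearity guard) but off
  by default: frames are assumed pre-aligned, as they are when the
  generating simulation restrains the solute.
* Tests and the acceptance script use desk-scale problem sizes chosen to
  make every statistical assertion decisive at 3 standard errors: 100–216
  waters, 150–2,000 frames, boxes of 10–18.6 Å.

## Limitations

Truncated electrostatics (no Ewald), orthorhombic boxes only, rigid
solutes (beyond the two-state group), no entropy estimation, and no
cross-system hydration-site matching. The per-group statistics assume the
group's atoms are resolvable by residue id and atom name. The hydration
site search is quadratic in the number of pooled observations and is meant
for pocket-scale regions, not whole boxes over long trajectories.
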