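---
title: "Conformational dynamics of methylated and unmethylated B- and Z-DNA: models and methods"
author: "duplexdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational dynamics of B- and Z-DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexdyn)
```

## The scientific problem

Cytosine methylation at CpG dinucleotides changes the conformational
dynamics of DNA: it shifts the balance between the BI and BII backbone
substates of B-DNA, perturbs base-pair-step geometry, and lowers the free
energy gap between right-handed B-DNA and left-handed Z-DNA, which is one
route by which methylated d(GC)~n~ tracts adopt Z-form. Studying these
effects from molecular-dynamics trajectories requires a chain of
well-defined analyses: backbone torsion extraction, discrete-state
classification, histogram free-energy profiling, helicoidal geometry,
flexibility metrics, and end-state (MM/PBSA-style) free-energy
bookkeeping. `duplexdyn` implements that chain as tested, reusable
components, together with a structure builder and synthetic-dynamics
generators that stand in for the expensive simulations when validating
the analysis code itself.

## The duplex builder

`build_duplex()` constructs heavy-atom models of alternating d(GC)~n~
duplexes by placing rigid idealized nucleotide templates on base-pair
reference frames that are chained with fixed construction step
parameters:

* **B form** — twist 36°, rise 3.38 Å, all other step and pair
  parameters zero (the canonical fiber values; a 10-bp repeat per turn).
* **Z form** — a left-handed dinucleotide repeat with alternating
  twists of −9° (CpG) and −51° (GpC) summing to −60° per dinucleotide,
  rise 3.7 Å, and opposite small slides (±1 Å) on the two step types so
  the zigzag CpG/GpC bimodality is present in the construction itself.
  Guanosine is *syn* (χ = +65°, C3′-endo sugar) and cytidine *anti*
  (C2′-endo), the ZI-like arrangement.

The templates themselves are idealized rather than copied from any
database: base rings are planar regular polygons (bond length 1.38 Å,
purine = hexagon fused to a regular pentagon on C4–C5), exocyclic heavy
atoms sit on in-plane external bisectors, and the sugar–phosphate arm is
chained on by standard bond lengths and angles with the form's canonical
torsions (B: γ 54°, β 176°, δ 128°, χ −117°, sugar phase 162° and
amplitude 38°). The three free placement constants of the pair — the two
glycosidic-bond angles λ~G~, λ~C~ and the C1′ half-separation — were
solved once so that the three Watson–Crick hydrogen-bond distances
(N1–N3 2.95, O6–N4 2.91, N2–O2 2.86 Å) are reproduced; the resulting
C1′–C1′ distance (10.8 Å) and helical radius are B-DNA-like. The
complementary strand is the 180° rotation of a strand-1 template about
the pair x axis, which makes the construction exactly self-complementary
and antiparallel.

Because placement uses exact frame algebra, regenerating step parameters
from the built coordinates recovers the construction values to numerical
precision — this round trip is the package's strongest self-check and is
enforced in the test suite at 0.1°/0.01 Å. Inter-residue features that
are *not* pinned by construction (the emergent ε, ζ, α torsions and the
O3′–P virtual bond) come out in the correct B-form wells (ε−ζ < 0
everywhere away from the ends), though their absolute values are those
of an idealized fiber model, not of a relaxed force-field structure.

`methylate()` converts selected cytosines to 5-methylcytosine (residue
name `5CM`) by adding a single methyl carbon `C7` in the base plane at
1.50 Å from C5; no other atom moves. The default rule methylates every
cytosine except those in the terminal base pairs — 8 of the 10 cytosines
of the 10-bp duplex, the hypermethylated arrangement. The phosphate
count, 2(N−1) for an N-bp duplex with free 5′ ends, doubles as the
neutralizing monovalent-ion count (18 for 10 bp) via
`neutralizing_ion_count()`.

## What the synthetic generators emulate — and what they do not

Two generators provide inputs with exactly the statistical structure the
analyses assume:

* `perturb_trajectory()` adds independent, isotropic, zero-mean Gaussian
  displacements (SD σ per axis) to every atom of a reference structure.
  The per-atom mean-square fluctuation is then 3σ² and the theoretical
  B-factor 8π²σ², giving closed-form targets for the flexibility
  metrics. It deliberately omits everything that makes real MD
  interesting: correlated motion, anisotropy, sequence dependence and
  end fraying.
* `simulate_two_state()` draws a hidden two-state Markov chain (initial
  state from the stationary distribution, dwell lengths geometric) and
  emits one angle per frame from a state-specific von Mises
  distribution on an ε−ζ-like coordinate (defaults: wells at ∓70°,
  concentration κ = 20). The stationary fraction of state 1 is
  (1−p₂)/((1−p₁)+(1−p₂)) and the mean dwell in state k is dt/(1−pₖ).
  The frame spacing defaults to 2 ps, which makes picosecond residence
  times legible directly in frame counts. Emissions are circular
  because the BI/BII wells live near the ±180° wrap, where a Gaussian
  would leak mass across the boundary; the sampler is the Best–Fisher
  (1979) rejection method, written here because the environment carries
  no circular-statistics package. Ground-truth labels are always
  returned so that classifier and dwell-time recovery can be scored
  against them.

Passing tests built on these generators demonstrate that the *analysis
operators* are correct — that the classifier, dwell bookkeeping and
Boltzmann inversion recover parameters they were fed. They say nothing
about force fields, sampling convergence, or whether real methylated
DNA behaves like the published trajectories; those are properties of
simulations this package does not run.

## Torsions, pucker and discrete states

`backbone_torsions()` computes α, β, γ, δ, ε, ζ, χ per residue per frame
with the usual atom quadruples, via a numerically stable two-argument
arctangent dihedral. All angles are reported on the half-open interval
[−180°, 180°); state classifications re-wrap to [0°, 360°) where sector
conventions demand. Terminal residues are computed but flagged —
5′-terminal residues have no phosphate (α, β undefined), 3′-terminal
ones no downstream phosphate (ε, ζ undefined) — and every ensemble
statistic excludes flagged residues, mirroring the usual practice of
dropping terminal base pairs to avoid end effects.

Sugar pucker uses the Altona–Sundaralingam parameterisation with the
standard indexing ν~j~ = τ~m~ cos(P + 144°(j−2)), so ν₂ = τ~m~ cos P and
tan P = ((ν₄+ν₁)−(ν₃+ν₀)) / (2ν₂(sin 36° + sin 72°)). The amplitude is
recovered as the norm of the (τ~m~ cos P, τ~m~ sin P) pair, which stays
stable near P = 90°/270° where ν₂ vanishes; rings with amplitude below
1° are reported as planar with an undefined phase. `classify_pucker()`
groups the twenty half-open 18° wheel sectors into the ten conventional
36° states (C3′-endo = [0°, 36°), ..., C2′-endo = [144°, 180°)); the
ring oxygen is labelled O1′ as in classic pseudorotation tables, with
O4′ available as a synonym. The sector grouping is a documented
convention of this package — published tables that report "O1′ Endo"
rarely state theirs.

Discrete states follow the field's definitions:

* **BI/BII** — the sign of ε−ζ, computed as the *minimal circular
  difference* wrapped to [−180°, 180°) before the sign test. The raw
  subtraction of two wrapped angles is convention-dependent (an
  unwrapped difference spans 720°); the circular rule makes the call
  independent of the reporting range. An exact zero is assigned BI — a
  measure-zero tie needing a deterministic break.
* **α/γ rotamers** — half-open 120° sectors on [0°, 360°): g+ = [0°,
  120°), t = [120°, 240°), g− = [240°, 360°). The canonical B-DNA state
  is (g−, g+).
* **syn/anti** — χ ∈ [−90°, 90°) is syn, anti otherwise.

`dwell_statistics()` treats a dwell as a maximal run of one label times
dt. Runs truncated by the trajectory ends are *censored*: they are
excluded from dwell means (including them biases means downward) but
still count toward occupancy. A passage is any label change, summed over
residues; because published passage counts appear unfiltered, no
debouncing of single-frame dwells is applied. Whether passage counts
should be read per trajectory or per residue is ambiguous in the
literature, so both the total and the per-residue mean are reported.
`fraction_series()` smooths per-frame state fractions with a centred
sliding window (default 500 ps) whose edges shrink rather than pad, and
a window of one frame reproduces the raw series exactly.

## Free-energy profiles

`build_profile()` wraps the coordinate to [−180°, 180°), partitions it
into half-open bins (default 18°, hence exactly 20 bins), and applies
Boltzmann inversion G~b~ = −RT ln(n~b~/N) with R = 1.987×10⁻³
kcal/(mol·K) and T defaulting to 300 K, shifting the minimum to zero.
Two choices deserve emphasis:

* The coordinate is wrapped *before* binning. An unwrapped ε−ζ spans
  720° and would need 40 bins of 18°; wrapping is what makes "20 bins"
  the natural reading, and is consistent with the circular BI/BII rule.
* Empty bins carry `NA`, never a pseudo-count. A finite sample says
  nothing about the free energy of an unvisited bin, and inventing
  occupancy would silently flatten barriers.

`well_and_barrier()` splits the profile at a boundary (default 0°),
takes the occupied minimum on each side, and reports the well gap ΔG and
the barrier from each well to the highest occupied bin between the
minima — both directions, because "the barrier" is ambiguous when the
wells differ in depth. An empty interior bin between the wells is
flagged rather than interpolated. The companion sampler
`sample_two_well()` draws from a two-component von Mises mixture whose
weights realise a prescribed ΔG = −RT ln(w₂/w₁); with equal
concentrations and wells placed symmetrically about zero, the binning
bias cancels exactly and the recovered ΔG is unbiased, which is what the
acceptance test exploits at 1.6 million observations (the published
observation count for the combined runs).

`density_estimate()` delegates to `stats::density()` with the Silverman
rule-of-thumb bandwidth. Note the small, well-understood smoothing bias
at sharp modes (about ½·bw²·f″): a standard-normal sample of 10⁵ gives
≈ 0.395 at the mode against the exact 0.3989.

## Helicoidal geometry and flexibility

Base reference frames are obtained by least-squares (Kabsch) fitting of
the package's own planar ring templates to the observed ring atoms, with
a proper-rotation constraint; complementary-strand frames are flipped
about x before pairing. Pair and step parameters both use the mid-frame
(CEHS-style) scheme: the relative rotation is factored as
Rz(Ω/2−φ)·Ry(Γ)·Rz(Ω/2+φ) — twist Ω, roll Γcos φ, tilt Γsin φ — and
displacements are expressed in the half-twist/half-bend mid frame,
giving (shift, slide, rise) between pairs and (shear, stretch, stagger,
buckle, propeller, opening) within them. Twist is positive for
right-handed stacking; strand reversal negates exactly the sign-odd
parameters (shear, buckle, shift, tilt), and all parameters are
invariant under global rigid motion — both properties are tested. This
standard reference-frame scheme replaces curvilinear-axis analyses
(Curves+-style): for the gently bent or straight helices treated here
the two agree closely, but on strongly bent DNA the curvilinear
definitions diverge and this package makes no attempt to reproduce them.
Bends below 10⁻⁴ degrees are treated as pure twist — beneath that
threshold the bend azimuth extracted from a rotation matrix is numerical
noise.

Flexibility metrics follow the usual trajectory conventions: the
reference is the average structure after iterative superposition onto
the running mean (two iterations, matching the common "average structure
as reference" recipe), atomic B-factors are (8π²/3)⟨|r−⟨r⟩|²⟩, residue
values average the residue's heavy atoms (hydrogens are not modelled:
every statistic in scope is heavy-atom), and terminal base pairs are
excluded. Superposition itself absorbs six rigid-body degrees of
freedom, so for a structure of N atoms a pure-noise trajectory yields
B-factors biased low by roughly 6/(3N) — about 0.5% for the 10-bp
duplex, which is why validation against the 8π²σ² closed form is done
at that size.

## MM/PBSA bookkeeping

`summarize_energies()` consumes per-snapshot component tables — E_ELE,
E_VDW, E_INT, E_PBCAL, and SA or a precomputed E_PBSUR (E_PBSUR wins if
both are present, with a warning) — and recomputes every derived column
per snapshot before averaging: E_MM = E_ELE+E_VDW+E_INT, E_PBSUR = γ·SA+b
(γ = 0.00542 kcal/(Å² mol), b = 0.92 kcal/mol by default,
overridable), E_PBSOL = E_PBSUR+E_PBCAL, E_PBELE = E_ELE+E_PBCAL,
E_PBTOT = E_MM+E_PBSOL and G = E_PBTOT+(−TS). The entropic term is an
input column, never computed here: normal-mode and quasi-harmonic
entropy estimation is a separate, convergence-fragile problem outside
this package's scope. Standard errors are sample SD/√n. If an input
table carries derived columns that disagree with their own components —
printed literature tables sometimes do — the summary *flags* the
discrepancy and reports the recomputed value rather than reproducing the
inconsistent one.

`energy_contrast()` differences two summaries per component with
propagated SE and a Welch t-test reconstructed from summary statistics
(Welch–Satterthwaite degrees of freedom); the unequal-variance form is
the robust default where the literature says only "two sample t-test".
`energy_ttest()` runs the same comparison on raw per-snapshot columns
through `stats::t.test()`, including the paired variant used for
geometric-parameter comparisons, and the two routes are cross-checked
against each other in the tests.

## Numerical choices and degenerate inputs

* Dihedrals error on coincident consecutive points or collinear
  triplets ("undefined dihedral") in the scalar interface; the
  trajectory path converts missing-atom quadruples to `NA` flags
  instead of failing globally.
* Kabsch superposition requires ≥ 3 points and enforces det(R) = +1, so
  mirror solutions are never returned; planar point sets (base rings)
  are fine because the two in-plane singular values remain distinct.
* Profiles reject bin widths that do not divide 360° and empty inputs;
  constant samples are rejected by the density estimator ("zero
  bandwidth").
* Multi-model PDB reading validates per-model atom counts before
  parsing and names the offending model; unknown residue names list the
  accepted set (DG, DC, 5CM and common aliases). Read/write round trips
  are exact to the 10⁻³ Å precision of the PDB fixed-width format.
* All generators are seed-deterministic; identical seeds give
  bit-identical output.

## Problem sizes used in validation

The shipped tests validate dwell-time and stationary-fraction recovery
on 10⁶-step chains (recovery within 5% and ±0.01 respectively), the
two-well ΔG on 1.6×10⁶ draws (within 0.1 kcal/mol of a 2.0 kcal/mol
preset), the dihedral operator against an independent rotation-matrix
oracle on 10⁴ random quadruples (10⁻⁶ degree agreement), and B-factors
on 1500-frame noise trajectories of the 10-bp duplex. These sizes were
chosen so every statistical check sits an order of magnitude inside its
tolerance while the whole suite runs in well under a minute.

## Known limitations

* The builder produces idealized fiber-like models. Emergent torsions
  sit in the correct wells but not at force-field-relaxed values; bond
  geometry across the O3′–P junction is approximate (≈ 2.3–2.6 Å in the
  B form rather than 1.6 Å). Published fiber parameter sets also differ
  slightly between sources; the construction parameters are recorded in
  `$step_parameters` so any discrepancy is auditable.
* Hydrogens are not modelled; analyses that need them (hydrogen-bond
  occupancy, for instance) are out of scope.
* The synthetic generators do not emulate correlated dynamics; tests
  built on them validate estimators, not simulations.
* Helical-axis parameters (x-displacement, inclination, tip) and groove
  geometry are not computed; step/pair parameters cover the analysis
  surface here.
* ZI/ZII substate analysis and hidden-Markov dwell modelling are not
  implemented.
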