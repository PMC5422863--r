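---
title: "Trajectory analysis of glycosylase-DNA complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis of glycosylase-DNA complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpgtraj)
```

## The scientific problem

Fpg (MutM) is a bacterial DNA glycosylase that initiates base excision
repair of 8-oxoguanine (oxoG), an abundant oxidized base.  Because oxoG
pairs with both C and A, the enzyme must excise it opposite C but spare
it opposite A; failure either way fixes a G->T transversion.  In the
pre-catalytic complex the damaged nucleotide is everted from the helix
into the active site, the DNA is sharply kinked, and the N-terminal
Pro1-Glu2 dyad is poised for nucleophilic attack at C1' with protonation
of O4'.  Molecular dynamics of such complexes produces ensembles of
thousands of coordinate snapshots, and the scientific questions -
*which hydrogen bonds distinguish the C and A complexes?  how often is
the attack geometry catalytically competent?  which waters are
structural?* - are all questions about per-snapshot geometry aggregated
over the ensemble.

`fpgtraj` implements that aggregation layer as a tested, reusable
pipeline: structure I/O, per-snapshot geometric descriptors, an
energy-criterion hydrogen-bond census with cross-model statistics, a
water-bridge census, the optimal-attack-geometry census, trajectory
comparison statistics, and a two-state fit for pH-activity profiles.
Because production MD trajectories of this system are large and rarely
deposited, the package also ships a first-class synthetic-trajectory
generator that plants every quantity of interest with known ground
truth; the test suite and the acceptance script exercise the entire
pipeline against those planted truths.

## Containers

A `topology` holds atoms, contiguous residues with a class in
{protein, dna, water, ion, other}, and hydrogen-bond donor/acceptor
annotations derived from per-residue templates (`residue_templates()`,
extensible through plain-text tables for modified residues such as
carbacyclic lesions).  A `trajectory` is an ordered coordinate array
(atoms x 3 x snapshots, Angstrom) over one topology with a snapshot
spacing in picoseconds (default 2 ps, the conventional cadence at which
a 10 ns production run yields 5000 frames).  `read_pdb()`/`write_pdb()`
map multi-model PDB files onto these containers; alternate locations
keep the highest-occupancy conformer (ties to `A`), elements are
inferred from atom names where the element column is blank, and the
round trip is stable to the 3-decimal precision of the PDB fixed
columns.

Atom sets are named by a small selection language
(`resolve_selection()`), which exists so that definitions like the
active site - *all protein residues with at least one atom within 4
Angstrom of the lesion* - can be written as
`byres (protein and within 4 of resname 8OG)` and resolved against a
context snapshot.

## Geometry descriptors

Distances, three-point angles (in [0, 180] degrees) and signed torsions
(IUPAC convention, in (-180, 180]) are computed per snapshot.  Torsions
with a degenerate central axis (norm below 1e-9 Angstrom) are masked
rather than raised as errors, so a pathological snapshot does not abort
a 5000-frame analysis.  Note one property of the IUPAC convention that
is often misremembered: reading the four atoms backwards leaves the
signed torsion unchanged (both the viewing direction and the role of
the two planes flip).

**Glycosidic chi and conformer domains.**  Chi is O4'-C1'-N9-C4 for
purines and O4'-C1'-N1-C2 for pyrimidines; for carbacyclic lesion
analogs the atom isosteric to O4' is looked up by a configurable name
list.  Classification uses the half-open primary partition
syn = [-90, 90) with anti as the remainder, plus the border
sub-vocabulary *high anti* = (-90, -30] and *high syn* = (60, 120]
reported alongside the primary label.  The sub-ranges deliberately
straddle the primary boundary: in the literature of this enzyme family
the border vocabulary is used loosely (values near -60 degrees are
called either syn or high-anti depending on the author), so the package
keeps the primary partition strict and configurable and treats the
border labels as annotations, not as a partition.  The boundary at
exactly +90 falls to anti and -90 to syn by the half-open convention.

**Superposition and r.m.s.d.**  `superpose_kabsch()` is the standard
SVD solution with the determinant correction; rank-deficient (collinear)
point sets are a hard error because the rotation is then undefined.
`rmsd_series()` superposes each snapshot on a fit selection and reports
r.m.s.d. over a measure selection, which is how the conventional
"backbone r.m.s.d. against the starting structure" and "active-site
r.m.s.d." traces are produced.

**DNA kink angle.**  Each arm's phosphates are reduced to a principal
axis (largest singular vector), each axis is oriented along its arm's
5'->3' atom order, and the kink is the angle between the two oriented
axes: collinear, consistently oriented arms give 0, and a glycosylase
style kink reads in the tens of degrees.  There is no community-standard
arm definition, so kink values are comparable only within one arm
convention; the package requires the caller to name the arms (e.g. the
6 bp on each side of the lesion, excluding the +-1 pairs).

**Propeller twist.**  Base-plane normals come from the least-squares
plane through the ring atoms; the twist is the signed rotation between
the two (consistently oriented) normals about the pair long axis
(C8->C6 for purine-pyrimidine pairs, centroid-centroid otherwise).  The
overall sign of such an angle is convention-relative across programs;
the package fixes it so that a duplex constructed with the canonical
B-DNA propeller sense reads positive (about +13 degrees for the
canonical magnitude).

**SASA family.**  Shrake-Rupley areas use a deterministic golden-spiral
sphere point set (no RNG; 960 points by default, <0.5% quadrature error
on a single sphere) and a bundled Bondi-type van der Waals radius table
(also installed as plain text under `extdata`).  Water burial is
SASA(water in complex)/SASA(isolated water), with the conventional <10%
exposure rule for "buried".  The occluded contact area between two
groups is the mean of the two groups' probe-buried areas computed with
only the two groups present; since only the probe radius is fixed by
convention, occluded-area values are definition-relative and should only
be compared within this definition.

**Eversion.**  The base-eversion pseudo-dihedral uses four configurable
points (defaults: base-ring centroid, C1', lesion P, 3'-neighbour P).
Published eversion definitions vary; absolute values are meaningful only
within one configuration, which is why the definition is part of the
function's interface rather than hidden.

**Moving averages.**  The conventional smoothing for plotting is a
centred 50-snapshot window.  Circular series (torsions) are averaged via
the vector (sin/cos) mean so that a series oscillating around the +-180
seam averages to +-180 rather than 0.

## Hydrogen bonds

Analysis tools attached to MD engines typically score hydrogen bonds
with a smooth energy function rather than a hard geometric rule.  The
package uses a 10-12 Lennard-Jones-type well with a cosine-quartic
angular weight:

E = epsilon * (6 (sigma/d)^10 - 5 (sigma/d)^12) * cos^4(theta), clamped at >= 0,

with d the donor-acceptor distance, theta the deviation of D-H...A from
linear, epsilon = 2.8 kcal/mol and sigma = 2.9 Angstrom, so the maximum
stabilization is exactly epsilon at d = sigma.  A bond *exists* in a
snapshot when E > 1.2 kcal/mol.  All parameters are configurable
(`hbond_params()`).  Two things about this function matter in practice:

* it is asymmetric about its optimum - the compression wall crosses the
  1.2 kcal/mol threshold at about 2.73 Angstrom while the long-range arm
  crosses it only near 3.45 Angstrom; and
* donors without hydrogens (crystal structures) are scored in a
  heavy-atom mode whose angular factor comes from the donor-antecedent
  geometry (deviation of antecedent-donor-acceptor from tetrahedral), or
  1 when no antecedent exists.

Donors with two hydrogens score each hydrogen and keep the maximum.  A
classic geometric criterion (d <= 3.5 Angstrom, D-H...A >= 120 degrees)
is available as `criterion = "geometric"` and agrees with the energy
rule on well over 90% of planted ideal/broken bonds in the synthetic
suite.  Candidate pairs are pre-filtered at 5 Angstrom, beyond which the
energy is an order of magnitude below any sensible threshold, so the
filtered search is exactly equivalent to all-pairs evaluation (this
equivalence is a tested invariant, not an assumption).

**Occurrence tables and cross-model statistics.**  Occurrences (the
fraction of snapshots in which a bond exists) are tabulated per model;
bonds below a 1% existence floor in every model are dropped.  Bonds are
keyed by heavy atoms (chain:residue:atom), not by hydrogens or residue
names, so tables stay comparable across alternative protonation states
of the same complex (a protonated and an unprotonated carboxylate differ
in hydrogens and residue naming but not in heavy atoms).  Downstream:

* `classify_stability()`: stable (> 90%), fluctuating (<= 25%,
  boundary inclusive), intermediate otherwise;
* `phi_coefficient()`: the 2x2 mean-square contingency coefficient of a
  binary category between two models, with zero margins flagged;
* `group_specific_bonds()`: the difference map between two groups of
  models.  A bond is selected when its between-group mean difference
  exceeds k = 3 pooled within-group standard deviations *and* an
  absolute floor of 0.10.  The pooled-sd reading was chosen because the
  alternative ("k sigma of the difference distribution across bonds")
  conflates the planted signal with the background; it remains available
  as `sigma_mode = "across_bonds"`.  The absolute floor suppresses
  sparse bonds whose within-group variance is accidentally tiny;
* `replicate_reproducibility()`: per-bond mean and coefficient of
  variation across replicate runs;
* `compare_to_reference()`: recovery of a crystal-structure bond list at
  the 90% cutoff, reported per bond class.

## Water bridges

A water that donates/accepts hydrogen bonds to k >= 2 non-water
partners in one snapshot contributes all C(k,2) pairs and C(k,3)
triplets of its partner set.  Chemically equivalent carboxylate oxygens
(Glu/Asp OE1/OE2, OD1/OD2) collapse into one logical partner by
default - a bond that alternates between the two oxygens of one
carboxylate is one interaction, not two - and the same merging is
optionally available for non-bridging phosphate oxygens.  A partner
set's snapshot is counted once regardless of how many waters bridge it
simultaneously; the multiplicity is kept in a per-set histogram, and
`multi_water_bridges()` reports the double-water signature for a fixed
pair directly.

Retention uses either fixed counts (2000 for pairs, 1500 for triplets
per 5000 snapshots, rescaled linearly for other lengths) or a quantile
rule: the smallest *level set* of counts whose records account for more
than 75% of all occurrences.  The level-set formulation matters when
counts tie at the cutoff: all tied records retain together, which keeps
the invariant that every retained record's count is at least every
dropped record's count.

## Catalytic-geometry census

The four-criterion definition of a catalytically poised snapshot is:
N[Pro1]...C1' < 4 Angstrom, Oe2[Glu2]...O4' < 4.5 Angstrom, and the two
attack angles within 20 degrees (boundary inclusive) of their ideals -
107 degrees for C1'...N...Cd (tetrahedral approach of the secondary
amine) and 180 degrees for O4'...C1'...N (in-line S_N_2 displacement).
`optimal_geometry_census()` counts snapshots satisfying all four;
the census is monotone in every cutoff and equals the intersection of
the four single-criterion masks by construction.  Distribution summaries
report the median and central 90% range (5th-95th percentiles) plus a
peak count: the histogram (Freedman-Diaconis bin width) is smoothed with
a 3-bin moving mean and local maxima above 10% of the global maximum are
counted, which turns the visual unimodal/bimodal language of trajectory
analysis into a reproducible number.

## Trajectory statistics

`moving_mwz()` compares two aligned series in disjoint 50-snapshot bins
(a sliding variant is available) via the Mann-Whitney U with the
tie-corrected normal approximation; completely tied bins return Z = 0
and are flagged.  `f_test_variance()` delegates to `stats::var.test()`
with the larger variance in the numerator (recorded), and
`benjamini_hochberg()` wraps `stats::p.adjust()` together with the
step-up rejection set.  Which parameters form the multiple-testing
family is the caller's declaration (`compare_parameters()`), since no
universal family exists for MD series.  A documented caveat applies to
all of these: consecutive MD snapshots are autocorrelated, so
window-level p-values understate uncertainty unless windows are long
compared with the correlation time; the package reports the statistics
and leaves effective-sample-size corrections out of scope.

## pH-activity fitting

Activity controlled by a single titratable group follows
`activity(pH) = B + A / (1 + 10^(pKa - pH))`.  `fit_two_state()` uses
Levenberg-Marquardt least squares (via `minpack.lm`) initialized from
the data (B at the minimum, A at the range, pKa at the half-range
crossing by linear interpolation) with Jacobian-based standard errors.
A fit is marked non-identifiable when SE(pKa) exceeds 1 pH unit or when
the fitted midpoint falls outside the sampled pH range; the latter
guards against designs that only see one tail of the transition, where
the optimizer can lock onto a small-amplitude transition just outside
the data with a deceptively small standard error.

## The synthetic-data generator

`build_toy_complex()` constructs a chemically plausible (bonded
distances 1.0-1.8 Angstrom) single-snapshot complex: a straight
B-DNA-like duplex (14 bp by default, positions numbered -7..+6 with the
8-oxoguanine lesion at 0 and either C or A opposite it - a 14-bp window
cannot span -7..+7, so the 3' side carries one position fewer), a small
protein scaffold whose Pro1/Glu2 dyad is *built* in the ideal attack
pose (d1 = 3.5, d2 = 4.0 Angstrom, angles 107/180 degrees), Arg/Phe/Thr
stand-ins, interface waters and a Zn ion.  Optional *stations* are
isolated, geometrically controlled donor/acceptor pairs and
water-bridge sites, spaced 15 Angstrom apart so planted events never
interact.

`simulate_trajectory()` realizes a `plant_spec()`:

* **Hydrogen-bond plants** toggle a station's acceptor residue between
  its bonded position and a broken one (donor-acceptor > 7 Angstrom,
  beyond the 5 Angstrom search cutoff).  The bonded acceptor sits at
  3.05 Angstrom on the donor's N-H line - within the flat top of the
  10-12 well (2.5 kcal/mol) but clear of its steep compression wall, so
  that Gaussian coordinate noise up to 0.1 Angstrom cannot push an
  on-state bond below the 1.2 kcal/mol existence threshold.  Placing the
  on-state exactly at the 2.9 Angstrom optimum would sit 0.17 Angstrom
  from the threshold wall and lose about a tenth of on-snapshots at
  that noise level, which would defeat ground-truth recovery.
* **Bridge plants** place one (or two) waters at trigonometrically
  solved positions 3.0 Angstrom from each partner, with the two water
  hydrogens along the two acceptor directions (104.5 degrees apart) and
  any third partner donating into the water oxygen; the off state
  displaces the water.  Partner sets a single water cannot span raise an
  error naming the plant.
* **The chi process** rotates the lesion base about the glycosidic bond
  through a Markov chain over configurable conformer states.
* **The census plant** withdraws Pro1 from its built ideal pose along
  the attack line in non-optimal snapshots, violating the d1 criterion
  only.
* **Noise** is isotropic Gaussian, added last (default sigma = 0.05
  Angstrom).

All two-state plants are Markov chains with a stationary occupancy equal
to the target and a configurable correlation time (default 10
snapshots), because real MD observables have persistence rather than
i.i.d. flips.  Setting `tau = 1` recovers Bernoulli planting, which is
what the binomial-3-sigma recovery checks in the test suite use - under
a correlated chain the realized occupancy itself fluctuates beyond
binomial bounds, which is a property of the chain, not of the detector.
Everything is reproducible from the seed, and the returned
`truth_manifest` records the per-snapshot states and realized counts,
which the detectors must match exactly at zero noise (a tested
invariant).

**What the generator does and does not emulate.**  It reproduces the
*observables* of a glycosylase-complex trajectory - bond occupancies
with persistence, bridging waters, conformer jumps, attack-geometry
fractions, coordinate noise - on top of a geometric scaffold, not a
folded protein.  There is no force field, no thermodynamics, no
coupling between planted events, and the duplex is straight rather than
kinked.  Passing the recovery suite therefore demonstrates that the
*measurement machinery* is correct and calibrated; it does not validate
any claim about real Fpg-DNA dynamics, whose trajectories must be
supplied by the user as multi-model PDB ensembles.

**Problem sizes.**  The validation suite runs the full pipeline at the
production cadence it targets (5000 snapshots, 2 ps spacing) on the toy
complex (about a thousand atoms with 20 bond stations and 5 bridge
stations), 10^4 null replicates for the F-test size check, 200 noisy
replicates for the pKa recovery, and 100-snapshot brute-force oracle
comparisons on a reduced 6-bp complex; these sizes give the binomial
3-sigma bounds used by the checks while keeping the whole suite at
desk scale.

## Known limitations

* Values that depend on an undisclosed convention in the literature
  (kink arm definition, eversion point set, occluded-area definition,
  propeller sign) are comparable only within this package's documented
  conventions.
* Heavy-atom-mode hydrogen-bond scoring is a geometric surrogate for
  hydrogen placement and will differ from explicit-hydrogen scoring for
  donors with unusual antecedent geometry.
* No autocorrelation-aware corrections are applied to window statistics.
* mmCIF, compressed trajectory formats, hydrogen building and sugar
  pucker analysis are out of scope.
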