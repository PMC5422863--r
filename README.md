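# fpgtraj

Trajectory analysis of Fpg–DNA pre-catalytic complexes in R.

Fpg (MutM) is a bacterial DNA glycosylase that excises 8-oxoguanine
(oxoG) from DNA, but only when the lesion pairs with C — excision
opposite A would fix a G→T mutation. Molecular dynamics of the
pre-catalytic Fpg–DNA complex produces ensembles of thousands of
coordinate snapshots; the questions that matter are statistical
properties of those ensembles: how often the Pro1–Glu2 catalytic dyad
adopts a geometry competent for nucleophilic attack at C1′, which
hydrogen bonds distinguish the C and A complexes, and which waters are
structural, bridging protein and DNA.

`fpgtraj` implements that analysis layer:

* **structure I/O** — single- and multi-model PDB files into a validated
  topology + trajectory representation, residue classification with
  extensible donor/acceptor templates, and a selection mini-language
  (`within 4 of resname 8OG`, …);
* **geometry** — distances, angles, torsions, glycosidic χ with syn/anti
  conformer classification, Kabsch-superposed r.m.s.d., radius of
  gyration, DNA kink angle, base-pair propeller twist, Shrake–Rupley
  SASA, water burial, occluded contact area, base-eversion
  pseudo-dihedral, and circular-aware moving averages;
* **hydrogen bonds** — an energy criterion
  `E = ε(6(σ/d)¹⁰ − 5(σ/d)¹²)·cos⁴θ` (ε = 2.8 kcal/mol, σ = 2.9 Å,
  existence at E > 1.2 kcal/mol), occurrence tables across models,
  stability classes (>90% stable, ≤25% fluctuating), φ coefficients,
  >3σ group-difference maps, replicate reproducibility, and recovery of
  crystal-structure bond lists;
* **water bridges** — pair/triplet partner-set censuses with
  multiplicity histograms, double-water bridge detection, and
  fixed (2000/1500 per 5000 snapshots) or quantile (>75% cumulative
  share) retention thresholds;
* **catalytic census** — the four-criterion optimal attack geometry
  (d(N…C1′) < 4 Å, d(Oε2…O4′) < 4.5 Å, angles within 20° of 107° and
  180°) and Table-style distribution summaries (median, 90% range,
  modality);
* **statistics** — moving-window Mann–Whitney Z (50-snapshot bins),
  variance F-tests, Benjamini–Hochberg FDR control;
* **pH profiles** — the two-state ionization model
  `activity = B + A/(1 + 10^(pKa − pH))` with identifiability
  diagnostics;
* **synthetic data** — a toy protein–DNA–water complex and trajectory
  simulator that plants hydrogen-bond occupancies, water bridges,
  conformer dynamics and census fractions with fully known ground
  truth, used to validate every stage end to end.

## Worked example

Build the toy complex with two hydrogen-bond stations and one
water-bridge station, simulate 1000 snapshots with planted truths, and
run the main analyses:

```r
library(fpgtraj)

cx <- build_toy_complex(n_hbond_stations = 2, bridge_sizes = 2)
plan <- plant_spec(hbond_occurrence = c(0.9, 0.3), bridge_occurrence = 0.7,
                   chi_states = c(-120, 30), census_fraction = 0.2,
                   noise_sigma = 0.05)
sim <- simulate_trajectory(cx, plan, n_snapshots = 1000, seed = 7)
sim$trajectory
#> <trajectory> 'synthetic': 1000 snapshots x 758 atoms, dt = 2 ps (2000 ps total)

ot <- occurrence_table(sim$trajectory)
mf <- sim$manifest$hbonds
data.frame(bond = mf$key, target = mf$target,
           recovered = round(ot$occurrence[mf$key, 1], 3))
#>          bond target recovered
#>  S:1:N--S:2:O    0.9     0.927
#>  S:3:N--S:4:O    0.3     0.319

cen <- optimal_geometry_census(
  catalytic_series(sim$trajectory, cx$info$catalytic_atoms))
sprintf("optimal attack geometry: %d / 1000 snapshots (planted %d)",
        cen$count, sim$manifest$census_count)
#> "optimal attack geometry: 241 / 1000 snapshots (planted 241)"

table(classify_chi(glycosidic_chi(sim$trajectory, 0, "B")))
#> anti  syn
#>  449  551

bridge_census(sim$trajectory)$pairs[, c("key", "count", "fraction")]
#>           key count fraction
#> 1 T:1:O+T:2:O   751    0.751
```

The recovered bond occupancies (0.927, 0.319) match the Markov plants'
realized occupancies; the optimal-geometry count equals the planted
count exactly because the dyad is toggled between the built ideal pose
and a withdrawn one; the χ table reflects the two-state conformer
process; and the bridge census counts the snapshots in which at least
one water spans both planted partner oxygens.

Real trajectories enter the same way: read a multi-model PDB ensemble
with `read_pdb()`, then apply the same functions to
`$trajectory`/`$topology`.

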