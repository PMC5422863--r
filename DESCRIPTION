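Package: fpgtraj
Title: Trajectory Analysis of Fpg-DNA Pre-Catalytic Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics ensembles of
    protein-DNA complexes, developed around the base-excision-repair
    glycosylase Fpg (MutM) bound to 8-oxoguanine-containing DNA.  Reads
    single- and multi-model PDB files into a validated topology plus
    trajectory representation, computes per-snapshot structural
    descriptors (distances, angles, glycosidic torsions with syn/anti
    conformer classification, Kabsch-superposed r.m.s.d., radius of
    gyration, DNA kink angle, propeller twist, Shrake-Rupley solvent
    accessible surface area, water burial, occluded contact area, base
    eversion pseudo-dihedral), detects hydrogen bonds with an energy
    criterion and builds cross-model occurrence tables with stability
    classes, phi coefficients and group-difference maps, censuses
    water-mediated pair and triplet bridges with quartile-based retention
    thresholds, evaluates the optimal nucleophilic-attack geometry of the
    Pro1-Glu2 catalytic dyad, fits the two-state ionization model to
    pH-activity data, and provides windowed Mann-Whitney Z, variance
    F-tests and Benjamini-Hochberg control for trajectory comparison.  A
    synthetic-trajectory generator with planted, fully known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
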