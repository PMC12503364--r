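---
title: "Distal-histidine gating, interface dynamics and heme-pocket solvent access: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distal-histidine gating, interface dynamics and heme-pocket solvent access: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemegating)
```

# The observables and their assumptions

Deoxyhemoglobin's distal histidine (HisE7) sits over the sixth
coordination site of the heme iron and acts as a gate: in its *down*
position the N&epsilon;&ndash;Fe distance is roughly 4&ndash;5 &Aring;,
and a swing toward the CE corner opens a solvent channel with the
distance rising to 8&ndash;10 &Aring;. This package turns MD
trajectories of such systems into five families of observables; each
rests on explicit, configurable conventions.

**Units and thresholds.** Internal lengths are nm throughout (the
GROMACS convention); the gating threshold of 7 &Aring; is stored as 0.7
nm and reports print both units. The threshold is *strict*: a frame at
exactly 0.7 nm has not swung out.

**Equilibration cutoff.** Every analyzed statistic ignores frames
before 1 ns (configurable). Averaged quantities use a closed window,
1&ndash;133 ns by default, truncated with the trajectory when shorter.

**Swing-out events.** An event is *binary per chain-replicate trace*:
did the HisE7 N&epsilon;&ndash;Fe distance ever exceed the threshold on
an analyzed frame. With two &alpha; chains and five replicates the
maximum count per treatment is therefore 10. Excursion-level detail
(maximal runs above threshold) is always recorded, but only the binary
outcome enters the counts. A *return to the down position* requires the
trace to fall to the down threshold (default, the same 0.7 nm) and stay
there for at least `dwell_min` = 5 ns; without a dwell requirement a
single-frame dip would count as a return, which is not what the term
means physically. Both thresholds and the dwell are arguments of
`detect_swing()`.

**Time normalizations.** Replicates can have unequal lengths, so
counts and times are corrected for simulation time. The event count is
scaled by `reference_total / treatment_total` (totals summed over
distinct replicates). First-passage times are reported only for
chain-replicates where an event occurred, and each is scaled by two
factors: `longest_replicate / replicate_total` (within-treatment length
differences) and `reference_total / treatment_total` (between-treatment
differences). The composition of these two factors is one consistent
reading of a verbally specified procedure; because the algebra admits
other readings, `normalized_swing_times()` returns both factors as
separate columns so any alternative can be recomputed from the same
table.

**Fe&ndash;L1 and iron displacement.** Fe&ndash;L1 is the plain
Euclidean distance from the proximal-histidine N&epsilon; to the heme
Fe. Iron displacement is defined as the *point-to-point distance*
between the Fe and the unweighted centroid of the four pyrrole
nitrogens (all four atoms are nitrogen, so mass weighting is a no-op),
signed positive when the Fe lies on the proximal side of the
least-squares pyrrole-N plane. The perpendicular projection onto that
plane's normal is computed as well and exposed as `perpendicular`, but
the centroid distance is the reported value: it is the literal reading
of "distance between the iron and the pyrrole-nitrogen center of
mass", and it upper-bounds the perpendicular component.

**Interface sites.** Four canonical &alpha;1&ndash;&beta;2 atom-pair
contacts are tracked (`interface_sites()`); the Thr(&alpha;1C6)
OG&ndash;Arg(&beta;2C6) CZ hydrogen bond exists only where &alpha;1C6
is a threonine &mdash; a trout-style map with Ala at C6 exposes three
sites, and requesting the fourth raises an applicability error rather
than silently measuring something else. In interspecies reports the
three shared sites are numbered 1&ndash;3 (G-helix hydrogen bond,
C-helix stacking, FG&ndash;C contact) and the bovine-only pair is
reported alongside site 2, with which it shares the Arg guanidinium;
both labelings are emitted because the 4-pair/3-site correspondence is
a reporting convention, not a measurement.

**Local interface RMSD.** The backbone selection is N, CA, O of
&alpha;1 C6/C7/FG4/G1 and &beta;2 C6/G4 for one chain pairing (18 atoms
when all six residues are present). The Kabsch superposition is
computed *on this selection itself*, not on the global backbone, so the
RMSD measures internal rearrangement of the contact patch rather than
rigid drift of the interface through the protein frame.
`interface_selection()` takes the atom-name set and an optional
expected count as arguments rather than hardcoding a number: published
atom counts for such selections depend on whether C or O (or both) are
included in "backbone" and on how many symmetric interfaces are
pooled, and a mismatch should fail loudly under the user's own
convention. The RMSD trend over the analysis window is summarized by an
ordinary least-squares slope in nm/ns.

**SASA.** Shrake&ndash;Rupley with a 0.14 nm probe and 960
quasi-uniform sphere points per atom (golden-spiral lattice). The
context is protein + heme (plus any synthetic occluders); water and
ions are excluded, mirroring the usual practice of indexing heme atoms
with the protein before SASA analysis. Radii come from the Bondi table
with Fe set to 0.200 nm (Bondi gives no Fe value; this is the common
choice for heme iron) and can be overridden per element, e.g. with a
GROMACS table &mdash; absolute SASA shifts with the radius table, so
comparisons should always be like-for-like within one table, which the
output headers record. Per-frame residue/heme values are sums of
atomwise areas; convergence is such that doubling the point count moves
reported sums by well under 0.5% (tested).

**Stacking geometry.** For aromatic pairs (e.g. HisE7 against the CE4
ring), `stacking_geometry()` reports centroid distance, interplanar
angle folded to &le;90&deg;, and lateral offset, and classifies
parallel-displaced (angle < 30&deg;, distance < 5.5 &Aring;) versus
T-shaped (angle > 60&deg;, distance < 6.0 &Aring;). These cutoffs are
package defaults in line with common stacking surveys and are
arguments, not constants; rings must be planar to RMS 0.3 &Aring;.

**Statistics.** One-way ANOVA uses the standard between/within
decomposition; "multiple comparisons" is Tukey HSD (the common default
for one-way designs in GraphPad-style workflows), in the
Tukey&ndash;Kramer form for unequal group sizes, with the method named
in the output. The unpaired t-test defaults to Student's pooled form
(again the common unpaired default) with Welch by flag. All three are
implemented from formulas and the test suite pins them to R's
`aov`/`TukeyHSD`/`t.test`/`lm` at 10^-8 relative tolerance on random
data, plus the exact F = t&sup2; identity on two groups.

# What the synthetic generator emulates

`generate_synthetic_system()` builds a chemically fake but structurally
well-formed minimal tetramer &mdash; per chain a heme (Fe + 4 pyrrole
N), distal and proximal histidines, an E11 residue, a CE4 aromatic and
the interface residues &mdash; and writes real PDB topology +
multi-model PDB trajectories whose analysis-relevant degrees of freedom
follow planted series:

- the distal-His N&epsilon;&ndash;Fe distance of each &alpha; chain is
  a continuous-time two-state Markov chain (down mean 0.45 nm, up mean
  0.90 nm) sampled at 0.2 ns frames, plus stationary
  Ornstein&ndash;Uhlenbeck noise (SD 0.03 nm, correlation time 0.5
  ns). OU noise rather than white noise makes traces resemble the
  correlated fluctuations of real distance data, and the default SD
  puts the state means more than 6 SD from the threshold so
  noise-induced false crossings are negligible (probability < 10^-9
  per frame). Explicit transition schedules can replace the sampler to
  plant exact ground truth;
- interface atom pairs follow baseline + OU series (baselines
  0.50/0.55/0.52 nm, SD 0.02 nm) with optional Gaussian-bump excursions
  above 1 nm, mimicking the Arg &beta;2C6 guanidinium swinging toward
  solvent; the bovine-only site shares the &beta; CZ atom and sits a
  fixed 0.05 nm further by construction;
- one interface backbone atom per pairing drifts linearly (default
  5 x 10^-4 nm/ns) so the local RMSD has a known upward trend. Note the
  fitted RMSD slope is *not* numerically equal to the atom's drift
  rate: the superposition absorbs part of a single-atom displacement
  into rotation, so the slope is a property of the whole selection;
- the proximal-His N&epsilon;, the pyrrole nitrogens and the E11 atoms
  carry low-amplitude OU jitter (SD 0.004/0.0025/0.002 nm) so
  Fe&ndash;L1, displacement and SASA observables fluctuate like
  measurements instead of being bit-identical constants; the Fe and
  the planted series stay exact;
- an optional occluder shell around the &alpha;1 E11 residue follows an
  open-fraction schedule: the fraction determines how much of the shell
  is displaced out of occlusion range (plus a slight swell of the
  remainder as a tie-breaker), so the residue's SASA increases
  monotonically with the planted schedule from &asymp;0 to the
  residue's isolated value.

Defaults (k_up = 0.02/ns, k_down = 0.002/ns, 5 replicates, 133 ns at
0.2 ns spacing, 2 &alpha; + 2 &beta; chains) reflect the study design
the analysis conventions come from: replicate totals on the 10^2 ns
scale, unequal lengths allowed, and events that are common but not
certain within one replicate.

What the generator does **not** emulate: force-field physics of any
kind (no energetics, no sterics, no solvent), correlated motion between
observables (gating does not couple to the interface or to Fe&ndash;L1,
whereas in real trajectories they may co-vary), rotational diffusion of
the tetramer, or periodic-boundary artifacts. Passing tests on
synthetic data therefore validate the *measurement pipeline* &mdash;
that each operation recovers exactly what is in the coordinates &mdash;
not any claim about real protein dynamics.

# Numerical choices and degenerate inputs

- PDB coordinates are written/read at 10^-3 &Aring; resolution, so
  round-trips are exact to 10^-4 nm; planted-series recovery is tested
  at 10^-3 nm.
- Kabsch superposition uses SVD with the determinant correction, so
  reflections are never applied; rigid motions cancel to < 10^-10 nm
  (tested at 10^-15 in practice). Selections need &ge;3 atoms.
- The pyrrole plane is the least-squares plane of the four N; collinear
  nitrogens raise a degeneracy error rather than returning an arbitrary
  normal.
- Distances apply no periodic-image correction by default: intra-protein
  pairs in a solvated box never span an image, and silent wrapping can
  mask real excursions. An orthorhombic minimum-image mode is available
  via the `box` argument for inputs where wrapping matters; whether the
  original .xvg distances were image-corrected is unknowable from the
  outputs, and for these intra-tetramer pairs the two conventions
  coincide.
- Ties at the swing threshold are "not exceeded" (strict `>`);
  excursions that are still above threshold at the last frame are
  recorded with an open end (`NA`).
- Zero-variance statistics (identical constant groups) raise structured
  errors instead of returning NaN.
- ANOVA/Tukey assume independent samples per group; the pipeline feeds
  them per-chain-replicate means (&alpha;1/&alpha;2 pooled, n = 10 per
  treatment), which matches that assumption at the replicate level but,
  as in the original design, treats the two chains of one replicate as
  independent.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` validate against synthetic
studies small enough to run comfortably on one CPU: unit tests use
3-replicate studies of 16&ndash;30 ns, the pipeline-closure check uses
5 replicates of 22&ndash;30 ns with 240 SASA sphere points, and the
acceptance script runs the full default study conditions (5 replicates
of 120&ndash;133 ns, 960 sphere points) plus a 500-trace gating-rate
calibration at k_up = 0.02/ns over 150 ns, where the swung fraction is
checked against 1 - exp(-k_up T) and mean first passage against the
truncated-exponential expectation. These sizes are the package's
choice of demonstration scale; every operation accepts full-length
inputs unchanged.

# Using real data

Real structures need a curated site map: residue numbers per helical
site per subunit class, plus the chain classification, in a small YAML
file (see `inst/extdata/sitemap-synthetic-bovine.yaml` for the schema).
Residue numbers for helical sites are a property of each structure's
numbering and must be taken from an alignment or from the structure's
annotation; `resolve_site()` cross-checks the residue *name* at
resolution time and fails loudly on mismatch (a map expecting TrpCE4
applied to a PheCE4 structure is an error, not a warning). Atom-name
dialects differ too &mdash; e.g. a threonine hydroxyl may be `OG` or
`OG1` depending on the source &mdash; so the canonical site table's
atom names may need the same curation. Trajectories are accepted as DCD
or multi-model PDB; XTC/TRR inputs should be converted (e.g. with
`gmx trjconv` or `mdconvert`) beforehand, as no installed R reader
exists for those formats.

# Known limitations

- Event detection is a fixed-threshold scan, not a hidden-Markov
  segmentation; fast re-crossings within one frame interval (0.2 ns) are
  invisible at the sampling resolution.
- The two-factor swing-time normalization is a documented convention
  (see above), not an asserted reconstruction of any particular
  published calculation; both factors are emitted so alternatives can
  be recomputed.
- SASA values depend on the radius table and point density; defaults
  are recorded in every output header, and cross-study comparisons
  should match tables.
- The synthetic tetramer is not a physical model; see the generator
  section for exactly which features of real data it reproduces.
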