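Package: hemegating
Title: Distal-Histidine Gating, Interface Dynamics and Heme-Pocket
    Solvent Access from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and statistical analysis of hemoglobin
    molecular dynamics trajectories. Detects distal-histidine (HisE7)
    swing-out gating events from Nepsilon-Fe distance traces with
    simulation-time normalization, measures proximal-bond (Fe-L1)
    geometry and heme-iron out-of-plane displacement, quantifies
    alpha1-beta2 interface contact dynamics and local backbone RMSD
    drift, and computes Shrake-Rupley solvent-accessible surface area
    of heme-pocket residues and the heme moiety. Includes a
    synthetic-trajectory generator with planted two-state Markov gating
    and Ornstein-Uhlenbeck noise so every analysis stage is testable
    against known ground truth, and a config-driven pipeline that
    reproduces the full per-treatment analysis tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
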