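Package: memlipo
Title: Depth-Dependent Lipophilicity Scoring for Alpha-Helical Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implicit-membrane scoring toolkit for alpha-helical membrane
    proteins built on experimentally derived, depth-dependent amino-acid
    insertion profiles. Raw insertion-energy tables are smoothed, symmetrised
    about the membrane midplane, special-cased for His/Cys and the rarely
    observed polar residues, converted to Rosetta energy units and encoded as
    cubic splines. Per-residue energies combine the lipophilicity spline with
    a neighbour-count burial weight, a paraboloid penalty on deviations from
    ideal alpha-helical backbone dihedrals, and a knowledge-based cubic
    penalty on helix tilt angles derived from observed versus random
    tilt-angle distributions. Also provides the iterative residual-encoding
    loop that calibrates per-position corrections against target profiles,
    and model-ensemble post-processing: energy and structure filters,
    score-wise RMSD clustering, Kabsch superposition, native-contact
    fractions and median ddG classification. A fixtures module generates
    ideal helices at arbitrary tilt, decoy dimer ensembles and synthetic raw
    profiles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
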