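Package: cryomrf
Title: Simultaneous Rigid-Body Fitting of Protein Subunits into Cryo-EM Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits atomic structures of protein subunits simultaneously into a
    cryo-electron microscopy density map of medium to low resolution. Candidate
    placements for each subunit are found by an exhaustive FFT-accelerated
    translational scan over a near-uniform rotation sampling of SO(3), scored by
    density cross-correlation plus contour overlap. Candidate poses and pairwise
    physical interactions (van der Waals, electrostatics, hydrogen and disulfide
    bonds, solvation, steric clashes) are assembled into a pairwise Markov random
    field scored by a log-linear energy; max-sum belief propagation followed by a
    heap-driven best-first search extracts the exact top-K assemblies. Includes
    permutation-aware complex RMSD and the residue-weighted assembly placement
    score for evaluation against a reference, MRC2014 map input/output, map
    simulation from coordinates, and a synthetic toy-complex benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
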