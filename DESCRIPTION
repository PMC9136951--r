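Package: waternet
Title: Grand-Canonical Monte Carlo and Grid-Based Solvation Thermodynamics
    for Protein-Bound Water Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for studying the thermodynamics of ordered
    water networks in buried and solvent-exposed binding sites. Implements a
    rigid-water grand-canonical Monte Carlo (GCMC) sampler with
    Adams-parameter insertion/deletion moves, titration of the mean water
    occupancy over a grid of Adams values and grand-canonical integration to
    network binding free energies, a voxel-resolved grid-based inhomogeneous
    solvation theory (GIST) analysis (solute-water and water-water energies,
    translational and orientational entropies by a nearest-neighbour
    estimator, density maps in OpenDX format), and the hydration-comparison
    statistics used to contrast simulation protocols: exponential
    equilibration fits, average-linkage water-site clustering, Tanimoto
    similarity of cluster sets, crystal-water recovery curves, Kruskal-Wallis
    comparisons of occupancy distributions and paired-site deviation metrics.
    Ships synthetic toy systems with exactly enumerable grand-canonical
    partition functions that serve as oracles for every sampler and
    free-energy routine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
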