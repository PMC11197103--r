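Package: fluorspin
Title: Strongly Coupled 1H/19F NMR Simulation, Spectral Fitting and
    Conformer-Ensemble Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantum-mechanical time-domain simulation of strongly coupled
    1H/19F spin systems in a restricted Liouville state space (correlation-order
    truncation, conservation-law filters, permutation-symmetry adaptation,
    Krylov matrix-exponential propagation), least-squares extraction of
    chemical shifts and scalar J-couplings from second-order NMR spectra by
    simultaneous Nelder-Mead fitting of 1H and 19F spectra, and
    conformer-ensemble thermodynamics for 1,3-difluoroalkane conformational
    analysis: Boltzmann populations with analytic uncertainty propagation,
    ensemble J-averaging, staggered-rotamer enumeration, dihedral-grid
    condensation, percent-antiperiplanar scoring and J-coupling correlation.
    Includes a synthetic-fixture generator (Karplus-governed rotamer ensembles,
    clash-screened dihedral sampling, seeded strongly coupled test systems)
    so that no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    pracma,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'spin-system.R'
    'state-space.R'
    'liouvillian.R'
    'propagate.R'
    'spectrum.R'
    'hilbert.R'
    'linelist-context.R'
    'simulate.R'
    'fitting.R'
    'conformers.R'
    'fixtures.R'
    'io-jcamp.R'
    'workflow.R'
    'RcppExports.R'
    'cli.R'
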