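Package: tcrdegen
Title: Co-Receptor Modulation of T-Cell Receptor Triggering and Degeneracy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Equilibrium and kinetic-proofreading model of T-cell receptor
    (TCR) triggering at the T-cell:antigen-presenting-cell interface,
    with explicit CD8 co-receptor kinetics. Solves the mass-action
    equilibrium for free TCR and CD8 surface densities, computes
    triggering probabilities on a two-lane chain of ITAM phosphorylation
    steps (an absorbing Markov chain with lane switching driven by
    CD8 binding), and derives the scaled functional sensitivity w of a
    ligand. A statistical layer draws ligand ensembles with log-normally
    distributed off-rates from a Gaussian dissociation-energy model and
    computes recognition-degeneracy curves P(w > omega), CD8-density
    operating-band scans, and HLA mutant scenarios with altered
    pMHCI/CD8 binding affinity. Includes independent validation oracles
    (full-chain linear solve, stochastic simulation) and sweep drivers
    with CSV output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
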