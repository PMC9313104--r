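Package: posetriage
Title: Interface Mapping and Inhibitor Triage for Receptor-Ligand Complex Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Contact-profile analysis of receptor-ligand complex ensembles for
    protein-protein interaction interface mapping, with pose filtering against a
    membrane-embedded receptor, cross-conformation interface consensus, ligand
    binding-site fate classification after refinement, and isothermal titration
    calorimetry derived thermodynamic state comparison. Designed around the
    Na,K-ATPase / amyloid-beta interaction-inhibitor workflow: docked or
    MD-refined complexes come in as multi-model PDB files, per-residue contact
    profiles and interface segments come out, and screened compounds are triaged
    by their binding-site fates across receptor conformations. Includes a
    deterministic synthetic-structure generator used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
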