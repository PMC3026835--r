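Package: gnmpath
Title: Ligand-Binding Pathways and Stiff Residue Triads from the Gaussian Network Model
Version: 0.1.0
Authors@R: person("gnmpath", "developers", email = "gnmpath@example.org", role = c("aut", "cre"))
Description: Predicts ligand-binding interaction pathways, hub and gate
    residues, and stiff residue triads (contact-map cliques) from an unbound
    protein structure using the fastest (maximum-eigenvalue) mode of the
    Gaussian Network Model. Builds the Kirchhoff connectivity matrix from a
    C-alpha trace at a distance cutoff, computes per-residue total coupling
    from the fastest mode averaged over a band of cutoff stations, extracts
    the interaction-path residue network, enumerates mutually contacting
    residue triads far apart in sequence, and validates predictions against
    a bound complex via a heavy-atom ligand-contact rule. Includes a minimal
    PDB reader, a synthetic-structure generator for fully offline testing, a
    cutoff-scaling calibration scan, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
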