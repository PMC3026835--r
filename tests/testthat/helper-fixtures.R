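# Hand-built PDB text fixtures exercising format corner cases.

atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                      occ = 1, altloc = " ", record = "ATOM", icode = " ",
                      element = "") {
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resid, chain, resno, icode,
          x, y, z, occ, 0, element)
}

# Three residues on a line; residue 2 has altloc A (occ 0.6) and B (occ 0.4).
fixture_altloc <- function() {
  c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0, occ = 0.6, altloc = "A"),
    atom_line(3, "CA", "ALA", "A", 2, 3.9, 1, 0, occ = 0.4, altloc = "B"),
    atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0),
    "END")
}

# Two chains A (3 residues) and B (2 residues), B's records first.
fixture_two_chains <- function(b_first = TRUE) {
  a <- c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
         atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
         atom_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0))
  b <- c(atom_line(4, "CA", "VAL", "B", 10, 20, 0, 0),
         atom_line(5, "CA", "VAL", "B", 11, 23.8, 0, 0))
  c(if (b_first) c(b, a) else c(a, b), "END")
}

# One HEM group, three waters, one zinc ion.
fixture_hetatms <- function() {
  c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "FE", "HEM", "A", 101, 10, 0, 0, record = "HETATM"),
    atom_line(4, "C1", "HEM", "A", 101, 11, 1, 0, record = "HETATM"),
    atom_line(5, "O", "HOH", "A", 201, 20, 0, 0, record = "HETATM"),
    atom_line(6, "O", "HOH", "A", 202, 21, 0, 0, record = "HETATM"),
    atom_line(7, "O", "HOH", "A", 203, 22, 0, 0, record = "HETATM"),
    atom_line(8, "ZN", "ZN", "A", 301, 30, 0, 0, record = "HETATM"),
    "END")
}

# Two models; model 2 coordinates shifted by 50 A.
fixture_multimodel <- function() {
  c("MODEL     1",
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL     2",
    atom_line(1, "CA", "GLY", "A", 1, 50, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 53.8, 0, 0),
    "ENDMDL",
    "END")
}

# Residue 2 has backbone atoms but no C-alpha.
fixture_missing_ca <- function() {
  c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "N", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "C", "GLY", "A", 2, 4.8, 0, 0),
    atom_line(4, "CA", "GLY", "A", 3, 7.6, 0, 0),
    "END")
}

# Chain at specified C-alpha positions (author numbers given).
chain_from_xyz <- function(xyz, resno = seq_len(nrow(xyz)), chain_id = "A",
                           resid = "ALA") {
  structure(list(pdb_id = "fixture", chain_id = chain_id,
                 resno = as.integer(resno),
                 icode = rep("", nrow(xyz)),
                 resid = rep(resid, length.out = nrow(xyz)),
                 xyz = unname(as.matrix(xyz)), n = nrow(xyz)),
            class = "calpha_chain")
}
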