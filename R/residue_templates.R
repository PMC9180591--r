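# Side-chain templates as internal coordinates (heavy atoms).
#
# Each atom is placed by natural extension from three already-placed atoms:
# list(name, element, refs = c(parent, grand, great), bond A, angle deg,
# dihedral deg). Backbone atoms N, CA, C, O (and CB) are placed by the chain
# builder; templates start beyond CB. Geometry is idealized (standard bond
# lengths/angles, extended chi angles); ring closures are listed as extra
# bonds.

sc_atom <- function(name, element, refs, bond, angle, dihedral) {
  list(name = name, element = element, refs = refs, bond = bond,
       angle = angle, dihedral = dihedral)
}

residue_templates <- local({
  t <- list()
  CB <- c("CB", "CA", "N")

  t$G <- list(atoms = list(), extra_bonds = NULL, has_cb = FALSE)
  t$A <- list(atoms = list(), extra_bonds = NULL, has_cb = TRUE)
  t$V <- list(atoms = list(
    sc_atom("CG1", "C", CB, 1.53, 111, 180),
    sc_atom("CG2", "C", CB, 1.53, 111, -60)), extra_bonds = NULL, has_cb = TRUE)
  t$L <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 114, 180),
    sc_atom("CD1", "C", c("CG", "CB", "CA"), 1.53, 111, 180),
    sc_atom("CD2", "C", c("CG", "CB", "CA"), 1.53, 111, 60)),
    extra_bonds = NULL, has_cb = TRUE)
  t$I <- list(atoms = list(
    sc_atom("CG1", "C", CB, 1.53, 111, 180),
    sc_atom("CG2", "C", CB, 1.53, 111, -60),
    sc_atom("CD1", "C", c("CG1", "CB", "CA"), 1.53, 111, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$M <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 112, 180),
    sc_atom("SD", "S", c("CG", "CB", "CA"), 1.81, 112, 180),
    sc_atom("CE", "C", c("SD", "CG", "CB"), 1.79, 100, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$F <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.51, 114, 180),
    sc_atom("CD1", "C", c("CG", "CB", "CA"), 1.39, 120, 90),
    sc_atom("CD2", "C", c("CG", "CB", "CA"), 1.39, 120, -90),
    sc_atom("CE1", "C", c("CD1", "CG", "CB"), 1.39, 120, 180),
    sc_atom("CE2", "C", c("CD2", "CG", "CB"), 1.39, 120, 180),
    sc_atom("CZ", "C", c("CE1", "CD1", "CG"), 1.39, 120, 0)),
    extra_bonds = list(c("CZ", "CE2")), has_cb = TRUE)
  t$Y <- list(atoms = c(t$F$atoms, list(
    sc_atom("OH", "O", c("CZ", "CE1", "CD1"), 1.36, 120, 180))),
    extra_bonds = list(c("CZ", "CE2")), has_cb = TRUE)
  t$W <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.50, 114, 180),
    sc_atom("CD1", "C", c("CG", "CB", "CA"), 1.37, 127, 90),
    sc_atom("CD2", "C", c("CG", "CB", "CA"), 1.43, 127, -90),
    sc_atom("NE1", "N", c("CD1", "CG", "CD2"), 1.37, 110, 0),
    sc_atom("CE2", "C", c("CD2", "CG", "CD1"), 1.41, 107, 0),
    sc_atom("CE3", "C", c("CD2", "CG", "CD1"), 1.40, 133, 180),
    sc_atom("CZ2", "C", c("CE2", "CD2", "CG"), 1.40, 122, 180),
    sc_atom("CZ3", "C", c("CE3", "CD2", "CE2"), 1.39, 118, 0),
    sc_atom("CH2", "C", c("CZ2", "CE2", "CD2"), 1.37, 117, 180)),
    extra_bonds = list(c("NE1", "CE2"), c("CH2", "CZ3")), has_cb = TRUE)
  t$S <- list(atoms = list(
    sc_atom("OG", "O", CB, 1.42, 111, 180)), extra_bonds = NULL, has_cb = TRUE)
  t$T <- list(atoms = list(
    sc_atom("OG1", "O", CB, 1.42, 111, 180),
    sc_atom("CG2", "C", CB, 1.53, 111, -60)), extra_bonds = NULL, has_cb = TRUE)
  t$C <- list(atoms = list(
    sc_atom("SG", "S", CB, 1.81, 114, 180)), extra_bonds = NULL, has_cb = TRUE)
  t$N <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.52, 113, 180),
    sc_atom("OD1", "O", c("CG", "CB", "CA"), 1.23, 121, 0),
    sc_atom("ND2", "N", c("CG", "CB", "CA"), 1.33, 116, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$Q <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 114, 180),
    sc_atom("CD", "C", c("CG", "CB", "CA"), 1.52, 113, 180),
    sc_atom("OE1", "O", c("CD", "CG", "CB"), 1.23, 121, 0),
    sc_atom("NE2", "N", c("CD", "CG", "CB"), 1.33, 116, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$D <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.52, 113, 180),
    sc_atom("OD1", "O", c("CG", "CB", "CA"), 1.25, 118, 0),
    sc_atom("OD2", "O", c("CG", "CB", "CA"), 1.25, 118, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$E <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 114, 180),
    sc_atom("CD", "C", c("CG", "CB", "CA"), 1.52, 113, 180),
    sc_atom("OE1", "O", c("CD", "CG", "CB"), 1.25, 118, 0),
    sc_atom("OE2", "O", c("CD", "CG", "CB"), 1.25, 118, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$K <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 114, 180),
    sc_atom("CD", "C", c("CG", "CB", "CA"), 1.53, 111, 180),
    sc_atom("CE", "C", c("CD", "CG", "CB"), 1.53, 111, 180),
    sc_atom("NZ", "N", c("CE", "CD", "CG"), 1.47, 111, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$R <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.53, 114, 180),
    sc_atom("CD", "C", c("CG", "CB", "CA"), 1.53, 111, 180),
    sc_atom("NE", "N", c("CD", "CG", "CB"), 1.46, 112, 180),
    sc_atom("CZ", "C", c("NE", "CD", "CG"), 1.33, 124, 180),
    sc_atom("NH1", "N", c("CZ", "NE", "CD"), 1.33, 120, 0),
    sc_atom("NH2", "N", c("CZ", "NE", "CD"), 1.33, 120, 180)),
    extra_bonds = NULL, has_cb = TRUE)
  t$H <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.50, 114, 180),
    sc_atom("ND1", "N", c("CG", "CB", "CA"), 1.38, 122, 90),
    sc_atom("CD2", "C", c("CG", "CB", "CA"), 1.36, 122, -90),
    sc_atom("CE1", "C", c("ND1", "CG", "CD2"), 1.32, 109, 0),
    sc_atom("NE2", "N", c("CD2", "CG", "ND1"), 1.37, 107, 0)),
    extra_bonds = list(c("CE1", "NE2")), has_cb = TRUE)
  t$P <- list(atoms = list(
    sc_atom("CG", "C", CB, 1.50, 104, 30),
    sc_atom("CD", "C", c("CG", "CB", "CA"), 1.50, 106, -35)),
    extra_bonds = list(c("CD", "N")), has_cb = TRUE)
  t
})

# three-letter residue names for PDB records
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
         Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)
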