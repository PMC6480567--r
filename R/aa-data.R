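# Static amino-acid reference tables used across the package.
# Geometry is idealized (bond lengths/angles typical of peptide stereochemistry);
# the scoring function is a surrogate, so sub-0.01 A fidelity is not a goal.

.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
.AA3TO1 <- stats::setNames(names(.AA1TO3), .AA1TO3)

# Number of sidechain chi torsions per residue type.  Proline's ring torsions
# are not counted (the ring is treated as rigid).
.CHI_COUNT <- c(
  ALA = 0L, GLY = 0L, PRO = 0L,
  SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
  LEU = 2L, ILE = 2L, ASP = 2L, ASN = 2L, HIS = 2L, PHE = 2L, TYR = 2L, TRP = 2L,
  MET = 3L, GLU = 3L, GLN = 3L,
  LYS = 4L, ARG = 4L
)

# Sidechain N-terminal exclusion set for fragment boundaries: residues whose
# nucleophilic sidechains would compete with the backbone amine during the
# modeled amide-forming reaction.
.NUCLEOPHILIC_NTERM <- c("TYR", "CYS", "SER", "THR", "ASN", "GLN")

# Sidechain z-matrix rows: atom placed from ref1 (bond), ref2 (angle),
# ref3 (dihedral).  `chi` gives the 1-based chi index driving the dihedral
# (0 = fixed); `off` is the offset (deg) added to that chi (or the fixed value).
# CB is handled separately in the builder.  Chi1 = N-CA-CB-CG by construction
# (CG placed from CB/CA/N).
.zrow <- function(name, ref1, ref2, ref3, r, theta, chi, off) {
  list(name = name, ref1 = ref1, ref2 = ref2, ref3 = ref3,
       r = r, theta = theta, chi = as.integer(chi), off = off)
}

.SIDECHAIN_Z <- list(
  ALA = list(),
  GLY = list(),
  SER = list(.zrow("OG",  "CB", "CA", "N",  1.42, 110.5, 1, 0)),
  CYS = list(.zrow("SG",  "CB", "CA", "N",  1.81, 114.0, 1, 0)),
  THR = list(.zrow("OG1", "CB", "CA", "N",  1.43, 109.5, 1, 0),
             .zrow("CG2", "CB", "CA", "N",  1.52, 110.5, 1, -122)),
  VAL = list(.zrow("CG1", "CB", "CA", "N",  1.52, 110.5, 1, 0),
             .zrow("CG2", "CB", "CA", "N",  1.52, 110.5, 1, 122)),
  LEU = list(.zrow("CG",  "CB", "CA", "N",  1.53, 116.3, 1, 0),
             .zrow("CD1", "CG", "CB", "CA", 1.52, 110.7, 2, 0),
             .zrow("CD2", "CG", "CB", "CA", 1.52, 110.7, 2, 122)),
  ILE = list(.zrow("CG1", "CB", "CA", "N",  1.53, 110.4, 1, 0),
             .zrow("CG2", "CB", "CA", "N",  1.52, 110.5, 1, -122),
             .zrow("CD1", "CG1", "CB", "CA", 1.52, 113.9, 2, 0)),
  MET = list(.zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
             .zrow("SD",  "CG", "CB", "CA", 1.81, 112.7, 2, 0),
             .zrow("CE",  "SD", "CG", "CB", 1.79, 100.9, 3, 0)),
  PRO = list(.zrow("CG",  "CB", "CA", "N",  1.49, 104.5, 0, 30),
             .zrow("CD",  "CG", "CB", "CA", 1.50, 106.1, 0, -35)),
  PHE = list(.zrow("CG",  "CB", "CA", "N",  1.50, 113.8, 1, 0),
             .zrow("CD1", "CG", "CB", "CA", 1.39, 120.8, 2, 0),
             .zrow("CD2", "CG", "CB", "CA", 1.39, 120.8, 2, 180),
             .zrow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 0, 180),
             .zrow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 0, 180),
             .zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0, 0)),
  TYR = list(.zrow("CG",  "CB", "CA", "N",  1.51, 113.9, 1, 0),
             .zrow("CD1", "CG", "CB", "CA", 1.39, 120.8, 2, 0),
             .zrow("CD2", "CG", "CB", "CA", 1.39, 120.8, 2, 180),
             .zrow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 0, 180),
             .zrow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 0, 180),
             .zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0, 0),
             .zrow("OH",  "CZ", "CE1", "CD1", 1.38, 119.9, 0, 180)),
  TRP = list(.zrow("CG",  "CB", "CA", "N",  1.50, 113.6, 1, 0),
             .zrow("CD1", "CG", "CB", "CA", 1.37, 126.9, 2, 0),
             .zrow("CD2", "CG", "CB", "CA", 1.43, 126.7, 2, 180),
             .zrow("NE1", "CD1", "CG", "CB", 1.38, 110.2, 0, 180),
             .zrow("CE2", "CD2", "CG", "CB", 1.41, 107.2, 0, 180),
             .zrow("CE3", "CD2", "CG", "CD1", 1.40, 133.9, 0, 0),
             .zrow("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 0, 180),
             .zrow("CZ3", "CE3", "CD2", "CE2", 1.39, 118.6, 0, 180),
             .zrow("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0, 180)),
  ASP = list(.zrow("CG",  "CB", "CA", "N",  1.52, 112.6, 1, 0),
             .zrow("OD1", "CG", "CB", "CA", 1.25, 118.4, 2, 0),
             .zrow("OD2", "CG", "CB", "CA", 1.25, 118.4, 2, 180)),
  ASN = list(.zrow("CG",  "CB", "CA", "N",  1.52, 112.6, 1, 0),
             .zrow("OD1", "CG", "CB", "CA", 1.23, 120.8, 2, 0),
             .zrow("ND2", "CG", "CB", "CA", 1.33, 116.4, 2, 180)),
  GLU = list(.zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 2, 0),
             .zrow("OE1", "CD", "CG", "CB", 1.25, 118.4, 3, 0),
             .zrow("OE2", "CD", "CG", "CB", 1.25, 118.4, 3, 180)),
  GLN = list(.zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 2, 0),
             .zrow("OE1", "CD", "CG", "CB", 1.23, 120.8, 3, 0),
             .zrow("NE2", "CD", "CG", "CB", 1.33, 116.4, 3, 180)),
  HIS = list(.zrow("CG",  "CB", "CA", "N",  1.49, 113.8, 1, 0),
             .zrow("ND1", "CG", "CB", "CA", 1.38, 122.7, 2, 0),
             .zrow("CD2", "CG", "CB", "CA", 1.35, 131.0, 2, 180),
             .zrow("CE1", "ND1", "CG", "CB", 1.32, 109.2, 0, 180),
             .zrow("NE2", "CD2", "CG", "CB", 1.37, 107.2, 0, 180)),
  LYS = list(.zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, 2, 0),
             .zrow("CE",  "CD", "CG", "CB", 1.52, 111.3, 3, 0),
             .zrow("NZ",  "CE", "CD", "CG", 1.49, 111.9, 4, 0)),
  ARG = list(.zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
             .zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, 2, 0),
             .zrow("NE",  "CD", "CG", "CB", 1.46, 112.0, 3, 0),
             .zrow("CZ",  "NE", "CD", "CG", 1.33, 124.2, 4, 0),
             .zrow("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0, 0),
             .zrow("NH2", "CZ", "NE", "CD", 1.33, 120.0, 0, 180))
)

# Hydrogen-bond capable heavy atoms, by residue type and atom name.
# Backbone N (except PRO) is a donor; backbone O (and OXT) is an acceptor.
.SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  TRP = "NE1", HIS = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)
.SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = "ND1"
)

# Symmetry-equivalent sidechain atom swaps for RMSD: each entry is a list of
# atom-name pairs exchanged together by the residue's internal symmetry.
.SYMMETRY_SWAPS <- list(
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2"))
)

# Sidechain pKa values used by the protonation rules.
.SIDECHAIN_PKA <- c(ASP = 3.9, GLU = 4.1, HIS = 6.0, CYS = 8.3, TYR = 10.1,
                    LYS = 10.5, ARG = 12.5)
.PKA_NTERM <- 9.0
.PKA_CTERM <- 2.0

# Partial charges: backbone defaults plus per-residue sidechain entries.
# Chosen so each neutral group sums to 0 and each charged group to its formal
# charge; magnitude-correct for the surrogate electrostatics, not a force field.
.BACKBONE_PARTIAL <- c(N = -0.45, CA = 0.45, C = 0.45, O = -0.45)
.SIDECHAIN_PARTIAL_NEUTRAL <- list(
  SER = c(CB = 0.40, OG = -0.40),
  THR = c(CB = 0.40, OG1 = -0.40),
  CYS = c(CB = 0.20, SG = -0.20),
  TYR = c(CZ = 0.40, OH = -0.40),
  ASN = c(CG = 0.55, OD1 = -0.45, ND2 = -0.10),
  GLN = c(CD = 0.55, OE1 = -0.45, NE2 = -0.10),
  TRP = c(CD1 = 0.10, NE1 = -0.10),
  HIS = c(CG = 0.10, ND1 = -0.30, CD2 = 0.10, CE1 = 0.30, NE2 = -0.20),
  MET = c(CG = 0.10, SD = -0.20, CE = 0.10)
)
# Charged-state sidechain charges (applied when the protonation rules say so).
.SIDECHAIN_PARTIAL_CHARGED <- list(
  ASP = c(CG = 0.30, OD1 = -0.65, OD2 = -0.65),
  GLU = c(CD = 0.30, OE1 = -0.65, OE2 = -0.65),
  LYS = c(CE = 0.30, NZ = 0.70),
  ARG = c(NE = -0.40, CZ = 0.60, NH1 = 0.40, NH2 = 0.40)
)
# Neutral fallbacks for the titratable residues (high/low pH).
.SIDECHAIN_PARTIAL_NEUTRAL_TITR <- list(
  ASP = c(CG = 0.45, OD1 = -0.45, OD2 = 0.00),
  GLU = c(CD = 0.45, OE1 = -0.45, OE2 = 0.00),
  LYS = c(CE = 0.20, NZ = -0.20),
  ARG = c(NE = -0.20, CZ = 0.40, NH1 = -0.10, NH2 = -0.10)
)

# Covalent radii (A) for distance-based bond perception.
.COVALENT_RADII <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, Cl = 0.99)

.aa_three <- function(seq1) {
  seq1 <- strsplit(toupper(seq1), "")[[1]]
  bad <- setdiff(seq1, names(.AA1TO3))
  if (length(bad) > 0) {
    stop("unsupported residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  unname(.AA1TO3[seq1])
}

.chi_count <- function(resname) {
  out <- .CHI_COUNT[resname]
  if (anyNA(out)) {
    stop("unsupported residue type(s): ",
         paste(unique(resname[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
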