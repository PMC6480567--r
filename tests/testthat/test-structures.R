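# Molecular data model: builder geometry, PDB round-trips, protonation rules
# and rotatable-bond counting.

test_that("peptide builder reproduces requested torsions and ideal bonds", {
  tor <- list(phi = c(NA, -60, -120, 60), psi = c(135, -45, 120, 60),
              chi = list(numeric(0), numeric(0), rep(180, 4), numeric(0)))
  p <- build_peptide("AGKA", tor)
  xyz <- coords(p)
  a <- p$atoms
  idx <- function(r, n) which(a$resid == r & a$name == n)
  dih <- function(i1, i2, i3, i4) irdl:::.dihedral(xyz[i1, ], xyz[i2, ],
                                                   xyz[i3, ], xyz[i4, ])
  expect_equal(dih(idx(1, "C"), idx(2, "N"), idx(2, "CA"), idx(2, "C")),
               -60, tolerance = 1e-8)
  expect_equal(dih(idx(2, "N"), idx(2, "CA"), idx(2, "C"), idx(3, "N")),
               -45, tolerance = 1e-8)
  expect_equal(dih(idx(3, "N"), idx(3, "CA"), idx(3, "CB"), idx(3, "CG")),
               180, tolerance = 1e-6)
  # omega amides trans by construction
  expect_equal(abs(dih(idx(1, "CA"), idx(1, "C"), idx(2, "N"),
                       idx(2, "CA"))), 180, tolerance = 1e-8)
  b <- p$bonds
  d <- sqrt(rowSums((xyz[b$i, ] - xyz[b$j, ])^2))
  expect_lt(max(abs(d - b$r0)), 1e-10)
})

test_that("PDB write/read round-trip preserves names, order and coordinates", {
  p <- build_peptide("ADLKNGSE")   # 8 residues
  path <- tempfile(fileext = ".pdb")
  write_pdb(p, path)
  q <- read_pdb(path, chain_policy = "keep-all", role = "peptide")
  expect_identical(q$atoms$name, p$atoms$name)
  expect_identical(nrow(q$atoms), nrow(p$atoms))
  expect_lt(max(abs(coords(q) - coords(p))), 1e-3 + 1e-12)
  expect_length(unique(q$atoms$resid), 8L)
})

test_that("reader drops waters and applies the first-monomer policy", {
  path <- write_two_chain_pdb(tempfile(fileext = ".pdb"))
  all_chains <- read_pdb(path, chain_policy = "keep-all")
  expect_setequal(unique(all_chains$atoms$chain), c("A", "B"))
  expect_false(any(all_chains$atoms$resname %in% c("HOH", "WAT")))
  mono <- read_pdb(path, chain_policy = "first-monomer")
  expect_identical(unique(mono$atoms$chain), "A")
})

test_that("reader rejects malformed and empty inputs", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   xxx     0.000  1.00  0.00"),
    bad)
  expect_error(read_pdb(bad), "line 2")
  empty <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "ATOM")
  expect_error(write_pdb(list(atoms = NULL), tempfile()), "empty")
})

test_that("protonation at pH 7.4 follows the charge rules", {
  p <- assign_protonation(build_peptide("KDAE"), 7.4)
  a <- p$atoms
  res_formal <- function(r, nm) sum(a$formal[a$resid == r & a$name %in% nm])
  expect_identical(res_formal(1, "NZ"), 1)      # Lys sidechain +1
  expect_identical(res_formal(2, "OD2"), -1)    # Asp sidechain -1
  expect_identical(res_formal(4, "OE2"), -1)    # Glu sidechain -1
  expect_identical(res_formal(1, "N"), 1)       # free N-terminus
  expect_identical(res_formal(4, "OXT"), -1)    # free C-terminus
  expect_identical(formal_charge(assign_protonation(build_peptide("DKDK"))),
                   0)
  expect_error(assign_protonation(build_peptide("AA"), pH = 0))
})

test_that("net formal charge matches the counting rule on random sequences", {
  set.seed(42)
  alphabet <- c("A", "G", "K", "R", "D", "E", "S", "L", "N", "H")
  for (i in 1:20) {
    s <- paste(sample(alphabet, sample(3:8, 1), replace = TRUE),
               collapse = "")
    p <- assign_protonation(build_peptide(s), 7.4)
    n <- table(factor(strsplit(s, "")[[1]], levels = alphabet))
    expected <- unname(n["K"] + n["R"] - n["D"] - n["E"]) + 1 - 1
    expect_identical(formal_charge(p), as.numeric(expected))
  }
})

test_that("rotatable-bond counting follows the stated convention", {
  expect_identical(count_rotatable_bonds("G"), 1L)
  expect_identical(count_rotatable_bonds("AAAAA"), 9L)
  # appending Ala adds exactly phi + psi = 2
  set.seed(7)
  for (s in c("G", "KD", "PLV", "ANSE")) {
    expect_identical(count_rotatable_bonds(paste0(s, "A")),
                     count_rotatable_bonds(s) + 2L)
  }
  expect_error(count_rotatable_bonds("AXZ"), "unsupported")
})

test_that("counting agrees with geometric torsion enumeration", {
  # independent oracle: enumerate rotatable axes on the built molecule's
  # bond graph (ring bonds excluded, amide omegas not in the sampled set)
  for (s in c("G", "AG", "PGA", "KDS", "ALKDV", "NQWY", "APA")) {
    geom <- length(irdl:::.torsion_defs(build_peptide(s)))
    expect_identical(count_rotatable_bonds(s), as.integer(geom))
  }
})
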