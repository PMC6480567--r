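# Shared fixtures, built in code and memoized per test session.

.fixture_env <- new.env(parent = emptyenv())

# A small certified pocket complex, reused across test files.
fixture_pocket <- function() {
  if (is.null(.fixture_env$pocket)) {
    .fixture_env$pocket <- make_pocket_system("ALKDV", n_contacts = 3,
                                              seed = 1)
  }
  .fixture_env$pocket
}

# Small-budget pipeline run on the shared pocket, memoized.
fixture_run_config <- function() {
  syn <- fixture_pocket()
  list(seed = 7, cavity_ref = syn$planted$xyz,
       n_conf = 16, n_conf_seed = 32, n_poses_seed = 8, n_orient_seed = 48,
       n_orient_link = 12, refine_top_link = 3, beam_k = 4)
}

fixture_run <- function() {
  if (is.null(.fixture_env$run)) {
    syn <- fixture_pocket()
    .fixture_env$run <- run_irdl(syn$receptor, syn$sequence,
                                 config = fixture_run_config())
  }
  .fixture_env$run
}

fixture_grid <- function() {
  if (is.null(.fixture_env$grid)) {
    syn <- fixture_pocket()
    .fixture_env$grid <- build_grid(syn$receptor, syn$planted$xyz,
                                    spacing = 0.4, margin = 5)
  }
  .fixture_env$grid
}

# Subset a full reference pose to a residue range (global numbering kept).
reference_segment <- function(reference, resids) {
  irdl:::.reference_subset(reference, resids)
}

# Write a tiny two-chain PDB file (with waters) for reader tests.
write_two_chain_pdb <- function(path) {
  lines <- character(0)
  serial <- 0
  emit <- function(name, resname, chain, resid, x, y, z, el) {
    serial <<- serial + 1
    lines <<- c(lines, sprintf(
      "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, name, resname, chain, resid, x, y, z, el))
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else 20
    for (r in 1:2) {
      base <- (r - 1) * 4
      emit("N", "ALA", ch, r, off + base, 0, 0, "N")
      emit("CA", "ALA", ch, r, off + base + 1.5, 0, 0, "C")
      emit("C", "ALA", ch, r, off + base + 2.2, 1.3, 0, "C")
      emit("O", "ALA", ch, r, off + base + 2.2, 2.5, 0, "O")
      emit("CB", "ALA", ch, r, off + base + 1.5, -1.5, 0, "C")
    }
    lines <- c(lines, "TER")
  }
  serial <- serial + 1
  lines <- c(lines, sprintf(
    "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
    serial, 1, 50.0, 50.0, 50.0))
  writeLines(c(lines, "END"), path)
  path
}
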