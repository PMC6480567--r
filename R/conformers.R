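# Conformer generation: systematic-plus-random torsion sampling over a
# fragment's rotatable bonds, clash filtering, RMSD deduplication and
# strain-ascending ranking.

# phi/psi on a 60-degree grid; the eclipsed 0-degree value is omitted since
# it clashes for essentially every residue pair
.TORSION_GRID_BB <- c(-180, -120, -60, 60, 120)
.TORSION_GRID_CHI <- c(-60, 60, 180)                 # staggered rotamers
.CLASH_MIN_DIST <- 2.0
.DEDUP_RADIUS <- 0.5

# Torsion slots of a sequence in build_peptide() order:
# phi (2..n, non-Pro), psi (1..n-1), carboxyl (= psi[n]), chis.
.torsion_slots <- function(resnames) {
  n <- length(resnames)
  slots <- list()
  for (i in seq_len(n)) {
    if (i >= 2 && resnames[i] != "PRO")
      slots[[length(slots) + 1]] <- list(kind = "phi", res = i)
    if (i <= n - 1)
      slots[[length(slots) + 1]] <- list(kind = "psi", res = i)
  }
  slots[[length(slots) + 1]] <- list(kind = "cterm", res = n)
  for (i in seq_len(n)) {
    for (k in seq_len(.CHI_COUNT[[resnames[i]]]))
      slots[[length(slots) + 1]] <- list(kind = "chi", res = i, chi = k)
  }
  slots
}

.torsions_from_values <- function(resnames, slots, values) {
  n <- length(resnames)
  tor <- list(phi = rep(-120, n), psi = rep(135, n),
              chi = lapply(resnames, function(r) rep(-60, .CHI_COUNT[[r]])))
  for (s in seq_along(slots)) {
    sl <- slots[[s]]
    if (sl$kind == "phi") tor$phi[sl$res] <- values[s]
    if (sl$kind == "psi") tor$psi[sl$res] <- values[s]
    if (sl$kind == "cterm") tor$psi[sl$res] <- values[s]
    if (sl$kind == "chi") tor$chi[[sl$res]][sl$chi] <- values[s]
  }
  tor
}

#' Generate a conformer ensemble for a peptide fragment
#'
#' Torsion space is sampled on a 60-degree backbone grid and staggered
#' sidechain rotamers: when the grid is small enough it is enumerated
#' exhaustively, otherwise it is completed by seeded random draws with
#' torsional jitter.  Conformers with a nonbonded heavy-atom contact below
#' the clash threshold are discarded; survivors are ranked by internal
#' strain and deduplicated at an internal-RMSD radius.
#'
#' @param fragment one-letter sequence string or peptide `irdl_system`
#' @param max_n ensemble cap (default 200)
#' @param seed RNG seed (determinism contract: same seed, same ensemble)
#' @param systematic_budget largest grid size enumerated exhaustively
#' @return an `irdl_conformers` object: shared atom template plus a list of
#'   coordinate matrices sorted by strain
#' @export
enumerate_conformers <- function(fragment, max_n = 200, seed = 1,
                                 systematic_budget = 4000) {
  stopifnot(max_n >= 1)
  sequence <- if (inherits(fragment, "irdl_system"))
    .system_sequence(fragment) else fragment
  resnames <- .aa_three(sequence)
  slots <- .torsion_slots(resnames)
  template <- build_peptide(sequence)
  nb <- .nonbonded_pairs(template)
  bonds <- as.matrix(template$bonds)
  grid_sizes <- vapply(slots, function(sl)
    if (sl$kind == "chi") length(.TORSION_GRID_CHI)
    else length(.TORSION_GRID_BB), numeric(1))
  total <- prod(grid_sizes)

  value_sets <- lapply(slots, function(sl)
    if (sl$kind == "chi") .TORSION_GRID_CHI else .TORSION_GRID_BB)
  cand <- list()
  if (total <= systematic_budget) {
    grid <- do.call(expand.grid, value_sets)
    cand <- lapply(seq_len(nrow(grid)), function(r) as.numeric(grid[r, ]))
  } else {
    cand <- .with_seed(seed, {
      lapply(seq_len(4 * max_n + 100), function(r) {
        v <- vapply(value_sets, function(vs) sample(vs, 1), numeric(1))
        v + stats::runif(length(v), -15, 15)
      })
    })
  }
  xyzs <- vector("list", length(cand))
  strains <- rep(NA_real_, length(cand))
  for (ci in seq_along(cand)) {
    tor <- .torsions_from_values(resnames, slots, cand[[ci]])
    xyz <- coords(build_peptide(sequence, tor))
    if (nrow(nb) > 0 && cpp_min_pair_dist(xyz, nb) < .CLASH_MIN_DIST) next
    xyzs[[ci]] <- xyz
    strains[ci] <- cpp_internal_strain(xyz, bonds, nb)
  }
  ok <- which(!is.na(strains))
  if (length(ok) == 0) stop("no clash-free conformer could be generated")
  ord <- ok[order(strains[ok])]
  kept <- cpp_greedy_dedup(xyzs[ord], .DEDUP_RADIUS, as.integer(max_n))
  sel <- ord[kept]
  structure(list(template = template, sequence = toupper(sequence),
                 coords = xyzs[sel], strain = strains[sel], seed = seed),
            class = "irdl_conformers")
}

#' @export
print.irdl_conformers <- function(x, ...) {
  cat(sprintf("<irdl_conformers: %s, %d conformer(s), strain %.2f..%.2f>\n",
              x$sequence, length(x$coords),
              min(x$strain), max(x$strain)))
  invisible(x)
}

#' Relax a conformer by deterministic coordinate descent on internal strain
#'
#' Greedy per-atom axis moves that never increase the internal energy (bond
#' restraints plus capped nonbonded repulsion), so bonded geometry is held
#' near ideal while clashes are relieved.
#'
#' @param xyz conformer coordinate matrix
#' @param template the fragment `irdl_system` the conformer instantiates
#' @param steps number of descent sweeps (0 returns the input unchanged)
#' @param step_size trial displacement per move (Angstrom)
#' @return relaxed coordinate matrix
#' @export
relax_conformer <- function(xyz, template, steps = 50, step_size = 0.05) {
  stopifnot(steps >= 0)
  if (steps == 0) return(xyz)
  bonds <- as.matrix(template$bonds)
  nb <- .nonbonded_pairs(template)
  e <- cpp_internal_strain(xyz, bonds, nb)
  for (s in seq_len(steps)) {
    improved <- FALSE
    for (at in seq_len(nrow(xyz))) {
      for (ax in 1:3) {
        for (dir in c(-1, 1)) {
          trial <- xyz
          trial[at, ax] <- trial[at, ax] + dir * step_size
          et <- cpp_internal_strain(trial, bonds, nb)
          if (et < e - 1e-12) {
            xyz <- trial; e <- et; improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  xyz
}
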