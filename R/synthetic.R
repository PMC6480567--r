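# Synthetic fixture generator: a rigid pseudo-atom receptor cage built around
# a planted peptide pose with designed hydrogen-bond partners and hydrophobic
# contacts, certified so that the planted pose out-scores random placements.
# Stands in for crystallographic complexes at desk scale; it is not a folded
# protein.

.APOLAR <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "GLY", "TRP")

# Random grid-aligned torsion set for the planted conformation.
.random_planted_torsions <- function(resnames) {
  n <- length(resnames)
  bb <- c(-120, -60, 60, 120, 180)
  list(phi = sample(bb, n, replace = TRUE),
       psi = sample(bb, n, replace = TRUE),
       chi = lapply(resnames, function(r)
         sample(.TORSION_GRID_CHI, .CHI_COUNT[[r]], replace = TRUE)))
}

# Outward direction for a donor/acceptor: opposite the mean of its bonded
# neighbors (donor lone-H direction), or the C=O extension for carbonyls.
.polar_direction <- function(xyz, idx, bonds) {
  nb <- c(bonds$j[bonds$i == idx], bonds$i[bonds$j == idx])
  if (length(nb) == 0) return(c(1, 0, 0))
  v <- -colMeans(xyz[nb, , drop = FALSE] -
                 matrix(xyz[idx, ], length(nb), 3, byrow = TRUE))
  .unit(v)
}

#' Build a synthetic receptor pocket around a planted peptide pose
#'
#' Generates a clash-free grid-aligned peptide conformation, then surrounds
#' it with pseudo-atoms: `n_contacts` hydrogen-bond partners at ideal
#' geometry opposite peptide donors/acceptors, hydrophobic carbons opposite
#' apolar sidechains, and a carbon cage carving the cavity.  The complex is
#' certified at generation time: the planted pose must out-score 95% of
#' 1000 random rigid in-box placements under the surrogate scoring function,
#' and its hydrogen-bond set must equal the designed contacts exactly;
#' otherwise a new sub-seed is tried.
#'
#' @param sequence one-letter peptide sequence (length 4-10)
#' @param n_contacts number of designed hydrogen-bond partners
#' @param seed master seed
#' @param max_retry certification retry budget
#' @return an `irdl_synthetic`: `receptor`, `planted` pose, `design` record
#' @export
make_pocket_system <- function(sequence, n_contacts = 3, seed = 1,
                               max_retry = 60) {
  resnames <- .aa_three(sequence)
  stopifnot(length(resnames) >= 4, length(resnames) <= 10)
  for (attempt in seq_len(max_retry)) {
    sub <- .derive_seed(seed, paste0("pocket", attempt))
    built <- .with_seed(sub, .build_pocket_once(sequence, resnames,
                                                n_contacts))
    if (is.null(built)) next
    if (.certify_pocket(built, n_contacts, sub)) {
      built$seed <- seed
      class(built) <- "irdl_synthetic"
      return(built)
    }
  }
  stop("pocket certification failed after ", max_retry, " attempts")
}

.build_pocket_once <- function(sequence, resnames, n_contacts) {
  # clash-free planted conformation on the sampling grid
  peptide <- NULL
  for (k in 1:80) {
    tor <- .random_planted_torsions(resnames)
    p <- build_peptide(sequence, tor)
    nb <- .nonbonded_pairs(p)
    if (nrow(nb) == 0 || cpp_min_pair_dist(coords(p), nb) >= 2.4) {
      peptide <- assign_protonation(p, 7.4)
      break
    }
  }
  if (is.null(peptide)) return(NULL)
  xyz <- coords(peptide)
  a <- peptide$atoms
  centroid <- colMeans(xyz)

  rec <- list()   # rows: element, x, y, z, kind
  add_rec <- function(el, pos, kind) {
    rec[[length(rec) + 1]] <<- data.frame(
      element = el, x = pos[1], y = pos[2], z = pos[3], kind = kind,
      stringsAsFactors = FALSE)
  }
  # hydrogen-bond partners opposite peptide polar atoms, spread along chain
  don <- which(a$is_donor)
  acc <- which(a$is_acceptor)
  polar <- c(don, acc)
  polar <- polar[order(a$resid[polar], a$name[polar])]
  if (length(polar) < n_contacts) return(NULL)
  # valid partner positions: the target atom must be the only nearby peptide
  # atom, and no other polar peptide atom close enough for an unintended
  # hydrogen bond
  cand_pos <- lapply(polar, function(i) {
    dirv <- .polar_direction(xyz, i, peptide$bonds)
    pos <- xyz[i, ] + 2.9 * dirv
    d_all <- sqrt(rowSums(sweep(xyz, 2, pos)^2))
    if (min(d_all[-i]) < 3.2) return(NULL)
    if (min(d_all[setdiff(polar, i)]) < 3.4) return(NULL)
    pos
  })
  valid <- which(!vapply(cand_pos, is.null, logical(1)))
  if (length(valid) < n_contacts) return(NULL)
  # allocate contacts across the fragmentation plan (C-terminal segment
  # first) so every growth stage has at least one designed hydrogen bond;
  # leftover contacts spread over the remaining valid candidates
  # The C-terminal (seed) segment is docked without a covalent restraint and
  # needs the strongest designed signature: it gets two contacts (preferring
  # backbone atoms near the C-terminus).  One contact goes to the N-terminal
  # segment to guide the final growth step; any remainder spreads over the
  # rest of the chain.
  pick <- integer(0)
  backbone_first <- function(cands, desc = FALSE) {
    nm <- a$name[polar[cands]]
    r <- a$resid[polar[cands]]
    cands[order(!(nm %in% c("N", "O", "OXT")), if (desc) -r else r)]
  }
  # contact 1 anchors the charged C-terminal carboxylate (registry
  # specificity comes from charge complementarity, not just the well),
  # contact 2 the charged N-terminal ammonium, and contact 3 pins the seed
  # segment's N-terminal (future junction) backbone
  plan <- tryCatch(fragment_peptide(sequence), error = function(e) NULL)
  charge_of <- rep(NA_real_, 0)
  n_res <- max(a$resid)
  cand_named <- function(resid, names) {
    v <- valid[a$resid[polar[valid]] == resid &
               a$name[polar[valid]] %in% names]
    setdiff(v, pick)
  }
  cterm <- cand_named(n_res, c("OXT", "O"))
  if (length(cterm) == 0) return(NULL)   # the carboxylate anchor is essential
  pick <- cterm[1]; charge_of <- 1.2
  nterm <- cand_named(1L, "N")
  if (length(nterm) && length(pick) < n_contacts) {
    pick <- c(pick, nterm[1]); charge_of <- c(charge_of, -1.2)
  }
  if (!is.null(plan) && length(pick) < n_contacts) {
    sg1 <- plan$segments[1, ]
    j1 <- backbone_first(setdiff(
      valid[a$resid[polar[valid]] >= sg1$start], pick))
    j1 <- j1[order(a$resid[polar[j1]])]
    if (length(j1)) {
      pick <- c(pick, j1[1]); charge_of <- c(charge_of, NA_real_)
    }
  }
  left <- backbone_first(setdiff(valid, pick))
  while (length(pick) < n_contacts && length(left) > 0) {
    pick <- c(pick, left[1]); charge_of <- c(charge_of, NA_real_)
    left <- left[-1]
  }
  if (length(pick) < n_contacts) return(NULL)
  pick <- pick[seq_len(n_contacts)]
  charge_of <- charge_of[seq_len(n_contacts)]
  design <- list()
  for (k in seq_along(pick)) {
    v <- pick[k]
    i <- polar[v]
    pos <- cand_pos[[v]]
    prev <- if (length(rec)) as.matrix(
      do.call(rbind, rec)[, c("x", "y", "z")]) else NULL
    if (!is.null(prev) && nrow(prev) &&
        min(sqrt(rowSums(sweep(prev, 2, pos)^2))) < 2.8) return(NULL)
    el <- if (i %in% don) "O" else "N"
    add_rec(el, pos, "hbond")
    design[[length(design) + 1]] <- list(
      peptide_atom = paste0(a$resname[i], a$resid[i], ".", a$name[i]),
      partner_element = el, dist = 2.9,
      partner_charge = charge_of[k])
  }
  # hydrophobic contacts opposite apolar sidechain tips
  apolar_idx <- which(a$resname %in% .APOLAR &
                      !a$name %in% c("N", "CA", "C", "O", "OXT"))
  hb_xyz <- as.matrix(do.call(rbind, rec)[, c("x", "y", "z")])
  for (i in apolar_idx) {
    outdir <- .unit(xyz[i, ] - centroid)
    pos <- xyz[i, ] + 4.1 * outdir
    d_all <- sqrt(rowSums(sweep(xyz, 2, pos)^2))
    if (min(d_all) < 3.6) next
    if (min(sqrt(rowSums(sweep(hb_xyz, 2, pos)^2))) < 2.8) next
    add_rec("C", pos, "hydrophobic")
    hb_xyz <- rbind(hb_xyz, pos)
  }
  # cage carbons carving the cavity
  dirs <- rbind(diag(3), -diag(3),
                matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), ncol = 3,
                       byrow = TRUE) / sqrt(3))
  heavy <- which(!a$is_hydrogen)
  rec_now <- function() {
    if (length(rec) == 0) matrix(numeric(0), 0, 3)
    else as.matrix(do.call(rbind, rec)[, c("x", "y", "z")])
  }
  for (i in heavy) {
    for (d in seq_len(nrow(dirs))) {
      pos <- xyz[i, ] + 4.45 * dirs[d, ]
      dmin_pep <- min(sqrt(rowSums(sweep(xyz, 2, pos)^2)))
      if (dmin_pep < 3.55) next
      rn <- rec_now()
      if (nrow(rn) > 0 &&
          min(sqrt(rowSums(sweep(rn, 2, pos)^2))) < 2.3) next
      add_rec("C", pos, "cage")
    }
  }
  rdf <- do.call(rbind, rec)
  atoms <- data.frame(
    name = ifelse(rdf$kind == "hydrophobic", "CH1",
                  paste0(rdf$element, "1")),
    element = rdf$element, resname = "PSD",
    resid = seq_len(nrow(rdf)), chain = "R",
    x = rdf$x, y = rdf$y, z = rdf$z, charge = 0, stringsAsFactors = FALSE)
  receptor <- .new_system(atoms,
                          data.frame(i = integer(0), j = integer(0),
                                     r0 = numeric(0)), "receptor")
  receptor <- assign_protonation(receptor, 7.4)
  # designed partner charges (salt-bridge anchors at the charged termini)
  hb_rows <- which(rdf$kind == "hbond")
  for (k in seq_along(design)) {
    pc <- design[[k]]$partner_charge
    if (!is.na(pc)) receptor$atoms$charge[hb_rows[k]] <- pc
  }
  planted <- .new_pose(peptide, xyz)
  list(receptor = receptor, planted = planted, design = design,
       contact_kinds = rdf$kind, sequence = toupper(sequence))
}

# Certification: exact designed H-bond set, clash-free, and planted pose
# below the 5th percentile of random in-box placements.
.certify_pocket <- function(built, n_contacts, sub_seed) {
  hb <- hbond_set(built$planted, built$receptor)
  if (nrow(hb) != n_contacts) return(FALSE)
  if (cpp_min_dist(built$planted$xyz, coords(built$receptor)) < 2.6) {
    return(FALSE)
  }
  grid <- build_grid(built$receptor, built$planted$xyz, spacing = 0.5,
                     margin = 5)
  planted_score <- score_pose(grid, built$planted)$total
  if (planted_score >= 0) return(FALSE)
  props <- .pose_props(built$planted$template)
  xyz <- built$planted$xyz
  cen <- colMeans(xyz)
  ext <- (grid$dims - 1) * grid$spacing
  rand_scores <- .with_seed(.derive_seed(sub_seed, "cert"), {
    vapply(1:1000, function(i) {
      R <- .random_rotations(1)[[1]]
      t <- grid$origin + stats::runif(3) * ext
      trial <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, -t)
      s <- .grid_sums(grid, trial, props)
      unname(.W_SP["vdw"] * s[1] + .W_SP["hb"] * (s[2] + s[3]) +
             .W_SP["el"] * s[4] + .OUT_PENALTY * s[6])
    }, numeric(1))
  })
  interaction <- planted_score  # strain included; random scores lack strain,
                                # which only makes the test stricter
  mean(rand_scores < interaction) <= 0.05
}

#' @export
print.irdl_synthetic <- function(x, ...) {
  if (!inherits(x, "irdl_synthetic")) class(x) <- "irdl_synthetic"
  cat(sprintf(
    "<irdl_synthetic: peptide %s, %d receptor pseudo-atoms, %d contact(s)>\n",
    x$sequence, nrow(x$receptor$atoms), length(x$design)))
  invisible(x)
}

#' Perturb a pose by a random rigid motion plus torsional jitter
#'
#' The perturbation is scaled so the heavy-atom RMSD from the input is close
#' to `magnitude` (expected within 20% over repeated draws).
#'
#' @param pose an `irdl_pose`
#' @param magnitude target RMSD (Angstrom); 0 returns the pose unchanged
#' @param seed RNG seed
#' @return the perturbed pose
#' @export
perturb_pose <- function(pose, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(pose)
  xyz0 <- pose$xyz
  tors <- .torsion_defs(pose$template)
  out <- .with_seed(seed, {
    xyz <- xyz0
    for (td in tors) {
      xyz <- .rotate_torsion(xyz, td, stats::rnorm(1, 0, 6 * magnitude))
    }
    cen <- colMeans(xyz)
    ax <- stats::rnorm(3)
    xyz <- .rotate_about(xyz, cen, ax, stats::rnorm(1, 0, 4 * magnitude))
    m <- sqrt(mean(rowSums((xyz - xyz0)^2)))
    if (m > magnitude) {
      # pull back toward the original along the displacement
      xyz <- xyz0 + (xyz - xyz0) * (magnitude / m)
      m <- sqrt(mean(rowSums((xyz - xyz0)^2)))
    }
    tlen <- sqrt(max(0, magnitude^2 - m^2))
    tdir <- stats::rnorm(3)
    sweep(xyz, 2, -(tlen * .unit(tdir)))
  })
  pose$xyz <- out
  pose$score <- NA_real_
  pose$terms <- NULL
  pose
}
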