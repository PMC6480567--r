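# One growth step of the protocol: dock the next fragment under a proximity
# restraint to the anchored partial peptide, form the amide bond in silico
# (acid-chloride chemistry: Cl is the leaving group), relax the junction,
# filter on conserved topology, cluster and score covalently.

.RESTRAINT_LO <- 2.5
.RESTRAINT_HI <- 4.0
.AMIDE_LENGTH <- 1.33

#' Convert a fragment's C-terminal carboxylate into an acid chloride
#'
#' The terminal OXT oxygen is replaced by a chlorine (the modeled leaving
#' group) at the acyl-chloride bond length; the heavy-atom count is
#' unchanged and the Cl atom is recorded as the leaving group.
#'
#' @param fragment a peptide `irdl_system` (or `irdl_conformers`) with a free
#'   C-terminal carboxyl
#' @return the modified object (conformer sets are converted in place)
#' @export
prepare_acid_chloride <- function(fragment) {
  if (inherits(fragment, "irdl_conformers")) {
    oxt <- which(fragment$template$atoms$name == "OXT")
    fragment$template <- prepare_acid_chloride(fragment$template)
    ci <- which(fragment$template$atoms$name == "C" &
                fragment$template$atoms$resid ==
                  max(fragment$template$atoms$resid))
    fragment$coords <- lapply(fragment$coords, function(xyz) {
      dirv <- .unit(xyz[oxt, ] - xyz[ci, ])
      xyz[oxt, ] <- xyz[ci, ] + 1.79 * dirv
      xyz
    })
    return(fragment)
  }
  a <- fragment$atoms
  last <- max(a$resid)
  oxt <- which(a$resid == last & a$name == "OXT")
  ci <- which(a$resid == last & a$name == "C")
  if (length(oxt) != 1 || length(ci) != 1) {
    stop("malformed terminus: no free C-terminal carboxyl to convert")
  }
  dirv <- .unit(as.numeric(a[oxt, c("x", "y", "z")]) -
                as.numeric(a[ci, c("x", "y", "z")]))
  a$name[oxt] <- "CL1"
  a$element[oxt] <- "Cl"
  a[oxt, c("x", "y", "z")] <- a[ci, c("x", "y", "z")] + 1.79 * dirv
  a$charge[oxt] <- 0
  fragment$atoms <- a
  fragment$atoms$is_backbone <- fragment$atoms$name %in%
    c("N", "CA", "C", "O")
  fragment$bonds <- .peptide_bonds(fragment)
  fragment$leaving_group <- oxt
  fragment
}

# Junction atom indices for an anchor pose: N (and CA) of its N-terminal
# residue.
.anchor_junction <- function(anchor) {
  a <- anchor$template$atoms
  first <- min(a$resid)
  n <- which(a$resid == first & a$name == "N")
  ca <- which(a$resid == first & a$name == "CA")
  if (length(n) != 1) stop("anchor has no free N-terminal amine")
  c(N = n, CA = ca)
}

# Partner descriptor (for pairwise fragment-anchor energies during
# restrained refinement).
.partner_of <- function(template, xyz, self_template) {
  a <- template$atoms
  sa <- self_template$atoms
  sig <- function(el) {
    s <- .ELEMENT_SIGMA[el]; s[is.na(s)] <- 3.4; unname(s)
  }
  list(xyz = xyz, sig = sig(a$element), charge = a$charge,
       don = a$is_donor, acc = a$is_acceptor,
       sig_self = sig(sa$element), don_self = sa$is_donor,
       acc_self = sa$is_acceptor)
}

#' Form the amide bond between an anchored pose and a placed fragment
#'
#' An ideal trans-planar amide junction is constructed on the anchor's free
#' amine (bond length 1.33 A, sp2 angles, omega 180 degrees), and the
#' fragment is rigidly superposed onto it by its acyl group (C, CA, O); the
#' free rotation of the junction frame about the anchor's N-CA axis is
#' chosen to minimize total fragment displacement.  The chlorine leaving
#' group is removed and the merged pose (anchor atoms first, then fragment
#' atoms) is returned.
#'
#' @param anchor anchored partial-peptide `irdl_pose`
#' @param placed_fragment docked acid-chloride fragment `irdl_pose`
#' @return a linked `irdl_pose` with `junction` and `leaving_group` metadata
#' @export
form_peptide_bond <- function(anchor, placed_fragment) {
  aj <- .anchor_junction(anchor)
  a_atoms <- anchor$template$atoms
  first <- min(a_atoms$resid)
  c_a <- which(a_atoms$resid == first & a_atoms$name == "C")[1]
  fa <- placed_fragment$template$atoms
  last <- max(fa$resid)
  ci <- which(fa$resid == last & fa$name == "C")
  cai <- which(fa$resid == last & fa$name == "CA")
  oi <- which(fa$resid == last & fa$name == "O")
  cli <- which(fa$name == "CL1")
  if (length(cli) != 1) stop("fragment carries no acid-chloride terminus")
  fxyz <- placed_fragment$xyz
  npos <- anchor$xyz[aj["N"], ]
  capos <- anchor$xyz[aj["CA"], ]
  cpos_a <- anchor$xyz[c_a, ]
  d <- sqrt(sum((fxyz[ci, ] - npos)^2))
  # inputs from restrained docking sit in the 2.5-4.0 A window; inputs that
  # already carry near-bonded geometry (re-forming an ideal junction) are
  # accepted down to the bond length itself
  if (d < 1.0 || d > .RESTRAINT_HI + 0.5) {
    stop(sprintf("proximity restraint violated: C..N distance %.2f A", d))
  }
  # ideal junction frame, scanned over the free rotation about N-CA (the
  # anchor residue's phi); pick the frame closest to the docked placement
  src <- fxyz[c(ci, cai, oi), ]
  best <- NULL
  for (th in seq(-180, 165, by = 15)) {
    C_id <- .place_atom(npos, capos, cpos_a, 1.329, 121.7, th)
    CA_id <- .place_atom(C_id, npos, capos, 1.525, 116.2, 180)
    O_id <- .place_atom(C_id, npos, capos, 1.231, 123.0, 0)
    fit <- .kabsch(src, rbind(C_id, CA_id, O_id))
    moved <- fit$apply(fxyz)
    disp <- mean(sqrt(rowSums((moved - fxyz)^2)))
    if (is.null(best) || disp < best$disp - 1e-9) {
      best <- list(disp = disp, xyz = moved)
    }
  }
  fxyz <- best$xyz
  keep <- setdiff(seq_len(nrow(fa)), cli)
  merged_atoms <- rbind(anchor$template$atoms[,
                          c("name", "element", "resname", "resid", "chain",
                            "x", "y", "z", "charge")],
                        fa[keep, c("name", "element", "resname", "resid",
                                   "chain", "x", "y", "z", "charge")])
  xyz <- rbind(anchor$xyz, fxyz[keep, , drop = FALSE])
  merged_atoms$x <- xyz[, 1]; merged_atoms$y <- xyz[, 2]
  merged_atoms$z <- xyz[, 3]
  sys <- .new_system(merged_atoms, NULL, "peptide")
  sys$bonds <- .peptide_bonds(sys)
  sys <- assign_protonation(sys, 7.4)
  pose <- .new_pose(sys, xyz, step_index = anchor$step_index + 1L,
                    parent_id = anchor$id)
  pose$junction <- c(anchor_N = unname(aj["N"]),
                     fragment_C = nrow(anchor$xyz) +
                       match(ci, keep))
  pose
}

# Torsion relaxation of a freshly linked pose with the anchor held fixed:
# torsion moved-sets are flipped to the N-terminal (fragment) side, and only
# torsions whose flipped set stays within the fragment plus the anchor's
# N-terminal residue are eligible.  Greedy, monotone in the combined score.
.relax_linked_fragment <- function(linked, grid, n_anchor_atoms,
                                   moves = c(-20, 20, -10, 10, -5, 5, -2, 2),
                                   sweeps = 3) {
  a <- linked$template$atoms
  anchor_first <- min(a$resid[seq_len(n_anchor_atoms)])
  allowed <- c(which(a$resid == anchor_first)[
                 which(a$resid == anchor_first) <= n_anchor_atoms],
               seq(n_anchor_atoms + 1, nrow(a)))
  defs <- .torsion_defs(linked$template)
  all_idx <- seq_len(nrow(a))
  flipped <- list()
  for (td in defs) {
    mv <- setdiff(all_idx, c(td$moved, td$axis))
    if (length(mv) == 0 || !all(mv %in% allowed)) next
    flipped[[length(flipped) + 1]] <- list(name = td$name,
                                           axis = rev(td$axis), moved = mv)
  }
  if (length(flipped) == 0) return(linked)
  props <- .pose_props(linked$template)
  bonds <- as.matrix(linked$template$bonds)
  nb <- .nonbonded_pairs(linked$template)
  w <- .weights_vec("sp")
  xyz <- linked$xyz
  e <- .pose_energy(grid, xyz, props, bonds, nb, w)
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (td in flipped) {
      for (ang in moves) {
        trial <- .rotate_torsion(xyz, td, ang)
        et <- .pose_energy(grid, trial, props, bonds, nb, w)
        if (et < e - 1e-10) {
          xyz <- trial; e <- et; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  linked$xyz <- xyz
  linked$template$atoms$x <- xyz[, 1]
  linked$template$atoms$y <- xyz[, 2]
  linked$template$atoms$z <- xyz[, 3]
  linked
}

#' Relax the two residues flanking a newly formed peptide bond
#'
#' Deterministic coordinate descent restricted to the atoms of the two
#' junction residues; all other atoms (and the receptor) stay fixed and the
#' combined score never increases.
#'
#' @param linked a linked `irdl_pose` with junction metadata
#' @param grid receptor grid
#' @param steps descent sweeps
#' @param step_size trial displacement (Angstrom)
#' @return the relaxed pose
#' @export
relax_junction <- function(linked, grid, steps = 6, step_size = 0.04) {
  a <- linked$template$atoms
  jn <- linked$junction
  res_pair <- unique(a$resid[jn])
  movable <- which(a$resid %in% res_pair &
                   a$name %in% c("N", "CA", "C", "O"))
  props <- .pose_props(linked$template)
  bonds <- as.matrix(linked$template$bonds)
  nb <- .nonbonded_pairs(linked$template)
  w <- .weights_vec("sp")
  xyz <- linked$xyz
  # preserve local angles: restrain 1-3 distances involving moved atoms
  g <- .system_graph(linked$template)
  gd <- igraph::distances(g, v = movable)
  p13 <- which(gd == 2, arr.ind = TRUE)
  pairs13 <- cbind(movable[p13[, 1]], p13[, 2])
  d13_0 <- sqrt(rowSums((xyz[pairs13[, 1], , drop = FALSE] -
                         xyz[pairs13[, 2], , drop = FALSE])^2))
  energy <- function(z) {
    d13 <- sqrt(rowSums((z[pairs13[, 1], , drop = FALSE] -
                         z[pairs13[, 2], , drop = FALSE])^2))
    djn <- sqrt(sum((z[jn[1], ] - z[jn[2], ])^2))
    .pose_energy(grid, z, props, bonds, nb, w) + 5 * sum((d13 - d13_0)^2) +
      100 * (djn - .AMIDE_LENGTH)^2
  }
  e <- energy(xyz)
  for (s in seq_len(steps)) {
    improved <- FALSE
    for (at in movable) {
      for (ax in 1:3) {
        for (dir in c(-1, 1)) {
          trial <- xyz
          trial[at, ax] <- trial[at, ax] + dir * step_size
          et <- energy(trial)
          if (et < e - 1e-10) {
            xyz <- trial; e <- et; improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  linked$xyz <- xyz
  linked$template$atoms$x <- xyz[, 1]
  linked$template$atoms$y <- xyz[, 2]
  linked$template$atoms$z <- xyz[, 3]
  linked
}

#' Check that a pose's perceived topology matches the expected bond graph
#'
#' Bonds are perceived from interatomic distances (sum of covalent radii
#' times 1.25) and the resulting graph is compared to the expected peptide
#' bond graph by element-colored graph isomorphism.
#'
#' @param linked an `irdl_pose`
#' @param expected bond data.frame (i, j); defaults to the pose template's
#'   own bond table
#' @return TRUE when the topology is conserved
#' @export
check_topology <- function(linked, expected = NULL) {
  a <- linked$template$atoms
  if (is.null(expected)) expected <- linked$template$bonds
  xyz <- linked$xyz
  rcov <- .COVALENT_RADII[a$element]
  rcov[is.na(rcov)] <- 0.77
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rcov, rcov, `+`) * 1.25
  adj <- d < cut & upper.tri(d)
  per <- which(adj, arr.ind = TRUE)
  col <- as.integer(factor(a$element,
                           levels = sort(unique(a$element))))
  g1 <- igraph::graph_from_edgelist(per, directed = FALSE)
  g1 <- igraph::add_vertices(g1, max(0, n - igraph::vcount(g1)))
  g2 <- igraph::graph_from_edgelist(as.matrix(expected[, c("i", "j")]),
                                    directed = FALSE)
  g2 <- igraph::add_vertices(g2, max(0, n - igraph::vcount(g2)))
  if (igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = col, vertex.color2 = col)
}

#' Cluster poses by pairwise RMSD and keep one representative per cluster
#'
#' Average-linkage hierarchical clustering on the plain heavy-atom RMSD
#' matrix, cut into `min(k, n)` clusters; the representative of a cluster is
#' its best-scoring member, and representatives are ranked by covalent score
#' (falling back to pose score).
#'
#' @param poses list of poses sharing one atom layout
#' @param k target number of clusters (protocol default 15)
#' @return list of representative poses, ranked
#' @export
cluster_poses <- function(poses, k = 15) {
  stopifnot(length(poses) > 0)
  if (length(poses) == 1) return(poses)
  scores <- vapply(poses, function(p)
    p$covalent_score %||% p$score %||% NA_real_, numeric(1))
  # collapse exact duplicate geometries up front (best-scoring survives), so
  # the representative count reflects distinct geometries
  ord0 <- order(scores, seq_along(poses))
  uniq <- cpp_greedy_dedup(lapply(poses[ord0], `[[`, "xyz"), 1e-6,
                           length(poses))
  poses <- poses[ord0[uniq]]
  scores <- scores[ord0[uniq]]
  if (length(poses) == 1) return(poses)
  m <- cpp_rmsd_matrix(lapply(poses, `[[`, "xyz"))
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  kk <- min(k, length(poses))
  cl <- stats::cutree(hc, k = kk)
  reps <- integer(0)
  for (c in seq_len(kk)) {
    members <- which(cl == c)
    reps <- c(reps, members[order(scores[members],
                                  members)][1])
  }
  reps <- reps[order(scores[reps], reps)]
  out <- poses[reps]
  for (i in seq_along(out)) out[[i]]$cluster <- unname(cl[reps[i]])
  out
}

#' Covalent score of a linked pose
#'
#' Arithmetic mean of the two noncovalent component scores (anchor and
#' incoming fragment, scored in place) and the linked covalent pose score.
#'
#' @param linked a linked pose with `component_scores` populated (or a
#'   3-vector of component scores)
#' @return the mean score
#' @export
covalent_score <- function(linked) {
  cs <- if (is.numeric(linked)) linked else linked$component_scores
  if (is.null(cs) || length(cs) != 3 || anyNA(cs)) {
    stop("component_scores must hold the anchor, fragment and linked scores")
  }
  mean(cs)
}

#' Covalent-restrained docking of the next fragment onto an anchored pose
#'
#' Fragment placements are sampled so the acyl carbon stays near the
#' anchor's free N-terminal amine (proximity window 2.5-4.0 Angstrom),
#' refined against the scoring function with the restraint active and the
#' anchor contributing pairwise interactions, then linked by
#' [form_peptide_bond()], junction-relaxed, and filtered on topology.
#'
#' @param grid receptor grid
#' @param anchor anchored partial-peptide `irdl_pose`
#' @param fragment acid-chloride `irdl_conformers` (see
#'   [prepare_acid_chloride()])
#' @param seed RNG seed for placement sampling
#' @param n_orient orientations per conformer
#' @param refine_top candidates refined per anchor
#' @return list of linked poses with `component_scores` and
#'   `covalent_score` populated
#' @export
dock_covalent <- function(grid, anchor, fragment, seed = 1, n_orient = 24,
                          refine_top = 8) {
  if (length(fragment$coords) == 0) stop("empty conformer set")
  template <- if (is.null(fragment$template$atoms$formal))
    assign_protonation(fragment$template, 7.4) else fragment$template
  fa <- template$atoms
  last <- max(fa$resid)
  ci <- which(fa$resid == last & fa$name == "C")
  if (!any(fa$name == "CL1")) {
    stop("fragment must carry the acid-chloride terminus")
  }
  aj <- .anchor_junction(anchor)
  npos <- anchor$xyz[aj["N"], ]
  props <- .pose_props(template)
  w <- .weights_vec("sp")
  wvec <- c(w["vdw"], w["hb"], w["el"], w["bur"], .OUT_PENALTY)
  # shell points around the anchor amine
  sampled <- .with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * 14), ncol = 3)
    list(dirs = dirs / sqrt(rowSums(dirs^2)),
         rots = .random_rotations(n_orient))
  })
  shell <- do.call(rbind, lapply(c(2.8, 3.2, 3.6), function(r)
    sweep(r * sampled$dirs, 2, npos, `+`)))
  partner <- .partner_of(anchor$template, anchor$xyz, template)
  anchor_sig <- partner$sig
  cand <- list()
  for (cfi in seq_along(fragment$coords)) {
    xyz <- fragment$coords[[cfi]]
    base <- sweep(xyz, 2, xyz[ci, ])
    strain_e <- w["str"] * fragment$strain[cfi]
    for (ri in seq_along(sampled$rots)) {
      xr <- base %*% t(sampled$rots[[ri]])
      sc <- cpp_score_translations(grid$fields, grid$origin, grid$spacing,
                                   grid$dims, xr, shell, props$donors,
                                   props$acceptors, props$charges, wvec)
      # cheap anchor-clash screen at the best few shell points
      best <- order(sc)[seq_len(min(2, length(sc)))]
      for (b in best) {
        placed <- sweep(xr, 2, -shell[b, ])
        if (cpp_min_dist(placed, anchor$xyz) < 1.8) next
        cand[[length(cand) + 1]] <- list(score = sc[b] + strain_e,
                                         xyz = placed)
      }
    }
  }
  if (length(cand) == 0) {
    stop("no linkable pose: no placement satisfies the proximity restraint")
  }
  cs <- vapply(cand, `[[`, numeric(1), "score")
  keep <- order(cs)[seq_len(min(refine_top, length(cand)))]
  restraint <- list(atom = ci, point = npos, lo = .RESTRAINT_LO,
                    hi = .RESTRAINT_HI, k = 10)
  # torsion moved-sets flipped to the N-terminal side: the restrained acyl
  # end stays anchored while the free end of the fragment explores
  tors <- lapply(.torsion_defs(template), function(td) {
    flip <- setdiff(seq_len(nrow(fa)), c(td$moved, td$axis))
    if (length(flip) == 0) return(NULL)
    list(name = td$name, axis = rev(td$axis), moved = flip)
  })
  tors <- Filter(Negate(is.null), tors)
  anchor_score <- score_in_place(grid, anchor)$total
  out <- list()
  for (k in keep) {
    r <- .refine_pose(grid, template, cand[[k]]$xyz, weights = "sp",
                      restraint = restraint, partner = partner, tors = tors)
    d <- sqrt(sum((r$xyz[ci, ] - npos)^2))
    if (d < .RESTRAINT_LO - 0.5 || d > .RESTRAINT_HI + 0.5) next
    fpose <- .new_pose(template, r$xyz, step_index = anchor$step_index,
                       parent_id = anchor$id)
    frag_score <- score_in_place(grid, fpose)$total
    linked <- form_peptide_bond(anchor, fpose)
    linked <- .relax_linked_fragment(linked, grid, nrow(anchor$xyz))
    linked <- relax_junction(linked, grid)
    if (!check_topology(linked)) next
    linked_score <- score_in_place(grid, linked)$total
    linked$component_scores <- c(anchor = anchor_score,
                                 fragment = frag_score,
                                 linked = linked_score)
    linked$covalent_score <- covalent_score(linked)
    out[[length(out) + 1]] <- linked
  }
  if (length(out) == 0) {
    stop("no linkable pose survived refinement and the topology filter")
  }
  ord <- order(vapply(out, `[[`, numeric(1), "covalent_score"),
               seq_along(out))
  out[ord]
}
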