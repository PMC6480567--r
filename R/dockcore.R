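# Rigid-receptor, flexible-fragment docking: receptor grid construction, the
# surrogate scoring function (soft Lennard-Jones steric term, geometric
# hydrogen-bond wells, screened Coulomb electrostatics, internal strain),
# pose search and the two rescoring modes.

.W_SP <- c(vdw = 1, hb = 2, el = 0.5, bur = 0, str = 0.25)
.W_XP <- c(vdw = 1, hb = 4, el = 0.5, bur = 0.004, str = 0.25)
.OUT_PENALTY <- 50   # per atom outside the grid box

#' Build a receptor grid over the bound-peptide cavity
#'
#' The box is the axis-aligned bounding box of the cavity reference inflated
#' by `margin` on every side.  Five per-gridpoint fields are precomputed from
#' the receptor heavy atoms: a soft Lennard-Jones steric potential,
#' hydrogen-bond affinity wells for peptide donors (around receptor
#' acceptors) and peptide acceptors (around receptor donors), a screened
#' Coulomb potential (distance-dependent dielectric), and a burial count.
#'
#' @param receptor receptor `irdl_system` (protonation is assigned at pH 7.4
#'   when missing)
#' @param cavity_ref reference peptide (`irdl_system`), coordinate matrix, or
#'   list(lo, hi) box corners
#' @param spacing grid spacing in Angstrom
#' @param margin box inflation in Angstrom
#' @return an `irdl_grid`
#' @export
build_grid <- function(receptor, cavity_ref, spacing = 0.4, margin = 5) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(receptor$atoms$formal)) {
    receptor <- assign_protonation(receptor, 7.4)
  }
  if (inherits(cavity_ref, "irdl_system")) cavity_ref <- coords(cavity_ref)
  if (is.list(cavity_ref) && !is.null(cavity_ref$lo)) {
    lo <- cavity_ref$lo; hi <- cavity_ref$hi
  } else {
    if (nrow(cavity_ref) == 0) stop("cavity reference is empty")
    lo <- apply(cavity_ref, 2, min); hi <- apply(cavity_ref, 2, max)
  }
  origin <- lo - margin
  extent <- (hi + margin) - origin
  dims <- as.integer(floor(extent / spacing)) + 1L
  ra <- receptor$atoms[!receptor$atoms$is_hydrogen, ]
  rx <- as.matrix(ra[, c("x", "y", "z")])
  inside <- rx[, 1] >= origin[1] - 8 & rx[, 1] <= origin[1] + extent[1] + 8 &
            rx[, 2] >= origin[2] - 8 & rx[, 2] <= origin[2] + extent[2] + 8 &
            rx[, 3] >= origin[3] - 8 & rx[, 3] <= origin[3] + extent[3] + 8
  if (!any(inside)) warning("grid box excludes all receptor atoms")
  sigma <- .ELEMENT_SIGMA[ra$element]
  sigma[is.na(sigma)] <- 3.4
  # pseudo-atom cages are weak nonspecific attractors; designed polar
  # partners are full-strength
  eps <- rep(0.2, nrow(ra))
  pseudo <- ra$resname == "PSD"
  eps[pseudo & ra$element == "C"] <- 0.07
  eps[pseudo & ra$name == "CH1"] <- 0.3      # designed hydrophobic contacts
  eps[pseudo & ra$element %in% c("N", "O")] <- 0.3
  fields <- cpp_build_fields(rx, unname(sigma), eps, ra$charge,
                             ra$is_donor %||% rep(FALSE, nrow(ra)),
                             ra$is_acceptor %||% rep(FALSE, nrow(ra)),
                             origin, spacing, dims)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 fields = fields,
                 receptor = list(xyz = rx, donor = ra$is_donor,
                                 acceptor = ra$is_acceptor,
                                 charge = ra$charge, element = ra$element,
                                 label = paste0(ra$resname, ra$resid, ".",
                                                ra$name))),
            class = "irdl_grid")
}

#' @export
print.irdl_grid <- function(x, ...) {
  cat(sprintf("<irdl_grid: %d x %d x %d points, spacing %.2f A>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pose container

.new_pose <- function(template, xyz, step_index = 0L, parent_id = NA_integer_) {
  if (is.null(template$atoms$formal)) {
    template <- assign_protonation(template, 7.4)
  }
  structure(list(template = template, xyz = xyz,
                 score = NA_real_, terms = NULL, n_hbond = NA_integer_,
                 step_index = as.integer(step_index),
                 parent_id = parent_id, id = .pose_counter()),
            class = "irdl_pose")
}

#' @export
print.irdl_pose <- function(x, ...) {
  cat(sprintf("<irdl_pose: %d atoms, step %d, score %s>\n", nrow(x$xyz),
              x$step_index,
              if (is.na(x$score)) "unscored" else sprintf("%.3f", x$score)))
  invisible(x)
}

# 0-based donor/acceptor indices and charges of a pose template.
.pose_props <- function(template) {
  a <- template$atoms
  list(donors = as.integer(which(a$is_donor) - 1L),
       acceptors = as.integer(which(a$is_acceptor) - 1L),
       charges = a$charge)
}

# Raw grid interaction sums for coordinates against a grid.
.grid_sums <- function(grid, xyz, props) {
  cpp_grid_sums(grid$fields, grid$origin, grid$spacing, grid$dims, xyz,
                props$donors, props$acceptors, props$charges)
}

.weights_vec <- function(weights) {
  if (is.character(weights)) {
    weights <- switch(match.arg(weights, c("sp", "xp")), sp = .W_SP,
                      xp = .W_XP)
  }
  weights
}

# Full breakdown for a pose.  The energy terms are trilinear grid lookups;
# the hydrogen-bond *count* is recomputed from exact pair geometry.
.score_breakdown <- function(grid, template, xyz, weights = "sp") {
  w <- .weights_vec(weights)
  props <- .pose_props(template)
  s <- .grid_sums(grid, xyz, props)
  strain_raw <- cpp_internal_strain(xyz, as.matrix(template$bonds),
                                    .nonbonded_pairs(template))
  terms <- c(vdw = unname(w["vdw"] * s[1] + .OUT_PENALTY * s[6]),
             hbond = unname(w["hb"] * (s[2] + s[3])),
             elec = unname(w["el"] * s[4]),
             internal_strain = unname(w["str"] * strain_raw),
             burial = unname(-w["bur"] * s[5]))
  hb <- .hbond_pairs_xyz(template, xyz, grid)
  list(total = sum(terms), terms = terms, n_hbond = nrow(hb),
       n_outside = as.integer(s[6]))
}

#' Score a pose against a receptor grid
#'
#' Total = steric + hydrogen-bond + electrostatic + internal-strain terms
#' (each already weighted; lower is better).  Atoms outside the grid box
#' incur a boundary penalty folded into the steric term.
#'
#' @param grid an `irdl_grid`
#' @param pose an `irdl_pose`
#' @param weights `"sp"` (default), `"xp"`, or a named weight vector
#' @return score breakdown: `total`, `terms`, `n_hbond`, `n_outside`
#' @export
score_pose <- function(grid, pose, weights = "sp") {
  .score_breakdown(grid, pose$template, pose$xyz, weights)
}

#' Score a pose in place (no coordinate modification)
#'
#' Identical to [score_pose()]; provided as the protocol's rescoring mode,
#' with the no-movement contract made explicit.
#'
#' @inheritParams score_pose
#' @export
score_in_place <- function(grid, pose, weights = "sp") {
  xyz0 <- pose$xyz
  out <- .score_breakdown(grid, pose$template, pose$xyz, weights)
  stopifnot(identical(xyz0, pose$xyz))
  out
}

#' Rescore a pose with the XP-surrogate weight set
#'
#' Same functional form as [score_pose()] with doubled hydrogen-bond weight
#' and an added burial bonus; used only for final ranking.
#'
#' @inheritParams score_pose
#' @export
rescore_xp <- function(grid, pose) {
  .score_breakdown(grid, pose$template, pose$xyz, weights = "xp")
}

# ---------------------------------------------------------------------------
# Search

.random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

.rotate_about <- function(xyz, center, axis, angle_deg) {
  th <- angle_deg * pi / 180
  ax <- .unit(axis)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, `+`)
}

# Interaction + strain (+ restraint, + pairwise energy vs an anchored
# partner) for refinement.
.pose_energy <- function(grid, xyz, props, bonds, nb, w, restraint = NULL,
                         partner = NULL) {
  s <- .grid_sums(grid, xyz, props)
  e <- w["vdw"] * s[1] + w["hb"] * (s[2] + s[3]) + w["el"] * s[4] -
       w["bur"] * s[5] + .OUT_PENALTY * s[6] +
       w["str"] * cpp_internal_strain(xyz, bonds, nb)
  if (!is.null(partner)) {
    ie <- cpp_inter_energy(xyz, partner$sig_self, props$charges,
                           partner$don_self, partner$acc_self,
                           partner$xyz, partner$sig, partner$charge,
                           partner$don, partner$acc)
    e <- e + w["vdw"] * ie[1] + w["hb"] * ie[2] + w["el"] * ie[3]
  }
  if (!is.null(restraint)) {
    rl <- if (!is.null(restraint$atom)) list(restraint) else restraint
    for (rs in rl) {
      d <- sqrt(sum((xyz[rs$atom, ] - rs$point)^2))
      if (d < rs$lo) e <- e + rs$k * (rs$lo - d)^2
      if (d > rs$hi) e <- e + rs$k * (d - rs$hi)^2
    }
  }
  unname(e)
}

# Distance-geometry matched placements: pairs of pose polar atoms are
# aligned onto pairs of receptor polar-site target points (the point 2.9 A
# from the site toward the cavity), subject to polarity and pair-distance
# compatibility; a few rotations about the pair axis complete the placement.
# Deterministic, and generates exactly the placements that satisfy two
# designed hydrogen bonds at once.
# Candidate partner positions for every receptor polar site: low-energy,
# mutually separated grid nodes on the 2.6-3.2 A shell around the site.
# The well is spherically symmetric, so the direction is ambiguous; a small
# set of well-separated candidates covers the feasible directions.
.site_targets <- function(grid, n_per_site = 8, min_sep = 1.4) {
  rec <- grid$receptor
  pol_site <- which((rec$donor | rec$acceptor) %in% TRUE)
  if (length(pol_site) == 0) {
    return(list(sites = integer(0), targets = list(), acc = logical(0)))
  }
  sp <- grid$spacing
  r_out <- ceiling(3.2 / sp)
  off <- expand.grid(i = -r_out:r_out, j = -r_out:r_out, k = -r_out:r_out)
  dr <- sqrt(rowSums(off^2)) * sp
  off <- off[dr >= 2.6 & dr <= 3.2, ]
  dims <- grid$dims
  targets <- vector("list", length(pol_site))
  for (t in seq_along(pol_site)) {
    s <- pol_site[t]
    base <- round((rec$xyz[s, ] - grid$origin) / sp)
    ii <- base[1] + off$i; jj <- base[2] + off$j; kk <- base[3] + off$k
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < dims[1] & jj < dims[2] &
          kk < dims[3]
    if (!any(ok)) next
    idx <- 1 + ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok])
    well <- if (rec$acceptor[s]) grid$fields$donor[idx]
            else grid$fields$acceptor[idx]
    e <- grid$fields$steric[idx] + 2 * well
    pts <- sweep(cbind(ii[ok], jj[ok], kk[ok]) * sp, 2, grid$origin, `+`)
    ord <- order(e)
    sel <- integer(0)
    for (cand in ord) {
      if (length(sel) >= n_per_site) break
      if (e[cand] > min(e) + 3) break
      if (length(sel) == 0 ||
          min(sqrt(rowSums(sweep(pts[sel, , drop = FALSE], 2,
                                 pts[cand, ])^2))) >= min_sep) {
        sel <- c(sel, cand)
      }
    }
    targets[[t]] <- pts[sel, , drop = FALSE]
  }
  keep <- vapply(targets, function(x) !is.null(x) && nrow(x) > 0,
                 logical(1))
  list(sites = pol_site[keep], targets = targets[keep],
       acc = rec$acceptor[pol_site[keep]])
}

# Cyclic-coordinate-descent closure: rotate the torsions lying between a
# pinned atom and a mobile atom so the mobile atom lands on its target,
# leaving the pinned atom untouched.
.ccd_close <- function(xyz, defs, pin, mobile, target, sweeps = 3,
                       tol = 0.2) {
  usable <- list()
  n <- nrow(xyz)
  for (td in defs) {
    in_moved <- c(pin, mobile) %in% td$moved
    if (in_moved[2] && !in_moved[1]) {
      usable[[length(usable) + 1]] <- td
    } else if (in_moved[1] && !in_moved[2]) {
      flip <- setdiff(seq_len(n), c(td$moved, td$axis))
      if (length(flip)) {
        usable[[length(usable) + 1]] <- list(axis = rev(td$axis),
                                             moved = flip)
      }
    }
  }
  if (length(usable) == 0) return(xyz)
  for (s in seq_len(sweeps)) {
    for (td in usable) {
      o <- xyz[td$axis[2], ]
      u <- .unit(xyz[td$axis[2], ] - xyz[td$axis[1], ])
      q <- xyz[mobile, ]
      r <- (q - o) - sum((q - o) * u) * u
      sv <- (target - o) - sum((target - o) * u) * u
      if (sum(r * r) < 1e-8 || sum(sv * sv) < 1e-8) next
      th <- atan2(sum(.cross(r, sv) * u), sum(r * sv)) * 180 / pi
      xyz <- .rotate_torsion(xyz, td, th)
    }
    if (sqrt(sum((xyz[mobile, ] - target)^2)) < tol) break
  }
  xyz
}

.match_candidates <- function(grid, xyz, template, props, wvec,
                              axis_angles = c(0, 120, 240),
                              dist_tol = 0.8, site_info = NULL,
                              max_out = 400, tors = NULL, nb = NULL,
                              ccd_tol = 0.8) {
  if (is.null(site_info)) site_info <- .site_targets(grid)
  pol_site <- site_info$sites
  if (length(pol_site) < 2) return(list())
  site_is_acc <- site_info$acc
  a <- template$atoms
  pep_don <- which(a$is_donor); pep_acc <- which(a$is_acceptor)
  compatible <- function(s) if (site_is_acc[s]) pep_don else pep_acc
  out <- list()
  ns <- length(pol_site)
  for (s1 in seq_len(ns)) {
    for (s2 in seq_len(ns)) {
      if (s1 == s2) next
      t1s <- site_info$targets[[s1]]
      t2s <- site_info$targets[[s2]]
      for (p in compatible(s1)) {
        for (q in compatible(s2)) {
          if (p == q) next
          v1 <- xyz[q, ] - xyz[p, ]
          d_p <- sqrt(sum(v1^2))
          if (d_p < 1e-6) next
          u1 <- v1 / d_p
          for (i1 in seq_len(nrow(t1s))) {
            for (i2 in seq_len(nrow(t2s))) {
              t1 <- t1s[i1, ]; t2 <- t2s[i2, ]
              v2 <- t2 - t1
              d_t <- sqrt(sum(v2^2))
              gap <- abs(d_p - d_t)
              if (gap > ccd_tol || d_t < 1e-6) next
              moved <- sweep(xyz, 2, xyz[p, ] - t1)
              u2 <- v2 / d_t
              ax <- .cross(u1, u2)
              sn <- sqrt(sum(ax^2))
              if (sn > 1e-8) {
                ang <- atan2(sn, sum(u1 * u2)) * 180 / pi
                moved <- .rotate_about(moved, t1, ax, ang)
              }
              if (gap > dist_tol) {
                # close the residual gap through the intervening torsions
                if (is.null(tors)) next
                moved <- .ccd_close(moved, tors, p, q, t2)
                if (sqrt(sum((moved[q, ] - t2)^2)) > dist_tol) next
                if (!is.null(nb) && nrow(nb) > 0 &&
                    cpp_min_pair_dist(moved, nb) < 1.9) next
              }
              for (th in axis_angles) {
                cand <- if (th == 0) moved
                        else .rotate_about(moved, t1, u2, th)
                out[[length(out) + 1]] <-
                  list(xyz = cand,
                       pins = list(list(atom = p, point = t1, lo = 0,
                                        hi = 0.35, k = 5),
                                   list(atom = q, point = t2, lo = 0,
                                        hi = 0.35, k = 5)))
                if (length(out) >= max_out) return(out)
              }
            }
          }
        }
      }
    }
  }
  out
}

# Greedy coordinate-descent refinement: rigid-body translations/rotations
# plus multi-scale torsion moves, never accepting a worse score.
.refine_pose <- function(grid, template, xyz, weights = "sp",
                         restraint = NULL, partner = NULL, sweeps = 5,
                         torsion_moves = c(-120, 120, -60, 60, -30, 30,
                                           -10, 10),
                         trans_steps = c(0.4, 0.15),
                         rot_steps = c(45, 15, 5),
                         tors = NULL) {
  w <- .weights_vec(weights)
  props <- .pose_props(template)
  bonds <- as.matrix(template$bonds)
  nb <- .nonbonded_pairs(template)
  if (is.null(tors)) tors <- .torsion_defs(template)
  e <- .pose_energy(grid, xyz, props, bonds, nb, w, restraint, partner)
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    try_move <- function(trial) {
      et <- .pose_energy(grid, trial, props, bonds, nb, w, restraint,
                         partner)
      if (et < e - 1e-10) {
        xyz <<- trial; e <<- et; improved <<- TRUE
      }
    }
    for (step in trans_steps) {
      for (ax in 1:3) {
        for (dir in c(-1, 1)) {
          trial <- xyz; trial[, ax] <- trial[, ax] + dir * step
          try_move(trial)
        }
      }
    }
    cen <- colMeans(xyz)
    for (ang in rot_steps) {
      for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        for (dir in c(-1, 1)) {
          try_move(.rotate_about(xyz, cen, ax, dir * ang))
        }
      }
    }
    for (td in tors) {
      for (ang in torsion_moves) {
        try_move(.rotate_torsion(xyz, td, ang))
      }
    }
    if (!improved) break
  }
  list(xyz = xyz, energy = e)
}

#' Dock a fragment conformer ensemble into a receptor grid
#'
#' Rigid-body placements are sampled over grid translations and seeded
#' uniform orientations for every conformer, the best candidates are locally
#' refined (rigid-body plus torsion coordinate descent against the scoring
#' function), and the refined poses are deduplicated and ranked.
#'
#' @param grid an `irdl_grid`
#' @param conformers an `irdl_conformers` ensemble
#' @param n_poses number of poses to return
#' @param seed RNG seed controlling orientation sampling
#' @param n_orient rigid orientations per conformer
#' @param trans_stride translation stride over the box (Angstrom)
#' @param refine_top number of coarse candidates refined
#' @param dedup_radius pose-RMSD deduplication radius (Angstrom)
#' @return list of `irdl_pose`, best score first
#' @export
dock_fragment <- function(grid, conformers, n_poses = 20, seed = 1,
                          n_orient = 64, trans_stride = 1.5,
                          refine_top = 20, dedup_radius = 1.5,
                          n_conf_orient = 32) {
  if (length(conformers$coords) == 0) stop("empty conformer set")
  template <- if (is.null(conformers$template$atoms$formal))
    assign_protonation(conformers$template, 7.4) else conformers$template
  props <- .pose_props(template)
  w <- .weights_vec("sp")
  ext <- (grid$dims - 1) * grid$spacing
  gseq <- function(k) {
    lo <- grid$origin[k] + 2; hi <- grid$origin[k] + ext[k] - 2
    if (hi <= lo) return(grid$origin[k] + ext[k] / 2)
    seq(lo, hi, by = trans_stride)
  }
  trans <- as.matrix(expand.grid(x = gseq(1), y = gseq(2), z = gseq(3)))
  rots <- .with_seed(seed, .random_rotations(n_orient))
  wvec <- c(w["vdw"], w["hb"], w["el"], w["bur"], .OUT_PENALTY)
  # polar-site matching: receptor donor/acceptor positions paired with the
  # pose's polar atoms generate targeted placements on top of the uniform
  # translation grid
  rec <- grid$receptor
  sites <- rec$xyz[(rec$donor | rec$acceptor) %in% TRUE, , drop = FALSE]
  pol <- which(template$atoms$is_donor | template$atoms$is_acceptor)
  offs <- 2.9 * rbind(diag(3), -diag(3))
  cand <- list()
  # uniform-orientation translation scan over the lowest-strain conformers
  # (the distance-geometry matcher below covers the full ensemble)
  for (ci in seq_len(min(n_conf_orient, length(conformers$coords)))) {
    xyz <- conformers$coords[[ci]]
    cen <- colMeans(xyz)
    base <- sweep(xyz, 2, cen)
    strain_e <- w["str"] * conformers$strain[ci]
    for (ri in seq_along(rots)) {
      xr <- base %*% t(rots[[ri]])
      mt <- NULL
      if (nrow(sites) > 0 && length(pol) > 0) {
        ns <- nrow(sites); np <- length(pol)
        D <- sites[rep(seq_len(ns), each = np), , drop = FALSE] -
             xr[pol, , drop = FALSE][rep(seq_len(np), ns), , drop = FALSE]
        mt <- D[rep(seq_len(ns * np), each = nrow(offs)), , drop = FALSE] +
              offs[rep(seq_len(nrow(offs)), ns * np), , drop = FALSE]
      }
      tr <- rbind(trans, mt)
      sc <- cpp_score_translations(grid$fields, grid$origin, grid$spacing,
                                   grid$dims, xr, tr, props$donors,
                                   props$acceptors, props$charges, wvec)
      b <- which.min(sc)
      cand[[length(cand) + 1]] <- list(score = sc[b] + strain_e, conf = ci,
                                       rot = ri, t = tr[b, ])
    }
  }
  # distance-geometry matched placements per conformer, scored directly
  zero_t <- matrix(0, 1, 3)
  site_info <- .site_targets(grid)
  tors <- .torsion_defs(template)
  nb_pairs <- .nonbonded_pairs(template)
  matched <- list()
  for (ci in seq_along(conformers$coords)) {
    strain_e <- w["str"] * conformers$strain[ci]
    mc <- .match_candidates(grid, conformers$coords[[ci]], template, props,
                           wvec, site_info = site_info, tors = tors,
                           nb = nb_pairs)
    for (m in mc) {
      sc <- cpp_score_translations(grid$fields, grid$origin, grid$spacing,
                                   grid$dims, m$xyz, zero_t, props$donors,
                                   props$acceptors, props$charges, wvec)
      matched[[length(matched) + 1]] <- list(score = sc[1] + strain_e,
                                             xyz = m$xyz, pins = m$pins,
                                             conf = ci)
    }
  }
  cs <- vapply(cand, `[[`, numeric(1), "score")
  confs <- vapply(cand, `[[`, numeric(1), "conf")
  # refine the globally best candidates (random-orientation search and
  # matched placements) plus the best placement of each of the most
  # promising conformers
  keep <- order(cs)[seq_len(min(refine_top, length(cand)))]
  per_conf <- vapply(unique(confs), function(ci) {
    w <- which(confs == ci)
    w[which.min(cs[w])]
  }, numeric(1))
  per_conf <- per_conf[order(cs[per_conf])]
  per_conf <- per_conf[seq_len(min(16, length(per_conf)))]
  keep <- unique(c(keep, per_conf))
  start_of <- function(cd) {
    xyz <- conformers$coords[[cd$conf]]
    cen <- colMeans(xyz)
    sweep(sweep(xyz, 2, cen) %*% t(rots[[cd$rot]]), 2, -cd$t)
  }
  starts <- lapply(cand[keep], start_of)
  if (length(matched)) {
    ms <- vapply(matched, `[[`, numeric(1), "score")
    mconf <- vapply(matched, `[[`, numeric(1), "conf")
    # best matched placement of each promising conformer, plus the globally
    # best matches
    mper <- vapply(unique(mconf), function(ci) {
      w <- which(mconf == ci)
      w[which.min(ms[w])]
    }, numeric(1))
    mper <- mper[order(ms[mper])]
    mper <- mper[seq_len(min(16, length(mper)))]
    mkeep <- unique(c(order(ms)[seq_len(min(12, length(matched)))], mper))
    starts <- c(starts, lapply(matched[mkeep], function(m)
      list(xyz = m$xyz, pins = m$pins)))
  }
  refined <- list()
  for (start in starts) {
    if (is.list(start) && !is.null(start$pins)) {
      # matched placement: settle with the designed contacts pinned, then
      # release and refine freely
      r0 <- .refine_pose(grid, template, start$xyz, weights = "sp",
                         restraint = start$pins, sweeps = 3, tors = tors)
      r <- .refine_pose(grid, template, r0$xyz, weights = "sp",
                        tors = tors)
    } else {
      xyz0 <- if (is.list(start)) start$xyz else start
      r <- .refine_pose(grid, template, xyz0, weights = "sp", tors = tors)
    }
    refined[[length(refined) + 1]] <- r
  }
  es <- vapply(refined, `[[`, numeric(1), "energy")
  ord <- order(es, seq_along(es))
  if (min(es) >= .OUT_PENALTY) {
    stop("no valid pose: every candidate scores at or above the boundary ",
         "penalty floor")
  }
  kept <- cpp_greedy_dedup(lapply(refined[ord], `[[`, "xyz"), dedup_radius,
                           as.integer(n_poses))
  out <- list()
  for (k in kept) {
    # fine polish of the surviving representatives
    r <- .refine_pose(grid, template, refined[[ord[k]]]$xyz, weights = "sp",
                      sweeps = 4,
                      torsion_moves = c(-30, 30, -10, 10, -5, 5, -2, 2),
                      trans_steps = c(0.2, 0.08, 0.03),
                      rot_steps = c(8, 3, 1), tors = tors)
    p <- .new_pose(template, r$xyz, step_index = 1L)
    br <- .score_breakdown(grid, template, p$xyz, "sp")
    p$score <- br$total; p$terms <- br$terms; p$n_hbond <- br$n_hbond
    out[[length(out) + 1]] <- p
  }
  ord2 <- order(vapply(out, `[[`, numeric(1), "score"), seq_along(out))
  out[ord2]
}
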