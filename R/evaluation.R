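# Pose-quality metrics: heavy-atom RMSD in the fixed receptor frame (no
# superposition), rank-of-first-correct analysis, and hydrogen-bond
# conservation against a reference pose.

.HB_DIST_MAX <- 3.5
.HB_ANGLE_MIN <- 120

.atoms_xyz <- function(x) {
  if (inherits(x, "irdl_pose")) {
    list(atoms = x$template$atoms, xyz = x$xyz, bonds = x$template$bonds)
  } else if (inherits(x, "irdl_system")) {
    list(atoms = x$atoms, xyz = coords(x), bonds = x$bonds)
  } else {
    stop("expected an irdl_pose or irdl_system")
  }
}

#' Heavy-atom RMSD between a pose and a reference
#'
#' Computed in the shared receptor frame without superposition, over heavy
#' atoms matched by residue index and atom name.  Backbone selection is
#' {N, CA, C, O}.  Symmetry-equivalent sidechain atoms (Phe/Tyr ring,
#' Asp OD1/OD2, Glu OE1/OE2, Arg NH1/NH2) are matched so as to minimize the
#' RMSD.
#'
#' @param pose an `irdl_pose` or peptide `irdl_system`
#' @param reference the reference pose (same residue sequence)
#' @param selection `"backbone"` or `"whole"`
#' @return RMSD in Angstrom
#' @export
rmsd <- function(pose, reference, selection = c("backbone", "whole")) {
  selection <- match.arg(selection)
  p <- .atoms_xyz(pose); r <- .atoms_xyz(reference)
  pk <- !p$atoms$is_hydrogen; rk <- !r$atoms$is_hydrogen
  if (selection == "backbone") {
    pk <- pk & p$atoms$name %in% c("N", "CA", "C", "O")
    rk <- rk & r$atoms$name %in% c("N", "CA", "C", "O")
  }
  pa <- p$atoms[pk, ]; px <- p$xyz[pk, , drop = FALSE]
  ra <- r$atoms[rk, ]; rx <- r$xyz[rk, , drop = FALSE]
  pkey <- paste(pa$resid, pa$name); rkey <- paste(ra$resid, ra$name)
  un <- c(setdiff(pkey, rkey), setdiff(rkey, pkey))
  if (length(un)) stop("atom sets do not match; unmatched: ",
                       paste(un, collapse = ", "))
  map <- match(rkey, pkey)
  d2 <- rowSums((rx - px[map, , drop = FALSE])^2)
  total <- 0
  for (res in unique(ra$resid)) {
    sel <- which(ra$resid == res)
    rn <- ra$resname[sel[1]]
    ss_base <- sum(d2[sel])
    swaps <- .SYMMETRY_SWAPS[[rn]]
    if (selection == "whole" && !is.null(swaps) &&
        all(unlist(swaps) %in% ra$name[sel])) {
      nm <- ra$name[sel]
      alt <- nm
      for (pr in swaps) {
        alt[nm == pr[1]] <- pr[2]; alt[nm == pr[2]] <- pr[1]
      }
      amap <- match(paste(res, alt), pkey)
      ss_alt <- sum(rowSums((rx[sel, , drop = FALSE] -
                             px[amap, , drop = FALSE])^2))
      total <- total + min(ss_base, ss_alt)
    } else {
      total <- total + ss_base
    }
  }
  sqrt(total / nrow(ra))
}

#' Rank of the first correct pose in a ranked list
#'
#' A pose is backbone-correct when its backbone heavy-atom RMSD to the
#' reference is below `bb_threshold` (2 Angstrom by convention) and
#' whole-peptide-correct below `wp_threshold` (3 Angstrom).
#'
#' @param poses ranked list of poses (best first)
#' @param reference reference pose
#' @param bb_threshold backbone RMSD threshold (Angstrom)
#' @param wp_threshold whole-peptide RMSD threshold (Angstrom)
#' @return list with `rank_bb` and `rank_wp` (1-based; `NA` when no pose
#'   qualifies) and the per-pose RMSD vectors
#' @export
rank_first_correct <- function(poses, reference, bb_threshold = 2,
                               wp_threshold = 3) {
  stopifnot(length(poses) > 0)
  bb <- vapply(poses, rmsd, numeric(1), reference = reference,
               selection = "backbone")
  wp <- vapply(poses, rmsd, numeric(1), reference = reference,
               selection = "whole")
  first <- function(v, thr) {
    w <- which(v < thr)
    if (length(w)) w[1] else NA_integer_
  }
  list(rank_bb = first(bb, bb_threshold), rank_wp = first(wp, wp_threshold),
       rmsd_bb = bb, rmsd_wp = wp)
}

# Shared hydrogen-bond pair detection.  Donor-angle criterion: some heavy
# neighbor X of the donor D must give angle(X, D, A) >= 120 degrees; donors
# without heavy neighbors (pseudo-atoms) pass unconditionally.
.hb_detect <- function(da, dx, dbonds, aa, ax) {
  if (length(da$idx) == 0 || length(aa$idx) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      dist = numeric(0)))
  }
  out <- list()
  for (i in seq_along(da$idx)) {
    dpos <- dx[i, ]
    nb <- da$neighbors[[i]]
    for (j in seq_along(aa$idx)) {
      d <- sqrt(sum((dpos - ax[j, ])^2))
      if (d > .HB_DIST_MAX || d < 2.0) next
      ok <- TRUE
      if (length(nb) > 0) {
        angs <- vapply(seq_len(nrow(nb)), function(k)
          .angle(nb[k, ], dpos, ax[j, ]), numeric(1))
        ok <- any(angs >= .HB_ANGLE_MIN)
      }
      if (ok) {
        out[[length(out) + 1]] <- data.frame(
          donor = da$label[i], acceptor = aa$label[j], dist = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      dist = numeric(0)))
  }
  do.call(rbind, out)
}

.polar_side <- function(atoms, xyz, bonds, which = c("donor", "acceptor")) {
  which <- match.arg(which)
  flag <- if (which == "donor") atoms$is_donor else atoms$is_acceptor
  if (is.null(flag)) flag <- rep(FALSE, nrow(atoms))
  idx <- which(flag & !atoms$is_hydrogen)
  label <- paste0(atoms$resname[idx], atoms$resid[idx], ".", atoms$name[idx])
  neighbors <- lapply(idx, function(i) {
    if (is.null(bonds) || nrow(bonds) == 0) {
      return(matrix(numeric(0), 0, 3))
    }
    nb <- c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
    xyz[nb, , drop = FALSE]
  })
  list(idx = idx, label = label, neighbors = neighbors)
}

#' Peptide-receptor hydrogen-bond set
#'
#' Pairs with heavy-atom donor-acceptor distance at most 3.5 Angstrom and a
#' donor angle of at least 120 degrees (measured at the donor against any of
#' its bonded heavy atoms; pseudo-atom donors without neighbors pass), in
#' both directions (peptide donor to receptor acceptor and vice versa).
#'
#' @param peptide_pose an `irdl_pose` or peptide `irdl_system` with
#'   protonation assigned
#' @param receptor receptor `irdl_system` with protonation assigned
#' @return data.frame of pairs: `peptide`, `receptor`, `dist`
#' @export
hbond_set <- function(peptide_pose, receptor) {
  p <- .atoms_xyz(peptide_pose)
  r <- .atoms_xyz(receptor)
  if (is.null(p$atoms$is_donor) || is.null(r$atoms$is_donor)) {
    stop("assign_protonation() must be run on both systems first")
  }
  pd <- .polar_side(p$atoms, p$xyz, p$bonds, "donor")
  pa <- .polar_side(p$atoms, p$xyz, p$bonds, "acceptor")
  rd <- .polar_side(r$atoms, r$xyz, r$bonds, "donor")
  racc <- .polar_side(r$atoms, r$xyz, r$bonds, "acceptor")
  a <- .hb_detect(list(idx = pd$idx, label = pd$label,
                       neighbors = pd$neighbors),
                  p$xyz[pd$idx, , drop = FALSE], p$bonds,
                  list(idx = racc$idx, label = racc$label),
                  r$xyz[racc$idx, , drop = FALSE])
  b <- .hb_detect(list(idx = rd$idx, label = rd$label,
                       neighbors = rd$neighbors),
                  r$xyz[rd$idx, , drop = FALSE], r$bonds,
                  list(idx = pa$idx, label = pa$label),
                  p$xyz[pa$idx, , drop = FALSE])
  out <- rbind(
    if (nrow(a)) data.frame(peptide = a$donor, receptor = a$acceptor,
                            dist = a$dist, stringsAsFactors = FALSE),
    if (nrow(b)) data.frame(peptide = b$acceptor, receptor = b$donor,
                            dist = b$dist, stringsAsFactors = FALSE))
  if (is.null(out)) out <- data.frame(peptide = character(0),
                                      receptor = character(0),
                                      dist = numeric(0))
  out
}

# Internal: hydrogen-bond pairs of a pose against the receptor stored in a
# grid (used for the scored-H-bond count in score breakdowns).
.hbond_pairs_xyz <- function(template, xyz, grid) {
  rec <- grid$receptor
  ratoms <- data.frame(resname = "REC", resid = seq_len(nrow(rec$xyz)),
                       name = sub("^.*\\.", "", rec$label),
                       is_donor = rec$donor, is_acceptor = rec$acceptor,
                       is_hydrogen = FALSE, stringsAsFactors = FALSE)
  ratoms$resname <- sub("\\..*$", "", rec$label)
  rsys <- list(atoms = ratoms, xyz = rec$xyz,
               bonds = data.frame(i = integer(0), j = integer(0)))
  psys <- list(atoms = template$atoms, xyz = xyz, bonds = template$bonds)
  pd <- .polar_side(psys$atoms, psys$xyz, psys$bonds, "donor")
  pa <- .polar_side(psys$atoms, psys$xyz, psys$bonds, "acceptor")
  rd <- .polar_side(rsys$atoms, rsys$xyz, rsys$bonds, "donor")
  racc <- .polar_side(rsys$atoms, rsys$xyz, rsys$bonds, "acceptor")
  a <- .hb_detect(pd, psys$xyz[pd$idx, , drop = FALSE], psys$bonds,
                  racc, rsys$xyz[racc$idx, , drop = FALSE])
  b <- .hb_detect(rd, rsys$xyz[rd$idx, , drop = FALSE], rsys$bonds,
                  pa, psys$xyz[pa$idx, , drop = FALSE])
  rbind(a, b)
}

#' Hydrogen-bond conservation ratio
#'
#' Fraction of the reference pose's peptide-receptor hydrogen bonds (as
#' atom-pair identities) also present in the evaluated pose; defined as 1
#' when the reference has no hydrogen bonds.
#'
#' @param pose evaluated pose
#' @param reference reference pose
#' @param receptor shared receptor `irdl_system`
#' @return fraction in \[0, 1\]
#' @export
hbond_conservation_ratio <- function(pose, reference, receptor) {
  ref <- hbond_set(reference, receptor)
  if (nrow(ref) == 0) return(1)
  got <- hbond_set(pose, receptor)
  ref_keys <- paste(ref$peptide, ref$receptor)
  got_keys <- paste(got$peptide, got$receptor)
  length(intersect(ref_keys, got_keys)) / length(unique(ref_keys))
}

#' Evaluation report for a ranked pose list
#'
#' @param poses ranked pose list (best first)
#' @param reference reference pose
#' @param receptor receptor system (for the hydrogen-bond ratio; optional)
#' @param bb_threshold backbone correctness threshold (Angstrom)
#' @param wp_threshold whole-peptide correctness threshold (Angstrom)
#' @return list of class `irdl_report`: per-pose table, ranks, and the
#'   hydrogen-bond conservation ratio of the best whole-peptide pose
#' @export
evaluation_report <- function(poses, reference, receptor = NULL,
                              bb_threshold = 2, wp_threshold = 3) {
  rk <- rank_first_correct(poses, reference, bb_threshold, wp_threshold)
  tab <- data.frame(rank = seq_along(poses),
                    score = vapply(poses, function(p) {
                      s <- if (inherits(p, "irdl_pose")) p$score else NULL
                      if (is.null(s)) NA_real_ else s
                    }, numeric(1)),
                    rmsd_bb = rk$rmsd_bb, rmsd_wp = rk$rmsd_wp)
  ratio <- NA_real_
  if (!is.null(receptor)) {
    best <- which.min(rk$rmsd_wp)
    ratio <- hbond_conservation_ratio(poses[[best]], reference, receptor)
  }
  structure(list(table = tab, rank_bb = rk$rank_bb, rank_wp = rk$rank_wp,
                 hbond_ratio = ratio),
            class = "irdl_report")
}

#' @export
print.irdl_report <- function(x, ...) {
  cat(sprintf("<irdl_report: rank_bb=%s rank_wp=%s hbond_ratio=%s>\n",
              x$rank_bb, x$rank_wp,
              ifelse(is.na(x$hbond_ratio), "NA",
                     sprintf("%.2f", x$hbond_ratio))))
  print(utils::head(x$table, 10))
  invisible(x)
}
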