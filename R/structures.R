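# Molecular data model: atoms/residues/systems, an internal-coordinate peptide
# builder, PDB I/O (via bio3d), protonation-state assignment, bond graphs and
# rotatable-bond counting.

#' @useDynLib irdl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.unit <- function(v) v / sqrt(sum(v * v))

# Dihedral angle (deg) for points p1-p2-p3-p4, IUPAC sign convention.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.angle <- function(p1, p2, p3) {
  v1 <- .unit(p1 - p2); v2 <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# NeRF atom placement: new atom X bonded to a at distance r, angle X-a-b =
# theta (deg), dihedral X-a-b-c = chi (deg).
.place_atom <- function(a, b, c, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  u <- .unit(b - a)
  w0 <- (c - b) - sum((c - b) * u) * u
  w0 <- .unit(w0)
  v <- .cross(u, w0)
  a + r * (cos(theta) * u + sin(theta) * (cos(chi) * w0 + sin(chi) * v))
}

.ELEMENT_SIGMA <- c(C = 3.4, N = 2.9, O = 2.9, S = 3.6, Cl = 3.5)

# Rigid superposition (Kabsch): rotation R and translation t with
# R %*% t(P) mapping P onto Q in the least-squares sense.
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, cp = cp, cq = cq,
       apply = function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, `+`))
}

.element_from_name <- function(name) {
  core <- gsub("[0-9']", "", name)
  ifelse(substr(core, 1, 2) == "CL", "Cl",
    ifelse(substr(core, 1, 1) %in% c("C", "N", "O", "S", "H"),
           substr(core, 1, 1), substr(core, 1, 1)))
}

.new_system <- function(atoms, bonds, role) {
  stopifnot(all(c("name", "element", "resname", "resid", "chain",
                  "x", "y", "z", "charge") %in% names(atoms)))
  atoms$is_backbone <- atoms$name %in% c("N", "CA", "C", "O")
  atoms$is_hydrogen <- atoms$element == "H"
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, role = role),
            class = "irdl_system")
}

#' Extract heavy-atom coordinates of a molecular system
#'
#' @param system an `irdl_system`
#' @return numeric matrix with one row per atom (columns x, y, z)
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value replacement coordinate matrix
#' @export
`coords<-` <- function(system, value) {
  stopifnot(nrow(value) == nrow(system$atoms), ncol(value) == 3)
  system$atoms$x <- value[, 1]
  system$atoms$y <- value[, 2]
  system$atoms$z <- value[, 3]
  system
}

#' @export
print.irdl_system <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$resid)))
  cat(sprintf("<irdl_system role=%s: %d atoms, %d residues, %d chain(s)>\n",
              x$role, nrow(x$atoms), nres, length(unique(x$atoms$chain))))
  invisible(x)
}

# Sequence (one-letter) of a peptide system, ordered by residue index.
.system_sequence <- function(system) {
  a <- system$atoms[!system$atoms$is_hydrogen, ]
  res <- a[!duplicated(a$resid), c("resid", "resname")]
  res <- res[order(res$resid), ]
  out <- .AA3TO1[res$resname]
  if (anyNA(out)) stop("unsupported residue type(s): ",
                       paste(res$resname[is.na(out)], collapse = ", "))
  paste(out, collapse = "")
}

# ---------------------------------------------------------------------------
# Peptide builder

# Default torsion set: extended chain, staggered chi1.
.default_torsions <- function(resnames) {
  n <- length(resnames)
  list(phi = rep(-120, n), psi = rep(135, n),
       chi = lapply(resnames, function(r) rep(-60, .CHI_COUNT[[r]])))
}

#' Build a peptide in 3-D from sequence and torsion angles
#'
#' Constructs all heavy atoms of a linear peptide with idealized bond lengths
#' and angles, driven by backbone phi/psi and sidechain chi torsions
#' (omega amides fixed trans).  The C-terminus carries a carboxylate with OXT;
#' `psi[n]` doubles as the C-terminal carboxyl rotation.
#'
#' @param sequence one-letter amino-acid string
#' @param torsions list with `phi`, `psi` (numeric, degrees, length n) and
#'   `chi` (list of per-residue chi vectors); defaults to an extended chain
#' @param chain chain identifier
#' @return an `irdl_system` with role `"peptide"`
#' @export
build_peptide <- function(sequence, torsions = NULL, chain = "P") {
  resnames <- .aa_three(sequence)
  n <- length(resnames)
  if (is.null(torsions)) torsions <- .default_torsions(resnames)
  phi <- torsions$phi; psi <- torsions$psi; chis <- torsions$chi
  phi[resnames == "PRO"] <- -70
  pos <- list()   # named "resid.atom"
  rows <- list()
  add <- function(resid, resname, name, xyz) {
    pos[[paste0(resid, ".", name)]] <<- xyz
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, element = .element_from_name(name), resname = resname,
      resid = resid, chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
      charge = 0, stringsAsFactors = FALSE)
  }
  get <- function(resid, name) pos[[paste0(resid, ".", name)]]

  for (i in seq_len(n)) {
    rn <- resnames[i]
    if (i == 1) {
      add(i, rn, "N", c(0, 0, 0))
      add(i, rn, "CA", c(1.458, 0, 0))
      a <- 111.2 * pi / 180
      add(i, rn, "C", c(1.458 - 1.525 * cos(a), 1.525 * sin(a), 0))
    } else {
      # N from psi(i-1); CA via trans omega; C via phi(i)
      add(i, rn, "N", .place_atom(get(i - 1, "C"), get(i - 1, "CA"),
                                  get(i - 1, "N"), 1.329, 116.2, psi[i - 1]))
      add(i, rn, "CA", .place_atom(get(i, "N"), get(i - 1, "C"),
                                   get(i - 1, "CA"), 1.458, 121.7, 180))
      add(i, rn, "C", .place_atom(get(i, "CA"), get(i, "N"),
                                  get(i - 1, "C"), 1.525, 111.2, phi[i]))
    }
    # carbonyl O: dihedral O-C-CA-N = psi - 180
    add(i, rn, "O", .place_atom(get(i, "C"), get(i, "CA"), get(i, "N"),
                                1.231, 120.8, psi[i] - 180))
    if (rn != "GLY") {
      add(i, rn, "CB", .place_atom(get(i, "CA"), get(i, "N"), get(i, "C"),
                                   1.53, 110.5, -122.5))
    }
    chi_i <- if (length(chis) >= i) chis[[i]] else numeric(0)
    for (zr in .SIDECHAIN_Z[[rn]]) {
      dih <- if (zr$chi > 0) chi_i[zr$chi] + zr$off else zr$off
      if (is.na(dih)) dih <- zr$off - 60
      add(i, rn, zr$name, .place_atom(get(i, zr$ref1), get(i, zr$ref2),
                                      get(i, zr$ref3), zr$r, zr$theta, dih))
    }
    if (i == n) {
      add(i, rn, "OXT", .place_atom(get(i, "C"), get(i, "CA"), get(i, "N"),
                                    1.25, 117.0, psi[i]))
    }
  }
  atoms <- do.call(rbind, rows)
  sys <- .new_system(atoms, NULL, "peptide")
  sys$bonds <- .peptide_bonds(sys)
  sys
}

# Ideal bond table for a standard peptide system (data.frame i, j, r0).
.peptide_bonds <- function(system) {
  a <- system$atoms
  idx <- function(resid, name) {
    w <- which(a$resid == resid & a$name == name)
    if (length(w) == 0) NA_integer_ else w[1]
  }
  res <- unique(a$resid)
  out <- list()
  bd <- function(i, j, r0) {
    if (!is.na(i) && !is.na(j)) out[[length(out) + 1]] <<- c(i, j, r0)
  }
  for (r in res) {
    rn <- a$resname[a$resid == r][1]
    bd(idx(r, "N"), idx(r, "CA"), 1.458)
    bd(idx(r, "CA"), idx(r, "C"), 1.525)
    bd(idx(r, "C"), idx(r, "O"), 1.231)
    bd(idx(r, "CA"), idx(r, "CB"), 1.53)
    for (zr in .SIDECHAIN_Z[[rn]]) bd(idx(r, zr$name), idx(r, zr$ref1), zr$r)
    # ring closures
    if (rn == "PRO") bd(idx(r, "N"), idx(r, "CD"), 1.47)
    if (rn %in% c("PHE", "TYR")) bd(idx(r, "CE2"), idx(r, "CZ"), 1.39)
    if (rn == "HIS") bd(idx(r, "CE1"), idx(r, "NE2"), 1.32)
    if (rn == "TRP") {
      bd(idx(r, "NE1"), idx(r, "CE2"), 1.37)
      bd(idx(r, "CZ3"), idx(r, "CH2"), 1.40)
    }
    bd(idx(r, "C"), idx(r, "OXT"), 1.25)
    bd(idx(r, "C"), idx(r, "CL1"), 1.79)
    nxt <- r + 1
    if (nxt %in% res) bd(idx(r, "C"), idx(nxt, "N"), 1.329)
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r0 = m[, 3])
}

# igraph over atoms from the bond table.
.system_graph <- function(system) {
  igraph::graph_from_edgelist(as.matrix(system$bonds[, c("i", "j")]),
                              directed = FALSE) |>
    igraph::add_vertices(max(0, nrow(system$atoms) -
                               max(system$bonds$i, system$bonds$j)))
}

# Nonbonded atom pairs with graph distance >= 3 (1-4 and beyond).
.nonbonded_pairs <- function(system) {
  g <- .system_graph(system)
  d <- igraph::distances(g)
  w <- which(upper.tri(d) & d >= 3, arr.ind = TRUE)
  matrix(as.integer(w), ncol = 2)
}

# ---------------------------------------------------------------------------
# Torsion bookkeeping

# All sampled torsions of a peptide system: backbone phi/psi, chi angles and
# the C-terminal carboxyl rotation.  Each entry: name, axis (two atom
# indices), moved (indices rotated when the torsion turns).
.torsion_defs <- function(system) {
  a <- system$atoms
  g <- .system_graph(system)
  res <- sort(unique(a$resid))
  n <- length(res)
  idx <- function(r, nm) {
    w <- which(a$resid == r & a$name == nm)
    if (length(w)) w[1] else NA_integer_
  }
  moved_set <- function(i, j) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)$membership
    if (comp[i] == comp[j]) return(NULL)   # bond in a ring: not rotatable
    which(comp == comp[j])
  }
  defs <- list()
  push <- function(name, i, j) {
    if (is.na(i) || is.na(j)) return()
    mv <- moved_set(i, j)
    if (is.null(mv) || length(mv) <= 1) return()
    defs[[length(defs) + 1]] <<- list(name = name, axis = c(i, j),
                                      moved = setdiff(mv, j))
  }
  for (k in seq_along(res)) {
    r <- res[k]
    rn <- a$resname[a$resid == r][1]
    if (k > 1 && rn != "PRO") push(paste0("phi", k), idx(r, "N"), idx(r, "CA"))
    if (k < n) push(paste0("psi", k), idx(r, "CA"), idx(r, "C"))
    nchi <- .CHI_COUNT[[rn]]
    if (nchi >= 1) push(paste0("chi1.", k), idx(r, "CA"), idx(r, "CB"))
    if (nchi >= 2) {
      zl <- .SIDECHAIN_Z[[rn]]
      for (ci in 2:nchi) {
        zr <- Filter(function(z) z$chi == ci, zl)[[1]]
        push(paste0("chi", ci, ".", k), idx(r, zr$ref2), idx(r, zr$ref1))
      }
    }
  }
  # C-terminal carboxyl (or acid-chloride) rotation
  rlast <- res[n]
  push(paste0("cterm", n), idx(rlast, "CA"), idx(rlast, "C"))
  defs
}

# Rotate a torsion in place: angle in degrees about axis a->b applied to the
# moved set.
.rotate_torsion <- function(xyz, def, angle) {
  p1 <- xyz[def$axis[1], ]; p2 <- xyz[def$axis[2], ]
  ax <- .unit(p2 - p1)
  th <- angle * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  mv <- def$moved
  xyz[mv, ] <- sweep(sweep(xyz[mv, , drop = FALSE], 2, p2) %*% t(R), 2, p2,
                     `+`)
  xyz
}

# ---------------------------------------------------------------------------
# Rotatable-bond counting

#' Count rotatable bonds of a peptide
#'
#' Convention: backbone phi (residues 2..n, proline excluded), psi (residues
#' 1..n-1), all sidechain chi angles, plus one C-terminal carboxyl rotation;
#' omega amide torsions are excluded.
#'
#' @param peptide one-letter sequence string or a peptide `irdl_system`
#' @return integer count
#' @export
count_rotatable_bonds <- function(peptide) {
  if (inherits(peptide, "irdl_system")) peptide <- .system_sequence(peptide)
  resnames <- .aa_three(peptide)
  n <- length(resnames)
  n_phi <- if (n >= 2) sum(resnames[2:n] != "PRO") else 0L
  n_psi <- n - 1L
  n_chi <- sum(.chi_count(resnames))
  as.integer(n_phi + n_psi + n_chi + 1L)
}

# ---------------------------------------------------------------------------
# PDB I/O

#' Read a molecular system from a PDB file
#'
#' Waters and non-peptide HETATM records are dropped; hydrogens are discarded
#' (all geometry in this package is heavy-atom based).  Under the
#' `"first-monomer"` policy only the first protein chain is retained,
#' mirroring selection of monomer A from multi-subunit crystals.
#'
#' @param path PDB file path
#' @param chain_policy `"first-monomer"` (default) or `"keep-all"`
#' @param role `"receptor"` or `"peptide"`
#' @return an `irdl_system`
#' @export
read_pdb <- function(path, chain_policy = c("first-monomer", "keep-all"),
                     role = "receptor") {
  chain_policy <- match.arg(chain_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  for (ln in rec) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz)) stop("malformed coordinate record at line ", ln)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  # keep standard residues and pseudo-residue cages (PSD); drop other HETATM
  keep <- at$resid %in% c(names(.AA3TO1), "PSD")
  at <- at[keep, ]
  if (nrow(at) == 0) stop("no protein chain found in ", path)
  at$elem <- ifelse(!is.na(at$elesy) & at$elesy != "", at$elesy,
                    .element_from_name(at$elety))
  at <- at[at$elem != "H", ]
  if (chain_policy == "first-monomer") {
    prot_chains <- unique(at$chain[at$resid %in% names(.AA3TO1)])
    if (length(prot_chains) == 0) prot_chains <- unique(at$chain)[1]
    at <- at[at$chain == prot_chains[1], ]
  }
  atoms <- data.frame(
    name = at$elety, element = at$elem, resname = at$resid,
    resid = as.integer(at$resno), chain = at$chain,
    x = at$x, y = at$y, z = at$z, charge = 0, stringsAsFactors = FALSE)
  sys <- .new_system(atoms, NULL, role)
  if (all(atoms$resname %in% names(.AA3TO1))) {
    sys$bonds <- .peptide_bonds(sys)
  } else {
    sys$bonds <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  }
  sys
}

#' Write a molecular system to a PDB file
#'
#' @param system an `irdl_system` (non-empty)
#' @param path output file path
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  if (is.null(a) || nrow(a) == 0) stop("cannot write an empty system")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resid, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = a$chain,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Protonation

#' Assign protonation states and partial charges
#'
#' Rule-based titration against fixed sidechain pKa values: at physiological
#' pH (7.4) Asp/Glu are deprotonated (-1), Lys/Arg protonated (+1), His
#' neutral, free N-terminus +1 and free C-terminus -1.  Partial charges come
#' from a fixed internal per-atom table; hydrogen-bond donor/acceptor flags
#' are set at the same time.
#'
#' @param system an `irdl_system` of standard residues
#' @param pH solution pH in (0, 14)
#' @return the system with `charge`, `formal`, `is_donor`, `is_acceptor`
#'   columns populated
#' @export
assign_protonation <- function(system, pH = 7.4) {
  stopifnot(pH > 0, pH < 14)
  a <- system$atoms
  bad <- setdiff(unique(a$resname), c(names(.AA3TO1), "PSD"))
  if (length(bad)) stop("unsupported residue type(s): ",
                        paste(bad, collapse = ", "))
  a$charge <- 0; a$formal <- 0
  a$is_donor <- FALSE; a$is_acceptor <- FALSE
  set <- function(sel, col, vals) a[sel, col] <<- vals
  for (ch in unique(a$chain)) {
    rs <- sort(unique(a$resid[a$chain == ch]))
    for (r in rs) {
      sel <- which(a$chain == ch & a$resid == r)
      rn <- a$resname[sel[1]]
      if (rn == "PSD") next
      nm <- a$name[sel]
      # backbone partials
      for (bn in names(.BACKBONE_PARTIAL))
        set(sel[nm == bn], "charge", .BACKBONE_PARTIAL[[bn]])
      # sidechain partials
      charged <- FALSE
      if (rn %in% names(.SIDECHAIN_PKA)) {
        pka <- .SIDECHAIN_PKA[[rn]]
        if (rn %in% c("ASP", "GLU")) charged <- pH > pka
        if (rn %in% c("LYS", "ARG")) charged <- pH < pka
        # His/Cys/Tyr stay neutral unless far from 7.4
        if (rn == "HIS") charged <- pH < pka
      }
      tab <- NULL
      if (charged && rn %in% names(.SIDECHAIN_PARTIAL_CHARGED)) {
        tab <- .SIDECHAIN_PARTIAL_CHARGED[[rn]]
      } else if (rn %in% names(.SIDECHAIN_PARTIAL_NEUTRAL_TITR) ||
                 rn == "HIS") {
        tab <- if (rn == "HIS") .SIDECHAIN_PARTIAL_NEUTRAL[[rn]]
               else .SIDECHAIN_PARTIAL_NEUTRAL_TITR[[rn]]
      } else if (rn %in% names(.SIDECHAIN_PARTIAL_NEUTRAL)) {
        tab <- .SIDECHAIN_PARTIAL_NEUTRAL[[rn]]
      }
      if (!is.null(tab)) {
        for (bn in names(tab)) set(sel[nm == bn], "charge", tab[[bn]])
      }
      if (charged) {
        fc <- if (rn %in% c("ASP", "GLU")) -1 else 1
        anchor <- switch(rn, ASP = "OD2", GLU = "OE2", LYS = "NZ",
                         ARG = "CZ", HIS = "ND1")
        set(sel[nm == anchor], "formal", fc)
      }
      # donors / acceptors
      if (rn != "PRO") set(sel[nm == "N"], "is_donor", TRUE)
      set(sel[nm %in% c("O", "OXT")], "is_acceptor", TRUE)
      dn <- .SIDECHAIN_DONORS[[rn]]
      if (!is.null(dn)) set(sel[nm %in% dn], "is_donor", TRUE)
      ac <- .SIDECHAIN_ACCEPTORS[[rn]]
      if (!is.null(ac)) set(sel[nm %in% ac], "is_acceptor", TRUE)
      # termini (peptide role only; receptors keep neutral chain ends)
      if (system$role == "peptide") {
        if (r == rs[1] && pH < .PKA_NTERM) {
          set(sel[nm == "N"], "charge", a$charge[sel[nm == "N"]] + 1)
          set(sel[nm == "N"], "formal", 1)
        }
        if (r == rs[length(rs)] && "OXT" %in% nm && pH > .PKA_CTERM) {
          set(sel[nm == "O"], "charge", -0.725)
          set(sel[nm == "OXT"], "charge", -0.725)
          set(sel[nm == "OXT"], "formal", -1)
        }
      }
    }
    # pseudo-receptor atoms: polarity by element
    psel <- which(a$chain == ch & a$resname == "PSD")
    if (length(psel)) {
      set(psel[a$element[psel] == "O"], "is_acceptor", TRUE)
      set(psel[a$element[psel] == "O"], "charge", -0.6)
      set(psel[a$element[psel] == "N"], "is_donor", TRUE)
      set(psel[a$element[psel] == "N"], "charge", 0.6)
    }
  }
  system$atoms <- a
  system
}

#' Net formal charge of a system
#'
#' @param system an `irdl_system` processed by [assign_protonation()]
#' @return total formal charge
#' @export
formal_charge <- function(system) {
  if (is.null(system$atoms$formal)) stop("run assign_protonation() first")
  sum(system$atoms$formal)
}
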