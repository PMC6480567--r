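# Independent brute-force oracles shared across test files.

# Minimal segment count over all tilings satisfying the fragmentation rules
# (NA when no tiling is feasible).
oracle_min_segments <- function(sequence, max_rot = 10) {
  res <- irdl:::.aa_three(sequence)
  n <- length(res)
  forbidden <- c("TYR", "CYS", "SER", "THR", "ASN", "GLN")
  seg_rot <- function(s, e) {
    rs <- res[s:e]
    m <- length(rs)
    nphi <- if (m >= 2) sum(rs[2:m] != "PRO") else 0
    nphi + (m - 1) + sum(irdl:::.CHI_COUNT[rs]) + 1
  }
  best <- NA_integer_
  recurse <- function(start, count) {
    if (!is.na(best) && count >= best) return()
    for (e in start:n) {
      if (start > 1 && res[start] %in% forbidden) return()
      if (seg_rot(start, e) > max_rot) next
      if (e == n) {
        if (is.na(best) || count + 1 < best) best <<- count + 1L
      } else {
        recurse(e + 1, count + 1L)
      }
    }
  }
  recurse(1, 0L)
  best
}

# Minimum plain RMSD over every combination of symmetry swaps (whole-atom
# selection), enumerated exhaustively.
oracle_rmsd <- function(pose, reference) {
  p <- irdl:::.atoms_xyz(pose); r <- irdl:::.atoms_xyz(reference)
  ra <- r$atoms; pa <- p$atoms
  pkey <- paste(pa$resid, pa$name)
  swaps <- irdl:::.SYMMETRY_SWAPS
  res_ids <- unique(ra$resid)
  alts <- lapply(res_ids, function(res) {
    sel <- which(ra$resid == res)
    nm <- ra$name[sel]
    rn <- ra$resname[sel[1]]
    out <- list(nm)
    sw <- swaps[[rn]]
    if (!is.null(sw) && all(unlist(sw) %in% nm)) {
      alt <- nm
      for (pr in sw) {
        alt[nm == pr[1]] <- pr[2]; alt[nm == pr[2]] <- pr[1]
      }
      out <- c(out, list(alt))
    }
    out
  })
  combos <- expand.grid(lapply(alts, seq_along))
  best <- Inf
  for (ci in seq_len(nrow(combos))) {
    total <- 0
    for (k in seq_along(res_ids)) {
      sel <- which(ra$resid == res_ids[k])
      nm <- alts[[k]][[combos[ci, k]]]
      map <- match(paste(res_ids[k], nm), pkey)
      total <- total + sum((r$xyz[sel, , drop = FALSE] -
                            p$xyz[map, , drop = FALSE])^2)
    }
    best <- min(best, sqrt(total / nrow(ra)))
  }
  best
}
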