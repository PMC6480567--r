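# Fragmentation planning: split a peptide into the minimal number of
# segments such that (a) every segment has at most `max_rotatable` rotatable
# bonds and (b) no segment except the peptide's own N-terminus starts with a
# nucleophilic-sidechain residue (Tyr, Cys, Ser, Thr, Asn, Gln).  Segments
# are reported C-terminal first, the order in which they are docked.

.MAX_ROTATABLE <- 10L

# All minimal tilings by breadth-limited enumeration (sequences here are
# short; worst case is tiny).  Returns list of integer boundary vectors
# (start indices of segments in N->C order, first element always 1).
.all_tilings <- function(resnames, max_rot) {
  n <- length(resnames)
  seg_ok <- function(s, e) {
    if (s > 1 && resnames[s] %in% .NUCLEOPHILIC_NTERM) return(FALSE)
    .segment_rotatable(resnames[s:e]) <= max_rot
  }
  out <- list()
  recurse <- function(start, bounds) {
    for (e in start:n) {
      if (!seg_ok(start, e)) next
      if (e == n) {
        out[[length(out) + 1]] <<- c(bounds, start)
      } else {
        recurse(e + 1, c(bounds, start))
      }
    }
  }
  recurse(1, integer(0))
  out
}

# Rotatable-bond count of a segment sub-sequence (free termini assumed: each
# fragment carries its own carboxyl / acid-chloride rotation).
.segment_rotatable <- function(resnames) {
  n <- length(resnames)
  n_phi <- if (n >= 2) sum(resnames[2:n] != "PRO") else 0L
  as.integer(n_phi + (n - 1L) + sum(.chi_count(resnames)) + 1L)
}

#' Plan the fragmentation of a peptide sequence
#'
#' Finds a tiling of the sequence into the minimal number of contiguous
#' segments such that every segment has at most ten rotatable bonds and no
#' segment boundary places a nucleophilic-sidechain residue (Tyr, Cys, Ser,
#' Thr, Asn, Gln) at a segment N-terminus.  The peptide's own N-terminal
#' residue is exempt (it never receives a bond).  Among minimal tilings the
#' plan maximizes the C-terminal (first-docked) segment's rotatable-bond
#' count, then takes the lexicographically earliest boundaries.
#'
#' @param sequence one-letter amino-acid string, length >= 2
#' @param max_rotatable per-segment rotatable-bond cap
#' @return an object of class `irdl_plan`: data.frame `segments` (C-terminal
#'   segment first: start, end, sequence, rotatable) plus the forbidden
#'   N-terminal set
#' @export
fragment_peptide <- function(sequence, max_rotatable = .MAX_ROTATABLE) {
  resnames <- .aa_three(sequence)
  if (length(resnames) < 2) stop("sequence must have length >= 2")
  tilings <- .all_tilings(resnames, max_rotatable)
  if (length(tilings) == 0) {
    # identify blocking positions for the error message
    blocked <- which(resnames %in% .NUCLEOPHILIC_NTERM)
    stop("no feasible fragmentation: every candidate boundary violates the ",
         "rules (nucleophilic N-terminal positions: ",
         paste(blocked, collapse = ", "), ")")
  }
  sizes <- vapply(tilings, length, integer(1))
  minimal <- tilings[sizes == min(sizes)]
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(resnames)
  plan_of <- function(bounds) {
    starts <- bounds
    ends <- c(bounds[-1] - 1L, n)
    data.frame(
      start = starts, end = ends,
      sequence = vapply(seq_along(starts), function(k)
        paste(seq1[starts[k]:ends[k]], collapse = ""), character(1)),
      rotatable = vapply(seq_along(starts), function(k)
        .segment_rotatable(resnames[starts[k]:ends[k]]), integer(1)),
      stringsAsFactors = FALSE)
  }
  # tie-break: maximize C-terminal segment rotatable count, then earliest
  # boundaries
  key <- vapply(minimal, function(b) {
    pl <- plan_of(b)
    pl$rotatable[nrow(pl)]
  }, integer(1))
  cand <- minimal[key == max(key)]
  ord <- order(vapply(cand, function(b) paste(sprintf("%03d", b),
                                              collapse = ""), character(1)))
  segs <- plan_of(cand[[ord[1]]])
  segs <- segs[rev(seq_len(nrow(segs))), ]   # C-terminal first
  rownames(segs) <- NULL
  structure(list(segments = segs, forbidden_nterm = .NUCLEOPHILIC_NTERM,
                 sequence = toupper(sequence),
                 max_rotatable = max_rotatable),
            class = "irdl_plan")
}

#' @export
print.irdl_plan <- function(x, ...) {
  cat(sprintf("<irdl_plan: %s -> %d segment(s), C->N build order>\n",
              x$sequence, nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' Validate a fragmentation plan against the fragmentation rules
#'
#' @param plan an `irdl_plan` (or a compatible list with `$segments`)
#' @param sequence the peptide sequence the plan should tile
#' @return character vector of violations (empty when the plan is valid)
#' @export
validate_plan <- function(plan, sequence) {
  segs <- plan$segments
  resnames <- .aa_three(sequence)
  n <- length(resnames)
  v <- character(0)
  nc <- segs[order(segs$start), ]
  starts <- nc$start; ends <- nc$end
  if (!(length(starts) && starts[1] == 1 && ends[length(ends)] == n &&
        all(starts[-1] == ends[-length(ends)] + 1))) {
    v <- c(v, "tiling: segments do not tile the sequence exactly")
  }
  for (k in seq_len(nrow(segs))) {
    s <- segs$start[k]; e <- segs$end[k]
    rot <- .segment_rotatable(resnames[s:e])
    if (rot > (plan$max_rotatable %||% .MAX_ROTATABLE)) {
      v <- c(v, sprintf("rule-a: segment %d-%d has %d rotatable bonds", s, e,
                        rot))
    }
    if (s > 1 && resnames[s] %in% .NUCLEOPHILIC_NTERM) {
      v <- c(v, sprintf("rule-b: segment %d-%d starts with nucleophilic %s",
                        s, e, resnames[s]))
    }
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
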