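# Growth-step chemistry and bookkeeping: acid-chloride preparation, bond
# formation geometry, junction relaxation, topology filtering, clustering,
# and the covalent score.

test_that("acid-chloride preparation swaps OXT for Cl and cannot repeat", {
  frag <- build_peptide("A")
  n0 <- nrow(frag$atoms)
  acl <- prepare_acid_chloride(frag)
  expect_identical(nrow(acl$atoms), n0)
  expect_identical(sum(acl$atoms$element == "Cl"), 1L)
  expect_false("OXT" %in% acl$atoms$name)
  expect_error(prepare_acid_chloride(acl), "malformed terminus")
  # conformer sets are converted in place, every member
  cs <- enumerate_conformers("GA", max_n = 5, seed = 1)
  cs2 <- prepare_acid_chloride(cs)
  expect_identical(sum(cs2$template$atoms$element == "Cl"), 1L)
  expect_length(cs2$coords, length(cs$coords))
})

make_linked_fixture <- function() {
  syn <- fixture_pocket()
  grid <- fixture_grid()
  plan <- fragment_peptide(syn$sequence)
  segs <- plan$segments
  conf1 <- irdl:::.offset_resids(
    enumerate_conformers(segs$sequence[1], max_n = 24, seed = 11),
    segs$start[1] - 1L)
  poses <- dock_fragment(grid, conf1, n_poses = 6, seed = 12, n_orient = 48)
  conf2 <- irdl:::.offset_resids(
    enumerate_conformers(segs$sequence[2], max_n = 24, seed = 21),
    segs$start[2] - 1L)
  conf2 <- prepare_acid_chloride(conf2)
  linked <- NULL
  for (anchor in poses) {
    linked <- tryCatch(dock_covalent(grid, anchor, conf2, seed = 31),
                       error = function(e) NULL)
    if (!is.null(linked)) break
  }
  list(syn = syn, grid = grid, anchor = anchor, conf2 = conf2,
       linked = linked)
}

linked_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_linked_fixture()
    cache
  }
})

test_that("covalent docking produces valid amide junctions", {
  fx <- linked_fixture()
  expect_gt(length(fx$linked), 0)
  for (lp in fx$linked) {
    a <- lp$template$atoms
    jn <- lp$junction
    d <- sqrt(sum((lp$xyz[jn["anchor_N"], ] - lp$xyz[jn["fragment_C"], ])^2))
    expect_lt(abs(d - 1.33), 0.05 + 1e-9)
    expect_true(check_topology(lp))
    # atom conservation: anchor + fragment - Cl
    expect_identical(nrow(lp$xyz),
                     nrow(fx$anchor$xyz) +
                       nrow(fx$conf2$template$atoms) - 1L)
    # component scores present and covalent score is their mean
    expect_length(lp$component_scores, 3)
    expect_equal(lp$covalent_score, mean(lp$component_scores))
  }
  # determinism
  again <- dock_covalent(fx$grid, fx$anchor, fx$conf2, seed = 31)
  expect_identical(lapply(again, `[[`, "xyz"),
                   lapply(fx$linked, `[[`, "xyz"))
})

test_that("bond formation on ideal geometry barely moves the fragment", {
  # take a linked pose, split it conceptually: rebuilding the bond from the
  # already-ideal placed fragment must leave atoms essentially in place
  fx <- linked_fixture()
  lp <- fx$linked[[1]]
  n_anchor <- nrow(fx$anchor$xyz)
  frag_rows <- seq(n_anchor + 1, nrow(lp$xyz))
  frag_tpl <- fx$conf2$template
  cli <- which(frag_tpl$atoms$name == "CL1")
  ci <- which(frag_tpl$atoms$resid == max(frag_tpl$atoms$resid) &
              frag_tpl$atoms$name == "C")
  # anchor as it sits inside the (junction-relaxed) linked pose
  anchor2 <- fx$anchor
  anchor2$xyz <- lp$xyz[seq_len(n_anchor), , drop = FALSE]
  coords(anchor2$template) <- anchor2$xyz
  # reconstruct fragment coords incl. a Cl placed along the old C->N axis
  fxyz <- matrix(NA_real_, nrow(frag_tpl$atoms), 3)
  keep <- setdiff(seq_len(nrow(frag_tpl$atoms)), cli)
  fxyz[keep, ] <- lp$xyz[frag_rows, ]
  npos <- anchor2$xyz[irdl:::.anchor_junction(anchor2)["N"], ]
  fxyz[cli, ] <- fxyz[ci, ] + 1.79 * irdl:::.unit(npos - fxyz[ci, ])
  fpose <- irdl:::.new_pose(frag_tpl, fxyz)
  relinked <- form_peptide_bond(anchor2, fpose)
  disp <- sqrt(rowSums((relinked$xyz - lp$xyz)^2))
  expect_lt(max(disp), 0.5)
})

test_that("junction relaxation moves only the flanking residues, monotonely", {
  fx <- linked_fixture()
  lp <- fx$linked[[1]]
  before <- score_in_place(fx$grid, lp)$total
  rel <- relax_junction(lp, fx$grid)
  after <- score_in_place(fx$grid, rel)$total
  expect_lte(after, before + 1e-9)
  a <- lp$template$atoms
  frozen <- !(a$resid %in% a$resid[lp$junction])
  expect_identical(rel$xyz[frozen, ], lp$xyz[frozen, ])
  # idempotence within tolerance
  rel2 <- relax_junction(rel, fx$grid)
  expect_lt(max(sqrt(rowSums((rel2$xyz - rel$xyz)^2))), 0.3)
})

test_that("topology filter rejects aberrant connectivity", {
  fx <- linked_fixture()
  lp <- fx$linked[[1]]
  expect_true(check_topology(lp))
  # drag the junction nitrogen onto a sidechain oxygen: wrong connectivity
  bad <- lp
  a <- bad$template$atoms
  od <- which(a$name %in% c("OD1", "OG", "O"))[1]
  bad$xyz[bad$junction["fragment_C"], ] <- bad$xyz[od, ] + c(1.3, 0, 0)
  expect_false(check_topology(bad))
  # label transposition with identical graph is still accepted
  swapped <- lp
  dd <- which(a$name == "OD1" | a$name == "OD2")
  if (length(dd) == 2) {
    swapped$xyz[dd, ] <- swapped$xyz[rev(dd), ]
    expect_true(check_topology(swapped))
  }
})

test_that("clustering returns min(k, n) score-ranked representatives and
           collapses duplicates", {
  fx <- linked_fixture()
  lp <- fx$linked[[1]]
  # synthetic pose cloud: jittered copies of one pose
  mk <- function(mag, seed) {
    p <- perturb_pose(lp, mag, seed = seed)
    p$covalent_score <- lp$covalent_score + mag + seed / 100
    p
  }
  cloud <- c(lapply(1:7, function(i) mk(i %% 3 + 0.5, i)), list(lp))
  expect_length(cluster_poses(cloud, k = 15), 8)
  expect_length(cluster_poses(cloud, k = 3), 3)
  # two identical geometries never give two representatives
  dup <- list(lp, lp, mk(4, 99))
  reps <- cluster_poses(dup, k = 3)
  xyzs <- lapply(reps, `[[`, "xyz")
  expect_lte(length(reps), 3)
  if (length(reps) == 3) {
    m <- irdl:::cpp_rmsd_matrix(xyzs)
    expect_gt(min(m[upper.tri(m)]), 0)   # no duplicated geometry
  }
  # representatives ranked by covalent score
  sc <- vapply(reps, function(p)
    if (is.null(p$covalent_score)) p$score else p$covalent_score,
    numeric(1))
  expect_false(is.unsorted(sc))
})

test_that("covalent score is the unweighted mean and symmetric", {
  expect_equal(covalent_score(c(-6, -4, -5)), -5)
  expect_equal(covalent_score(c(-4, -6, -5)), -5)
  expect_equal(covalent_score(c(2, 2, 2)), 2)
  expect_error(covalent_score(c(-6, -4)), "component")
})
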