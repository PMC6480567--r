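# Grid construction, the surrogate scoring function, rescoring modes, and
# the docking search contracts.

test_that("grid box is the cavity bounding box inflated by the margin", {
  rec <- fixture_pocket()$receptor
  box <- list(lo = c(0, 0, 0), hi = c(10, 8, 6))
  g <- build_grid(rec, box, spacing = 0.5, margin = 5)
  expect_equal(g$origin, c(-5, -5, -5))
  expect_equal((g$dims - 1) * g$spacing, c(20, 18, 16), tolerance = 0.5)
  expect_error(build_grid(rec, box, spacing = 0), "spacing")
})

test_that("zero receptor charges give an identically zero potential field", {
  rec <- fixture_pocket()$receptor
  rec$atoms$charge <- 0
  # neutralize and rebuild without re-assigning protonation
  rec$atoms$formal <- 0
  g <- build_grid(rec, list(lo = c(-5, -5, -5), hi = c(5, 5, 5)),
                  spacing = 0.8)
  expect_true(all(g$fields$elec == 0))
})

test_that("a single-atom steric field is spherically symmetric", {
  atoms <- data.frame(name = "C1", element = "C", resname = "PSD",
                      resid = 1L, chain = "R", x = 0, y = 0, z = 0,
                      charge = 0)
  rec <- irdl:::.new_system(atoms, data.frame(i = integer(0),
                                              j = integer(0),
                                              r0 = numeric(0)), "receptor")
  rec <- assign_protonation(rec, 7.4)
  g <- build_grid(rec, list(lo = c(-4, -4, -4), hi = c(4, 4, 4)),
                  spacing = 0.25, margin = 0)
  probe <- function(p) {
    irdl:::cpp_grid_sums(g$fields, g$origin, g$spacing, g$dims,
                         matrix(p, 1, 3), integer(0), integer(0), 0)[1]
  }
  r <- 3.6
  vals <- c(probe(c(r, 0, 0)), probe(c(0, r, 0)), probe(c(0, 0, r)),
            probe(r * c(1, 1, 1) / sqrt(3)), probe(r * c(-1, 1, 0) /
                                                   sqrt(2)))
  expect_lt(max(vals) - min(vals), 0.02)
})

test_that("score breakdown sums to the total and counts designed H-bonds", {
  syn <- fixture_pocket()
  g <- fixture_grid()
  br <- score_pose(g, syn$planted)
  expect_equal(br$total, sum(br$terms), tolerance = 1e-12)
  expect_identical(br$n_hbond, 3L)
  expect_lte(br$terms[["hbond"]], 0)
  # far-outside pose is dominated by the boundary penalty
  far <- syn$planted
  far$xyz <- sweep(far$xyz, 2, c(100, 0, 0))
  expect_gt(score_pose(g, far)$total, br$total + 100)
})

test_that("score_in_place equals score_pose and never moves coordinates", {
  syn <- fixture_pocket()
  g <- fixture_grid()
  xyz0 <- syn$planted$xyz
  a <- score_in_place(g, syn$planted)
  b <- score_pose(g, syn$planted)
  expect_identical(a, b)
  expect_identical(syn$planted$xyz, xyz0)
  expect_identical(score_in_place(g, syn$planted),
                   score_in_place(g, syn$planted))
})

test_that("the XP-surrogate reduces to strain when interactions vanish", {
  syn <- fixture_pocket()
  # receptor far away from the scored box: empty interaction fields
  rec <- syn$receptor
  rec$atoms[, c("x", "y", "z")] <- rec$atoms[, c("x", "y", "z")] + 500
  g <- suppressWarnings(build_grid(rec, syn$planted$xyz, spacing = 0.8,
                                   margin = 5))
  br <- rescore_xp(g, syn$planted)
  expect_equal(br$terms[["vdw"]], 0, tolerance = 1e-8)
  expect_equal(br$terms[["hbond"]], 0, tolerance = 1e-8)
  expect_equal(br$total, br$terms[["internal_strain"]], tolerance = 1e-6)
})

test_that("scores are invariant under a joint rigid motion", {
  syn <- fixture_pocket()
  g0 <- build_grid(syn$receptor, syn$planted$xyz, spacing = 0.3, margin = 5)
  s0 <- score_pose(g0, syn$planted)$total
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  t <- c(3, -2, 1)
  rec2 <- syn$receptor
  rx <- as.matrix(rec2$atoms[, c("x", "y", "z")]) %*% t(R)
  rec2$atoms[, c("x", "y", "z")] <- sweep(rx, 2, t, `+`)
  pose2 <- syn$planted
  pose2$xyz <- sweep(syn$planted$xyz %*% t(R), 2, t, `+`)
  g2 <- build_grid(rec2, pose2$xyz, spacing = 0.3, margin = 5)
  s2 <- score_pose(g2, pose2)$total
  expect_lt(abs(s2 - s0), max(0.01 * abs(s0), 0.05))
})

test_that("docking respects n_poses, determinism, and score-sorted output", {
  syn2 <- make_pocket_system("GDKA", n_contacts = 2, seed = 7)
  g <- build_grid(syn2$receptor, syn2$planted$xyz, spacing = 0.4, margin = 5)
  conf <- enumerate_conformers(syn2$sequence, max_n = 20, seed = 5)
  p1 <- dock_fragment(g, conf, n_poses = 1, seed = 3, n_orient = 16)
  expect_length(p1, 1)
  a <- dock_fragment(g, conf, n_poses = 8, seed = 3, n_orient = 16)
  b <- dock_fragment(g, conf, n_poses = 8, seed = 3, n_orient = 16)
  expect_identical(lapply(a, `[[`, "xyz"), lapply(b, `[[`, "xyz"))
  expect_identical(vapply(a, `[[`, numeric(1), "score"),
                   vapply(b, `[[`, numeric(1), "score"))
  expect_false(is.unsorted(vapply(a, `[[`, numeric(1), "score")))
})

test_that("a planted conformer present in the ensemble is recovered", {
  # recovery-by-construction, over several independently designed pockets:
  # the pocket is built around the full planted peptide and the exact
  # planted conformation is injected into the ensemble
  hits <- 0
  n_rep <- 6
  for (sd in seq_len(n_rep)) {
    syn <- make_pocket_system("GDKA", n_contacts = 4, seed = 100 + sd)
    g <- build_grid(syn$receptor, syn$planted$xyz, spacing = 0.4,
                    margin = 5)
    conf <- enumerate_conformers(syn$sequence, max_n = 20, seed = sd)
    conf$coords[[1]] <- syn$planted$xyz
    conf$strain[1] <- irdl:::cpp_internal_strain(
      syn$planted$xyz, as.matrix(conf$template$bonds),
      irdl:::.nonbonded_pairs(conf$template))
    poses <- dock_fragment(g, conf, n_poses = 10, seed = sd, n_orient = 48)
    rms <- vapply(poses[seq_len(min(5, length(poses)))], rmsd, numeric(1),
                  reference = syn$planted, selection = "whole")
    if (min(rms) <= 1.5) hits <- hits + 1
  }
  # recovered to within the sidechain-registry resolution of the surrogate
  # (long sidechains settle within ~1.5 A even when the backbone is exact)
  expect_gte(hits, n_rep - 1)
})
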