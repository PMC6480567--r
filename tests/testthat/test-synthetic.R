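# Synthetic pocket generator: determinism, designed-contact exactness,
# certification, serialization round-trip, and pose perturbation.

test_that("pocket generation is deterministic and plants exact contacts", {
  s1 <- make_pocket_system("GKLDA", n_contacts = 3, seed = 4)
  s2 <- make_pocket_system("GKLDA", n_contacts = 3, seed = 4)
  expect_identical(coords(s1$receptor), coords(s2$receptor))
  expect_identical(s1$planted$xyz, s2$planted$xyz)
  hb <- hbond_set(s1$planted, s1$receptor)
  expect_identical(nrow(hb), 3L)
  expect_equal(rmsd(s1$planted, s1$planted, "whole"), 0)
  # certification invariant: planted pose beats 95% of random placements
  g <- build_grid(s1$receptor, s1$planted$xyz, spacing = 0.5, margin = 5)
  planted_score <- score_pose(g, s1$planted)$total
  props <- irdl:::.pose_props(s1$planted$template)
  xyz <- s1$planted$xyz
  cen <- colMeans(xyz)
  ext <- (g$dims - 1) * g$spacing
  set.seed(77)
  rand <- vapply(1:300, function(i) {
    R <- irdl:::.random_rotations(1)[[1]]
    t <- g$origin + stats::runif(3) * ext
    s <- irdl:::.grid_sums(g, sweep(sweep(xyz, 2, cen) %*% t(R), 2, -t),
                           props)
    unname(s[1] + 2 * (s[2] + s[3]) + 0.5 * s[4] + 50 * s[6])
  }, numeric(1))
  expect_lte(mean(rand < planted_score), 0.05)
})

test_that("serialized complexes reproduce identical evaluation metrics", {
  syn <- fixture_pocket()
  td <- tempfile(); dir.create(td)
  write_pdb(syn$receptor, file.path(td, "receptor.pdb"))
  ref <- syn$planted$template
  coords(ref) <- syn$planted$xyz
  write_pdb(ref, file.path(td, "reference.pdb"))
  rec2 <- assign_protonation(read_pdb(file.path(td, "receptor.pdb"),
                                      "keep-all"), 7.4)
  ref2 <- assign_protonation(read_pdb(file.path(td, "reference.pdb"),
                                      "keep-all", role = "peptide"), 7.4)
  expect_equal(rmsd(ref2, ref, "whole"), 0, tolerance = 2e-3)
  hb1 <- hbond_set(syn$planted, syn$receptor)
  hb2 <- hbond_set(ref2, rec2)
  expect_identical(nrow(hb2), nrow(hb1))
  expect_equal(hbond_conservation_ratio(ref2, ref2, rec2), 1)
})

test_that("pose perturbation hits the requested magnitude on average", {
  syn <- fixture_pocket()
  expect_identical(perturb_pose(syn$planted, 0, seed = 1)$xyz,
                   syn$planted$xyz)
  same1 <- perturb_pose(syn$planted, 2, seed = 9)
  same2 <- perturb_pose(syn$planted, 2, seed = 9)
  expect_identical(same1$xyz, same2$xyz)
  draws <- vapply(1:100, function(i)
    rmsd(perturb_pose(syn$planted, 3, seed = i), syn$planted, "whole"),
    numeric(1))
  expect_gte(mean(draws), 2.4)
  expect_lte(mean(draws), 3.6)
})
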