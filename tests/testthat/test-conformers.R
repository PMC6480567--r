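# Conformer generation: cap, determinism, clash filtering, deduplication,
# strain ordering, and relaxation contracts.

test_that("ensemble respects the cap and the seed-determinism contract", {
  c1 <- enumerate_conformers("GG", max_n = 10, seed = 5)
  expect_lte(length(c1$coords), 10)
  c2 <- enumerate_conformers("GG", max_n = 10, seed = 5)
  expect_identical(c1$coords, c2$coords)
  expect_identical(c1$strain, c2$strain)
  # large random-sampling path is deterministic too
  b1 <- enumerate_conformers("KLK", max_n = 30, seed = 9)
  b2 <- enumerate_conformers("KLK", max_n = 30, seed = 9)
  expect_identical(b1$coords, b2$coords)
  expect_lte(length(b1$coords), 30)
  # the hard cap holds even when many more clash-free conformers exist
  big <- enumerate_conformers("AKLD", max_n = 200, seed = 2)
  expect_lte(length(big$coords), 200)
})

test_that("conformers are clash-free, deduplicated and strain-sorted", {
  cs <- enumerate_conformers("AAA", max_n = 200, seed = 3)
  nb <- irdl:::.nonbonded_pairs(cs$template)
  for (xyz in cs$coords) {
    expect_gte(irdl:::cpp_min_pair_dist(xyz, nb), 2.0)
  }
  expect_false(is.unsorted(cs$strain))
  if (length(cs$coords) > 1) {
    m <- irdl:::cpp_rmsd_matrix(cs$coords)
    expect_gte(min(m[upper.tri(m)]), 0.5)
  }
})

test_that("relaxation is monotone, identity at zero steps, and repairs clashes", {
  cs <- enumerate_conformers("AKA", max_n = 5, seed = 4)
  xyz <- cs$coords[[1]]
  expect_identical(relax_conformer(xyz, cs$template, steps = 0), xyz)
  nb <- irdl:::.nonbonded_pairs(cs$template)
  bonds <- as.matrix(cs$template$bonds)
  # artificially clash two sidechain atoms
  bad <- xyz
  i <- which(cs$template$atoms$name == "NZ")
  j <- which(cs$template$atoms$name == "CB")[1]
  bad[i, ] <- bad[j, ] + c(1.4, 0, 0)
  e0 <- irdl:::cpp_internal_strain(bad, bonds, nb)
  d0 <- irdl:::cpp_min_pair_dist(bad, nb)
  rel <- relax_conformer(bad, cs$template, steps = 30)
  e1 <- irdl:::cpp_internal_strain(rel, bonds, nb)
  expect_lte(e1, e0)
  expect_gte(irdl:::cpp_min_pair_dist(rel, nb), d0)
})
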