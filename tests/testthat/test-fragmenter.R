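# Fragmentation planning: minimal tilings under the rotatable-bond cap and
# the nucleophilic-N-terminus exclusion, checked against a brute-force
# oracle.

test_that("plans are minimal, tile the sequence, and respect both rules", {
  alphabet <- c("A", "G", "L", "K", "S", "E")
  set.seed(11)
  seqs <- c("AAAAA", "AAAAAAAAAAAA",
            replicate(120, paste(sample(alphabet, sample(2:12, 1),
                                        replace = TRUE), collapse = "")))
  for (s in seqs) {
    want <- oracle_min_segments(s)
    if (is.na(want)) {
      expect_error(fragment_peptide(s), "no feasible")
      next
    }
    plan <- fragment_peptide(s)
    expect_identical(nrow(plan$segments), as.integer(want))
    expect_length(validate_plan(plan, s), 0)
    # N->C concatenation reproduces the input
    nc <- plan$segments[order(plan$segments$start), ]
    expect_identical(paste(nc$sequence, collapse = ""), toupper(s))
    expect_true(all(plan$segments$rotatable <= 10))
  }
})

test_that("single-segment and multi-segment boundary cases", {
  expect_identical(nrow(fragment_peptide("AAAAA")$segments), 1L)   # 9 bonds
  p12 <- fragment_peptide(strrep("A", 12))                         # 23 bonds
  expect_gte(nrow(p12$segments), 2L)
  expect_error(fragment_peptide("A"), "length")
})

test_that("boundaries shift away from nucleophilic N-terminal residues", {
  # KKKAA: the rotatable cap forces a split; S at the only minimal cut
  # position must push the boundary elsewhere
  s <- "KKSAA"
  plan <- fragment_peptide(s)
  expect_length(validate_plan(plan, s), 0)
  starts <- plan$segments$start
  res <- irdl:::.aa_three(s)
  inner <- starts[starts > 1]
  expect_false(any(res[inner] %in% c("TYR", "CYS", "SER", "THR", "ASN",
                                     "GLN")))
})

test_that("validate_plan reports rule violations on tampered plans", {
  plan <- fragment_peptide("ALKDVA")
  ok <- validate_plan(plan, "ALKDVA")
  expect_length(ok, 0)
  # hand-built overweight segment (rule a)
  bad_a <- plan
  bad_a$segments <- data.frame(start = 1L, end = 6L, sequence = "ALKDVA",
                               rotatable = count_rotatable_bonds("ALKDVA"))
  va <- validate_plan(bad_a, "ALKDVA")
  expect_true(any(grepl("rule-a", va)))
  # segment starting with Cys (rule b)
  s2 <- "AACAA"
  bad_b <- list(segments = data.frame(start = c(1L, 3L), end = c(2L, 5L)),
                max_rotatable = 10)
  vb <- validate_plan(bad_b, s2)
  expect_true(any(grepl("rule-b.*CYS", vb)))
})
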