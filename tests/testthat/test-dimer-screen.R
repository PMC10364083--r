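make_two_cys_chain <- function(chain, sg_positions) {
  # minimal cysteines: CB + SG (+HG) per residue at prescribed SG spots
  rows <- purrr::imap_dfr(sg_positions, function(p, i) {
    tibble::tibble(
      name = c("CA", "CB", "SG"), element = c("C", "C", "S"),
      residue_name = "CYS", chain = chain, residue_seq = i,
      x = p[1] + c(-2.5, -1.3, 0), y = p[2], z = p[3])
  })
  rows
}

test_that("inter-cysteine distances match construction and brute force", {
  atoms <- dplyr::bind_rows(
    make_two_cys_chain("A", list(c(0, 0, 0))),
    make_two_cys_chain("B", list(c(5, 0, 0))))
  s <- as_structure(atoms)
  pr <- inter_cys_distances(s)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$distance, 5)
  # 2 x 2 cysteines: 4 pairs in ascending order
  atoms4 <- dplyr::bind_rows(
    make_two_cys_chain("A", list(c(0, 0, 0), c(0, 8, 0))),
    make_two_cys_chain("B", list(c(6, 0, 0), c(6, 8, 0))))
  s4 <- as_structure(atoms4)
  pr4 <- inter_cys_distances(s4)
  expect_equal(nrow(pr4), 4)
  expect_true(!is.unsorted(pr4$distance))
  # naive double-loop oracle on a 6-cysteine-per-chain fixture
  m <- make_helix_monomer(20, cys_positions = c(2, 5, 8, 11, 14, 17))
  pose <- make_dimer_pose(m, 6, c2 = TRUE)
  got <- inter_cys_distances(pose)
  ref <- naive_cys_pairs(pose)
  expect_equal(got$distance, ref$distance, tolerance = 1e-12)
  expect_equal(got$seq_a, ref$seq_a)
  expect_equal(got$seq_b, ref$seq_b)
})

test_that("distances are symmetric under chain swap and rigid motion", {
  m <- make_helix_monomer(12, cys_positions = c(3, 7))
  pose <- make_dimer_pose(m, 7, c2 = TRUE)
  ab <- inter_cys_distances(pose, chains = c("A", "B"))
  ba <- inter_cys_distances(pose, chains = c("B", "A"))
  expect_equal(sort(ab$distance), sort(ba$distance))
  set.seed(5)
  moved <- rigid_move(pose, random_rotation(), c(-4, 2, 9))
  expect_equal(inter_cys_distances(moved)$distance, ab$distance,
               tolerance = 1e-9)
  expect_equal(screen_pose(moved)$verdict, screen_pose(pose)$verdict)
  expect_equal(check_c2_symmetry(moved)$c2_rmsd,
               check_c2_symmetry(pose)$c2_rmsd, tolerance = 1e-6)
})

test_that("a cysteine lacking its distance atom is a named error", {
  atoms <- dplyr::bind_rows(
    make_two_cys_chain("A", list(c(0, 0, 0))),
    make_two_cys_chain("B", list(c(5, 0, 0))))
  atoms <- atoms[!(atoms$chain == "B" & atoms$name == "SG"), ]
  expect_error(inter_cys_distances(as_structure(atoms)), "B1")
})

test_that("verdict bands: 5 A candidate, 8 A marginal, 12 A rejected; monotone", {
  m <- make_helix_monomer(12, cys_positions = 5)
  verdicts <- vapply(c(5, 8, 12), function(t) {
    as.character(screen_pose(make_dimer_pose(m, t, c2 = TRUE))$verdict)
  }, character(1))
  expect_equal(verdicts, c("candidate", "marginal", "rejected"))
  # monotone: shrinking min_ss never moves a pose toward rejection
  ds <- seq(3, 14, by = 0.5)
  vs <- vapply(ds, function(t) {
    as.integer(screen_pose(make_dimer_pose(m, t, c2 = TRUE))$verdict)
  }, integer(1))
  expect_true(!is.unsorted(vs))
  # boundary values sit in the lenient band
  expect_equal(as.character(screen_pose(make_dimer_pose(m, 6, c2 = TRUE))$verdict),
               "candidate")
  expect_equal(as.character(screen_pose(make_dimer_pose(m, 10, c2 = TRUE))$verdict),
               "marginal")
})

test_that("poses without cysteine pairs are rejected with a reason", {
  plain <- make_helix_monomer(6)
  b <- plain; b$chain <- "B"; b$x <- b$x + 20
  pose <- as_structure(dplyr::bind_rows(plain, b))
  sc <- screen_pose(pose)
  expect_equal(as.character(sc$verdict), "rejected")
  expect_match(sc$reason, "no cysteine pairs")
})

test_that("rank_poses orders by verdict class then distance, stably", {
  m <- make_helix_monomer(12, cys_positions = 5)
  targets <- c(12, 5, 8, 4, 11, 6.5, 9.5, 3.5, 13, 7)
  poses <- purrr::imap_dfr(targets, function(t, i) {
    dplyr::mutate(screen_pose(make_dimer_pose(m, t, c2 = TRUE)), pose_id = i)
  })
  ranked <- rank_poses(poses)
  # brute-force reference sort
  ref <- poses[order(as.integer(poses$verdict), poses$min_ss), ]
  expect_equal(ranked$pose_id, ref$pose_id)
  expect_true(all(diff(as.integer(ranked$verdict)) >= 0))
  within <- split(ranked$min_ss, ranked$verdict)
  expect_true(all(vapply(within, function(v) !is.unsorted(v), logical(1))))
})

test_that("disulfide formation removes exactly the two thiol hydrogens", {
  m <- make_helix_monomer(10, cys_positions = 4)
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  pr <- inter_cys_distances(pose)
  out <- form_disulfide(pose, "A", pr$seq_a[1], "B", pr$seq_b[1])
  expect_equal(nrow(out), nrow(pose) - 2)
  expect_false(any(out$residue_name == "CYS" & out$name == "HG"))
  bonds <- ssbonds(out)
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$distance, pr$distance[1], tolerance = 1e-9)
  # all other atoms untouched
  kept <- pose[!(pose$residue_name == "CYS" & pose$name == "HG"), ]
  expect_equal(out$x, kept$x)
  # already-deprotonated input: atom count unchanged, bond recorded
  bare <- as_structure(
    pose[!(pose$residue_name == "CYS" & pose$name == "HG"), ])
  out2 <- form_disulfide(bare, "A", pr$seq_a[1], "B", pr$seq_b[1])
  expect_equal(nrow(out2), nrow(bare))
  expect_equal(nrow(ssbonds(out2)), 1)
  # stripping the bond record recovers the deprotonated structure exactly
  stripped <- out2
  attr(stripped, "ssbonds") <- NULL
  expect_equal(as.data.frame(stripped), as.data.frame(bare))
})

test_that("disulfide preconditions: cysteine-only, SG required, no duplicates", {
  m <- make_helix_monomer(10, cys_positions = 4)
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  expect_error(form_disulfide(pose, "A", 2, "B", 4), "ALA")
  nosg <- as_structure(pose[!(pose$chain == "B" & pose$name == "SG"), ])
  expect_error(form_disulfide(nosg, "A", 4, "B", 4), "SG")
  once <- form_disulfide(pose, "A", 4, "B", 4)
  expect_error(form_disulfide(once, "A", 4, "B", 4), "already")
  expect_error(form_disulfide(once, "B", 4, "A", 4), "already")
  # SSBOND record survives a PDB round trip as header text
  txt <- write_pdb(once)
  expect_true(any(grepl("^SSBOND", txt)))
})

test_that("C2 symmetry detection distinguishes built symmetry from perturbation", {
  m <- make_helix_monomer(10, cys_positions = 4)
  pose <- make_dimer_pose(m, 6, c2 = TRUE)
  r <- check_c2_symmetry(pose)
  expect_true(r$symmetric)
  expect_lt(r$c2_rmsd, 1e-6)
  # tolerance 0 still accepts an exactly constructed C2 pose
  expect_true(check_c2_symmetry(pose, rmsd_tolerance = 0)$symmetric)
  # asymmetric pose: deform chain B (a pure translation of one chain
  # would leave the pose C2 about a shifted axis, so jitter instead)
  asym <- pose
  set.seed(31)
  bsel <- asym$chain == "B"
  asym$x[bsel] <- asym$x[bsel] + rnorm(sum(bsel), sd = 1.5)
  asym$y[bsel] <- asym$y[bsel] + rnorm(sum(bsel), sd = 1.5)
  ra <- check_c2_symmetry(asym, rmsd_tolerance = 1)
  expect_false(ra$symmetric)
  expect_gt(ra$c2_rmsd, 1)
  # non-C2 translated pose is detected as asymmetric too
  slid <- make_dimer_pose(m, 6, c2 = FALSE)
  expect_gt(check_c2_symmetry(slid, rmsd_tolerance = 0.5)$c2_rmsd, 0)
  # unequal chains are an error
  trunc <- as_structure(pose[!(pose$chain == "B" & pose$residue_seq == 1), ])
  expect_error(check_c2_symmetry(trunc), "unequal|atom counts")
})
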