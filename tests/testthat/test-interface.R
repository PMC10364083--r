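test_that("Kabsch superposition: identity, exact recovery, proper rotation", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  same <- kabsch_superpose(X, X)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)
  R <- random_rotation(); tvec <- c(3, -7, 2)
  Y <- X %*% t(R); Y <- sweep(Y, 2, tvec, "+")
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$fitted, Y, tolerance = 1e-8)
  expect_error(kabsch_superpose(X, X[1:5, ]), "point counts")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "3 points")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on 100 random instances", {
  set.seed(99)
  for (k in 1:100) {
    X <- matrix(rnorm(150, sd = 4), ncol = 3)
    Y <- X %*% t(random_rotation()) + matrix(rnorm(150, sd = 0.6), ncol = 3)
    fit <- kabsch_superpose(X, Y)
    expect_equal(fit$rmsd, quaternion_rmsd(X, Y), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("reflection-degenerate inputs still return a proper rotation", {
  set.seed(3)
  X <- matrix(rnorm(60), ncol = 3)
  Y <- X %*% diag(c(1, 1, -1))   # mirror image
  fit <- kabsch_superpose(X, Y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("RMSD series is zero for identical or rigidly moved frames", {
  m <- make_helix_monomer(10)
  still <- synthesize_trajectory(m, n_frames = 4, jitter_sigma = 0, seed = 1)
  rs <- rmsd_series(still)
  expect_equal(rs$rmsd, rep(0, 4), tolerance = 1e-10)
  # rigidly transformed copies superpose to ~0
  set.seed(8)
  moved <- purrr::map_dfr(1:4, function(i) {
    fr <- rigid_move(m, random_rotation(), rnorm(3, sd = 10))
    dplyr::mutate(fr, model = i)
  })
  rs2 <- rmsd_series(as_structure(moved))
  expect_lt(max(rs2$rmsd), 1e-8)
})

test_that("RMSD series matches a naive superpose-then-RMS oracle under jitter", {
  m <- make_helix_monomer(10)
  tr <- synthesize_trajectory(m, n_frames = 6, jitter_sigma = 0.3, seed = 5)
  rs <- rmsd_series(tr, reference_frame = 1)
  ref <- tr[tr$model == 1 & tr$name %in% c("N", "CA", "C", "O"), ]
  refxyz <- cbind(ref$x, ref$y, ref$z)
  naive <- vapply(1:6, function(i) {
    fr <- tr[tr$model == i & tr$name %in% c("N", "CA", "C", "O"), ]
    fit <- kabsch_superpose(cbind(fr$x, fr$y, fr$z), refxyz)
    sqrt(mean(rowSums((fit$fitted - refxyz)^2)))
  }, numeric(1))
  expect_equal(rs$rmsd, naive, tolerance = 1e-9)
  expect_equal(attr(rs, "mean"), mean(naive))
  expect_error(rmsd_series(tr, reference_frame = 99), "not a model")
})

test_that("RMSF is zero for static ensembles and local for one mobile atom", {
  m <- make_helix_monomer(8)
  still <- synthesize_trajectory(m, n_frames = 3, jitter_sigma = 0, seed = 1)
  rf <- rmsf(still)
  expect_equal(rf$rmsf, rep(0, nrow(rf)), tolerance = 1e-10)
  expect_error(rmsf(m), "single frame")
  # one mobile atom among fixed atoms
  set.seed(2)
  frames_df <- purrr::map_dfr(1:50, function(i) {
    fr <- m
    j <- which(fr$name == "CB" & fr$residue_seq == 4)[1]
    fr$x[j] <- fr$x[j] + rnorm(1, sd = 0.8)
    dplyr::mutate(fr, model = i)
  })
  rfm <- rmsf(as_structure(frames_df), selection = "carbon")
  mobile <- rfm$residue_seq == 4 & rfm$name == "CB"
  # superposition spreads a little apparent motion onto the fixed atoms,
  # so require dominance rather than exact zeros elsewhere
  expect_gt(rfm$rmsf[mobile], 5 * max(rfm$rmsf[!mobile]))
})

test_that("isotropic jitter RMSF converges to sigma * sqrt(3)", {
  m <- make_helix_monomer(24, cys_positions = 5)
  tr <- synthesize_trajectory(m, n_frames = 1200, jitter_sigma = 0.5,
                              seed = 21)
  rf <- rmsf(tr, selection = "carbon")
  expect_gt(nrow(rf), 50)
  expect_true(all(abs(rf$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
})

test_that("radius of gyration matches closed forms and direct summation", {
  one <- as_structure(data.frame(name = "X", element = "C",
                                 residue_name = "TOY", chain = "A",
                                 residue_seq = 1, x = 3, y = -2, z = 7))
  expect_equal(radius_of_gyration(one)$rg, 0)
  two <- as_structure(data.frame(name = c("X", "Y"), element = "C",
                                 residue_name = "TOY", chain = "A",
                                 residue_seq = 1:2,
                                 x = c(-1, 1), y = 0, z = 0))
  expect_equal(radius_of_gyration(two)$rg, 1)
  # direct-summation oracle on a random cloud with real masses
  set.seed(11)
  n <- 100
  cloud <- as_structure(data.frame(
    name = "X", element = sample(c("C", "N", "O", "S"), n, TRUE),
    residue_name = "TOY", chain = "A", residue_seq = seq_len(n),
    x = rnorm(n, sd = 8), y = rnorm(n, sd = 8), z = rnorm(n, sd = 8)))
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)[cloud$element]
  com <- c(sum(cloud$x * masses), sum(cloud$y * masses),
           sum(cloud$z * masses)) / sum(masses)
  direct <- sqrt(sum(masses * ((cloud$x - com[1])^2 + (cloud$y - com[2])^2 +
                                 (cloud$z - com[3])^2)) / sum(masses))
  expect_equal(radius_of_gyration(cloud)$rg, direct, tolerance = 1e-10)
})

test_that("interaction energy reproduces Coulomb and LJ closed forms", {
  par2 <- function(q1, q2, eps = 0, rmin2 = 1) {
    data.frame(chain = c("A", "B"), residue_seq = 1, name = "X",
               charge = c(q1, q2), epsilon = eps, rmin2 = rmin2)
  }
  # opposite unit charges at 5 A (inside the switch region): -332.0636/5
  e5 <- interaction_energy(two_atom_dimer(5), params = par2(1, -1))
  expect_equal(e5$e_elec, -332.0636 / 5, tolerance = 1e-10)
  expect_equal(e5$e_vdw, 0)
  # any pair beyond the 12 A cutoff contributes nothing
  e13 <- interaction_energy(two_atom_dimer(13), params = par2(1, -1, eps = 0.3))
  expect_equal(e13$e_tot, 0)
  # LJ minimum: r = rmin and no charges gives exactly -epsilon
  elj <- interaction_energy(two_atom_dimer(4),
                            params = par2(0, 0, eps = 0.25, rmin2 = 2))
  expect_equal(elj$e_vdw, -0.25, tolerance = 1e-12)
  expect_equal(elj$e_elec, 0)
})

test_that("switched energy is continuous across both switch boundaries", {
  par2 <- data.frame(chain = c("A", "B"), residue_seq = 1, name = "X",
                     charge = c(1, -1), epsilon = 0.2, rmin2 = 1.7)
  energy_at <- function(r) {
    interaction_energy(two_atom_dimer(r), params = par2)$e_tot
  }
  grid <- seq(9.9, 12.1, by = 0.001)
  vals <- vapply(grid, energy_at, numeric(1))
  expect_true(all(is.finite(vals)))
  expect_true(all(vals[grid >= 12] == 0))
  # continuity at the 10 and 12 A boundaries: the two-sided limits agree
  eps <- 1e-9
  for (b in c(10, 12)) {
    expect_lt(abs(energy_at(b - eps) - energy_at(b + eps)), 1e-6)
  }
  expect_error(interaction_energy(two_atom_dimer(5), params = par2,
                                  cutoff = 10, switch_start = 10), "below")
})

test_that("atoms without parameters are reported by name", {
  s <- two_atom_dimer(5)
  par_a <- data.frame(chain = "A", residue_seq = 1, name = "X",
                      charge = 0, epsilon = 0.1, rmin2 = 2)
  expect_error(interaction_energy(s, params = par_a), "B1:X")
})

test_that("interface area: zero when separated, cap value in contact, monotone", {
  far <- interface_area(two_atom_dimer(2 * 3.1 + 0.1))
  expect_equal(far$a_is, 0)
  touching <- interface_area(two_atom_dimer(3.1))
  expect_equal(touching$a_is, two_sphere_buried_area(3.1, 3.1),
               tolerance = 0.01)
  seps <- c(3.1, 4.0, 5.0, 5.9, 6.5)
  a <- vapply(seps, function(d) interface_area(two_atom_dimer(d))$a_is,
              numeric(1))
  expect_true(all(diff(a) <= 1e-9))
  # symmetric under chain relabeling
  s <- two_atom_dimer(3.5)
  expect_equal(interface_area(s, chains = c("A", "B"))$a_is,
               interface_area(s, chains = c("B", "A"))$a_is)
  expect_error(interface_area(s, chains = c("A", "A")), "distinct")
})

test_that("hydrogen-bond detection obeys distance and angle criteria", {
  ladder <- function(angle_deg, no = 2.9) {
    # donor N with H pointing at acceptor O, bend by rotating the acceptor
    th <- angle_deg * pi / 180
    as_structure(data.frame(
      name = c("N", "H", "O"), element = c("N", "H", "O"),
      residue_name = c("GLN", "GLN", "SER"),
      chain = c("A", "A", "B"), residue_seq = c(1, 1, 1),
      x = c(0, 1.0, 1.0 + (no - 1.0) * cos(th)),
      y = c(0, 0, (no - 1.0) * sin(th)), z = 0))
  }
  hit <- detect_hbonds(ladder(0), chains = c("A", "B"))   # perfectly linear
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9, tolerance = 1e-9)
  expect_equal(hit$angle, 180, tolerance = 1e-6)
  miss <- detect_hbonds(ladder(90), chains = c("A", "B"))
  expect_equal(nrow(miss), 0)
  toofar <- detect_hbonds(ladder(0, no = 3.8), chains = c("A", "B"))
  expect_equal(nrow(toofar), 0)
  nohyd <- ladder(0)
  nohyd <- as_structure(nohyd[nohyd$element != "H", ])
  expect_error(detect_hbonds(nohyd), "hydrogens")
  expect_equal(nrow(detect_hbonds(nohyd, heavy_only = TRUE)), 1)
})

test_that("a synthetic ladder with four built-in bonds yields exactly four", {
  rung <- function(i) {
    data.frame(
      name = c("N", "H", "O"), element = c("N", "H", "O"),
      residue_name = c("GLN", "GLN", "SER"),
      chain = c("A", "A", "B"), residue_seq = i,
      x = c(0, 1.0, 2.9), y = i * 5, z = 0)
  }
  ladder <- as_structure(purrr::map_dfr(1:4, rung))
  found <- detect_hbonds(ladder, chains = c("A", "B"))
  expect_equal(nrow(found), 4)
  # brute-force triple loop oracle
  donors <- ladder[ladder$name == "N", ]
  hs <- ladder[ladder$name == "H", ]
  accs <- ladder[ladder$name == "O", ]
  count <- 0
  for (i in seq_len(nrow(donors))) for (j in seq_len(nrow(accs))) {
    d <- sqrt(sum((c(donors$x[i], donors$y[i], donors$z[i]) -
                     c(accs$x[j], accs$y[j], accs$z[j]))^2))
    if (d > 3.5) next
    for (k in seq_len(nrow(hs))) {
      if (hs$residue_seq[k] != donors$residue_seq[i]) next
      v1 <- c(donors$x[i] - hs$x[k], donors$y[i] - hs$y[k],
              donors$z[i] - hs$z[k])
      v2 <- c(accs$x[j] - hs$x[k], accs$y[j] - hs$y[k],
              accs$z[j] - hs$z[k])
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= 140) count <- count + 1
    }
  }
  expect_equal(nrow(found), count)
})

test_that("salt-bridge occupancy filter is strictly greater-than", {
  m <- make_helix_monomer(16, cys_positions = 5, lys_positions = 12,
                          asp_positions = 3)
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  occs <- c(0.05, 0.10, 0.11)
  res <- lapply(occs, function(o) {
    sched <- data.frame(chain_acid = "A", seq_acid = 3,
                        chain_base = "B", seq_base = 12, occupancy = o)
    tr <- synthesize_trajectory(pose, n_frames = 100, jitter_sigma = 0.1,
                                schedule = sched, seed = 13)
    detect_salt_bridges(tr)
  })
  expect_equal(nrow(res[[1]]), 0)    # 5/100 excluded
  expect_equal(nrow(res[[2]]), 0)    # exactly 10/100 excluded (strict)
  expect_equal(nrow(res[[3]]), 1)    # 11/100 retained
  expect_equal(res[[3]]$occupancy, 0.11)
  cands <- attr(res[[2]], "candidates")
  expect_equal(cands$occupancy, 0.10)  # the candidate was seen, then filtered
})

test_that("the interface panel is compositionally consistent with its parts", {
  m <- make_helix_monomer(12, cys_positions = 4, lys_positions = 9,
                          asp_positions = 2)
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  tr <- synthesize_trajectory(pose, n_frames = 5, jitter_sigma = 0.2,
                              seed = 17)
  panel <- build_interface_panel(tr, n_sphere_points = 240)
  pf <- panel$per_frame
  expect_equal(pf$e_tot,
               interaction_energy(tr)$e_tot)
  expect_equal(pf$rg, radius_of_gyration(tr)$rg)
  expect_equal(pf$rmsd, rmsd_series(tr)$rmsd)
  expect_equal(pf$a_is, interface_area(tr, n_sphere_points = 240)$a_is)
  s <- panel$summary
  expect_equal(s$mean[s$metric == "e_tot"], mean(pf$e_tot))
  expect_equal(s$sd[s$metric == "rg"], sd(pf$rg))
  expect_equal(s$mean[s$metric == "rmsf"], attr(rmsf(tr), "mean"))
  # broom-style accessors agree with the summary
  expect_equal(tidy(panel), s)
  expect_equal(glance(panel)$a_is, s$mean[s$metric == "a_is"])
  expect_s3_class(ggplot2::autoplot(panel), "ggplot")
})

test_that("a static ensemble gives zero spread and single-frame means", {
  m <- make_helix_monomer(10, cys_positions = 4)
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  still <- synthesize_trajectory(pose, n_frames = 4, jitter_sigma = 0,
                                 seed = 1)
  panel <- build_interface_panel(still, n_sphere_points = 240)
  s <- panel$summary
  perframe_sd <- s$sd[s$metric %in% c("e_tot", "rg", "rmsd", "a_is",
                                      "hydrogen_bonds")]
  expect_equal(perframe_sd, rep(0, 5), tolerance = 1e-9)
  one_e <- interaction_energy(pose)$e_tot
  expect_equal(s$mean[s$metric == "e_tot"], one_e, tolerance = 1e-9)
})

test_that("panel counts only the scheduled bridges above the occupancy filter", {
  m <- make_helix_monomer(20, cys_positions = 5,
                          lys_positions = c(12, 16), asp_positions = c(3, 8))
  pose <- make_dimer_pose(m, 5, c2 = TRUE)
  sched <- data.frame(
    chain_acid = c("A", "A", "B"), seq_acid = c(3, 8, 3),
    chain_base = c("B", "B", "A"), seq_base = c(12, 16, 16),
    occupancy = c(0.5, 0.5, 0.05))
  tr <- synthesize_trajectory(pose, n_frames = 20, jitter_sigma = 0.1,
                              schedule = sched, seed = 23)
  panel <- build_interface_panel(tr, n_sphere_points = 120)
  s <- panel$summary
  expect_equal(s$mean[s$metric == "salt_bridges"], 2)
})
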