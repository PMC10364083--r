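ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, FE = 55.845, ZN = 65.38,
                   MG = 24.305, CL = 35.45, BR = 79.904, F = 18.998,
                   `NA` = 22.99, CA = 40.078)

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`, via SVD of the weighted covariance matrix with the
#' usual reflection correction (the returned rotation always has
#' determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fit
#'   is `mobile %*% t(rotation)` then `+ translation`), `rmsd` (Angstrom)
#'   and `fitted` (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort("mobile and reference have different point counts")
  }
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  U <- sv$v %*% D %*% t(sv$u)   # rotation: fitted = P %*% t(U)
  fitted <- P %*% t(U)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  fitted <- sweep(fitted, 2, cr, "+")
  list(rotation = U, translation = cr - as.vector(U %*% cm),
       rmsd = rmsd, fitted = fitted)
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' Each frame's selected atoms are optimally superposed on the reference
#' frame's selection before the root-mean-square deviation is taken, so
#' global rigid motion does not contribute.
#'
#' @param ensemble multi-model structure tibble.
#' @param reference_frame model index of the reference (default the first
#'   model present).
#' @param selection `"backbone"` (default), `"calpha"`, `"carbon"`,
#'   `"heavy"` or `"all"`.
#' @return Tibble `model`, `rmsd` with attributes `mean` and `sd`.
#' @export
rmsd_series <- function(ensemble, reference_frame = NULL,
                        selection = "backbone") {
  frs <- frames(ensemble)
  ids <- vapply(frs, function(f) f$model[1], numeric(1))
  if (is.null(reference_frame)) reference_frame <- ids[1]
  ref_i <- match(reference_frame, ids)
  if (is.na(ref_i)) abort("reference_frame is not a model of the ensemble")
  ref <- coords(select_atoms(frs[[ref_i]], selection))
  if (nrow(ref) == 0) abort("empty atom selection")
  vals <- vapply(frs, function(f) {
    kabsch_superpose(coords(select_atoms(f, selection)), ref)$rmsd
  }, numeric(1))
  out <- tibble::tibble(model = ids, rmsd = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

# Superpose every frame onto a common mean structure (iterative: superpose
# to frame 1, average, re-superpose to the average; repeated `passes`
# times, which converges to well below coordinate noise for rigid-ish
# ensembles).
superpose_to_mean <- function(coord_list, passes = 2) {
  ref <- coord_list[[1]]
  for (p in seq_len(passes)) {
    fitted <- lapply(coord_list, function(xy) kabsch_superpose(xy, ref)$fitted)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  lapply(coord_list, function(xy) kabsch_superpose(xy, ref)$fitted)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed onto their (iteratively refined) mean structure;
#' the RMSF of atom j is the root-mean-square distance of its position
#' from its ensemble-average position.
#'
#' @param ensemble multi-model structure tibble with >= 2 frames.
#' @param selection atom selection (default `"carbon"`, i.e. every carbon;
#'   use `"calpha"` for Ca only).
#' @return Tibble with the selected atoms' identity columns and `rmsf`
#'   (Angstrom); attributes `mean` and `sd` summarise over atoms.
#' @export
rmsf <- function(ensemble, selection = "carbon") {
  frs <- frames(ensemble)
  if (length(frs) < 2) abort("RMSF undefined for a single frame")
  sel <- lapply(frs, select_atoms, selection = selection)
  if (nrow(sel[[1]]) == 0) abort("empty atom selection")
  cl <- superpose_to_mean(lapply(sel, coords))
  mean_xyz <- Reduce(`+`, cl) / length(cl)
  ssq <- Reduce(`+`, lapply(cl, function(xy) rowSums((xy - mean_xyz)^2)))
  vals <- sqrt(ssq / length(cl))
  out <- sel[[1]][, c("chain", "residue_seq", "residue_name", "name")]
  out$rmsf <- vals
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

#' Radius of gyration
#'
#' `R_g = sqrt( sum m_i |r_i - r_com|^2 / sum m_i )`, a measure of the
#' compactness of the structure. Computed per model.
#'
#' @param structure structure tibble (single- or multi-model).
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return Tibble `model`, `rg` (Angstrom).
#' @export
radius_of_gyration <- function(structure, mass_weighted = TRUE) {
  purrr::map_dfr(frames(structure), function(fr) {
    m <- if (mass_weighted) {
      el <- toupper(fr$element)
      unmapped <- setdiff(unique(el), names(ATOMIC_MASSES))
      if (length(unmapped) > 0) {
        abort(paste0("no atomic mass for element(s): ",
                     paste(unmapped, collapse = ", ")))
      }
      unname(ATOMIC_MASSES[el])
    } else rep(1, nrow(fr))
    if (sum(m) <= 0) abort("zero total mass")
    xyz <- coords(fr)
    com <- colSums(xyz * m) / sum(m)
    tibble::tibble(model = fr$model[1],
                   rg = sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m)))
  })
}

# CHARMM-style switching function, 1 below switch_start, 0 beyond cutoff,
# C1-continuous in between.
switch_fn <- function(r, switch_start, cutoff) {
  s <- numeric(length(r))
  s[r <= switch_start] <- 1
  mid <- r > switch_start & r < cutoff
  if (any(mid)) {
    r2 <- r[mid]^2; on2 <- switch_start^2; off2 <- cutoff^2
    s[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  s
}

#' Minimal bundled non-bonded parameter table
#'
#' Element-keyed Lennard-Jones parameters and residue-level formal charges
#' placed on charged-group atoms (Asp/Glu carboxylate oxygens -0.5 e each,
#' Lys NZ +1 e, Arg NH1/NH2 +0.5 e each). This is a deliberately minimal
#' table so the inter-monomer energy machinery is testable without any
#' force-field distribution; absolute agreement with a full force field's
#' energies is not claimed.
#'
#' @param structure structure tibble (single model or the topology frame of
#'   an ensemble).
#' @return Parameter tibble `chain, residue_seq, name, charge, epsilon,
#'   rmin2` (kcal/mol and Angstrom).
#' @export
default_nonbonded_params <- function(structure) {
  fr <- frames(structure)[[1]]
  lj <- list(H = c(0.030, 1.34), C = c(0.070, 2.00), N = c(0.200, 1.85),
             O = c(0.120, 1.70), S = c(0.450, 2.00), P = c(0.585, 2.15),
             FE = c(0.010, 1.10))
  el <- toupper(fr$element)
  eps <- vapply(el, function(e) if (e %in% names(lj)) lj[[e]][1] else 0.1,
                numeric(1))
  rm2 <- vapply(el, function(e) if (e %in% names(lj)) lj[[e]][2] else 1.8,
                numeric(1))
  q <- numeric(nrow(fr))
  q[fr$residue_name == "ASP" & fr$name %in% c("OD1", "OD2")] <- -0.5
  q[fr$residue_name == "GLU" & fr$name %in% c("OE1", "OE2")] <- -0.5
  q[fr$residue_name == "LYS" & fr$name == "NZ"] <- 1
  q[fr$residue_name == "ARG" & fr$name %in% c("NH1", "NH2")] <- 0.5
  tibble::tibble(chain = fr$chain, residue_seq = fr$residue_seq,
                 name = fr$name, charge = q, epsilon = unname(eps),
                 rmin2 = unname(rm2))
}

#' Inter-monomer non-bonded interaction energy
#'
#' Sums Lennard-Jones 12-6 and Coulomb terms over inter-chain atom pairs
#' only (no bonded terms are ever computed, so a covalent S-S term is
#' excluded by construction), with a smooth switching function applied to
#' both terms between `switch_start` and `cutoff` and zero beyond the
#' cutoff — the 12 A cutoff / 10 A switching-distance convention.
#'
#' @param structure pose tibble (single- or multi-model; energies reported
#'   per model).
#' @param chains length-2 chain ids.
#' @param params parameter tibble (`chain, residue_seq, name, charge,
#'   epsilon, rmin2`); default [default_nonbonded_params()].
#' @param cutoff,switch_start Angstrom, `switch_start < cutoff`.
#' @param dielectric relative dielectric constant.
#' @param coulomb_constant kcal A / (mol e^2).
#' @return Tibble `model, e_vdw, e_elec, e_tot` (kcal/mol).
#' @export
interaction_energy <- function(structure, chains = NULL, params = NULL,
                               cutoff = 12, switch_start = 10,
                               dielectric = 1,
                               coulomb_constant = 332.0636) {
  if (switch_start >= cutoff) abort("switch_start must be below cutoff")
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  if (is.null(params)) params <- default_nonbonded_params(structure)
  purrr::map_dfr(frames(structure), function(fr) {
    merged <- dplyr::left_join(
      fr, params, by = c("chain", "residue_seq", "name"))
    if (anyNA(merged$charge) || anyNA(merged$epsilon) || anyNA(merged$rmin2)) {
      bad <- merged[is.na(merged$charge) | is.na(merged$epsilon) |
                      is.na(merged$rmin2), ]
      abort(paste0("missing non-bonded parameters for atom(s): ",
                   paste(utils::head(
                     paste0(bad$chain, bad$residue_seq, ":", bad$name), 5),
                     collapse = ", ")))
    }
    a <- merged[merged$chain == chains[1], ]
    b <- merged[merged$chain == chains[2], ]
    if (nrow(a) == 0 || nrow(b) == 0) abort("both chains must be present")
    pa <- coords(a); pb <- coords(b)
    # pairwise distances chain A x chain B
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    d <- sqrt(pmax(d2, 0))
    keep <- d < cutoff & d > 0
    if (!any(keep)) {
      return(tibble::tibble(model = fr$model[1], e_vdw = 0, e_elec = 0,
                            e_tot = 0))
    }
    ij <- which(keep, arr.ind = TRUE)
    rij <- d[keep]
    sw <- switch_fn(rij, switch_start, cutoff)
    eps <- sqrt(a$epsilon[ij[, 1]] * b$epsilon[ij[, 2]])
    rmin <- a$rmin2[ij[, 1]] + b$rmin2[ij[, 2]]
    sr6 <- (rmin / rij)^6
    e_vdw <- sum(eps * (sr6^2 - 2 * sr6) * sw)
    e_elec <- sum(coulomb_constant * a$charge[ij[, 1]] * b$charge[ij[, 2]] /
                    (dielectric * rij) * sw)
    tibble::tibble(model = fr$model[1], e_vdw = e_vdw, e_elec = e_elec,
                   e_tot = e_vdw + e_elec)
  })
}

#' Buried interface area of a two-chain complex
#'
#' `A_IS = SASA(A) + SASA(B) - SASA(AB)`: the solvent-accessible surface
#' area lost on complex formation, i.e. the mutually buried surface. It is
#' non-negative and exactly zero once the chains are out of probe contact.
#'
#' @param structure pose tibble (per-model results for ensembles).
#' @param chains length-2 chain ids.
#' @param probe_radius,n_sphere_points,radii passed to
#'   [shrake_rupley_sasa()].
#' @return Tibble `model`, `a_is` (Angstrom^2).
#' @export
interface_area <- function(structure, chains = NULL, probe_radius = 1.4,
                           n_sphere_points = 960, radii = vdw_radii()) {
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  if (chains[1] == chains[2]) abort("chains must be two distinct chain ids")
  purrr::map_dfr(frames(structure), function(fr) {
    ab <- fr[fr$chain %in% chains, , drop = FALSE]
    a <- ab[ab$chain == chains[1], , drop = FALSE]
    b <- ab[ab$chain == chains[2], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) abort("both chains must be present")
    s <- function(x) sum(shrake_rupley_sasa(
      x, probe_radius, n_sphere_points, radii)$area)
    a_is <- s(a) + s(b) - s(ab)
    tibble::tibble(model = fr$model[1], a_is = max(a_is, 0))
  })
}

#' Detect inter-chain hydrogen bonds
#'
#' Geometric criterion: donor and acceptor heavy atoms (N or O, S
#' optional) on different chains within `max_distance`, with the
#' donor-hydrogen-acceptor angle at least `min_angle` for some hydrogen
#' covalently attached to the donor (within 1.25 A). When the structure
#' has no hydrogens, a heavy-atom-only fallback (distance criterion alone)
#' can be enabled.
#'
#' @param structure single-model pose tibble.
#' @param chains length-2 chain ids.
#' @param max_distance donor-acceptor ceiling, Angstrom (default 3.5).
#' @param min_angle D-H-A floor, degrees (default 140).
#' @param elements donor/acceptor element set.
#' @param heavy_only skip the angle test (for hydrogen-free models);
#'   default `FALSE`, and an error is raised if no hydrogens exist.
#' @return Tibble of bonds: donor/acceptor identities, `distance`, `angle`.
#' @export
detect_hbonds <- function(structure, chains = NULL, max_distance = 3.5,
                          min_angle = 140, elements = c("N", "O"),
                          heavy_only = FALSE) {
  if (n_models(structure) > 1) abort("detect_hbonds expects a single model")
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  heavy <- structure[structure$element %in% elements &
                       structure$chain %in% chains, , drop = FALSE]
  hyd <- structure[structure$element == "H" &
                     structure$chain %in% chains, , drop = FALSE]
  if (nrow(hyd) == 0 && !heavy_only) {
    abort("no hydrogens present; set heavy_only = TRUE for a distance-only criterion")
  }
  empty <- tibble::tibble(
    donor_chain = character(0), donor_seq = integer(0),
    donor_name = character(0), acceptor_chain = character(0),
    acceptor_seq = integer(0), acceptor_name = character(0),
    hydrogen = character(0), distance = numeric(0), angle = numeric(0))
  if (nrow(heavy) < 2) return(empty)
  da <- tidyr::expand_grid(i = seq_len(nrow(heavy)), j = seq_len(nrow(heavy)))
  da <- da[heavy$chain[da$i] != heavy$chain[da$j], , drop = FALSE]
  if (nrow(da) == 0) return(empty)
  pi_ <- coords(heavy)[da$i, , drop = FALSE]
  pj_ <- coords(heavy)[da$j, , drop = FALSE]
  dist <- sqrt(rowSums((pi_ - pj_)^2))
  da <- da[dist <= max_distance, , drop = FALSE]
  dist <- dist[dist <= max_distance]
  if (nrow(da) == 0) return(empty)
  rows <- purrr::pmap_dfr(
    list(da$i, da$j, dist), function(i, j, dij) {
      don <- heavy[i, ]; acc <- heavy[j, ]
      if (heavy_only) {
        if (i > j) return(NULL)   # one row per unordered pair
        return(tibble::tibble(
          donor_chain = don$chain, donor_seq = don$residue_seq,
          donor_name = don$name, acceptor_chain = acc$chain,
          acceptor_seq = acc$residue_seq, acceptor_name = acc$name,
          hydrogen = NA_character_, distance = dij, angle = NA_real_))
      }
      hs <- hyd[hyd$chain == don$chain & hyd$residue_seq == don$residue_seq, ]
      if (nrow(hs) == 0) return(NULL)
      dh <- sqrt((hs$x - don$x)^2 + (hs$y - don$y)^2 + (hs$z - don$z)^2)
      hs <- hs[dh <= 1.25, , drop = FALSE]
      if (nrow(hs) == 0) return(NULL)
      v1 <- cbind(don$x - hs$x, don$y - hs$y, don$z - hs$z)
      v2 <- cbind(acc$x - hs$x, acc$y - hs$y, acc$z - hs$z)
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      k <- which.max(ang)
      if (ang[k] < min_angle) return(NULL)
      tibble::tibble(
        donor_chain = don$chain, donor_seq = don$residue_seq,
        donor_name = don$name, acceptor_chain = acc$chain,
        acceptor_seq = acc$residue_seq, acceptor_name = acc$name,
        hydrogen = hs$name[k], distance = dij, angle = ang[k])
    })
  if (nrow(rows) == 0) empty else rows
}

SALT_ANIONIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SALT_CATIONIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                      HIS = c("ND1", "NE2"))

#' Detect occupancy-filtered inter-chain salt bridges
#'
#' A candidate bridge is an (anionic sidechain group, cationic sidechain
#' group) pair on different chains; it is present in a frame iff the
#' minimum distance between the groups' charged heavy atoms is at most
#' `max_distance`. Only bridges present in strictly more than
#' `occupancy_threshold` of the frames are retained — the "more than 10%
#' of frames" convention, with a strict inequality.
#'
#' @param ensemble multi-model pose tibble (a single model counts as one
#'   frame).
#' @param chains length-2 chain ids.
#' @param max_distance Angstrom (default 4.0).
#' @param occupancy_threshold fraction of frames (default 0.10, strict >).
#' @param include_his count histidine ring nitrogens as cationic?
#'   Default `FALSE`.
#' @return Tibble of retained bridges: acidic/basic residue identities,
#'   `n_present`, `occupancy`; all candidates (with occupancy) in the
#'   `candidates` attribute.
#' @export
detect_salt_bridges <- function(ensemble, chains = NULL, max_distance = 4,
                                occupancy_threshold = 0.10,
                                include_his = FALSE) {
  if (is.null(chains)) chains <- utils::head(unique(ensemble$chain), 2)
  cationic <- SALT_CATIONIC
  if (!include_his) cationic$HIS <- NULL
  frs <- frames(ensemble)
  nf <- length(frs)
  group_rows <- function(fr, defs) {
    keep <- rep(FALSE, nrow(fr))
    for (rn in names(defs)) {
      keep <- keep | (fr$residue_name == rn & fr$name %in% defs[[rn]])
    }
    fr[keep & fr$chain %in% chains, , drop = FALSE]
  }
  tally <- list()
  for (fr in frs) {
    an <- group_rows(fr, SALT_ANIONIC)
    ca <- group_rows(fr, cationic)
    if (nrow(an) == 0 || nrow(ca) == 0) next
    grid <- tidyr::expand_grid(i = seq_len(nrow(an)), j = seq_len(nrow(ca)))
    grid <- grid[an$chain[grid$i] != ca$chain[grid$j], , drop = FALSE]
    if (nrow(grid) == 0) next
    pa <- coords(an)[grid$i, , drop = FALSE]
    pb <- coords(ca)[grid$j, , drop = FALSE]
    d <- sqrt(rowSums((pa - pb)^2))
    key <- paste0(an$chain[grid$i], an$residue_seq[grid$i], ":",
                  an$residue_name[grid$i], "|",
                  ca$chain[grid$j], ca$residue_seq[grid$j], ":",
                  ca$residue_name[grid$j])
    present <- tapply(d, key, min) <= max_distance
    for (k in names(present)[present]) {
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  if (length(tally) == 0) {
    out <- tibble::tibble(acidic = character(0), basic = character(0),
                          n_present = integer(0), occupancy = numeric(0))
    attr(out, "candidates") <- out
    attr(out, "n_frames") <- nf
    return(out)
  }
  keys <- sort(names(tally))
  parts <- strsplit(keys, "|", fixed = TRUE)
  n_present <- unname(vapply(keys, function(k) tally[[k]], integer(1)))
  cand <- tibble::tibble(
    acidic = vapply(parts, `[`, character(1), 1),
    basic = vapply(parts, `[`, character(1), 2),
    n_present = n_present,
    occupancy = n_present / nf)
  out <- cand[cand$occupancy > occupancy_threshold, , drop = FALSE]
  attr(out, "candidates") <- cand
  attr(out, "n_frames") <- nf
  out
}

#' Interface metric panel over a dimer ensemble
#'
#' Computes, per frame, the inter-monomer non-bonded interaction energy
#' (van der Waals + electrostatic), the radius of gyration of the complex,
#' the backbone RMSD against a reference frame, the buried interface area
#' and the inter-chain hydrogen-bond count; plus per-atom RMSF and the
#' occupancy-filtered salt-bridge count over the whole ensemble. Per-frame
#' metrics are summarised as mean +/- SD.
#'
#' @param ensemble multi-model two-chain pose tibble.
#' @param chains length-2 chain ids.
#' @param reference_frame model index for the RMSD reference.
#' @param params non-bonded parameter table (default
#'   [default_nonbonded_params()]).
#' @param n_sphere_points SASA lattice size used for the interface area.
#' @param hbond_heavy_only pass `TRUE` for hydrogen-free ensembles.
#' @param rmsf_selection selection for the RMSF (default `"carbon"`).
#' @param salt_max_distance,salt_occupancy salt-bridge criteria.
#' @return Object of class `interface_panel`: list with `summary` (metric,
#'   mean, sd, unit), `per_frame`, `rmsf`, `salt_bridges`, `criteria`.
#'   Supports [tidy()], [glance()], [autoplot()][ggplot2::autoplot].
#' @export
build_interface_panel <- function(ensemble, chains = NULL,
                                  reference_frame = NULL, params = NULL,
                                  n_sphere_points = 960,
                                  hbond_heavy_only = FALSE,
                                  rmsf_selection = "carbon",
                                  salt_max_distance = 4,
                                  salt_occupancy = 0.10) {
  if (is.null(chains)) chains <- utils::head(unique(ensemble$chain), 2)
  if (is.null(params)) params <- default_nonbonded_params(ensemble)
  en <- interaction_energy(ensemble, chains, params)
  rg <- radius_of_gyration(ensemble)
  rs <- rmsd_series(ensemble, reference_frame, selection = "backbone")
  ai <- interface_area(ensemble, chains, n_sphere_points = n_sphere_points)
  hb <- purrr::map_int(frames(ensemble), function(fr) {
    nrow(detect_hbonds(fr, chains, heavy_only = hbond_heavy_only))
  })
  rf <- if (n_models(ensemble) >= 2) rmsf(ensemble, rmsf_selection) else NULL
  sb <- detect_salt_bridges(ensemble, chains, salt_max_distance,
                            salt_occupancy)
  per_frame <- en %>%
    dplyr::left_join(rg, by = "model") %>%
    dplyr::left_join(rs, by = "model") %>%
    dplyr::left_join(ai, by = "model") %>%
    dplyr::mutate(n_hbonds = hb)
  msd <- function(v) c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
  rows <- list(
    e_tot = c(msd(per_frame$e_tot), "kcal/mol"),
    e_vdw = c(msd(per_frame$e_vdw), "kcal/mol"),
    e_elec = c(msd(per_frame$e_elec), "kcal/mol"),
    rg = c(msd(per_frame$rg), "A"),
    rmsd = c(msd(per_frame$rmsd), "A"),
    rmsf = if (is.null(rf)) c(NA_real_, NA_real_, "A")
           else c(attr(rf, "mean"), attr(rf, "sd"), "A"),
    a_is = c(msd(per_frame$a_is), "A^2"),
    hydrogen_bonds = c(msd(per_frame$n_hbonds), "count"),
    salt_bridges = c(nrow(sb), 0, "count"))
  summary <- tibble::tibble(
    metric = names(rows),
    mean = as.numeric(vapply(rows, `[`, character(1), 1)),
    sd = as.numeric(vapply(rows, `[`, character(1), 2)),
    unit = vapply(rows, `[`, character(1), 3))
  structure(
    list(summary = summary, per_frame = per_frame, rmsf = rf,
         salt_bridges = sb,
         criteria = list(chains = chains,
                         n_frames = n_models(ensemble),
                         n_sphere_points = n_sphere_points,
                         hbond = list(max_distance = 3.5, min_angle = 140,
                                      heavy_only = hbond_heavy_only),
                         salt = list(max_distance = salt_max_distance,
                                     occupancy = salt_occupancy))),
    class = "interface_panel")
}

#' @export
print.interface_panel <- function(x, ...) {
  cat("Interface panel over", x$criteria$n_frames, "frame(s), chains",
      paste(x$criteria$chains, collapse = "-"), "\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @rdname build_interface_panel
#' @param x an `interface_panel`.
#' @param ... unused.
#' @method tidy interface_panel
#' @export
tidy.interface_panel <- function(x, ...) x$summary

#' @rdname build_interface_panel
#' @method glance interface_panel
#' @export
glance.interface_panel <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  tibble::as_tibble(wide) %>%
    dplyr::mutate(n_frames = x$criteria$n_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
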