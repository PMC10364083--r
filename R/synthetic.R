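# Sidechain atom chains used by the idealized builders. Branched residues
# are laid out as a zigzag chain: only atom counts/elements (hence surface
# areas) matter for the reference fixtures, not rotamer realism.
SIDECHAIN_ATOMS <- list(
  GLY = character(0),
  ALA = "CB",
  SER = c("CB", "OG"),
  CYS = c("CB", "SG"),
  THR = c("CB", "OG1", "CG2"),
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "SD", "CE"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2")
)

# run code under a temporary RNG state so generators are pure in their seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# zigzag chain of sidechain atoms growing from `origin` along unit `dir`
sidechain_positions <- function(n, origin, dir) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  perp <- c(dir[2], -dir[1], 0)
  if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  t(vapply(seq_len(n), function(k) {
    origin + dir * (1.3 * k) + perp * (0.55 * (k %% 2))
  }, numeric(3)))
}

#' Build an idealized alpha-helix monomer fixture
#'
#' A toy single-chain monomer on ideal helix geometry (rise 1.5 A, 100
#' degrees per residue, Ca radius 2.3 A), with alanine sidechains except
#' at caller-placed cysteines, lysines, aspartates. Surface cysteines
#' point their sidechain radially outward; buried cysteines additionally
#' receive a shell of dummy shield atoms (HETATM residue `SHL`) that
#' blocks the probe, so their SASA is close to zero. Cysteines carry CB,
#' SG and the thiol hydrogen HG; backbone amide hydrogens are included so
#' hydrogen-bond detection has donors.
#'
#' @param helix_length residues.
#' @param cys_positions,lys_positions,asp_positions residue indices (1-based).
#' @param buried_cys logical vector parallel to `cys_positions` (default
#'   all surface).
#' @param chain chain id (default `"A"`).
#' @return Single-model structure tibble.
#' @export
make_helix_monomer <- function(helix_length = 20, cys_positions = integer(0),
                               lys_positions = integer(0),
                               asp_positions = integer(0),
                               buried_cys = rep(FALSE, length(cys_positions)),
                               chain = "A") {
  pos <- c(cys_positions, lys_positions, asp_positions)
  if (any(pos < 1 | pos > helix_length)) {
    abort("residue placements outside [1, helix_length]")
  }
  if (anyDuplicated(pos)) abort("overlapping residue placements")
  if (length(buried_cys) != length(cys_positions)) {
    abort("buried_cys must parallel cys_positions")
  }
  rows <- list()
  add <- function(name, el, resn, seq, p, record = "ATOM") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      record = record, name = name, element = el, residue_name = resn,
      residue_seq = as.integer(seq), chain = chain,
      x = p[1], y = p[2], z = p[3])
  }
  r_ca <- 2.3
  for (i in seq_len(helix_length)) {
    th <- (i - 1) * 100 * pi / 180
    zi <- (i - 1) * 1.5
    resn <- if (i %in% cys_positions) "CYS"
            else if (i %in% lys_positions) "LYS"
            else if (i %in% asp_positions) "ASP"
            else "ALA"
    ca <- c(r_ca * cos(th), r_ca * sin(th), zi)
    nth <- th - 28 * pi / 180; cth <- th + 28 * pi / 180
    npos <- c(1.7 * cos(nth), 1.7 * sin(nth), zi - 0.45)
    cpos <- c(1.7 * cos(cth), 1.7 * sin(cth), zi + 0.45)
    opos <- cpos + c(0.4 * cos(cth), 0.4 * sin(cth), 1.1)
    add("N", "N", resn, i, npos)
    add("HN", "H", resn, i, npos + c(0.6 * cos(nth), 0.6 * sin(nth), -0.8))
    add("CA", "C", resn, i, ca)
    add("C", "C", resn, i, cpos)
    add("O", "O", resn, i, opos)
    out_dir <- c(cos(th), sin(th), 0)
    sc <- SIDECHAIN_ATOMS[[resn]]
    if (length(sc) > 0) {
      sp <- sidechain_positions(length(sc), ca, out_dir)
      for (k in seq_along(sc)) {
        add(sc[k], guess_element(sc[k]), resn, i, sp[k, ])
      }
      if (resn == "CYS") {
        sg <- sp[which(sc == "SG"), ]
        add("HG", "H", resn, i, sg + out_dir * 1.34)
      }
    }
  }
  # shield shells for buried cysteines
  shl_seq <- 9000L
  for (k in seq_along(cys_positions)) {
    if (!buried_cys[k]) next
    i <- cys_positions[k]
    cy <- do.call(rbind, rows)
    sg <- cy[cy$residue_seq == i & cy$name == "SG", ]
    centre <- c(sg$x, sg$y, sg$z)
    shell <- sweep(sphere_lattice(32) * 3.2, 2, centre, "+")
    # drop shell points that would collide with the protein itself — the
    # protein already blocks the probe there
    exist <- cbind(cy$x, cy$y, cy$z)
    keep <- vapply(seq_len(nrow(shell)), function(s) {
      min(sqrt(rowSums(sweep(exist, 2, shell[s, ])^2))) >= 0.9
    }, logical(1))
    for (s in which(keep)) {
      add(paste0("C", s), "C", "SHL", shl_seq, shell[s, ],
          record = "HETATM")
    }
    shl_seq <- shl_seq + 1L
  }
  atoms <- dplyr::bind_rows(rows)
  d <- stats::dist(cbind(atoms$x, atoms$y, atoms$z))
  if (min(d) < 0.5) abort("overlapping atom placements in fixture geometry")
  as_structure(atoms, title = "idealized helix monomer fixture")
}

min_ss_of_pose <- function(pose, atom = "SG") {
  pr <- inter_cys_distances(pose, distance_atom = atom)
  if (nrow(pr) == 0) return(NA_real_)
  pr$distance[1]
}

#' Build a homodimer pose with a prescribed minimum S-S distance
#'
#' Places a second copy of the monomer (chain `B`) by a rigid motion such
#' that the minimum inter-chain Sg-Sg distance equals `target_ss` to
#' within 0.01 A. In C2 mode the copy is a 180-degree rotation about an
#' axis parallel to the helix axis placed just outside the designated
#' cysteine, so the pose is exactly two-fold symmetric; otherwise the copy
#' is translated radially outward.
#'
#' @param monomer single-chain structure from [make_helix_monomer()].
#' @param target_ss Angstrom.
#' @param c2 build an exactly C2-symmetric pose? Default `TRUE`.
#' @param target_cys residue index of the cysteine to aim at (default the
#'   first cysteine).
#' @return Two-chain structure tibble (chains `A`, `B`).
#' @export
make_dimer_pose <- function(monomer, target_ss, c2 = TRUE,
                            target_cys = NULL) {
  cys <- monomer[monomer$residue_name == "CYS" & monomer$name == "SG", ]
  if (nrow(cys) == 0) abort("monomer has no cysteine with SG")
  if (is.null(target_cys)) target_cys <- cys$residue_seq[1]
  sg <- cys[cys$residue_seq == target_cys, ]
  if (nrow(sg) == 0) abort("target_cys has no SG atom")
  sg_xy <- c(sg$x[1], sg$y[1])
  cen_xy <- c(mean(monomer$x), mean(monomer$y))
  u <- sg_xy - cen_xy
  u <- u / sqrt(sum(u^2))

  build <- function(t) {
    b <- monomer
    p <- sg_xy + u * t             # axis point; SG-image distance = 2t
    b$x <- 2 * p[1] - monomer$x
    b$y <- 2 * p[2] - monomer$y
    # non-C2: a 1 A shift along the helix axis turns the two-fold rotation
    # into a screw motion, breaking the symmetry without causing clashes
    if (!c2) b$z <- b$z + 1
    b$chain <- "B"
    pose <- dplyr::bind_rows(monomer, b)
    as_structure(pose, title = "synthetic homodimer pose")
  }
  f <- function(t) min_ss_of_pose(build(t)) - target_ss
  lo <- 0.05
  hi <- target_ss / 2 + 30
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-4)
  pose <- build(root$root)
  heavy <- pose[pose$element != "H", ]
  a <- coords(heavy[heavy$chain == "A", ]); b <- coords(heavy[heavy$chain == "B", ])
  mind <- sqrt(max(0, min(outer(rowSums(a^2), rowSums(b^2), "+") -
                            2 * a %*% t(b))))
  if (!is.finite(mind) || mind < 1.0) {
    abort("infeasible target_ss: chains clash below the hard-sphere limit")
  }
  pose
}

#' Synthesize a multi-frame ensemble with prescribed jitter and contacts
#'
#' Stand-in for a simulation trajectory: `n_frames` copies of the pose
#' with i.i.d. isotropic Gaussian jitter of standard deviation
#' `jitter_sigma` per atom coordinate, fully determined by `seed`. Each
#' scheduled salt-bridge contact (an Asp residue on one chain, a Lys on
#' the other) is placed within `contact_distance` in exactly
#' `round(occupancy * n_frames)` frames (deterministic stride assignment,
#' so occupancies are exact, never Bernoulli-noisy) and at
#' `apart_distance` otherwise; the participating sidechain atoms are
#' exempt from jitter so the schedule is honoured exactly.
#'
#' @param pose single-model structure tibble.
#' @param n_frames number of frames.
#' @param jitter_sigma Angstrom (default 0.3, an equilibrated-backbone
#'   fluctuation scale).
#' @param schedule optional tibble `chain_acid, seq_acid, chain_base,
#'   seq_base, occupancy` (Lys on the basic side).
#' @param seed integer; fixes all randomness.
#' @param contact_distance,apart_distance Angstrom.
#' @return Multi-model structure tibble with `n_frames` models.
#' @export
synthesize_trajectory <- function(pose, n_frames = 50, jitter_sigma = 0.3,
                                  schedule = NULL, seed = 1,
                                  contact_distance = 3.5,
                                  apart_distance = 8) {
  if (n_models(pose) > 1) abort("pose must be a single model")
  n_atoms <- nrow(pose)
  fixed <- rep(FALSE, n_atoms)
  sched <- NULL
  if (!is.null(schedule) && nrow(schedule) > 0) {
    sched <- purrr::pmap(schedule, function(chain_acid, seq_acid, chain_base,
                                            seq_base, occupancy, ...) {
      acid_idx <- which(pose$chain == chain_acid &
                          pose$residue_seq == seq_acid &
                          pose$name %in% c("OD1", "OD2", "OE1", "OE2"))
      base_sc <- which(pose$chain == chain_base &
                         pose$residue_seq == seq_base &
                         pose$name %in% SIDECHAIN_ATOMS$LYS)
      nz <- which(pose$chain == chain_base & pose$residue_seq == seq_base &
                    pose$name == "NZ")
      if (length(acid_idx) == 0 || length(nz) == 0) {
        abort(paste0("occupancy schedule references absent atoms (",
                     chain_acid, seq_acid, " / ", chain_base, seq_base, ")"))
      }
      k <- round(occupancy * n_frames)
      contact_frames <- if (k > 0) ((seq_len(k) - 1) * (n_frames %/% k)) + 1
                        else integer(0)
      fixed[acid_idx] <<- TRUE
      fixed[base_sc] <<- TRUE
      fixed[nz] <<- TRUE
      list(acid_idx = acid_idx, base_sc = base_sc, nz = nz,
           contact_frames = contact_frames)
    })
  }
  base_xyz <- coords(pose)
  with_seed(seed, {
    frames_list <- lapply(seq_len(n_frames), function(f) {
      fr <- pose
      fr$model <- f
      xyz <- base_xyz
      if (jitter_sigma > 0) {
        noise <- matrix(stats::rnorm(3 * n_atoms, 0, jitter_sigma),
                        ncol = 3)
        noise[fixed, ] <- 0
        xyz <- xyz + noise
      }
      if (!is.null(sched)) {
        for (sc in sched) {
          target <- if (f %in% sc$contact_frames) contact_distance
                    else apart_distance
          nz0 <- base_xyz[sc$nz, ]
          acid <- base_xyz[sc$acid_idx, , drop = FALSE]
          dists <- sqrt(rowSums(sweep(acid, 2, nz0)^2))
          a_star <- acid[which.min(dists), ]
          u <- nz0 - a_star
          u <- u / sqrt(sum(u^2))
          shift <- (a_star + u * target) - nz0
          xyz[sc$base_sc, ] <- sweep(base_xyz[sc$base_sc, , drop = FALSE],
                                     2, shift, "+")
          xyz[sc$acid_idx, ] <- acid
        }
      }
      set_coords(fr, xyz)
    })
    as_structure(dplyr::bind_rows(frames_list), title = attr(pose, "title"))
  })
}

#' Build an idealized Gly-X-Gly tripeptide
#'
#' Extended backbone (3.8 A Ca-Ca spacing) with the template sidechain
#' for the central residue X; the reference conformer for maximum-SASA
#' normalisation.
#'
#' @param residue 3-letter code of X.
#' @param conformation only `"extended"` is provided.
#' @return Single-model structure tibble with 3 residues.
#' @export
make_tripeptide <- function(residue, conformation = "extended") {
  residue <- toupper(residue)
  if (!residue %in% names(SIDECHAIN_ATOMS)) {
    abort(paste0("unknown residue code '", residue, "'"))
  }
  conformation <- match.arg(conformation, "extended")
  resnames <- c("GLY", residue, "GLY")
  rows <- list()
  add <- function(name, el, resn, seq, p) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      record = "ATOM", name = name, element = el, residue_name = resn,
      residue_seq = as.integer(seq), chain = "A",
      x = p[1], y = p[2], z = p[3])
  }
  for (i in 1:3) {
    resn <- resnames[i]
    x0 <- (i - 1) * 3.8
    flip <- if (i %% 2 == 0) -1 else 1
    ca <- c(x0, 0, 0)
    add("N", "N", resn, i, c(x0 - 1.3, 0.5 * flip, 0))
    add("CA", "C", resn, i, ca)
    add("C", "C", resn, i, c(x0 + 1.3, 0.5 * flip, 0))
    add("O", "O", resn, i, c(x0 + 1.4, 1.2 * flip, 0.9))
    sc <- SIDECHAIN_ATOMS[[resn]]
    if (length(sc) > 0) {
      sp <- sidechain_positions(length(sc), ca, c(0, -flip, 0))
      for (k in seq_along(sc)) {
        add(sc[k], guess_element(sc[k]), resn, i, sp[k, ])
      }
      if (resn == "CYS") {
        sg <- sp[which(sc == "SG"), ]
        add("HG", "H", resn, i, sg + c(0, -flip * 1.34, 0))
      }
    }
  }
  as_structure(dplyr::bind_rows(rows),
               title = paste0("Gly-", residue, "-Gly extended tripeptide"))
}

pkg_cache <- new.env(parent = emptyenv())

#' Default maximum-SASA reference table
#'
#' The 20 standard residues' MSA values computed from the idealized
#' extended Gly-X-Gly tripeptides of [make_tripeptide()] (one conformer
#' each, so `max` and `mean` coincide). Cached per lattice size.
#'
#' @param n_sphere_points SASA lattice size.
#' @return MSA tibble (see [compute_msa_reference()]).
#' @export
default_msa_table <- function(n_sphere_points = 960) {
  key <- paste0("msa_", n_sphere_points)
  if (!is.null(pkg_cache[[key]])) return(pkg_cache[[key]])
  tps <- stats::setNames(lapply(names(SIDECHAIN_ATOMS), make_tripeptide),
                         names(SIDECHAIN_ATOMS))
  msa <- compute_msa_reference(tps, n_sphere_points = n_sphere_points)
  pkg_cache[[key]] <- msa
  msa
}

#' Generate a synthetic Ellman (DTNB) dataset
#'
#' Calibration series (absorbance = slope x concentration + Gaussian
#' noise) over the standard 0-30 uM free-cysteine design, plus sample
#' absorbances generated from known accessible-cysteine counts:
#' `E = slope * N_Cys * c_protein (+ noise)`.
#'
#' @param true_slope absorbance per uM.
#' @param noise_sigma absorbance noise SD.
#' @param concentrations calibration concentrations, uM.
#' @param true_ncys named vector of true accessible-cysteine counts.
#' @param protein_conc protein concentration, uM.
#' @param seed integer.
#' @return List with `calibration` (tibble `concentration`, `absorbance`)
#'   and `samples` (tibble `sample`, `true_ncys`, `protein_conc`, `E`).
#' @export
make_ellman_dataset <- function(true_slope = 0.012, noise_sigma = 0,
                                concentrations = c(0, 5, 10, 15, 20, 25, 30),
                                true_ncys = c(WT = 5), protein_conc = 5,
                                seed = 1) {
  if (true_slope <= 0) abort("true_slope must be positive")
  with_seed(seed, {
    calib <- tibble::tibble(
      concentration = concentrations,
      absorbance = true_slope * concentrations +
        stats::rnorm(length(concentrations), 0, noise_sigma))
    samples <- tibble::tibble(
      sample = names(true_ncys) %||% as.character(seq_along(true_ncys)),
      true_ncys = unname(true_ncys),
      protein_conc = protein_conc,
      E = true_slope * unname(true_ncys) * protein_conc +
        stats::rnorm(length(true_ncys), 0, noise_sigma))
    list(calibration = calib, samples = samples)
  })
}
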