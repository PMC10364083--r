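#' Default van der Waals radii
#'
#' Element-keyed van der Waals radii (Bondi-type values, Angstrom) used by
#' the solvent-accessible surface area engine. Hydrogens are excluded from
#' SASA by default, mirroring common heavy-atom SASA conventions, but a
#' hydrogen radius is provided for callers who include them.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, FE = 1.40, ZN = 1.39, MG = 1.73,
    `NA` = 2.27, CA = 2.31)
}

# Deterministic quasi-uniform unit-sphere lattice (golden-spiral).
# No randomness: SASA is reproducible without seeds.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing, for each
#' atom, a deterministic golden-spiral lattice of points on its extended
#' sphere (radius + probe) against the extended spheres of its neighbours.
#'
#' @param structure structure tibble (single model).
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points lattice points per atom (default 960; at least 32).
#' @param radii named vector mapping element symbols to van der Waals radii.
#' @param include_hydrogens include hydrogen atoms in the calculation?
#'   Default `FALSE` (heavy-atom SASA).
#' @return The atom tibble restricted to the atoms considered, with an
#'   `area` column (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_sphere_points = 960,
                               radii = vdw_radii(),
                               include_hydrogens = FALSE) {
  if (n_sphere_points < 32) {
    abort("n_sphere_points < 32 is below the accuracy floor; refusing")
  }
  if (n_models(structure) > 1) {
    abort("shrake_rupley_sasa expects a single-model structure; map over frames() for ensembles")
  }
  s <- structure
  if (!include_hydrogens) s <- s[s$element != "H", , drop = FALSE]
  if (nrow(s) == 0) abort("no atoms to compute SASA for")
  el <- toupper(s$element)
  unmapped <- setdiff(unique(el), names(radii))
  if (length(unmapped) > 0) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unmapped, collapse = ", ")))
  }
  r_ext <- unname(radii[el]) + probe_radius
  xyz <- coords(s)
  n <- nrow(xyz)
  pts <- sphere_lattice(n_sphere_points)

  # neighbour lists from the pairwise distance matrix (fixtures are small;
  # the n^2 matrix is fine at these sizes)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (r_ext[i] + r_ext)^2
    nb <- which(d2[i, ] < cutoff2)
    nb <- nb[nb != i]
    p <- pts * r_ext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(acc)) break
        dx <- p[acc, 1, drop = TRUE] - xyz[j, 1]
        dy <- p[acc, 2, drop = TRUE] - xyz[j, 2]
        dz <- p[acc, 3, drop = TRUE] - xyz[j, 3]
        acc[acc] <- dx * dx + dy * dy + dz * dz > r_ext[j]^2
      }
      n_acc <- sum(acc)
    } else {
      n_acc <- n_sphere_points
    }
    area[i] <- 4 * pi * r_ext[i]^2 * n_acc / n_sphere_points
  }
  s$area <- area
  s
}

# Sidechain membership: everything outside the peptide backbone. CA counts
# as sidechain for glycine only (the usual relative-accessibility
# convention, so glycine has a non-empty "sidechain").
is_sidechain_atom <- function(name, residue_name, element) {
  bb <- name %in% c("N", "CA", "C", "O", "OXT") |
    (element == "H" & name %in% c("H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN"))
  sc <- !bb
  sc[residue_name == "GLY" & name == "CA"] <- TRUE
  sc
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Per-residue SASA aggregation of a per-atom SASA table.
aggregate_residue_sasa <- function(sasa_atoms) {
  sasa_atoms %>%
    dplyr::mutate(sidechain = is_sidechain_atom(
      .data$name, .data$residue_name, .data$element)) %>%
    dplyr::group_by(.data$chain, .data$residue_seq, .data$residue_name) %>%
    dplyr::summarise(
      sasa_total = sum(.data$area),
      sasa_sidechain = sum(.data$area[.data$sidechain]),
      .groups = "drop"
    )
}

#' Maximum-SASA reference table from Gly-X-Gly tripeptides
#'
#' Computes, for each supplied residue type X, the reference SASA of X in a
#' Gly-X-Gly tripeptide over a conformer ensemble — the normalisation
#' denominator of the relative-exposure calculation. `mode = "max"` takes
#' the maximum over conformers (the default, matching a "maximum SASA"
#' reference); `"mean"` is offered for sensitivity analysis.
#'
#' @param tripeptides named list (names = 3-letter codes) of Gly-X-Gly
#'   structure tibbles, possibly multi-model.
#' @param mode `"max"` or `"mean"` over conformers.
#' @param probe_radius,n_sphere_points,radii passed to [shrake_rupley_sasa()].
#' @return Tibble with columns `residue_name`, `msa_total`, `msa_sidechain`,
#'   `n_conformers` (areas in Angstrom^2, all strictly positive).
#' @export
compute_msa_reference <- function(tripeptides, mode = c("max", "mean"),
                                  probe_radius = 1.4, n_sphere_points = 960,
                                  radii = vdw_radii()) {
  mode <- match.arg(mode)
  agg <- if (mode == "max") max else mean
  purrr::imap_dfr(tripeptides, function(tp, code) {
    per_frame <- purrr::map_dfr(frames(tp), function(fr) {
      res <- fr %>%
        dplyr::distinct(.data$residue_seq, .data$residue_name) %>%
        dplyr::arrange(.data$residue_seq)
      if (nrow(res) != 3 || res$residue_name[1] != "GLY" ||
          res$residue_name[3] != "GLY" || res$residue_name[2] != code) {
        abort(paste0("tripeptide for '", code,
                     "' is not a Gly-", code, "-Gly sequence"))
      }
      sa <- shrake_rupley_sasa(fr, probe_radius, n_sphere_points, radii)
      aggregate_residue_sasa(sa) %>%
        dplyr::filter(.data$residue_seq == res$residue_seq[2])
    })
    tibble::tibble(
      residue_name = code,
      msa_total = agg(per_frame$sasa_total),
      msa_sidechain = agg(per_frame$sasa_sidechain),
      n_conformers = nrow(per_frame)
    )
  })
}

#' Per-residue solvent exposure relative to the Gly-X-Gly maximum
#'
#' Exposure of residue i is `100 * SASA_i / MSA_i` where MSA is the
#' maximum-SASA reference for that residue type. Values above 100% are
#' possible (a conformation can expose more surface than the tripeptide
#' reference); they are flagged in the `over_reference` column, never
#' clamped.
#'
#' @param structure single-model structure tibble.
#' @param msa MSA reference table from [compute_msa_reference()] (or
#'   [default_msa_table()]).
#' @param scope `"sidechain"` (default; matches sidechain-accessibility
#'   reporting) or `"whole_residue"`.
#' @param probe_radius,n_sphere_points,radii passed to [shrake_rupley_sasa()].
#' @param sasa optional precomputed per-atom SASA table (output of
#'   [shrake_rupley_sasa()]) to avoid recomputation.
#' @return Exposure profile tibble: `chain`, `residue_seq`, `residue_name`,
#'   `sasa_abs`, `msa`, `exposure_pct`, `over_reference`, plus an
#'   `n_frames` attribute (1 here). Non-standard residues (cofactors,
#'   shield dummies, waters) are skipped; a standard residue missing from
#'   `msa` is an error.
#' @export
residue_exposure <- function(structure, msa,
                             scope = c("sidechain", "whole_residue"),
                             probe_radius = 1.4, n_sphere_points = 960,
                             radii = vdw_radii(), sasa = NULL) {
  scope <- match.arg(scope)
  if (is.null(sasa)) {
    sasa <- shrake_rupley_sasa(structure, probe_radius, n_sphere_points, radii)
  }
  res <- aggregate_residue_sasa(sasa) %>%
    dplyr::filter(.data$residue_name %in% STANDARD_AA)
  missing_msa <- setdiff(unique(res$residue_name), msa$residue_name)
  if (length(missing_msa) > 0) {
    abort(paste0("MSA reference lacks residue type(s): ",
                 paste(missing_msa, collapse = ", ")))
  }
  msa_col <- if (scope == "sidechain") "msa_sidechain" else "msa_total"
  sasa_col <- if (scope == "sidechain") "sasa_sidechain" else "sasa_total"
  out <- res %>%
    dplyr::left_join(msa[, c("residue_name", msa_col)], by = "residue_name") %>%
    dplyr::mutate(
      sasa_abs = .data[[sasa_col]],
      msa = .data[[msa_col]],
      exposure_pct = 100 * .data$sasa_abs / .data$msa,
      over_reference = .data$exposure_pct > 100
    ) %>%
    dplyr::select("chain", "residue_seq", "residue_name",
                  "sasa_abs", "msa", "exposure_pct", "over_reference") %>%
    dplyr::arrange(.data$chain, .data$residue_seq)
  attr(out, "n_frames") <- 1L
  attr(out, "scope") <- scope
  out
}

#' Frame-averaged exposure over an ensemble
#'
#' Computes the exposure profile per frame and then averages per residue
#' (exposure first, mean second). The alternative order — average the SASA
#' over frames, then divide by MSA — is available via
#' `average = "sasa_first"`; for a fixed MSA denominator the two orders
#' agree, but they are both provided for transparency.
#'
#' @param ensemble multi-model structure tibble.
#' @param msa,scope,probe_radius,n_sphere_points,radii as in
#'   [residue_exposure()].
#' @param average `"exposure_first"` (default) or `"sasa_first"`.
#' @return Exposure profile tibble with `exposure_sd` and an `n_frames`
#'   attribute.
#' @export
time_average_exposure <- function(ensemble, msa,
                                  scope = c("sidechain", "whole_residue"),
                                  probe_radius = 1.4, n_sphere_points = 960,
                                  radii = vdw_radii(),
                                  average = c("exposure_first", "sasa_first")) {
  scope <- match.arg(scope)
  average <- match.arg(average)
  profs <- purrr::map_dfr(frames(ensemble), function(fr) {
    residue_exposure(fr, msa, scope, probe_radius, n_sphere_points, radii)
  })
  nf <- n_models(ensemble)
  out <- profs %>%
    dplyr::group_by(.data$chain, .data$residue_seq, .data$residue_name) %>%
    dplyr::summarise(
      msa = .data$msa[1],
      exposure_sd = stats::sd(.data$exposure_pct),
      exposure_pct = if (average == "exposure_first") mean(.data$exposure_pct)
                     else 100 * mean(.data$sasa_abs) / .data$msa[1],
      sasa_abs = mean(.data$sasa_abs),
      .groups = "drop"
    ) %>%
    dplyr::mutate(over_reference = .data$exposure_pct > 100) %>%
    dplyr::select("chain", "residue_seq", "residue_name", "sasa_abs",
                  "msa", "exposure_pct", "exposure_sd", "over_reference") %>%
    dplyr::arrange(.data$chain, .data$residue_seq)
  attr(out, "n_frames") <- nf
  attr(out, "scope") <- scope
  out
}

#' Classify cysteines by solvent exposure
#'
#' Partitions the cysteines of an exposure profile into exposed
#' (exposure strictly greater than `exposed_threshold`), buried (strictly
#' less than `buried_threshold`) and intermediate (everything else,
#' including values exactly at a threshold). Defaults follow the 20% / 7%
#' sidechain-accessibility bands used to pick disulfide-candidate
#' cysteines.
#'
#' @param profile exposure profile tibble from [residue_exposure()] or
#'   [time_average_exposure()].
#' @param exposed_threshold,buried_threshold percentages; must satisfy
#'   `buried_threshold <= exposed_threshold`.
#' @return The cysteine rows with a `class` factor
#'   (`exposed`/`intermediate`/`buried`), ordered by class then descending
#'   exposure.
#' @export
classify_cysteines <- function(profile, exposed_threshold = 20,
                               buried_threshold = 7) {
  if (buried_threshold > exposed_threshold) {
    abort("buried_threshold must not exceed exposed_threshold")
  }
  cys <- profile[profile$residue_name == "CYS", , drop = FALSE]
  cls <- ifelse(cys$exposure_pct > exposed_threshold, "exposed",
         ifelse(cys$exposure_pct < buried_threshold, "buried", "intermediate"))
  cys$class <- factor(cls, levels = c("exposed", "intermediate", "buried"))
  cys %>% dplyr::arrange(.data$class, dplyr::desc(.data$exposure_pct))
}
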