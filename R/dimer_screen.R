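#' Inter-monomer cysteine distance table
#'
#' Enumerates every cross-chain cysteine pair and the Euclidean distance
#' between the configured distance atoms (sulfur Sg by default; Cb for
#' models lacking sidechain detail).
#'
#' @param structure single-model structure tibble containing both chains.
#' @param chains length-2 character vector of chain ids (default the first
#'   two chains present).
#' @param distance_atom `"SG"` or `"CB"`.
#' @return Tibble `chain_a, seq_a, chain_b, seq_b, distance` sorted by
#'   ascending distance (stable for ties).
#' @export
inter_cys_distances <- function(structure, chains = NULL,
                                distance_atom = c("SG", "CB")) {
  distance_atom <- match.arg(distance_atom)
  if (n_models(structure) > 1) {
    abort("inter_cys_distances expects a single-model pose")
  }
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  if (length(chains) != 2) abort("exactly two chain ids required")
  cys_atoms <- function(cid) {
    ch <- chain_atoms(structure, cid)
    cys <- ch[ch$residue_name == "CYS", , drop = FALSE]
    have <- cys[cys$name == distance_atom, , drop = FALSE]
    lacking <- setdiff(unique(cys$residue_seq), have$residue_seq)
    if (length(lacking) > 0) {
      abort(paste0("cysteine(s) ", paste0(cid, lacking, collapse = ", "),
                   " lack the ", distance_atom, " atom"))
    }
    have
  }
  a <- cys_atoms(chains[1])
  b <- cys_atoms(chains[2])
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(chain_a = character(0), seq_a = integer(0),
                          chain_b = character(0), seq_b = integer(0),
                          distance = numeric(0)))
  }
  grid <- tidyr::expand_grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  pa <- coords(a)[grid$ia, , drop = FALSE]
  pb <- coords(b)[grid$ib, , drop = FALSE]
  tibble::tibble(
    chain_a = a$chain[grid$ia], seq_a = a$residue_seq[grid$ia],
    chain_b = b$chain[grid$ib], seq_b = b$residue_seq[grid$ib],
    distance = sqrt(rowSums((pa - pb)^2))
  ) %>%
    dplyr::arrange(.data$distance)
}

#' Screen a homodimer pose for disulfide feasibility
#'
#' Three-band verdict on the minimum inter-monomer S-S distance:
#' `candidate` when `min_ss <= select_cutoff` (default 6 A, the
#' close-contact criterion for possible intermolecular disulfides),
#' `rejected` when `min_ss > reject_cutoff` (default 10 A, beyond which
#' poses are not worth pursuing), and `marginal` in between (such poses
#' can sometimes be rescued by restrained refinement, which is outside
#' this package's scope — they are flagged for the user).
#'
#' @param structure single- or multi-model two-chain pose tibble; each
#'   model is screened as one pose.
#' @param chains length-2 chain ids (default first two present).
#' @param select_cutoff,reject_cutoff Angstrom;
#'   `select_cutoff <= reject_cutoff`.
#' @param distance_atom `"SG"` (default) or `"CB"`.
#' @return One row per model: `model`, `min_ss`, `best_pair`, `n_pairs`,
#'   `verdict` (ordered factor candidate < marginal < rejected), `reason`;
#'   the full pair table is kept in the list-column `cys_pairs`.
#' @export
screen_pose <- function(structure, chains = NULL,
                        select_cutoff = 6, reject_cutoff = 10,
                        distance_atom = c("SG", "CB")) {
  distance_atom <- match.arg(distance_atom)
  if (select_cutoff > reject_cutoff) {
    abort("select_cutoff must not exceed reject_cutoff")
  }
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  purrr::map_dfr(frames(structure), function(fr) {
    pairs <- inter_cys_distances(fr, chains, distance_atom)
    if (nrow(pairs) == 0) {
      return(tibble::tibble(
        model = fr$model[1], min_ss = NA_real_, best_pair = NA_character_,
        n_pairs = 0L,
        verdict = factor("rejected",
                         levels = c("candidate", "marginal", "rejected")),
        reason = "no cysteine pairs", cys_pairs = list(pairs)))
    }
    min_ss <- pairs$distance[1]
    verdict <- if (min_ss <= select_cutoff) "candidate"
               else if (min_ss > reject_cutoff) "rejected"
               else "marginal"
    tibble::tibble(
      model = fr$model[1],
      min_ss = min_ss,
      best_pair = paste0(pairs$chain_a[1], pairs$seq_a[1], "-",
                         pairs$chain_b[1], pairs$seq_b[1]),
      n_pairs = nrow(pairs),
      verdict = factor(verdict,
                       levels = c("candidate", "marginal", "rejected")),
      reason = paste0("min S-S ", formatC(min_ss, format = "f", digits = 2),
                      " A"),
      cys_pairs = list(pairs))
  })
}

#' Rank screened poses
#'
#' Orders a table of screened poses by verdict class (candidate, marginal,
#' rejected) and, within a class, by ascending minimum S-S distance; the
#' sort is stable for ties.
#'
#' @param poses tibble as returned by [screen_pose()] (possibly row-bound
#'   over many poses, e.g. with a `pose_id` column).
#' @return The same tibble, reordered.
#' @export
rank_poses <- function(poses) {
  dplyr::arrange(poses, .data$verdict, .data$min_ss)
}

#' Form an in-silico disulfide bond
#'
#' Mimics covalent-dimer construction: the thiol hydrogens (HG) of the two
#' cysteines are removed and an S-S bond record is stored (emitted as an
#' SSBOND header by [write_pdb()]). Coordinates are otherwise untouched —
#' geometric relaxation of the (typically abnormally long) new bond is a
#' simulation engine's job, not this package's.
#'
#' @param structure structure tibble.
#' @param chain_a,seq_a,chain_b,seq_b the two cysteines.
#' @return The structure minus the two HG atoms, with the bond appended to
#'   the `ssbonds` attribute (tibble `chain_a, seq_a, chain_b, seq_b,
#'   distance`).
#' @export
form_disulfide <- function(structure, chain_a, seq_a, chain_b, seq_b) {
  pick <- function(cid, seq) {
    r <- structure[structure$chain == cid & structure$residue_seq == seq, ]
    if (nrow(r) == 0) abort(paste0("residue ", cid, seq, " not found"))
    if (any(r$residue_name != "CYS")) {
      abort(paste0("residue ", cid, seq, " is ", r$residue_name[1],
                   ", not CYS"))
    }
    if (!any(r$name == "SG")) abort(paste0("cysteine ", cid, seq, " lacks SG"))
    r
  }
  ra <- pick(chain_a, seq_a)
  rb <- pick(chain_b, seq_b)
  ss <- attr(structure, "ssbonds")
  if (!is.null(ss) && nrow(ss) > 0) {
    dup <- any((ss$chain_a == chain_a & ss$seq_a == seq_a &
                  ss$chain_b == chain_b & ss$seq_b == seq_b) |
               (ss$chain_a == chain_b & ss$seq_a == seq_b &
                  ss$chain_b == chain_a & ss$seq_b == seq_a))
    if (dup) abort("disulfide already recorded for this cysteine pair")
  }
  sg_a <- ra[ra$name == "SG", ][1, ]
  sg_b <- rb[rb$name == "SG", ][1, ]
  dist <- sqrt(sum((c(sg_a$x, sg_a$y, sg_a$z) - c(sg_b$x, sg_b$y, sg_b$z))^2))
  drop_hg <- (structure$chain == chain_a & structure$residue_seq == seq_a |
                structure$chain == chain_b & structure$residue_seq == seq_b) &
    structure$residue_name == "CYS" & structure$name == "HG"
  out <- structure[!drop_hg, , drop = FALSE]
  bond <- tibble::tibble(chain_a = chain_a, seq_a = as.integer(seq_a),
                         chain_b = chain_b, seq_b = as.integer(seq_b),
                         distance = dist)
  new_ss <- if (is.null(ss)) bond else dplyr::bind_rows(ss, bond)
  out <- as_structure(out, title = attr(structure, "title"))
  attr(out, "ssbonds") <- new_ss
  out
}

#' Retrieve recorded disulfide bonds
#' @param structure structure tibble.
#' @return Tibble of S-S bond records (empty if none).
#' @export
ssbonds <- function(structure) {
  ss <- attr(structure, "ssbonds")
  if (is.null(ss)) {
    ss <- tibble::tibble(chain_a = character(0), seq_a = integer(0),
                         chain_b = character(0), seq_b = integer(0),
                         distance = numeric(0))
  }
  ss
}

#' Check two-fold (C2) symmetry of a homodimer pose
#'
#' Swaps the two chains and superposes the swapped dimer onto the original
#' with the Kabsch algorithm; the residual RMSD is zero for an exactly
#' two-fold symmetric pose.
#'
#' @param structure single-model two-chain pose.
#' @param chains length-2 chain ids.
#' @param rmsd_tolerance Angstrom; symmetric iff RMSD <= tolerance. A
#'   numerical floor of 1e-6 A is applied so that an exactly symmetric
#'   pose passes even at tolerance 0 despite floating-point residue.
#' @param selection atom selection used for the superposition (default
#'   heavy atoms).
#' @return One-row tibble `symmetric` (logical), `c2_rmsd` (Angstrom).
#' @export
check_c2_symmetry <- function(structure, chains = NULL, rmsd_tolerance = 1,
                              selection = "heavy") {
  if (is.null(chains)) chains <- utils::head(unique(structure$chain), 2)
  a <- select_atoms(chain_atoms(structure, chains[1]), selection)
  b <- select_atoms(chain_atoms(structure, chains[2]), selection)
  if (nrow(a) != nrow(b)) {
    abort("chains have unequal atom counts; cannot test C2 symmetry")
  }
  if (any(a$residue_name != b$residue_name)) {
    abort("chains have different residue sequences; cannot test C2 symmetry")
  }
  orig <- rbind(coords(a), coords(b))
  swapped <- rbind(coords(b), coords(a))
  fit <- kabsch_superpose(swapped, orig)
  tibble::tibble(symmetric = fit$rmsd <= max(rmsd_tolerance, 1e-6),
                 c2_rmsd = fit$rmsd)
}
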