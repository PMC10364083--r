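AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

LINKER_DEFAULTS <- c(DSSO = 27, DSBU = 27, disulfide = 6)

parse_residue_token <- function(tok, line) {
  tok <- trimws(tok)
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1]]
  if (length(m) == 0) {
    abort(paste0("malformed residue token '", tok, "' at line ", line,
                 " (expected e.g. K152)"))
  }
  aa <- toupper(m[2])
  if (!aa %in% names(AA1TO3)) {
    abort(paste0("unknown amino-acid letter '", aa, "' at line ", line))
  }
  list(seq = as.integer(m[3]), name = unname(AA1TO3[aa]))
}

#' Parse a cross-link / disulfide table
#'
#' Reads a delimited table with columns `residue_a`, `residue_b` (tokens
#' like `K152`, `C412`), `linker` (`DSSO`, `DSBU` or `disulfide`) and
#' `provenance` (`monomer_fraction`, `dimer_fraction`, `both`, `unknown`).
#' DSSO/DSBU records default to a 27 A Ca-Ca ceiling (the ~2.7 nm reach of
#' these lysine linkers); disulfide records default to the 6 A Sg-Sg
#' formability bound (use `ceilings` to override, e.g. 2.5 A for formed
#' bonds).
#'
#' @param source file path, character vector of lines, or a data frame
#'   already holding the columns.
#' @param sep field separator for text input (default `","`).
#' @param ceilings named numeric vector of per-linker ceiling overrides
#'   (Angstrom).
#' @return Tibble of records: `seq_a, name_a, seq_b, name_b, linker,
#'   ceiling, provenance, self_pair`.
#' @export
parse_crosslink_table <- function(source, sep = ",", ceilings = NULL) {
  ceil <- LINKER_DEFAULTS
  if (!is.null(ceilings)) ceil[names(ceilings)] <- ceilings
  if (is.data.frame(source)) {
    df <- tibble::as_tibble(source)
    df$.line <- seq_len(nrow(df)) + 1L
  } else {
    if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
      lines <- readLines(source, warn = FALSE)
    } else {
      lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    }
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) <= 1) {
      return(tibble::tibble(seq_a = integer(0), name_a = character(0),
                            seq_b = integer(0), name_b = character(0),
                            linker = character(0), ceiling = numeric(0),
                            provenance = character(0), self_pair = logical(0)))
    }
    hdr <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
    need <- c("residue_a", "residue_b", "linker", "provenance")
    if (!all(need %in% hdr)) {
      abort(paste0("cross-link table header must contain: ",
                   paste(need, collapse = ", ")))
    }
    body <- strsplit(lines[-1], sep, fixed = TRUE)
    bad <- which(vapply(body, length, integer(1)) < length(hdr))
    if (length(bad) > 0) {
      abort(paste0("malformed cross-link row at line ", bad[1] + 1L))
    }
    df <- tibble::as_tibble(stats::setNames(
      as.data.frame(do.call(rbind, lapply(body, trimws)),
                    stringsAsFactors = FALSE), hdr))
    df$.line <- seq_along(body) + 1L
  }
  purrr::pmap_dfr(df, function(residue_a, residue_b, linker, provenance,
                               .line, ...) {
    if (!linker %in% names(ceil)) {
      abort(paste0("unknown linker '", linker, "' at line ", .line))
    }
    ra <- parse_residue_token(residue_a, .line)
    rb <- parse_residue_token(residue_b, .line)
    expected <- if (linker == "disulfide") "CYS" else "LYS"
    for (r in list(ra, rb)) {
      if (r$name != expected) {
        abort(paste0(linker, " record at line ", .line, " names a ",
                     r$name, " residue; expected ", expected))
      }
    }
    prov <- match.arg(provenance, c("monomer_fraction", "dimer_fraction",
                                    "both", "unknown"))
    tibble::tibble(seq_a = ra$seq, name_a = ra$name,
                   seq_b = rb$seq, name_b = rb$name,
                   linker = linker, ceiling = unname(ceil[linker]),
                   provenance = prov,
                   self_pair = ra$seq == rb$seq & ra$name == rb$name)
  })
}

#' Assign intra- vs inter-molecular character from fraction provenance
#'
#' Links found only in the dimer fraction are assigned intermolecular;
#' links also (or only) found in the monomer fraction are more likely
#' intra-monomer; a self-pair (a residue linked to its own sequence
#' position) observed in the dimer fraction is necessarily intermolecular,
#' since a residue cannot link to itself.
#'
#' @param records tibble from [parse_crosslink_table()].
#' @return The records with an `assignment` column
#'   (`inter` / `intra` / `ambiguous`).
#' @export
classify_links <- function(records) {
  records %>%
    dplyr::mutate(assignment = dplyr::case_when(
      .data$provenance == "dimer_fraction" ~ "inter",
      .data$provenance %in% c("monomer_fraction", "both") ~ "intra",
      TRUE ~ "ambiguous"))
}

link_atom_name <- function(linker) if (linker == "disulfide") "SG" else "CA"

# distance between two specific atoms, NA when either is absent
atom_distance <- function(model, chain1, seq1, name1, chain2, seq2, name2) {
  a <- model[model$chain == chain1 & model$residue_seq == seq1 &
               model$name == name1, ]
  b <- model[model$chain == chain2 & model$residue_seq == seq2 &
               model$name == name2, ]
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  sqrt((a$x[1] - b$x[1])^2 + (a$y[1] - b$y[1])^2 + (a$z[1] - b$z[1])^2)
}

#' Evaluate a distance restraint on a monomer or homodimer model
#'
#' For a two-chain model every chain assignment is measured: intra-chain
#' (A-A and B-B) and inter-chain (A-B and B-A, equal for identical
#' chains). An assignment satisfies the record when its measured distance
#' (Ca-Ca for amine cross-linkers, Sg-Sg for disulfides) is at most the
#' record's ceiling. The verdict is `satisfied` when exactly one of
#' {intra, inter} can satisfy it, `ambiguous` when both can, `violated`
#' when neither does, and `untestable` when no distance is defined (a
#' self-pair on a single-chain model).
#'
#' @param model structure tibble with 1 or 2 chains (single model).
#' @param records cross-link record tibble from [parse_crosslink_table()]
#'   (one or more rows).
#' @return One row per record: the record columns plus `d_intra_a`,
#'   `d_intra_b`, `d_inter_ab`, `d_inter_ba`, `satisfied_as`
#'   (comma-joined subset of intra/inter) and `verdict`.
#' @export
evaluate_constraint <- function(model, records) {
  if (n_models(model) > 1) abort("evaluate_constraint expects a single model")
  chains <- unique(model$chain)
  if (!length(chains) %in% c(1, 2)) {
    abort("model must have one or two chains")
  }
  purrr::pmap_dfr(records, function(seq_a, name_a, seq_b, name_b, linker,
                                    ceiling, provenance, self_pair, ...) {
    atom <- link_atom_name(linker)
    resolvable <- function(cid, seq, name) {
      any(model$chain == cid & model$residue_seq == seq &
            model$residue_name == name)
    }
    for (cid in chains) {
      if (!resolvable(cid, seq_a, name_a)) {
        abort(paste0("residue ", name_a, seq_a, " not resolvable in chain ",
                     cid))
      }
      if (!resolvable(cid, seq_b, name_b)) {
        abort(paste0("residue ", name_b, seq_b, " not resolvable in chain ",
                     cid))
      }
    }
    self <- self_pair
    dia <- if (self) NA_real_ else
      atom_distance(model, chains[1], seq_a, atom, chains[1], seq_b, atom)
    dib <- if (length(chains) == 2 && !self)
      atom_distance(model, chains[2], seq_a, atom, chains[2], seq_b, atom)
      else NA_real_
    dab <- if (length(chains) == 2)
      atom_distance(model, chains[1], seq_a, atom, chains[2], seq_b, atom)
      else NA_real_
    dba <- if (length(chains) == 2)
      atom_distance(model, chains[2], seq_a, atom, chains[1], seq_b, atom)
      else NA_real_
    intra_ok <- any(c(dia, dib) <= ceiling, na.rm = TRUE)
    inter_ok <- any(c(dab, dba) <= ceiling, na.rm = TRUE)
    testable <- any(!is.na(c(dia, dib, dab, dba)))
    sat <- c(if (intra_ok) "intra", if (inter_ok) "inter")
    verdict <- if (!testable) "untestable"
      else if (intra_ok && inter_ok) "ambiguous"
      else if (intra_ok || inter_ok) "satisfied"
      else "violated"
    tibble::tibble(seq_a = seq_a, name_a = name_a, seq_b = seq_b,
                   name_b = name_b, linker = linker, ceiling = ceiling,
                   provenance = provenance, self_pair = self_pair,
                   d_intra_a = dia, d_intra_b = dib,
                   d_inter_ab = dab, d_inter_ba = dba,
                   satisfied_as = paste(sat, collapse = ","),
                   verdict = verdict)
  })
}

#' Constraint report for a model
#'
#' Evaluates every record against the model, merges the provenance-based
#' assignment, and attaches summary counts (`n_satisfied`, `n_violated`,
#' `n_ambiguous`, `n_untestable`, `fraction_satisfied` — ambiguous counts
#' as satisfied since some assignment passes).
#'
#' @param model structure tibble (1 or 2 chains, single model).
#' @param records cross-link record tibble.
#' @return Per-record tibble ordered by `seq_a`, with a `summary`
#'   attribute (one-row tibble of counts).
#' @export
constraint_report <- function(model, records) {
  res <- evaluate_constraint(model, classify_links(records)) %>%
    dplyr::left_join(
      classify_links(records)[, c("seq_a", "seq_b", "linker", "assignment")],
      by = c("seq_a", "seq_b", "linker")) %>%
    dplyr::arrange(.data$seq_a, .data$seq_b)
  n_sat <- sum(res$verdict %in% c("satisfied", "ambiguous"))
  n_test <- sum(res$verdict != "untestable")
  summary <- tibble::tibble(
    n_records = nrow(res),
    n_satisfied = sum(res$verdict == "satisfied"),
    n_ambiguous = sum(res$verdict == "ambiguous"),
    n_violated = sum(res$verdict == "violated"),
    n_untestable = sum(res$verdict == "untestable"),
    fraction_satisfied = if (n_test > 0) n_sat / n_test else NA_real_)
  attr(res, "summary") <- summary
  res
}
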