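#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Column set every structure tibble carries, in canonical order.
STRUCT_COLS <- c(
  "model", "record", "serial", "name", "alt_loc", "residue_name",
  "chain", "residue_seq", "x", "y", "z", "occupancy", "element"
)

WATER_NAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL")

#' Build a structure tibble from atom fields
#'
#' The package represents a structure (or a multi-frame ensemble) as a plain
#' tibble with one row per atom and the columns `model`, `record`, `serial`,
#' `name`, `alt_loc`, `residue_name`, `chain`, `residue_seq`, `x`, `y`, `z`,
#' `occupancy`, `element`. Frames of an ensemble share a `model` index;
#' within a model, atoms keep file order. All user-facing functions accept
#' any data frame with these columns, so structures compose with dplyr verbs.
#'
#' @param atoms data frame containing at least `name`, `residue_name`,
#'   `chain`, `residue_seq`, `x`, `y`, `z`; missing bookkeeping columns are
#'   filled with defaults (`model = 1`, `record = "ATOM"`, serial order,
#'   full occupancy, element inferred from the atom name).
#' @param title free-text title carried as an attribute.
#' @return A tibble of class `cry_structure`.
#' @export
as_structure <- function(atoms, title = "") {
  atoms <- tibble::as_tibble(atoms)
  need <- c("name", "residue_name", "chain", "residue_seq", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"serial" %in% names(atoms)) {
    atoms <- atoms %>%
      dplyr::group_by(.data$model) %>%
      dplyr::mutate(serial = dplyr::row_number()) %>%
      dplyr::ungroup()
  }
  if (!"alt_loc" %in% names(atoms)) atoms$alt_loc <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$name)
  }
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) abort("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element))) abort("empty element symbol in atom table")
  out <- atoms[, STRUCT_COLS]
  class(out) <- c("cry_structure", class(tibble::tibble()))
  attr(out, "title") <- title
  out
}

# Infer an element symbol from a PDB atom name (digits stripped, leading
# character; two-letter elements only for names that start with them).
guess_element <- function(name) {
  nm <- toupper(gsub("[0-9'\\*]", "", trimws(name)))
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  el[two %in% c("FE", "ZN", "MG", "CL", "BR", "NA", "CA") &
       nchar(nm) == 2 & !grepl("^(CA|NA)$", nm)] <-
    two[two %in% c("FE", "ZN", "MG", "CL", "BR", "NA", "CA") &
          nchar(nm) == 2 & !grepl("^(CA|NA)$", nm)]
  el
}

n_models <- function(structure) length(unique(structure$model))

# Split an ensemble tibble into an ordered list of single-model tibbles.
frames <- function(structure) {
  ids <- sort(unique(structure$model))
  lapply(ids, function(m) structure[structure$model == m, , drop = FALSE])
}

# Coordinates of a (single-model) atom table as an n x 3 matrix.
coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

# Replace coordinates of an atom table from an n x 3 matrix.
set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

# Assert all models agree on atom count and identity sequence.
check_topology <- function(atoms) {
  key <- paste(atoms$chain, atoms$residue_seq, atoms$name)
  keys <- split(key, atoms$model)
  ref <- keys[[1]]
  for (k in keys) {
    if (length(k) != length(ref) || any(k != ref)) {
      abort("inconsistent topology across MODEL blocks (atom count or atom identity differs)")
    }
  }
  invisible(atoms)
}

#' Read a PDB file or text into a structure tibble
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL`/`TER` records. Each `MODEL` block
#' becomes one value of the `model` column; a file without `MODEL` records
#' yields a single-model tibble. HETATM entries (e.g. an FAD cofactor) are
#' retained as their own residues. Alternate locations are resolved per
#' atom; insertion codes are rejected since they make residue keys
#' ambiguous.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @param alt_loc_policy `"highest_occupancy"` (default; ties broken by
#'   first occurrence) or `"first"`.
#' @param keep_waters keep water residues (HOH/WAT/TIP3...)? Default `TRUE`.
#' @param keep_hydrogens keep hydrogen atoms? They are needed for disulfide
#'   formation and hydrogen-bond detection. Default `TRUE`.
#' @return A structure tibble (see [as_structure()]); multi-model input
#'   yields an ensemble with one `model` value per frame, in file order.
#' @export
read_pdb <- function(source,
                     alt_loc_policy = c("highest_occupancy", "first"),
                     keep_waters = TRUE,
                     keep_hydrogens = TRUE) {
  alt_loc_policy <- match.arg(alt_loc_policy)
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | grepl("^(ATOM|HETATM)", rec)
  is_model <- grepl("^MODEL", rec)
  is_endmdl <- grepl("^ENDMDL", rec)
  title <- paste(trimws(substr(lines[grepl("^TITLE", rec)], 11, 80)),
                 collapse = " ")

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L

  idx <- which(is_atom)
  if (length(idx) == 0) abort("no ATOM/HETATM records found (empty input)")
  al <- lines[idx]

  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  seqs <- suppressWarnings(as.integer(substr(al, 23, 26)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | is.na(seqs) |
                 nchar(al) < 54)
  if (length(bad) > 0) {
    abort(paste0("malformed ATOM/HETATM record at line ", idx[bad[1]],
                 ": ", trimws(al[bad[1]])))
  }
  icode <- trimws(substr(al, 27, 27))
  if (any(nzchar(icode))) {
    abort(paste0("insertion codes are not supported (first at line ",
                 idx[which(nzchar(icode))[1]], ")"))
  }
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(substr(al, 77, 78))
  nm <- trimws(substr(al, 13, 16))
  elem[!nzchar(elem)] <- guess_element(nm[!nzchar(elem)])

  atoms <- tibble::tibble(
    model = model_id[idx],
    record = ifelse(grepl("^HETATM", al), "HETATM", "ATOM"),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = nm,
    alt_loc = trimws(substr(al, 17, 17)),
    residue_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    residue_seq = seqs,
    x = xs, y = ys, z = zs,
    occupancy = occ,
    element = elem
  )
  atoms$model <- match(atoms$model, sort(unique(atoms$model)))

  if (!keep_waters) {
    atoms <- atoms[!atoms$residue_name %in% WATER_NAMES, , drop = FALSE]
  }
  if (!keep_hydrogens) {
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
  }
  if (nrow(atoms) == 0) abort("no atoms left after filtering (empty input)")

  # alt-loc resolution: one row per (model, chain, residue_seq, name)
  if (any(nzchar(atoms$alt_loc))) {
    atoms$.ord <- seq_len(nrow(atoms))
    atoms <- atoms %>%
      dplyr::group_by(.data$model, .data$chain, .data$residue_seq,
                      .data$residue_name, .data$name) %>%
      dplyr::filter(
        if (alt_loc_policy == "first") dplyr::row_number() == 1
        else dplyr::row_number() ==
          which.max(.data$occupancy)  # ties -> first occurrence
      ) %>%
      dplyr::ungroup() %>%
      dplyr::arrange(.data$.ord)
    atoms$.ord <- NULL
    atoms$alt_loc <- ""
  }

  key <- paste(atoms$model, atoms$chain, atoms$residue_seq, atoms$name,
               atoms$alt_loc)
  if (anyDuplicated(key)) {
    abort("duplicate atom key (chain, residue_seq, name) after alt-loc resolution")
  }
  if (n_models_int(atoms) > 1) check_topology(atoms)
  as_structure(atoms, title = title)
}

n_models_int <- function(atoms) length(unique(atoms$model))

#' Write a structure tibble as PDB text
#'
#' Emits fixed-column `ATOM`/`HETATM` records (coordinates to 3 decimals),
#' `MODEL`/`ENDMDL` blocks when more than one model is present, `TER` at
#' chain ends, and `SSBOND` header records for any disulfides recorded by
#' [form_disulfide()].
#'
#' @param structure structure tibble.
#' @param path optional output file; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) a character vector
#'   of PDB lines.
#' @export
write_pdb <- function(structure, path = NULL) {
  if (max(abs(c(structure$x, structure$y, structure$z))) >= 10000) {
    abort("coordinate magnitude >= 10000 A cannot be represented in PDB fixed columns")
  }
  out <- character(0)
  title <- attr(structure, "title")
  if (!is.null(title) && nzchar(title)) {
    out <- c(out, sprintf("TITLE     %s", title))
  }
  ss <- attr(structure, "ssbonds")
  if (!is.null(ss) && nrow(ss) > 0) {
    out <- c(out, sprintf(
      "SSBOND %3d CYS %s %4d    CYS %s %4d %29s %5.2f",
      seq_len(nrow(ss)), ss$chain_a, ss$seq_a, ss$chain_b, ss$seq_b, "",
      ss$distance))
  }
  multi <- n_models(structure) > 1
  for (fr in frames(structure)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", fr$model[1]))
    pad_name <- ifelse(nchar(fr$name) < 4, paste0(" ", fr$name), fr$name)
    lines <- sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      fr$record, fr$serial %% 100000L, pad_name,
      substr(paste0(fr$alt_loc, " "), 1, 1),
      fr$residue_name, fr$chain, fr$residue_seq, " ",
      fr$x, fr$y, fr$z, fr$occupancy, 0, fr$element)
    # TER after each chain's last ATOM record
    chain_end <- c(fr$chain[-1] != fr$chain[-nrow(fr)], TRUE)
    pieces <- character(0)
    for (i in seq_along(lines)) {
      pieces <- c(pieces, lines[i])
      if (chain_end[i] && fr$record[i] == "ATOM") pieces <- c(pieces, "TER")
    }
    out <- c(out, pieces)
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Split a structure into one tibble per chain
#'
#' Monomer separation is needed to compute buried interface area, which is
#' the difference between the monomer surface areas and the complex surface
#' area.
#'
#' @param structure structure tibble (single- or multi-model).
#' @return Named list of structure tibbles, one per chain, atom order
#'   preserved; their union is exactly the input atom set.
#' @export
split_chains <- function(structure) {
  ids <- unique(structure$chain)
  out <- lapply(ids, function(cid) {
    s <- structure[structure$chain == cid, , drop = FALSE]
    as_structure(s, title = attr(structure, "title"))
  })
  names(out) <- ids
  out
}

# Select rows of a single chain, error when absent.
chain_atoms <- function(structure, chain_id) {
  s <- structure[structure$chain == chain_id, , drop = FALSE]
  if (nrow(s) == 0) abort(paste0("chain '", chain_id, "' not present"))
  s
}

# Backbone / selection helpers shared by RMSD, RMSF and the panel.
select_atoms <- function(structure,
                         selection = c("backbone", "calpha", "carbon", "heavy", "all")) {
  selection <- match.arg(selection)
  switch(selection,
    backbone = structure[structure$name %in% c("N", "CA", "C", "O"), ],
    calpha   = structure[structure$name == "CA" & structure$element == "C", ],
    carbon   = structure[structure$element == "C", ],
    heavy    = structure[structure$element != "H", ],
    all      = structure
  )
}
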