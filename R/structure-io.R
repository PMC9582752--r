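#' Read a molecular structure from PDB-family coordinate text
#'
#' Parses fixed-column ATOM/HETATM records (PDB v3.3 columns). Three dialects
#' are supported: plain single-model `"pdb"`, `"multi_model_pdb"`
#' (MODEL/ENDMDL blocks, e.g. AutoDock Vina output converted to PDB), and
#' `"pdbqt_minimal"`, which reads Vina-style PDBQT by taking the PDB-shaped
#' columns and ignoring the trailing partial-charge/atom-type fields.
#' `REMARK VINA RESULT` lines, when present, are collected per model and
#' attached as the `"vina_scores"` attribute (kcal/mol).
#'
#' Alternate locations are collapsed per (chain, residue, atom name): the
#' highest-occupancy conformer is kept, ties going to altloc "A". When the
#' element column is blank the element is inferred from the atom name.
#'
#' @param path Path to the coordinate file.
#' @param dialect One of `"pdb"`, `"multi_model_pdb"`, `"pdbqt_minimal"`.
#' @param chain Optional single chain identifier to keep.
#' @return A tibble of atoms with columns `model`, `serial`, `name`,
#'   `element`, `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`,
#'   `is_hetero`. Single-model files have `model == 1` throughout.
#' @export
read_structure <- function(path, dialect = c("pdb", "multi_model_pdb", "pdbqt_minimal"),
                           chain = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_gt(sprintf("Coordinate file not found: %s", path), "gt_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  parse_structure_lines(lines, dialect = dialect, chain = chain, source = path)
}

parse_structure_lines <- function(lines, dialect, chain = NULL, source = "<text>") {
  rec <- substr(lines, 1, 6)
  model_no <- cumsum(startsWith(rec, "MODEL "))
  has_models <- any(model_no > 0)
  model_no[model_no == 0] <- 1L

  is_atom <- startsWith(rec, "ATOM  ") | startsWith(rec, "HETATM")
  if (!any(is_atom)) {
    stop_gt(sprintf("No ATOM/HETATM records in %s (empty structure).", source),
            "gt_empty_structure_error")
  }

  idx <- which(is_atom)
  al <- lines[idx]
  num_field <- function(txt, what, lineno) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) | !nzchar(trimws(txt)))
    if (length(bad)) {
      stop_gt(sprintf("Malformed %s field at line %d of %s: '%s'",
                      what, lineno[bad[1]], source, txt[bad[1]]),
              "gt_format_error")
    }
    out
  }
  x <- num_field(substr(al, 31, 38), "x coordinate", idx)
  y <- num_field(substr(al, 39, 46), "y coordinate", idx)
  z <- num_field(substr(al, 47, 54), "z coordinate", idx)
  serial <- suppressWarnings(as.integer(trimws(substr(al, 7, 11))))
  serial[is.na(serial)] <- seq_along(al)[is.na(serial)]
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain_id <- substr(al, 22, 22)
  resno <- suppressWarnings(as.integer(trimws(substr(al, 23, 26))))
  if (anyNA(resno)) {
    bad <- which(is.na(resno))[1]
    stop_gt(sprintf("Malformed residue number at line %d of %s", idx[bad], source),
            "gt_format_error")
  }
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(al, 77, 78))
  if (identical(dialect, "pdbqt_minimal")) {
    # PDBQT reuses cols 78-79 for the AutoDock atom type; strip type suffixes
    adtype <- trimws(substr(al, 78, 79))
    element <- ifelse(nzchar(adtype), sub("[^A-Za-z].*$", "", adtype), "")
  }
  element <- ifelse(nzchar(element), toupper(element), infer_element(name))

  atoms <- tibble::tibble(
    model = as.integer(model_no[idx]),
    serial = serial,
    name = name,
    altloc = altloc,
    element = element,
    residue_name = resname,
    residue_number = resno,
    chain_id = chain_id,
    x = x, y = y, z = z,
    occupancy = occ,
    is_hetero = startsWith(rec[idx], "HETATM")
  )

  if (!is.null(chain)) {
    atoms <- dplyr::filter(atoms, .data$chain_id == chain)
    if (nrow(atoms) == 0) {
      stop_gt(sprintf("Chain '%s' not present in %s.", chain, source),
              "gt_empty_structure_error")
    }
  }

  # altloc resolution: highest occupancy, tie -> altloc "A"
  atoms <- atoms |>
    dplyr::group_by(.data$model, .data$chain_id, .data$residue_number,
                    .data$residue_name, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy),
                   .data$altloc != "A", .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$model, .data$serial) |>
    dplyr::select(-"altloc", -"occupancy")

  scores <- parse_vina_scores(lines)
  if (!is.null(scores)) attr(atoms, "vina_scores") <- scores
  atoms
}

parse_vina_scores <- function(lines) {
  hit <- grepl("^REMARK VINA RESULT:", lines)
  if (!any(hit)) return(NULL)
  vals <- vapply(strsplit(trimws(sub("^REMARK VINA RESULT:", "", lines[hit])), "\\s+"),
                 function(v) as.numeric(v[1]), numeric(1))
  tibble::tibble(model = seq_along(vals), score = vals)
}

# element inference from atom-name leading characters (blank element column)
infer_element <- function(name) {
  core <- sub("^[0-9']+", "", toupper(name))
  two <- substr(core, 1, 2)
  one <- substr(core, 1, 1)
  two_letter <- c("CL", "BR", "FE", "MG", "ZN", "MN", "SE", "NA", "SI")
  # CA/CB/... in protein context are carbons; only accept two-letter metals
  # when the remainder is not a typical position label
  ifelse(one %in% c("C", "N", "O", "S", "P", "H", "F"), one,
         ifelse(two %in% two_letter, two, one))
}

#' Split a multi-model atom table into one tibble per model
#'
#' @param atoms Atom tibble from [read_structure()].
#' @return Named list of single-model atom tibbles.
#' @export
split_models <- function(atoms) {
  split(atoms, atoms$model)
}

#' Write an atom table as fixed-column PDB text
#'
#' Multi-model tables (more than one distinct `model` value) are wrapped in
#' MODEL/ENDMDL blocks. Coordinates are written with 3 decimals (PDB column
#' precision), so a write/read round trip reproduces them exactly.
#'
#' @param atoms Atom tibble (see [read_structure()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  if (nrow(atoms) == 0) stop_gt("Cannot write an empty structure.", "gt_empty_structure_error")
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  models <- unique(atoms$model)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    a <- atoms[atoms$model == m, ]
    if (length(models) > 1) writeLines(sprintf("MODEL %8d", m), con)
    rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
    # atom names of <4 chars start in column 14 per PDB convention
    nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4), sprintf(" %-3s", a$name))
    writeLines(sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, a$serial %% 100000L, nm, a$residue_name, a$chain_id,
                       a$residue_number, a$x, a$y, a$z, 1, 0, a$element), con)
    if (length(models) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
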