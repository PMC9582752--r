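#' Construct a reference ligand from an atom table
#'
#' A reference ligand is a heavy-atom tibble carrying three anchor atom
#' names (axis start/end defining the substrate-binding axis and the origin
#' atom whose projection defines the coordinate origin) and a per-atom
#' subsite assignment. In the acarbose convention the anchors are C4A, C1
#' and N4A, and the moieties span subsites -1 through +3.
#'
#' @param atoms Atom tibble; hydrogens are dropped.
#' @param subsite Integer vector, one subsite per retained heavy atom
#'   (negative = donor side, positive = acceptor side, no 0). Alternatively
#'   supply `moiety_map`.
#' @param axis_start,axis_end,origin Anchor atom names.
#' @param moiety_map Named integer vector mapping atom name to subsite, used
#'   when `subsite` is `NULL`.
#' @return A `ref_ligand` tibble: atom columns plus `subsite`, with anchor
#'   names stored as attributes.
#' @export
ref_ligand <- function(atoms, subsite = NULL, axis_start = "C4A", axis_end = "C1",
                       origin = "N4A", moiety_map = NULL) {
  lig <- heavy_atoms(atoms)
  if (nrow(lig) == 0) stop_gt("Reference ligand has no heavy atoms.", "gt_empty_structure_error")
  if (is.null(subsite)) {
    if (is.null(moiety_map)) {
      stop_gt("Provide either `subsite` or `moiety_map`.", "gt_annotation_error")
    }
    missing_atoms <- setdiff(lig$name, names(moiety_map))
    if (length(missing_atoms)) {
      stop_gt(sprintf("moiety_map does not cover atom(s): %s",
                      paste(missing_atoms, collapse = ", ")),
              "gt_annotation_error")
    }
    subsite <- as.integer(moiety_map[lig$name])
  }
  if (length(subsite) != nrow(lig) || anyNA(subsite) || any(subsite == 0)) {
    stop_gt("Every heavy atom needs exactly one nonzero subsite label.",
            "gt_annotation_error")
  }
  lig$subsite <- as.integer(subsite)

  anchors <- c(axis_start = axis_start, axis_end = axis_end, origin = origin)
  for (a in anchors) {
    if (!a %in% lig$name) {
      stop_gt(sprintf("Anchor atom '%s' not found among the ligand's heavy atoms.", a),
              "gt_anchor_not_found_error")
    }
  }
  if (anyDuplicated(anchors)) {
    stop_gt("Axis and origin anchor atoms must be three distinct atoms.",
            "gt_validation_error")
  }
  structure(lig,
            class = c("ref_ligand", class(tibble::as_tibble(lig))),
            axis_start = axis_start, axis_end = axis_end, origin = origin)
}

#' Extract and annotate the reference ligand from a structure
#'
#' Pulls one HETATM residue (e.g. a bound acarbose) out of a structure,
#' drops hydrogens, and annotates it with binding-axis anchors and a
#' moiety-to-subsite map.
#'
#' @param structure Atom tibble from [read_structure()].
#' @param residue_name Three-letter residue code of the ligand.
#' @param residue_number,chain Optional selectors when several copies exist;
#'   the residue must be uniquely identified.
#' @param anchors Character vector of three atom names
#'   `c(axis_start, axis_end, origin)`; default the acarbose convention
#'   C4A / C1 / N4A.
#' @param moiety_map Named integer vector: atom name -> subsite.
#' @return A [ref_ligand()] tibble.
#' @export
extract_reference_ligand <- function(structure, residue_name,
                                     residue_number = NULL, chain = NULL,
                                     anchors = c("C4A", "C1", "N4A"),
                                     moiety_map) {
  sel <- structure[structure$residue_name == residue_name, ]
  if (!is.null(chain)) sel <- sel[sel$chain_id == chain, ]
  if (!is.null(residue_number)) sel <- sel[sel$residue_number == residue_number, ]
  if (nrow(sel) == 0) {
    stop_gt(sprintf("Residue '%s' not found in structure.", residue_name),
            "gt_not_found_error")
  }
  ids <- unique(paste(sel$chain_id, sel$residue_number))
  if (length(ids) > 1) {
    stop_gt(sprintf("Residue '%s' is ambiguous (%d copies); give `chain`/`residue_number`.",
                    residue_name, length(ids)),
            "gt_validation_error")
  }
  ref_ligand(sel, axis_start = anchors[1], axis_end = anchors[2],
             origin = anchors[3], moiety_map = moiety_map)
}

anchor_coord <- function(reference, which) {
  nm <- attr(reference, which)
  as.numeric(reference[match(nm, reference$name), c("x", "y", "z")])
}

#' Truncate one residue to alanine
#'
#' Models an alanine point mutant the way docking studies do: all side-chain
#' atoms of the target residue beyond the beta-carbon are deleted, keeping
#' the main-chain atoms (N, CA, C, O, plus OXT when terminal) and CB, and
#' the residue is renamed ALA. Every other residue is untouched. Applying
#' the operation twice equals applying it once.
#'
#' @param structure Atom tibble.
#' @param chain_id Chain of the target residue.
#' @param residue_number Residue number of the target residue.
#' @return A new atom tibble; the input is not modified.
#' @export
make_alanine_mutant <- function(structure, chain_id, residue_number) {
  in_res <- structure$chain_id == chain_id & structure$residue_number == residue_number &
    !structure$is_hetero
  if (!any(in_res)) {
    stop_gt(sprintf("Residue %s/%d not found.", chain_id, residue_number),
            "gt_not_found_error")
  }
  resname <- unique(structure$residue_name[in_res])
  if (identical(resname, "GLY")) {
    stop_gt("Glycine has no beta-carbon; alanine truncation is not defined.",
            "gt_unsupported_mutation_error")
  }
  if (!"CB" %in% structure$name[in_res]) {
    stop_gt(sprintf("Residue %s/%d lacks a CB atom.", chain_id, residue_number),
            "gt_unsupported_mutation_error")
  }
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT")
  drop <- in_res & !(structure$name %in% keep_names)
  out <- structure[!drop, ]
  out$residue_name[out$chain_id == chain_id & out$residue_number == residue_number &
                     !out$is_hetero] <- "ALA"
  out
}

#' Docking box configuration centred on the reference ligand origin atom
#'
#' The search box is a cube centred at the origin anchor atom of the
#' reference ligand (the active-site atom), matching the convention of
#' grid-box docking around a bound inhibitor.
#'
#' @param reference A [ref_ligand()].
#' @param edge_length Cube edge, Angstrom (default 30).
#' @param exhaustiveness Search effort (default 100).
#' @param num_modes Number of binding modes to keep (default 20).
#' @return A `docking_config` list with `center`, `edge_length`,
#'   `exhaustiveness`, `num_modes`.
#' @export
emit_docking_config <- function(reference, edge_length = 30,
                                exhaustiveness = 100, num_modes = 20) {
  assert_scalar_num(edge_length, "edge_length", positive = TRUE)
  if (!is.numeric(exhaustiveness) || exhaustiveness < 1 ||
      !is.numeric(num_modes) || num_modes < 1) {
    stop_gt("exhaustiveness and num_modes must be >= 1.", "gt_validation_error")
  }
  center <- anchor_coord(reference, "origin")
  structure(list(center = center, edge_length = edge_length,
                 exhaustiveness = as.integer(exhaustiveness),
                 num_modes = as.integer(num_modes)),
            class = "docking_config")
}

#' @export
format.docking_config <- function(x, ...) {
  c(sprintf("center_x = %.3f", x$center[1]),
    sprintf("center_y = %.3f", x$center[2]),
    sprintf("center_z = %.3f", x$center[3]),
    sprintf("size_x = %g", x$edge_length),
    sprintf("size_y = %g", x$edge_length),
    sprintf("size_z = %g", x$edge_length),
    sprintf("exhaustiveness = %d", x$exhaustiveness),
    sprintf("num_modes = %d", x$num_modes))
}

#' @export
print.docking_config <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a docking configuration as key = value text
#'
#' @param config A `docking_config` from [emit_docking_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_docking_config <- function(config, path) {
  writeLines(format(config), path)
  invisible(path)
}
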