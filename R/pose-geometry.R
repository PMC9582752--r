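#' Build the substrate-binding axis from a reference ligand
#'
#' The axis is the unit vector between the two axis anchor atoms of the
#' reference ligand (C4A to C1 in the acarbose convention); the coordinate
#' origin is the orthogonal projection of the origin anchor atom (N4A, the
#' atom linking the -1 and +1 moieties) onto the infinite line through the
#' axis start along that direction.
#'
#' @param reference A [ref_ligand()].
#' @return A `binding_axis` list with `origin` (3-vector, Angstrom) and
#'   `direction` (unit 3-vector).
#' @export
build_binding_axis <- function(reference) {
  p_start <- anchor_coord(reference, "axis_start")
  p_end <- anchor_coord(reference, "axis_end")
  p_origin <- anchor_coord(reference, "origin")
  d <- p_end - p_start
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) {
    stop_gt("Axis anchor atoms coincide; the binding axis is degenerate.",
            "gt_degenerate_axis_error")
  }
  direction <- d / nd
  origin <- p_start + sum((p_origin - p_start) * direction) * direction
  structure(list(origin = origin, direction = direction), class = "binding_axis")
}

#' Positional coordinate of a pose along the binding axis
#'
#' Projects the centroid of the pose's heavy atoms onto the binding axis and
#' returns the signed distance from the axis origin, in Angstrom. Positive
#' values lie toward the acceptor subsites, negative toward the donor side.
#'
#' @param pose Atom tibble (one pose); hydrogens are ignored.
#' @param axis A `binding_axis` from [build_binding_axis()].
#' @return Signed scalar coordinate, Angstrom.
#' @export
positional_coordinate <- function(pose, axis) {
  pose <- heavy_atoms(pose)
  if (nrow(pose) == 0) stop_gt("Pose has no heavy atoms.", "gt_empty_input_error")
  centroid <- colMeans(coord_matrix(pose))
  sum((centroid - axis$origin) * axis$direction)
}

#' Greedy sub-angstrom atom match between a pose and the reference ligand
#'
#' Pairwise distances between pose and reference heavy atoms are computed;
#' the globally shortest remaining pair is selected, counted as a match when
#' its distance is strictly below `threshold`, and both atoms are removed.
#' The loop stops once no pose atom remains or the shortest remaining
#' distance reaches the threshold (no later pair can be shorter). Equal
#' distances are broken lexicographically on (pose index, reference index).
#' The percentage is taken over the pose's heavy-atom count.
#'
#' @param pose Atom tibble (one pose).
#' @param reference A [ref_ligand()] or atom tibble; hydrogens ignored.
#' @param threshold Match distance cutoff, Angstrom (default 1; strict `<`).
#' @return List with `match_percent` (0-100) and `matched_pairs`, a tibble
#'   of `pose_index`, `pose_name`, `ref_index`, `ref_name`, `distance`.
#' @export
greedy_match_percent <- function(pose, reference, threshold = 1.0) {
  assert_scalar_num(threshold, "threshold", positive = TRUE)
  pose <- heavy_atoms(pose)
  ref <- heavy_atoms(reference)
  if (nrow(pose) == 0 || nrow(ref) == 0) {
    stop_gt("Pose and reference must both contain heavy atoms.", "gt_empty_input_error")
  }
  dm <- cross_dist(coord_matrix(pose), coord_matrix(ref))
  n_pose <- nrow(dm)
  pairs <- list()
  repeat {
    mn <- min(dm)
    if (!is.finite(mn) || mn >= threshold) break
    hits <- which(dm == mn, arr.ind = TRUE)
    pick <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
    pairs[[length(pairs) + 1L]] <- c(pick[["row"]], pick[["col"]], mn)
    dm[pick[["row"]], ] <- Inf
    dm[, pick[["col"]]] <- Inf
    if (all(!is.finite(dm))) break
  }
  matched <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(pose_index = as.integer(m[, 1]),
                   pose_name = pose$name[m[, 1]],
                   ref_index = as.integer(m[, 2]),
                   ref_name = ref$name[m[, 2]],
                   distance = m[, 3])
  } else {
    tibble::tibble(pose_index = integer(), pose_name = character(),
                   ref_index = integer(), ref_name = character(),
                   distance = numeric())
  }
  list(match_percent = 100 * nrow(matched) / n_pose, matched_pairs = matched)
}

fmt_subsite <- function(s) sprintf("%+d", as.integer(s))

#' Subsite calibration: positional coordinate of each reference moiety
#'
#' For each subsite of the reference ligand, computes the positional
#' coordinate of that moiety's heavy-atom centroid along the binding axis.
#' Subsites must come out monotone increasing along the axis in the order
#' ..., -2, -1, +1, +2, ...; a non-monotone result indicates swapped axis
#' anchors.
#'
#' @param reference A [ref_ligand()] with subsite annotation.
#' @param axis A `binding_axis`; defaults to [build_binding_axis()] on the
#'   reference itself.
#' @return Tibble of `subsite` (integer), `label`, `coordinate` (Angstrom),
#'   sorted by subsite.
#' @export
calibrate_subsites <- function(reference, axis = build_binding_axis(reference)) {
  cal <- reference |>
    dplyr::group_by(.data$subsite) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(coordinate = positional_coordinate(df, axis))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subsite) |>
    dplyr::mutate(label = fmt_subsite(.data$subsite), .after = "subsite")
  if (nrow(cal) > 1 && any(diff(cal$coordinate) <= 0)) {
    stop_gt(paste("Subsite centroids are not monotone increasing along the axis;",
                  "the axis anchors are probably swapped."),
            "gt_orientation_error")
  }
  cal
}

#' Assign a positional coordinate to the nearest calibrated subsite
#'
#' @param coordinate Positional coordinate, Angstrom.
#' @param calibration Tibble from [calibrate_subsites()] or a named numeric
#'   vector of subsite centroid coordinates (names like "-1", "+1").
#' @param max_distance Maximum distance to the nearest centroid before the
#'   pose is reported `"unassigned"` (default 2 Angstrom).
#' @return Subsite label string (e.g. `"+1"`) or `"unassigned"`. Ties go to
#'   the more negative (donor-side) subsite.
#' @export
assign_subsite <- function(coordinate, calibration, max_distance = 2.0) {
  assert_scalar_num(max_distance, "max_distance", positive = TRUE)
  if (is.data.frame(calibration)) {
    subsites <- calibration$subsite
    centers <- calibration$coordinate
  } else {
    if (length(calibration) == 0) stop_gt("Empty subsite calibration.", "gt_validation_error")
    subsites <- as.integer(names(calibration))
    centers <- as.numeric(calibration)
  }
  ord <- order(subsites)
  subsites <- subsites[ord]; centers <- centers[ord]
  d <- abs(coordinate - centers)
  if (min(d) > max_distance) return("unassigned")
  fmt_subsite(subsites[which(d == min(d))[1]])  # first = most negative on tie
}

#' Minimum side-chain distance between a residue and a ligand
#'
#' Reports the minimum heavy-atom Euclidean distance between the side-chain
#' atoms of one residue and a set of ligand atoms, the quantity used to
#' describe contacts between aromatic residues and bound sugar moieties.
#' Glycine has no side-chain heavy atoms; its CA is used instead and the
#' fallback is flagged.
#'
#' @param structure Atom tibble containing the residue.
#' @param chain_id,residue_number Residue selector.
#' @param ligand_atoms Atom tibble of the ligand; hydrogens ignored.
#' @return One-row tibble: `chain_id`, `residue_number`, `residue_name`,
#'   `min_distance` (Angstrom), `used_ca` (logical).
#' @export
min_residue_ligand_distance <- function(structure, chain_id, residue_number,
                                        ligand_atoms) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  res <- structure[structure$chain_id == chain_id &
                     structure$residue_number == residue_number &
                     !structure$is_hetero, ]
  if (nrow(res) == 0) {
    stop_gt(sprintf("Residue %s/%d not found.", chain_id, residue_number),
            "gt_not_found_error")
  }
  lig <- heavy_atoms(ligand_atoms)
  if (nrow(lig) == 0) stop_gt("Ligand has no heavy atoms.", "gt_empty_input_error")
  side <- heavy_atoms(res[!res$name %in% backbone, ])
  used_ca <- nrow(side) == 0
  if (used_ca) side <- res[res$name == "CA", ]
  if (nrow(side) == 0) {
    stop_gt(sprintf("Residue %s/%d has no usable atoms.", chain_id, residue_number),
            "gt_empty_input_error")
  }
  tibble::tibble(chain_id = chain_id, residue_number = residue_number,
                 residue_name = res$residue_name[1],
                 min_distance = min(cross_dist(coord_matrix(side), coord_matrix(lig))),
                 used_ca = used_ca)
}

#' Per-pose geometry metrics against a reference ligand
#'
#' Computes, for every pose (MODEL) in a multi-model atom table, the
#' positional coordinate along the binding axis, the greedy sub-angstrom
#' match percentage, and the nearest calibrated subsite.
#'
#' @param poses Atom tibble with a `model` column (e.g. from
#'   [read_structure()] with the multi-model dialect, or [gen_poses()]).
#' @param reference A [ref_ligand()].
#' @param threshold Greedy match cutoff, Angstrom.
#' @param max_distance Subsite assignment cutoff, Angstrom.
#' @param ligand_name Label carried into the output.
#' @param scores Optional tibble `model`, `score`; defaults to the
#'   `"vina_scores"` attribute of `poses` when present.
#' @return Tibble with one row per pose: `ligand`, `model`, `score`,
#'   `n_heavy_atoms`, `positional_coordinate`, `match_percent`, `subsite`.
#' @export
pose_metrics <- function(poses, reference, threshold = 1.0, max_distance = 2.0,
                         ligand_name = "ligand", scores = NULL) {
  axis <- build_binding_axis(reference)
  calibration <- calibrate_subsites(reference, axis)
  scores <- scores %||% attr(poses, "vina_scores")
  if (!"model" %in% names(poses)) poses$model <- 1L
  out <- purrr::map_dfr(split_models(poses), function(p) {
    ph <- heavy_atoms(p)
    coord <- positional_coordinate(ph, axis)
    gm <- greedy_match_percent(ph, reference, threshold = threshold)
    tibble::tibble(
      ligand = ligand_name,
      model = p$model[1],
      n_heavy_atoms = nrow(ph),
      positional_coordinate = coord,
      match_percent = gm$match_percent,
      subsite = assign_subsite(coord, calibration, max_distance = max_distance)
    )
  })
  if (!is.null(scores)) {
    out <- dplyr::left_join(out, scores, by = "model") |>
      dplyr::relocate("score", .after = "model")
  } else {
    out$score <- NA_real_
    out <- dplyr::relocate(out, "score", .after = "model")
  }
  dplyr::arrange(out, .data$model)
}
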