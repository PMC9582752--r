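axis_fixture <- function(start, end, origin) {
  atoms <- atoms_from_xyz(rbind(start, end, origin), name = c("C4A", "C1", "N4A"))
  ref_ligand(atoms, subsite = c(-1L, 1L, 1L))
}

test_that("binding axis is the unit anchor vector with a projected origin", {
  ax <- build_binding_axis(axis_fixture(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0)))
  expect_equal(ax$direction, c(1, 0, 0))
  expect_equal(ax$origin, c(1, 0, 0))

  # dot-product projection worked by hand: dir (0.6, 0.8, 0); the origin atom
  # (3,4,12) projects onto the line at (3,4,0)
  ax2 <- build_binding_axis(axis_fixture(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)))
  expect_equal(ax2$direction, c(0.6, 0.8, 0))
  expect_equal(ax2$origin, c(3, 4, 0))
  expect_equal(sqrt(sum(ax2$direction^2)), 1, tolerance = 1e-9)

  expect_error(build_binding_axis(axis_fixture(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))),
               class = "gt_degenerate_axis_error")
})

test_that("positional coordinate is the signed centroid projection", {
  ref <- axis_fixture(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0))
  ax <- build_binding_axis(ref)
  at_origin <- atoms_from_xyz(rbind(c(1, 3, 0), c(1, -3, 0)))  # centroid (1,0,0)
  expect_equal(positional_coordinate(at_origin, ax), 0)
  shifted <- atoms_from_xyz(rbind(c(3.5, 3, 0), c(3.5, -3, 0)))  # origin + 2.5 dir
  expect_equal(positional_coordinate(shifted, ax), 2.5)
  expect_error(positional_coordinate(at_origin[0, ], ax), class = "gt_empty_input_error")
})

test_that("positional coordinate is linear in translations along the axis", {
  set.seed(21)
  ref <- gen_reference_ligand(seed = 21)
  ax <- build_binding_axis(ref)
  pose <- random_atoms(12)
  s0 <- positional_coordinate(pose, ax)
  for (t_shift in c(-7.25, 0.5, 3, 12.125)) {
    moved <- pose
    moved$x <- moved$x + t_shift * ax$direction[1]
    moved$y <- moved$y + t_shift * ax$direction[2]
    moved$z <- moved$z + t_shift * ax$direction[3]
    expect_equal(positional_coordinate(moved, ax), s0 + t_shift, tolerance = 1e-9)
  }
})

test_that("greedy match reproduces hand-worked examples", {
  ref <- axis_fixture(c(0, 0, 0), c(5, 0, 0), c(2, 0, 0))
  # identity: pose equal to the reference atoms
  ident <- greedy_match_percent(tibble::as_tibble(ref), ref)
  expect_equal(ident$match_percent, 100)

  # one reference atom at the origin, two pose atoms: the nearer matches and
  # consumes the reference atom, the second cannot match -> 50%
  one_ref <- atoms_from_xyz(rbind(c(0, 0, 0)))
  pose2 <- atoms_from_xyz(rbind(c(0.5, 0, 0), c(0.9, 0, 0)))
  res <- greedy_match_percent(pose2, one_ref)
  expect_equal(res$match_percent, 50)
  expect_equal(res$matched_pairs$pose_index, 1L)
  expect_equal(res$matched_pairs$distance, 0.5)

  # well-separated reference translated by 2 A: every pairwise distance >= 2
  far <- atoms_from_xyz(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  moved <- far; moved$x <- moved$x + 2
  expect_equal(greedy_match_percent(moved, far)$match_percent, 0)

  expect_error(greedy_match_percent(pose2, one_ref, threshold = 0),
               class = "gt_validation_error")
})

test_that("greedy match equals the brute-force sorted-pair replay", {
  set.seed(22)
  for (i in 1:250) {
    np <- sample(5:40, 1); nr <- sample(5:40, 1)
    pose <- random_atoms(np); ref <- random_atoms(nr)
    got <- greedy_match_percent(pose, ref)
    want <- brute_force_match_count(as.matrix(pose[, c("x", "y", "z")]),
                                    as.matrix(ref[, c("x", "y", "z")]))
    expect_equal(nrow(got$matched_pairs), want)
    expect_equal(got$match_percent, 100 * want / np)
    # every reference atom used at most once
    expect_false(anyDuplicated(got$matched_pairs$ref_index) > 0)
  }
})

test_that("greedy match count never exceeds the optimal bipartite matching", {
  set.seed(23)
  for (i in 1:150) {
    np <- sample(2:8, 1); nr <- sample(2:8, 1)
    pose <- random_atoms(np, 0, 3); ref <- random_atoms(nr, 0, 3)
    greedy <- nrow(greedy_match_percent(pose, ref)$matched_pairs)
    optimal <- max_bipartite_matches(as.matrix(pose[, c("x", "y", "z")]),
                                     as.matrix(ref[, c("x", "y", "z")]))
    expect_lte(greedy, optimal)
  }
})

test_that("match percent is invariant to atom input order (distinct distances)", {
  set.seed(24)
  for (i in 1:25) {
    pose <- random_atoms(12); ref <- random_atoms(15)
    base <- greedy_match_percent(pose, ref)$match_percent
    perm <- greedy_match_percent(pose[sample(12), ], ref[sample(15), ])$match_percent
    expect_equal(perm, base)
  }
})

test_that("pose metrics are equivariant under a shared rigid motion", {
  set.seed(25)
  ref <- gen_reference_ligand(seed = 25)
  poses <- gen_poses(ref, n_poses = 5, displacement_along_axis = c(0, 1, -2, 3.5, 5),
                     jitter_sd = 0.3, seed = 25)
  base <- pose_metrics(poses, ref)
  for (i in 1:5) {
    R <- random_rotation(); t <- runif(3, -20, 20)
    ref_t <- transform_reference(ref, R, t)
    poses_t <- transform_atoms(poses, R, t)
    attr(poses_t, "vina_scores") <- attr(poses, "vina_scores")
    moved <- pose_metrics(poses_t, ref_t)
    expect_equal(moved$positional_coordinate, base$positional_coordinate,
                 tolerance = 1e-6)
    expect_equal(moved$match_percent, base$match_percent)
    expect_equal(moved$subsite, base$subsite)
  }
})

test_that("subsite calibration recovers constructed moiety centroids and flags swaps", {
  ref <- gen_reference_ligand(n_moieties = 4, atoms_per_moiety = 5, spacing = 4, seed = 26)
  cal <- calibrate_subsites(ref)
  expect_equal(cal$subsite, c(-1L, 1L, 2L, 3L))
  expect_equal(cal$coordinate, c(-2, 2, 6, 10), tolerance = 1e-9)

  # swapped axis anchors reverse the axis -> orientation error
  swapped <- ref
  attr(swapped, "axis_start") <- "C1"
  attr(swapped, "axis_end") <- "C4A"
  expect_error(calibrate_subsites(swapped), class = "gt_orientation_error")

  # single-moiety map: no monotonicity check possible
  single <- ref_ligand(tibble::as_tibble(ref) |> dplyr::mutate(subsite = NULL),
                       subsite = rep(-1L, nrow(ref)))
  expect_equal(nrow(calibrate_subsites(single)), 1)
})

test_that("coordinates map to the nearest calibrated subsite, donor side on ties", {
  cal <- c("-1" = -4, "1" = 3)
  expect_equal(assign_subsite(3.0, cal), "+1")
  expect_equal(assign_subsite(-4.0, cal), "-1")
  # exact midpoint between the two centroids: donor-side tie-break
  expect_equal(assign_subsite(-0.5, cal, max_distance = 10), "-1")
  expect_equal(assign_subsite(50, cal), "unassigned")
  expect_error(assign_subsite(0, numeric(0)), class = "gt_validation_error")
})

test_that("minimum residue-ligand distance matches brute force and flags glycine", {
  # residue with backbone at y = 9 and a single side-chain atom at the origin;
  # ligand atoms at (3,4,0) and (6,8,0): 3-4-5 triangle -> 5.0
  res <- atoms_from_xyz(rbind(c(0, 9, 0), c(1, 9, 0), c(2, 9, 0), c(3, 9, 0),
                              c(0, 0, 0)),
                        name = c("N", "CA", "C", "O", "CB"),
                        is_hetero = FALSE) |>
    dplyr::mutate(residue_name = "SER", residue_number = 7L)
  lig <- atoms_from_xyz(rbind(c(3, 4, 0), c(6, 8, 0)))
  d <- min_residue_ligand_distance(res, "A", 7, lig)
  expect_equal(d$min_distance, 5)
  expect_false(d$used_ca)

  same <- min_residue_ligand_distance(res, "A", 7,
                                      atoms_from_xyz(rbind(c(0, 0, 0))))
  expect_equal(same$min_distance, 0)
  st <- trp_gly_pdb_lines()

  set.seed(27)
  res3 <- atoms_from_xyz(matrix(runif(9, 0, 5), ncol = 3),
                         name = c("CB", "CG", "CD1"), is_hetero = FALSE) |>
    dplyr::mutate(residue_name = "XXX", residue_number = 50L)
  lig4 <- random_atoms(4)
  got <- min_residue_ligand_distance(res3, "A", 50, lig4)
  want <- min(cross <- outer(seq_len(3), seq_len(4), Vectorize(function(i, j) {
    sqrt(sum((as.numeric(res3[i, c("x", "y", "z")]) -
                as.numeric(lig4[j, c("x", "y", "z")]))^2))
  })))
  expect_equal(got$min_distance, want)

  gly <- min_residue_ligand_distance(st, "A", 11, lig)
  expect_true(gly$used_ca)
})
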