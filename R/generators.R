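#' Generate a toy reference ligand spanning the subsite array
#'
#' Builds an acarbose-like heavy-atom ligand of `n_moieties` sugar-ring
#' stand-ins whose centroids are equally spaced along +x. The first moiety
#' is assigned subsite -1 and the rest +1, +2, ... The axis anchors (C4A in
#' the first moiety, C1 in the second) lie on the x axis, and the origin
#' anchor N4A projects exactly midway between the -1 and +1 moiety
#' centroids, so the calibrated subsite coordinates are known in closed
#' form: moiety i sits at `spacing * (i - 1) - spacing / 2`.
#'
#' @param n_moieties Number of moieties (>= 2).
#' @param atoms_per_moiety Heavy atoms per moiety (>= 2).
#' @param spacing Centroid spacing, Angstrom (> 0).
#' @param seed Random seed for the within-moiety atom scatter.
#' @return A [ref_ligand()]; the true axis/origin are recorded in the
#'   `"ground_truth"` attribute.
#' @export
gen_reference_ligand <- function(n_moieties = 4, atoms_per_moiety = 5,
                                 spacing = 4, seed = 1) {
  if (n_moieties < 2) stop_gt("Need at least 2 moieties.", "gt_validation_error")
  if (atoms_per_moiety < 2) {
    stop_gt("Need at least 2 atoms per moiety (the first moiety hosts two anchors).",
            "gt_validation_error")
  }
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  set.seed(seed)
  centers <- spacing * (seq_len(n_moieties) - 1)
  origin_x <- mean(centers[1:2])
  subsites <- c(-1L, seq_len(n_moieties - 1L))

  rows <- purrr::map(seq_len(n_moieties), function(i) {
    m <- atoms_per_moiety
    off <- matrix(stats::runif(3 * m, -spacing / 4, spacing / 4), ncol = 3)
    name <- sprintf("X%d%d", i, seq_len(m))
    if (i == 1) {
      name[1] <- "C4A"; off[1, 2:3] <- 0        # axis start, on the x axis
      name[2] <- "N4A"                          # origin anchor
      off[2, 1] <- origin_x - centers[1]        # projects to the true origin
      free <- setdiff(seq_len(m), 2L)
    } else if (i == 2) {
      name[1] <- "C1"; off[1, 2:3] <- 0         # axis end, on the x axis
      free <- seq_len(m)
    } else {
      free <- seq_len(m)
    }
    # shift the unconstrained x offsets so the moiety centroid is exact
    off[free, 1] <- off[free, 1] - sum(off[, 1]) / length(free)
    tibble::tibble(
      serial = (i - 1L) * m + seq_len(m),
      name = name, element = "C",
      residue_name = "LIG", residue_number = 1L, chain_id = "A",
      x = centers[i] + off[, 1], y = off[, 2], z = off[, 3],
      is_hetero = TRUE, subsite = subsites[i]
    )
  })
  atoms <- dplyr::bind_rows(rows)
  out <- ref_ligand(atoms, subsite = atoms$subsite)
  attr(out, "ground_truth") <- list(direction = c(1, 0, 0),
                                    origin = c(origin_x, 0, 0),
                                    moiety_coordinates = centers - origin_x)
  out
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate docked poses as rigid displacements of a reference ligand
#'
#' Each pose is the reference heavy-atom set rigidly translated along the
#' binding axis by `displacement_along_axis` (recycled over poses),
#' optionally rotated by a uniform random rotation about its centroid, and
#' perturbed by isotropic Gaussian jitter. The generating displacement of
#' every pose is recorded as ground truth, and placeholder docking scores
#' ranked by model are attached.
#'
#' @param reference A [ref_ligand()], e.g. from [gen_reference_ligand()].
#' @param n_poses Number of poses (default 20, a typical docking-run size).
#' @param displacement_along_axis Rigid shift(s) along the axis, Angstrom.
#' @param jitter_sd Isotropic Gaussian jitter SD per coordinate, Angstrom.
#' @param rotation Apply a uniform random rotation about the pose centroid.
#' @param seed Random seed.
#' @return Atom tibble with a `model` column; attributes `"ground_truth"`
#'   (tibble `model`, `displacement`) and `"vina_scores"` (placeholder).
#' @export
gen_poses <- function(reference, n_poses = 20, displacement_along_axis = 0,
                      jitter_sd = 0, rotation = FALSE, seed = 1) {
  if (n_poses < 1) stop_gt("n_poses must be >= 1.", "gt_validation_error")
  assert_scalar_num(jitter_sd, "jitter_sd", nonneg = TRUE)
  set.seed(seed)
  axis <- build_binding_axis(reference)
  disp <- rep_len(displacement_along_axis, n_poses)
  base <- coord_matrix(reference)
  poses <- purrr::map(seq_len(n_poses), function(i) {
    xyz <- base
    if (rotation) {
      u <- stats::rnorm(3)
      ang <- stats::runif(1, 0, 2 * pi)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(rotation_matrix(u, ang)), 2, ctr, `+`)
    }
    xyz <- sweep(xyz, 2, disp[i] * axis$direction, `+`)
    if (jitter_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_sd), ncol = 3)
    }
    tibble::tibble(
      model = i,
      serial = seq_len(nrow(xyz)),
      name = reference$name, element = reference$element,
      residue_name = reference$residue_name,
      residue_number = reference$residue_number,
      chain_id = reference$chain_id,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      is_hetero = TRUE
    )
  })
  out <- dplyr::bind_rows(poses)
  attr(out, "ground_truth") <- tibble::tibble(model = seq_len(n_poses),
                                              displacement = disp)
  attr(out, "vina_scores") <- tibble::tibble(model = seq_len(n_poses),
                                             score = -10 + 0.1 * (seq_len(n_poses) - 1))
  out
}

#' Generate a Michaelis-Menten initial-velocity dataset
#'
#' Velocities follow v = Vmax [S] / (KM + [S]) with Vmax = kcat times the
#' molar enzyme concentration, over the acceptor concentration design used
#' for glucanotransferase acceptor kinetics (0.32-10 mM by default), with
#' optional multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`.
#'
#' @param km Michaelis constant, mM.
#' @param kcat Turnover number, min^-1.
#' @param enzyme_concentration Enzyme, mg/ml (default 0.097).
#' @param enzyme_molar_mass Molar mass, Da (default 76002).
#' @param concentrations Acceptor concentrations, mM.
#' @param noise_cv Multiplicative noise CV (default 0).
#' @param seed Random seed.
#' @return Tibble `concentration_mM`, `velocity` (uM min^-1); generating
#'   parameters in the `"ground_truth"` attribute.
#' @export
gen_mm_dataset <- function(km, kcat, enzyme_concentration = 0.097,
                           enzyme_molar_mass = 76002,
                           concentrations = c(0.32, 0.63, 1.25, 2.5, 5, 10),
                           noise_cv = 0, seed = 1) {
  assert_scalar_num(km, "km", positive = TRUE)
  assert_scalar_num(kcat, "kcat", nonneg = TRUE)
  assert_scalar_num(noise_cv, "noise_cv", nonneg = TRUE)
  set.seed(seed)
  e_um <- enzyme_molar_concentration(enzyme_concentration, enzyme_molar_mass)
  vmax <- kcat * e_um
  v <- vmax * concentrations / (km + concentrations)
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), sd = noise_cv))
  out <- tibble::tibble(concentration_mM = concentrations, velocity = v)
  attr(out, "ground_truth") <- list(km = km, kcat = kcat, vmax = vmax,
                                    enzyme_concentration = enzyme_concentration,
                                    enzyme_molar_mass = enzyme_molar_mass,
                                    noise_cv = noise_cv, seed = seed)
  out
}

#' Generate a microbial growth curve with lag, exponential and stationary phases
#'
#' Density stays at `n0` until `lag_h`, grows as `n0 * exp(k * (t - lag_h))`
#' afterwards, and is capped at `stationary_cap`, with optional
#' multiplicative Gaussian noise.
#'
#' @param k Specific growth rate, h^-1.
#' @param n0 Inoculum density, cells/ml.
#' @param lag_h Lag duration, h.
#' @param stationary_cap Carrying capacity, cells/ml (default Inf).
#' @param sample_times Sampling times, h.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Random seed.
#' @return Tibble `time_h`, `density`; generating parameters in the
#'   `"ground_truth"` attribute.
#' @export
gen_growth_curve <- function(k, n0 = 1e7, lag_h = 0, stationary_cap = Inf,
                             sample_times = seq(0, 8, by = 1),
                             noise_cv = 0, seed = 1) {
  assert_scalar_num(k, "k")
  assert_scalar_num(n0, "n0", positive = TRUE)
  assert_scalar_num(noise_cv, "noise_cv", nonneg = TRUE)
  set.seed(seed)
  d <- ifelse(sample_times <= lag_h, n0, n0 * exp(k * (sample_times - lag_h)))
  d <- pmin(d, stationary_cap)
  if (noise_cv > 0) d <- d * (1 + stats::rnorm(length(d), sd = noise_cv))
  out <- tibble::tibble(time_h = sample_times, density = d)
  attr(out, "ground_truth") <- list(k = k, n0 = n0, lag_h = lag_h,
                                    stationary_cap = stationary_cap,
                                    noise_cv = noise_cv, seed = seed)
  out
}
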