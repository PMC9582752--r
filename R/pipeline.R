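# Pipeline orchestration: config-driven runs with manifests, mirroring the
# analyze-poses / fit-kinetics / simulate / gen-fixtures subcommands of the
# command-line wrapper (inst/cli/gt-pipeline.R).

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_gt(sprintf("Config file not found: %s", config), "gt_io_error")
    }
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_gt("YAML configs need the 'yaml' package; use JSON instead.", "gt_io_error")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_gt("Config must be a list or a JSON/YAML path.", "gt_validation_error")
  config
}

write_manifest <- function(out_dir, stage, config, seed) {
  manifest <- list(
    stage = stage,
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("gtkit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

resolve_reference <- function(cfg, seed) {
  if (!is.null(cfg$synthetic)) {
    s <- cfg$synthetic
    gen_reference_ligand(n_moieties = s$n_moieties %||% 4,
                         atoms_per_moiety = s$atoms_per_moiety %||% 5,
                         spacing = s$spacing %||% 4,
                         seed = s$seed %||% seed)
  } else {
    if (is.null(cfg$path)) stop_gt("Reference config needs `path` or `synthetic`.", "gt_validation_error")
    st <- read_structure(cfg$path, dialect = cfg$dialect %||% "pdb")
    mm <- unlist(cfg$moiety_map)
    extract_reference_ligand(st, residue_name = cfg$residue_name,
                             residue_number = cfg$residue_number,
                             chain = cfg$chain,
                             anchors = unlist(cfg$anchors) %||% c("C4A", "C1", "N4A"),
                             moiety_map = mm)
  }
}

#' Run the docking-pose analysis stage
#'
#' Reads (or synthesises) a reference ligand and a set of docked poses,
#' computes per-pose geometry metrics (positional coordinate along the
#' binding axis, greedy sub-angstrom match percentage, assigned subsite),
#' optionally reports minimum residue-ligand distances for configured
#' residues of a receptor structure, and writes TSV + JSON results plus a
#' reproducibility manifest.
#'
#' @param config A list or JSON/YAML path. Sections: `reference` (either
#'   `path`/`residue_name`/`anchors`/`moiety_map` or `synthetic`), `poses`
#'   (either `path`/`dialect` or `synthetic` with `n_poses`,
#'   `displacement_along_axis`, `jitter_sd`, `rotation`), optional
#'   `receptor` (`path`, `residues` as list of `chain`/`number`), and
#'   scalars `threshold`, `max_distance`, `seed`, `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with `metrics` (tibble) and `distances`
#'   (tibble or NULL).
#' @export
run_analyze_poses <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  reference <- resolve_reference(config$reference %||% list(synthetic = list()), seed)

  pcfg <- config$poses %||% list(synthetic = list())
  poses <- if (!is.null(pcfg$synthetic)) {
    s <- pcfg$synthetic
    gen_poses(reference,
              n_poses = s$n_poses %||% 20,
              displacement_along_axis = unlist(s$displacement_along_axis) %||% 0,
              jitter_sd = s$jitter_sd %||% 0,
              rotation = isTRUE(s$rotation),
              seed = s$seed %||% seed)
  } else {
    if (is.null(pcfg$path) || !file.exists(pcfg$path %||% "")) {
      stop_gt(sprintf("[analyze-poses] pose file not found: %s", pcfg$path %||% "<missing>"),
              "gt_io_error")
    }
    read_structure(pcfg$path, dialect = pcfg$dialect %||% "multi_model_pdb")
  }

  metrics <- pose_metrics(poses, reference,
                          threshold = config$threshold %||% 1.0,
                          max_distance = config$max_distance %||% 2.0,
                          ligand_name = pcfg$ligand_name %||% "ligand")

  utils::write.table(metrics, file.path(out_dir, "pose_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "pose_metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  distances <- NULL
  if (!is.null(config$receptor)) {
    rc <- config$receptor
    receptor <- read_structure(rc$path, dialect = rc$dialect %||% "pdb")
    distances <- purrr::map_dfr(rc$residues, function(r) {
      min_residue_ligand_distance(receptor, r$chain %||% "A", r$number,
                                  ligand_atoms = reference)
    })
    utils::write.table(distances, file.path(out_dir, "residue_distances.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  write_manifest(out_dir, "analyze-poses", config, seed)
  invisible(list(metrics = metrics, distances = distances))
}

#' Run the kinetics-fitting stage
#'
#' Fits Michaelis-Menten parameters per acceptor by the Lineweaver-Burk
#' method (with kcat and kcat/KM when enzyme concentration and molar mass
#' are configured), computes transglycosylation factors from an activity
#' table, and writes a kinetics report. A fit failure for one acceptor is
#' reported without aborting the others.
#'
#' @param config List or JSON/YAML path. Sections: `datasets` (list of
#'   `name` + either `path` to a CSV with columns concentration_mM,velocity
#'   or `synthetic` with `km`/`kcat`/`noise_cv`), `enzyme_concentration`
#'   (mg/ml), `enzyme_molar_mass` (Da), optional `activity` (`path` to a CSV
#'   with condition,specific_activity,sd or inline `rows`), `baseline`,
#'   `seed`, `out_dir`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `fits` (tibble), `transglycosylation`
#'   (tibble or NULL), `errors` (named character).
#' @export
run_fit_kinetics <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  ec <- config$enzyme_concentration
  mm <- config$enzyme_molar_mass

  if (is.null(config$datasets) || !length(config$datasets)) {
    stop_gt("[fit-kinetics] config$datasets is empty.", "gt_validation_error")
  }

  errors <- character(0)
  fit_rows <- purrr::map(config$datasets, function(ds) {
    data <- if (!is.null(ds$synthetic)) {
      s <- ds$synthetic
      gen_mm_dataset(km = s$km, kcat = s$kcat,
                     enzyme_concentration = ec %||% 0.097,
                     enzyme_molar_mass = mm %||% 76002,
                     concentrations = unlist(s$concentrations) %||%
                       c(0.32, 0.63, 1.25, 2.5, 5, 10),
                     noise_cv = s$noise_cv %||% 0,
                     seed = s$seed %||% seed)
    } else {
      if (is.null(ds$path) || !file.exists(ds$path)) {
        stop_gt(sprintf("[fit-kinetics] dataset file not found: %s", ds$path %||% "<missing>"),
                "gt_io_error")
      }
      tibble::as_tibble(utils::read.csv(ds$path))
    }
    tryCatch({
      fit <- fit_lineweaver_burk(data, enzyme_concentration = ec,
                                 enzyme_molar_mass = mm)
      tibble::tibble(acceptor = ds$name %||% "unnamed",
                     KM_mM = fit$KM, Vmax = fit$Vmax,
                     kcat_per_min = fit$kcat, efficiency = fit$efficiency,
                     r_squared = fit$r_squared, n = fit$n)
    }, gtkit_error = function(e) {
      errors[[ds$name %||% "unnamed"]] <<- conditionMessage(e)
      NULL
    })
  })
  fits <- dplyr::bind_rows(fit_rows)

  tf <- NULL
  if (!is.null(config$activity)) {
    act <- if (!is.null(config$activity$path)) {
      tibble::as_tibble(utils::read.csv(config$activity$path))
    } else {
      dplyr::bind_rows(purrr::map(config$activity$rows, tibble::as_tibble))
    }
    if (!"sd" %in% names(act)) act$sd <- NA_real_
    tf <- transglycosylation_factors(act, baseline = config$baseline %||% "no acceptor")
    utils::write.table(tf, file.path(out_dir, "transglycosylation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  utils::write.table(fits, file.path(out_dir, "kinetics_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fits = fits, transglycosylation = tf,
                            errors = as.list(errors)),
                       file.path(out_dir, "kinetic_fits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "fit-kinetics", config, seed)
  invisible(list(fits = fits, transglycosylation = tf, errors = errors))
}

#' Run the disproportionation-simulation stage
#'
#' @param config List or JSON/YAML path. Fields: `preset` (or `profile`
#'   overrides: `affinities`, rates), `initial` (named amounts, e.g.
#'   `list(G5 = 10)`), `duration` (min), `mode`, `seed`, `omega`,
#'   `early_time` (snapshot for the product summary; default duration/10),
#'   `out_dir`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `simulation` (gt_sim) and `profile_at_early`
#'   (tibble).
#' @export
run_simulate <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  prof_args <- config$profile %||% list()
  profile <- subsite_profile(
    preset = config$preset %||% "GH57_PSGT",
    affinities = unlist(prof_args$affinities),
    cleavage_rate = prof_args$cleavage_rate %||% 0.003,
    hydrolysis_rate = prof_args$hydrolysis_rate %||% 0.05,
    transfer_rate = prof_args$transfer_rate %||% 1,
    plus_overhang = prof_args$plus_overhang %||% 1L,
    max_length = prof_args$max_length %||% 20L,
    max_pnp_length = prof_args$max_pnp_length %||% 12L
  )
  initial <- unlist(config$initial %||% list(G5 = 10))
  duration <- config$duration %||% 120

  sim <- simulate_disproportionation(initial, profile, duration,
                                     mode = config$mode %||% "deterministic",
                                     seed = seed,
                                     omega = config$omega %||% 1)
  early <- config$early_time %||% (duration / 10)
  prof_early <- product_profile(sim, early)

  utils::write.csv(sim$trajectory, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.table(prof_early, file.path(out_dir, "product_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "simulate", config, seed)
  invisible(list(simulation = sim, profile_at_early = prof_early))
}

#' Generate the full synthetic fixture set
#'
#' Writes a toy reference ligand and docked poses as PDB, Michaelis-Menten
#' datasets and growth curves as CSV, and a ground-truth JSON sidecar, so a
#' complete pipeline run needs no external downloads.
#'
#' @param config List or JSON/YAML path; fields `seed`, `out_dir`, plus
#'   optional overrides mirroring the generator arguments.
#' @param out_dir Output directory.
#' @return Invisibly, the ground-truth list.
#' @export
run_gen_fixtures <- function(config = list(), out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  reference <- gen_reference_ligand(seed = seed)
  poses <- gen_poses(reference, n_poses = config$n_poses %||% 20,
                     displacement_along_axis = config$displacement_along_axis %||% 0,
                     jitter_sd = config$jitter_sd %||% 0.2,
                     rotation = FALSE, seed = seed)
  write_structure(reference, file.path(out_dir, "reference_ligand.pdb"))
  write_structure(poses, file.path(out_dir, "poses.pdb"))

  mm_params <- config$mm %||% list(
    list(name = "glucose", km = 6.76, kcat = 1141),
    list(name = "maltose", km = 1.81, kcat = 2008),
    list(name = "maltotriose", km = 0.86, kcat = 2635)
  )
  for (p in mm_params) {
    d <- gen_mm_dataset(p$km, p$kcat, noise_cv = p$noise_cv %||% 0, seed = seed)
    utils::write.csv(d, file.path(out_dir, sprintf("mm_%s.csv", p$name)),
                     row.names = FALSE)
  }
  growth_params <- config$growth %||% list(
    list(name = "starch", k = 0.493),
    list(name = "maltose", k = 0.332)
  )
  for (p in growth_params) {
    g <- gen_growth_curve(p$k, noise_cv = p$noise_cv %||% 0, seed = seed)
    utils::write.csv(g, file.path(out_dir, sprintf("growth_%s.csv", p$name)),
                     row.names = FALSE)
  }

  truth <- list(seed = seed,
                reference = attr(reference, "ground_truth"),
                poses = attr(poses, "ground_truth"),
                mm = mm_params, growth = growth_params)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "gen-fixtures", config, seed)
  invisible(truth)
}
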