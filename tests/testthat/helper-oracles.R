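# Independent oracles and fixture builders used across the test files.

# atom tibble from a coordinate matrix
atoms_from_xyz <- function(xyz, name = NULL, element = "C", residue_name = "LIG",
                           chain_id = "A", residue_number = 1L, is_hetero = TRUE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    model = 1L,
    serial = seq_len(n),
    name = name %||% sprintf("X%d", seq_len(n)),
    element = rep_len(element, n),
    residue_name = residue_name,
    residue_number = residue_number,
    chain_id = chain_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hetero = is_hetero
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_atoms <- function(n, lo = 0, hi = 10) {
  atoms_from_xyz(matrix(runif(3 * n, lo, hi), ncol = 3))
}

# brute-force replay of the sorted-pair removal rule: materialise every
# pose-reference pair, sort by (distance, pose index, ref index), accept a
# pair when both atoms are still unused and the distance is < threshold
brute_force_match_count <- function(pose_xyz, ref_xyz, threshold = 1.0) {
  np <- nrow(pose_xyz); nr <- nrow(ref_xyz)
  pairs <- expand.grid(p = seq_len(np), r = seq_len(nr))
  pairs$d <- sqrt(rowSums((pose_xyz[pairs$p, , drop = FALSE] -
                             ref_xyz[pairs$r, , drop = FALSE])^2))
  pairs <- pairs[order(pairs$d, pairs$p, pairs$r), ]
  used_p <- logical(np); used_r <- logical(nr)
  matches <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (pairs$d[i] >= threshold) break
    p <- pairs$p[i]; r <- pairs$r[i]
    if (!used_p[p] && !used_r[r]) {
      used_p[p] <- TRUE; used_r[r] <- TRUE
      matches <- matches + 1L
    }
  }
  matches
}

# exact maximum bipartite matching size under a distance cap
# (Kuhn's augmenting-path algorithm on the <threshold adjacency)
max_bipartite_matches <- function(pose_xyz, ref_xyz, threshold = 1.0) {
  np <- nrow(pose_xyz); nr <- nrow(ref_xyz)
  adj <- lapply(seq_len(np), function(p) {
    d <- sqrt(colSums((t(ref_xyz) - pose_xyz[p, ])^2))
    which(d < threshold)
  })
  aug <- function(p, env) {
    for (r in adj[[p]]) {
      if (!env$seen[r]) {
        env$seen[r] <- TRUE
        if (env$match_r[r] == 0L || aug(env$match_r[r], env)) {
          env$match_r[r] <- p
          return(TRUE)
        }
      }
    }
    FALSE
  }
  env <- new.env()
  env$match_r <- integer(nr)
  total <- 0L
  for (p in seq_len(np)) {
    env$seen <- logical(nr)
    if (aug(p, env)) total <- total + 1L
  }
  total
}

# apply one rigid transform (rotation matrix R, translation t) to an atom table
transform_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

random_rotation <- function() {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# rigid transform of a ref_ligand, preserving its attributes
transform_reference <- function(reference, R, t) {
  out <- transform_atoms(reference, R, t)
  attributes(out) <- modifyList(attributes(reference),
                                attributes(out)[c("names", "row.names")])
  out
}

# hand-written PDB fixture: a tryptophan residue (all 14 heavy atoms) plus a
# second residue, used by the alanine-truncation tests
trp_gly_pdb_lines <- function() {
  trp_names <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                 "CE2", "CE3", "CZ2", "CZ3", "CH2")
  trp <- atoms_from_xyz(cbind(seq_along(trp_names), 0, 0), name = trp_names,
                        element = substr(trp_names, 1, 1),
                        residue_name = "TRP", residue_number = 10L,
                        is_hetero = FALSE)
  gly <- atoms_from_xyz(cbind(20 + 1:4, 0, 0), name = c("N", "CA", "C", "O"),
                        element = c("N", "C", "C", "O"),
                        residue_name = "GLY", residue_number = 11L,
                        is_hetero = FALSE)
  ala <- atoms_from_xyz(cbind(30 + 1:5, 0, 0), name = c("N", "CA", "C", "O", "CB"),
                        element = c("N", "C", "C", "O", "C"),
                        residue_name = "ALA", residue_number = 12L,
                        is_hetero = FALSE)
  dplyr::bind_rows(trp, gly, ala) |>
    dplyr::mutate(serial = dplyr::row_number())
}

write_tmp_structure <- function(atoms) {
  path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  write_structure(atoms, path)
  path
}
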