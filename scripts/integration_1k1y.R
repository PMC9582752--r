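#!/usr/bin/env Rscript
# OPTIONAL integration run against the real template structure.
#
# Downloads the Thermococcus litoralis 4-alpha-glucanotransferase /acarbose
# complex (PDB 1K1Y), extracts the bound acarbose from chain A, builds the
# substrate-binding axis from its C4A/C1 anchors with the N4A projection as
# origin, and writes the docking-box configuration plus the subsite
# calibration. Given a multi-model pose file for a docked acceptor (e.g.
# converted AutoDock Vina output), it also writes per-pose metrics; pose
# coordinates are expected to cluster near +3 and -4 Angstrom for acceptors
# bound at the +1 and -1 subsites.
#
# Requires network access for the PDB download; not part of the test suite.
#
# Usage:
#   Rscript scripts/integration_1k1y.R [poses.pdb] [out_dir]

suppressPackageStartupMessages(library(gtkit))

args <- commandArgs(trailingOnly = TRUE)
poses_path <- if (length(args) >= 1) args[1] else NA
out_dir <- if (length(args) >= 2) args[2] else "results/1k1y"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pdb_path <- file.path(out_dir, "1k1y.pdb")
if (!file.exists(pdb_path)) {
  utils::download.file("https://files.rcsb.org/download/1K1Y.pdb", pdb_path,
                       quiet = TRUE)
}

st <- read_structure(pdb_path, chain = "A")

# acarbose is deposited as linked glucose/acarviosine residues; collect the
# HETATM records of the inhibitor chain and annotate moieties by residue:
# the acarviosine unit spans -1/+1 and the two glucoses sit at +2/+3
acr <- st[st$is_hetero & st$residue_name %in% c("ACR", "GLC", "ACI", "4AD", "GAC"), ]
if (!"N4A" %in% acr$name) {
  stop("Could not locate the acarbose N4A atom in 1K1Y chain A; ",
       "inspect the HETATM residue names and adjust the selector.")
}
acr <- heavy_atoms(acr)
resids <- sort(unique(acr$residue_number))
subsite_by_res <- stats::setNames(c(-1L, 1L, 2L, 3L)[seq_along(resids)], resids)
reference <- ref_ligand(acr, subsite = subsite_by_res[as.character(acr$residue_number)])

cfg <- emit_docking_config(reference)  # 30 A cube, exhaustiveness 100, 20 modes
write_docking_config(cfg, file.path(out_dir, "vina_box.txt"))

cal <- calibrate_subsites(reference)
utils::write.table(cal, file.path(out_dir, "subsite_calibration.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
print(cal)

if (!is.na(poses_path)) {
  poses <- read_structure(poses_path, dialect = "multi_model_pdb")
  metrics <- pose_metrics(poses, reference)
  utils::write.table(metrics, file.path(out_dir, "pose_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  print(metrics)
}
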