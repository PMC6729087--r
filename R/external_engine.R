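# Adapter for an external Vina-compatible docking binary. The meta-protocols
# are engine-agnostic: any binary speaking the conventional CLI contract
# (--receptor/--ligand PDBQT, --center_*/--size_*, --exhaustiveness,
# --num_modes, --energy_range, --seed, multi-MODEL PDBQT output) can stand in
# for the built-in engine.

external_engine_args <- function(config, box, receptor_path, ligand_path,
                                 out_path) {
  c("--receptor", receptor_path,
    "--ligand", ligand_path,
    "--out", out_path,
    "--center_x", format(box$center[1]), "--center_y", format(box$center[2]),
    "--center_z", format(box$center[3]),
    "--size_x", format(box$size[1]), "--size_y", format(box$size[2]),
    "--size_z", format(box$size[3]),
    "--exhaustiveness", format(config$exhaustiveness),
    "--num_modes", format(config$num_modes),
    "--energy_range", format(config$energy_range),
    "--seed", format(config$seed))
}

#' Dock with an external Vina-compatible binary
#'
#' Writes the receptor and ligand as PDBQT, invokes the binary, and parses
#' its multi-MODEL PDBQT output into a pose pool. On any failure (missing
#' binary, nonzero exit, unparseable output) an error carrying the tool's
#' stderr is raised and the temporary files are removed.
#'
#' @param cplx a \code{prepared_complex}.
#' @param config an \code{engine_config}.
#' @param binary_path path to the docking executable.
#' @param tree the ligand's \code{torsion_tree} (computed if missing).
#' @param fragment optional \code{fragment_state}; the full ligand by default.
#' @param workdir directory for the temporary input/output files.
#' @return A \code{pose_pool} sorted by score.
#' @export
dock_external <- function(cplx, config, binary_path, tree = NULL,
                          fragment = NULL, workdir = tempfile("dock")) {
  stopifnot(inherits(cplx, "prepared_complex"), inherits(config, "engine_config"))
  if (!nzchar(Sys.which(binary_path)) && !file.exists(binary_path))
    stop("external docking engine not found: ", binary_path, call. = FALSE)
  lig <- cplx$ligand
  if (is.null(tree)) tree <- build_torsion_tree(lig)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  rec_path <- file.path(workdir, "receptor.pdbqt")
  lig_path <- file.path(workdir, "ligand.pdbqt")
  out_path <- file.path(workdir, "out.pdbqt")
  writeLines(format_atom_line(cplx$receptor$atoms, "ATOM", pdbqt = TRUE), rec_path)
  coords <- if (is.null(fragment)) lig$reference_coords else fragment$coords
  write_pdbqt(lig, tree, pose_coords = coords, path = lig_path)
  box <- config$box %||% cplx$box
  args <- external_engine_args(config, box, rec_path, lig_path, out_path)
  err_file <- file.path(workdir, "stderr.txt")
  status <- suppressWarnings(
    system2(binary_path, args, stdout = FALSE, stderr = err_file))
  if (!identical(status, 0L) || !file.exists(out_path))
    stop("external docking engine failed (exit ", status, "): ",
         paste(readLines(err_file, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  parse_external_output(readLines(out_path), lig, tree)
}

# Parse multi-MODEL PDBQT engine output into a pose pool over the ligand's
# atoms. PDBQT output renumbers atoms in tree order, so coordinates are
# mapped back through the same tree ordering used on write.
parse_external_output <- function(lines, lig, tree) {
  parsed <- read_pdbqt(lines)
  order_idx <- c(tree$root, unlist(lapply(tree$branches, `[[`, "atoms")))
  pose_list <- parsed$poses %||% list(atom_coords(parsed$ligand$atoms))
  scores <- parsed$scores %||% NA_real_
  n <- nrow(lig$atoms)
  poses <- lapply(seq_along(pose_list), function(i) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[order_idx, ] <- pose_list[[i]]
    new_pose(xyz, seq_len(n),
             score = if (i <= length(scores)) scores[i] else NA_real_,
             provenance = list(instance = NA_integer_, run = i, seed = NA))
  })
  sort_pool(pose_pool(poses))
}
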