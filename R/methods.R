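# Compact print and summary methods for the package's S3 classes.

#' @export
print.dock_ligand <- function(x, ...) {
  cat(sprintf("<dock_ligand> %s: %d atoms (%d heavy), %d bonds, %d rotatable\n",
              x$id %||% "ligand", nrow(x$atoms), sum(is_heavy(x)),
              nrow(x$bonds), count_dofs(x)))
  invisible(x)
}

#' @export
print.dock_receptor <- function(x, ...) {
  cat(sprintf("<dock_receptor> %s: %d atoms (%d heavy)\n",
              x$id %||% "receptor", nrow(x$atoms), sum(is_heavy(x))))
  invisible(x)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d model(s); model 1: %d atoms\n",
              length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

#' @export
print.prepared_complex <- function(x, ...) {
  cat(sprintf(
    "<%s> receptor %d atoms | ligand %d atoms, %d rotatable bonds\n",
    class(x)[1], nrow(x$receptor$atoms), nrow(x$ligand$atoms),
    count_dofs(x$ligand)))
  cat(sprintf("  box center (%.1f, %.1f, %.1f), size (%.1f, %.1f, %.1f) A\n",
              x$box$center[1], x$box$center[2], x$box$center[3],
              x$box$size[1], x$box$size[2], x$box$size[3]))
  invisible(x)
}

#' @export
print.torsion_tree <- function(x, ...) {
  cat(sprintf("<torsion_tree> root group of %d atoms, %d branches (%d DoFs)\n",
              length(x$root), length(x$branches), x$n_dofs))
  invisible(x)
}

#' @export
print.dock_schedule <- function(x, ...) {
  cat(sprintf(
    "<dock_schedule> %d round(s), %d initial DoFs, +%d bonds/round: %s\n",
    x$rounds, x$k, x$new_bonds,
    paste(x$explored_counts, collapse = " -> ")))
  invisible(x)
}

#' @export
print.fragment_state <- function(x, ...) {
  cat(sprintf(
    "<fragment_state> round %d: %d atoms, %d explored bonds (%d active)\n",
    x$round_index, length(x$atoms), length(x$explored), length(x$active)))
  invisible(x)
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf("<dock_pose> %d atoms, score %.3f\n", length(x$atoms), x$score))
  invisible(x)
}

#' @export
print.pose_pool <- function(x, ...) {
  s <- vapply(x$poses, `[[`, 0, "score")
  cat(sprintf("<pose_pool> %d pose(s)", length(s)))
  if (length(s)) cat(sprintf(", scores %.3f .. %.3f", min(s), max(s)))
  cat("\n")
  invisible(x)
}

#' @export
summary.pose_pool <- function(object, lig = NULL, ...) {
  s <- vapply(object$poses, `[[`, 0, "score")
  out <- data.frame(pose = seq_along(s), score = s)
  if (!is.null(lig))
    out$rmsd <- vapply(object$poses, function(p) rmsd_all_atom(lig, p),
                       numeric(1))
  out
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf(
    "<engine_config> exhaustiveness %d (%d runs), num_modes %d, energy_range %g, seed %d\n",
    x$exhaustiveness, x$runs_per_exhaustiveness * x$exhaustiveness,
    x$num_modes, x$energy_range, x$seed))
  invisible(x)
}

#' @export
print.protocol_config <- function(x, ...) {
  detail <- switch(x$kind,
    single = "1 engine call",
    multi = sprintf("%d instances", x$instances),
    incremental = sprintf("%d threads x %d rounds, +%d bonds/round",
                          x$threads, x$rounds, x$new_bonds))
  cat(sprintf("<protocol_config> %s (%s), engine exhaustiveness %d, master seed %d\n",
              x$kind, detail, x$engine$exhaustiveness, x$master_seed))
  invisible(x)
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat(sprintf(
    "<evaluation_record> %s [%s]: top-RMSD %.2f +/- %.2f A (best %.2f, %s)\n",
    x$complex_id, x$protocol, x$mean, x$sd, x$best,
    if (x$success) "success" else "failure"))
  invisible(x)
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table> %d complexes x %d protocols\n",
              nrow(x$table) - 1L, length(x$protocols)))
  print(x$table, digits = 3, row.names = FALSE)
  cat("\nsummary:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
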