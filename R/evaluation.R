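# Redocking evaluation: all-atom no-superposition RMSD, top-RMSD vs
# top-scoring conformations, strict 2 A success calls, replicate statistics
# and benchmark tables.

#' All-atom RMSD between a reference conformation and a pose
#'
#' The strictest RMSD convention: computed over all ligand heavy atoms with
#' fixed 1:1 correspondence and no superposition, so it measures changes in
#' conformation, position and orientation within the fixed receptor frame.
#' Hydrogens are excluded.
#'
#' @param lig a \code{dock_ligand}; its \code{reference_coords} are the
#'   reference (crystal or planted) pose. Alternatively an n x 3 coordinate
#'   matrix paired with \code{heavy = NULL} (all rows used).
#' @param pose a \code{dock_pose} covering all ligand atoms, or an n x 3
#'   coordinate matrix.
#' @param backbone_only optional logical vector marking atoms to restrict
#'   the RMSD to (e.g. a backbone mask); the default uses all heavy atoms.
#' @return RMSD in Angstrom.
#' @export
rmsd_all_atom <- function(lig, pose, backbone_only = NULL) {
  if (inherits(lig, "dock_ligand")) {
    ref <- lig$reference_coords
    heavy <- is_heavy(lig)
  } else {
    ref <- as.matrix(lig)
    heavy <- rep(TRUE, nrow(ref))
  }
  xyz <- if (inherits(pose, "dock_pose")) {
    if (length(pose$atoms) != nrow(ref))
      stop("pose does not cover all ligand atoms (atom-count mismatch)",
           call. = FALSE)
    pose$coords
  } else as.matrix(pose)
  if (nrow(xyz) != nrow(ref))
    stop("coordinate sets differ in atom count", call. = FALSE)
  mask <- if (is.null(backbone_only)) heavy else heavy & backbone_only
  d <- ref[mask, , drop = FALSE] - xyz[mask, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Top-RMSD conformation of a pose pool
#'
#' The produced pose closest to the reference in all-atom RMSD, regardless
#' of score: the sampling-power summary of a pool. Ties are broken by better
#' score, then lower pose index.
#'
#' @param pool a non-empty \code{pose_pool} of full-ligand poses.
#' @param lig the \code{dock_ligand} carrying the reference coordinates.
#' @return List with elements \code{pose} and \code{rmsd}.
#' @export
top_rmsd <- function(pool, lig) {
  stopifnot(inherits(pool, "pose_pool"))
  if (!length(pool$poses)) stop("pose pool is empty", call. = FALSE)
  r <- vapply(pool$poses, function(p) rmsd_all_atom(lig, p), numeric(1))
  s <- vapply(pool$poses, `[[`, 0, "score")
  best <- order(r, s, seq_along(r))[1L]
  list(pose = pool$poses[[best]], rmsd = r[best])
}

#' Top-scoring conformation of a pose pool
#'
#' The pose with the best (lowest) engine score: the scoring-power summary.
#' Ties are broken by lower RMSD to the reference when one is supplied,
#' otherwise by pose index.
#'
#' @param pool a non-empty \code{pose_pool}.
#' @param lig optional \code{dock_ligand} reference for tie-breaking.
#' @return A \code{dock_pose}.
#' @export
top_scoring <- function(pool, lig = NULL) {
  stopifnot(inherits(pool, "pose_pool"))
  if (!length(pool$poses)) stop("pose pool is empty", call. = FALSE)
  s <- vapply(pool$poses, `[[`, 0, "score")
  r <- if (is.null(lig)) seq_along(s)
       else vapply(pool$poses, function(p) rmsd_all_atom(lig, p), numeric(1))
  pool$poses[[order(s, r, seq_along(s))[1L]]]
}

#' Redocking success call
#'
#' A crystal structure counts as successfully reproduced when the all-atom
#' RMSD is strictly below 2 Angstrom.
#'
#' @param rmsd non-negative RMSD value(s) in Angstrom.
#' @return Logical vector.
#' @export
is_success <- function(rmsd) {
  if (any(rmsd < 0)) stop("RMSD must be non-negative", call. = FALSE)
  rmsd < 2.0
}

#' Replicate statistics
#'
#' @param values per-replicate top-RMSD values (Angstrom), length >= 1.
#' @return Named numeric vector: \code{mean}, \code{sd} (sample, n-1; 0 for
#'   a single replicate) and \code{best} (minimum).
#' @export
replicate_stats <- function(values) {
  if (!length(values)) stop("no replicate values", call. = FALSE)
  s <- if (length(values) == 1L) 0 else sd(values)
  c(mean = mean(values), sd = s, best = min(values))
}

#' Per-complex evaluation record
#'
#' @param complex_id complex label.
#' @param n_dofs,n_heavy ligand rotatable-bond and heavy-atom counts.
#' @param rmsds per-replicate top-RMSD values (Angstrom).
#' @param protocol protocol label.
#' @return Object of class \code{evaluation_record}: the inputs plus
#'   \code{mean}, \code{sd}, \code{best} and \code{success}
#'   (\code{best < 2} Angstrom).
#' @export
evaluation_record <- function(complex_id, n_dofs, n_heavy, rmsds,
                              protocol = "protocol") {
  st <- replicate_stats(rmsds)
  structure(list(complex_id = complex_id, n_dofs = as.integer(n_dofs),
                 n_heavy = as.integer(n_heavy), protocol = protocol,
                 per_replicate_top_rmsd = rmsds,
                 mean = unname(st["mean"]), sd = unname(st["sd"]),
                 best = unname(st["best"]),
                 success = unname(is_success(st["best"]))),
            class = "evaluation_record")
}

#' Benchmark table over complexes and protocols
#'
#' One row per complex (id, DoFs, heavy atoms, then mean and sd columns per
#' protocol), a final average row, and a per-protocol failure rate (fraction
#' of complexes whose best replicate RMSD is >= 2 Angstrom).
#'
#' @param records list of \code{evaluation_record}s covering every complex
#'   under every protocol.
#' @param protocols protocol labels and column order; default: order of
#'   first appearance in \code{records}.
#' @return Object of class \code{benchmark_table}: list with \code{table}
#'   (data.frame) and \code{summary} (per-protocol mean of means, mean of
#'   sds, failure rate).
#' @export
benchmark_table <- function(records, protocols = NULL) {
  stopifnot(length(records) > 0)
  ids <- unique(vapply(records, `[[`, "", "complex_id"))
  protocols <- protocols %||% unique(vapply(records, `[[`, "", "protocol"))
  key <- paste(vapply(records, `[[`, "", "complex_id"),
               vapply(records, `[[`, "", "protocol"))
  need <- as.vector(outer(ids, protocols, paste))
  if (!all(need %in% key) || anyDuplicated(key))
    stop("records must contain exactly one entry per complex per protocol",
         call. = FALSE)
  rec_at <- function(id, pr) records[[match(paste(id, pr), key)]]
  tab <- data.frame(complex_id = ids,
                    dofs = vapply(ids, function(i) rec_at(i, protocols[1])$n_dofs, 0L),
                    atoms = vapply(ids, function(i) rec_at(i, protocols[1])$n_heavy, 0L),
                    stringsAsFactors = FALSE)
  for (pr in protocols) {
    tab[[paste0("mean_", pr)]] <- vapply(ids, function(i) rec_at(i, pr)$mean, 0)
    tab[[paste0("sd_", pr)]] <- vapply(ids, function(i) rec_at(i, pr)$sd, 0)
  }
  avg <- tab[1, ]
  avg$complex_id <- "average"; avg$dofs <- NA_integer_; avg$atoms <- NA_integer_
  for (pr in protocols) {
    avg[[paste0("mean_", pr)]] <- mean(tab[[paste0("mean_", pr)]])
    avg[[paste0("sd_", pr)]] <- mean(tab[[paste0("sd_", pr)]])
  }
  summary <- data.frame(
    protocol = protocols,
    mean_of_means = vapply(protocols, function(pr) mean(tab[[paste0("mean_", pr)]]), 0),
    mean_of_sds = vapply(protocols, function(pr) mean(tab[[paste0("sd_", pr)]]), 0),
    failure_rate = vapply(protocols, function(pr)
      mean(!vapply(ids, function(i) rec_at(i, pr)$success, logical(1))), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = rbind(tab, avg), summary = summary,
                 protocols = protocols),
            class = "benchmark_table")
}

#' Write a benchmark table as CSV
#'
#' @param bt a \code{benchmark_table}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_benchmark_csv <- function(bt, path) {
  stopifnot(inherits(bt, "benchmark_table"))
  utils::write.csv(bt$table, path, row.names = FALSE)
  invisible(path)
}
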