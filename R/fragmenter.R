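# Incremental fragment schedule and geometric fragment growth.
#
# The incremental protocol docks larger and larger overlapping fragments of
# the ligand. Only a constant number k of bonds (the fragment size) is
# actively sampled in any round; previously explored bonds are frozen at
# their docked torsion values. Growth order is breadth-first from the root so
# fragments stay compact contiguous subtrees.

#' Build an incremental docking schedule
#'
#' Given N rotatable bonds, r docking rounds and b new bonds per round, the
#' fragment size is determined as k = N - (r - 1) * b. When that k would drop
#' below 1, the number of rounds is reduced to the largest value keeping
#' k >= 1 (with a message).
#'
#' @param n_dofs number of rotatable bonds N of the full ligand.
#' @param rounds requested number of docking rounds r.
#' @param new_bonds new flexible bonds added at each round b.
#' @return An object of class \code{dock_schedule}: list with \code{rounds},
#'   \code{new_bonds}, \code{k} (fragment size) and \code{explored_counts}
#'   (cumulative explored-bond count per round, ending at N).
#' @export
make_schedule <- function(n_dofs, rounds, new_bonds) {
  n_dofs <- stopifnot_scalar_int(n_dofs, "n_dofs", min = 0L)
  rounds <- stopifnot_scalar_int(rounds, "rounds")
  new_bonds <- stopifnot_scalar_int(new_bonds, "new_bonds")
  if (n_dofs == 0L)
    stop("ligand is rigid (0 rotatable bonds): use single-round rigid docking",
         call. = FALSE)
  k <- n_dofs - (rounds - 1L) * new_bonds
  if (k < 1L) {
    rounds <- (n_dofs - 1L) %/% new_bonds + 1L
    k <- n_dofs - (rounds - 1L) * new_bonds
    message(sprintf("rounds clamped to %d so the fragment size stays >= 1 (k = %d)",
                    rounds, k))
  }
  structure(list(rounds = rounds, new_bonds = new_bonds, k = k,
                 explored_counts = as.integer(seq(k, n_dofs, by = new_bonds))),
            class = "dock_schedule")
}

# All atoms in the subtree hanging off branch b (the branch's own rigid group
# plus every descendant branch's group).
branch_subtree_atoms <- function(tree, b) {
  parents <- vapply(tree$branches, `[[`, 0L, "parent")
  todo <- b
  out <- integer()
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    out <- c(out, tree$branches[[cur]]$atoms)
    todo <- c(todo, which(parents == cur))
  }
  sort(out)
}

new_fragment_state <- function(atoms, explored, active, round_index, coords) {
  structure(list(atoms = atoms, explored = explored, active = active,
                 round_index = round_index, coords = coords),
            class = "fragment_state")
}

#' Initial fragment of the incremental protocol
#'
#' The first fragment is the root rigid group plus the k branches closest to
#' the root in breadth-first order, all of them active. Atoms beyond an
#' unexplored rotatable bond are absent.
#'
#' @param lig a \code{dock_ligand}.
#' @param tree its \code{torsion_tree}.
#' @param schedule a \code{dock_schedule} from \code{\link{make_schedule}}.
#' @return An object of class \code{fragment_state}: list with \code{atoms}
#'   (sorted ligand atom indices), \code{explored} and \code{active} (branch
#'   indices in exploration order), \code{round_index} and \code{coords}
#'   (template coordinates for the fragment's atoms, rows in \code{atoms}
#'   order; initially the reference geometry).
#' @export
initial_fragment <- function(lig, tree, schedule) {
  stopifnot(inherits(tree, "torsion_tree"), inherits(schedule, "dock_schedule"))
  k <- min(schedule$k, tree$n_dofs)
  explored <- seq_len(k)
  atoms <- sort(c(tree$root, unlist(lapply(explored, function(b)
    tree$branches[[b]]$atoms))))
  new_fragment_state(atoms, explored, active = explored, round_index = 1L,
                     coords = lig$reference_coords[atoms, , drop = FALSE])
}

#' Whole-ligand fragment (all bonds explored and active)
#'
#' Used by the single-run and multi-instance protocols, where the full ligand
#' is docked in one go.
#'
#' @inheritParams initial_fragment
#' @return A \code{fragment_state} covering every atom.
#' @export
full_fragment <- function(lig, tree) {
  n <- nrow(lig$atoms)
  all_b <- seq_len(tree$n_dofs)
  new_fragment_state(seq_len(n), all_b, all_b, round_index = 1L,
                     coords = lig$reference_coords)
}

# Deterministic three-atom frame anchored at `a` (an atom index of the full
# ligand), built from atoms already present in `frag_atoms`, walking toward
# the root via BFS parent pointers.
frame_triple <- function(a, parent_of, frag_atoms) {
  in_frag <- function(x) length(x) && !is.na(x) && x %in% frag_atoms
  f2 <- parent_of[a]
  if (!in_frag(f2)) {
    cand <- setdiff(which(parent_of == a), NA)
    cand <- cand[cand %in% frag_atoms]
    f2 <- if (length(cand)) min(cand) else NA_integer_
  }
  if (is.na(f2)) stop("fragment too small to define a growth frame", call. = FALSE)
  f3 <- parent_of[f2]
  if (!in_frag(f3) || f3 == a) {
    cand <- c(which(parent_of == f2), which(parent_of == a))
    cand <- setdiff(cand[cand %in% frag_atoms], c(a, f2))
    f3 <- if (length(cand)) min(cand) else f2  # collinear fallback in local_frame
  }
  c(a, f2, f3)
}

#' Grow a fragment pose by the next unexplored bonds
#'
#' Adds the next \code{new_bonds} unexplored rotatable bonds (breadth-first
#' from the fragment frontier) together with their atoms. New atoms are
#' positioned by rigidly transplanting the reference internal geometry: each
#' new rigid group is expressed in the local frame of three anchor atoms in
#' the reference conformation and re-expressed in the same frame of the
#' current pose. Existing atoms are not moved, so frozen torsions keep their
#' docked values. The active set becomes the newly added bonds plus the most
#' recently explored previous bonds, up to the fragment size k.
#'
#' @param fragment the current \code{fragment_state}.
#' @param pose a \code{dock_pose} covering the fragment's atoms.
#' @param lig,tree,schedule the ligand, its torsion tree and the schedule.
#' @return The expanded \code{fragment_state} (its \code{coords} carry the
#'   grown geometry).
#' @export
expand_fragment <- function(fragment, pose, lig, tree, schedule) {
  stopifnot(inherits(fragment, "fragment_state"))
  if (!identical(pose$atoms, fragment$atoms))
    stop("pose does not cover the fragment's atoms", call. = FALSE)
  if (fragment$round_index >= schedule$rounds &&
      length(fragment$explored) >= tree$n_dofs)
    stop("fragment already covers the whole ligand", call. = FALSE)
  n_explored <- length(fragment$explored)
  new_idx <- seq(n_explored + 1L, min(n_explored + schedule$new_bonds, tree$n_dofs))

  # full-ligand coordinate scratchpad: current pose + reference for new atoms
  n <- nrow(lig$atoms)
  cur <- matrix(NA_real_, n, 3)
  cur[fragment$atoms, ] <- pose$coords
  ref <- lig$reference_coords

  parent_of <- bfs_parents(lig, tree)
  frag_atoms <- fragment$atoms
  for (b in new_idx) {
    br <- tree$branches[[b]]
    tri <- frame_triple(br$anchor, parent_of, frag_atoms)
    M_ref <- local_frame(ref[tri[1], ], ref[tri[2], ], ref[tri[3], ])
    M_cur <- local_frame(cur[tri[1], ], cur[tri[2], ], cur[tri[3], ])
    rel <- sweep(ref[br$atoms, , drop = FALSE], 2, ref[tri[1], ], "-") %*% M_ref
    cur[br$atoms, ] <- sweep(rel %*% t(M_cur), 2, cur[tri[1], ], "+")
    frag_atoms <- sort(c(frag_atoms, br$atoms))
  }
  explored <- c(fragment$explored, new_idx)
  active <- tail(explored, min(schedule$k, length(explored)))
  new_fragment_state(frag_atoms, explored, active,
                     round_index = fragment$round_index + 1L,
                     coords = cur[frag_atoms, , drop = FALSE])
}

# BFS parent pointer per atom (NA at the starting root atom), rooted in the
# torsion tree's root group.
bfs_parents <- function(lig, tree) {
  g <- ligand_graph(lig)
  res <- igraph::bfs(g, root = tree$root[1], father = TRUE)
  p <- as.integer(res$father)
  p[p == -1L] <- NA_integer_
  p
}

#' Select poses for expansion
#'
#' Poses are ranked by score (best first) and greedily kept when their
#' heavy-atom RMSD to every already-kept pose is at least
#' \code{diversity_rmsd}; if fewer than \code{m} poses survive the diversity
#' filter, the best remaining poses are backfilled regardless of diversity.
#'
#' @param pool a \code{pose_pool}.
#' @param m number of poses to select.
#' @param diversity_rmsd minimum pairwise RMSD (Angstrom) between selected
#'   poses (default 1.0).
#' @param lig optional \code{dock_ligand} supplying heavy-atom flags for the
#'   RMSD; by default all pose atoms are used.
#' @return List of selected \code{dock_pose} objects, scores non-decreasing.
#' @export
select_for_expansion <- function(pool, m, diversity_rmsd = 1.0, lig = NULL) {
  stopifnot(inherits(pool, "pose_pool"))
  if (!length(pool$poses)) stop("pose pool is empty", call. = FALSE)
  m <- stopifnot_scalar_int(m, "m")
  poses <- pool$poses[order(vapply(pool$poses, `[[`, 0, "score"))]
  heavy_rows <- if (is.null(lig)) seq_len(nrow(poses[[1]]$coords))
                else which(is_heavy(lig)[poses[[1]]$atoms])
  prmsd <- function(p, q) {
    d <- p$coords[heavy_rows, , drop = FALSE] - q$coords[heavy_rows, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }
  kept <- list(); kept_i <- integer()
  for (i in seq_along(poses)) {
    if (length(kept) >= m) break
    if (all(vapply(kept, function(q) prmsd(poses[[i]], q) >= diversity_rmsd,
                   logical(1)))) {
      kept[[length(kept) + 1L]] <- poses[[i]]
      kept_i <- c(kept_i, i)
    }
  }
  if (length(kept) < m) {
    rest <- setdiff(seq_along(poses), kept_i)
    extra <- head(rest, m - length(kept))
    kept <- c(kept, poses[extra])
    kept <- kept[order(vapply(kept, `[[`, 0, "score"))]
  }
  kept
}
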