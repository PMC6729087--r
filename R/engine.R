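# Built-in seeded stochastic docking engine.
#
# Each engine call performs runs_per_exhaustiveness * exhaustiveness
# independent runs. A run draws a random conformation (uniform active
# torsions, uniform rigid-body orientation, translation uniform in the box,
# clash-rejected) and refines it by cyclic coordinate descent over
# translation / rotation / active torsions with step halving (2 A and 30 deg
# down to 0.01 A and 0.25 deg, to score convergence 1e-4). Resulting poses
# are clustered at 1 A heavy-atom RMSD and filtered by num_modes and
# energy_range, mirroring the output conventions of Vina-family engines.

#' Engine configuration
#'
#' @param exhaustiveness number of independent-run units; the engine performs
#'   \code{runs_per_exhaustiveness * exhaustiveness} runs (default 8, the
#'   conventional default of Vina-family engines).
#' @param num_modes maximum number of binding modes returned (default 25).
#' @param energy_range maximum score difference between the best and worst
#'   returned mode (default 10).
#' @param seed integer seed; every source of randomness in an engine call is
#'   derived from it.
#' @param runs_per_exhaustiveness internal runs per exhaustiveness unit
#'   (default 4).
#' @param cluster_rmsd heavy-atom RMSD threshold (Angstrom) for clustering
#'   the refined poses (default 1.0).
#' @param box optional box override (list of \code{center}, \code{size});
#'   by default the prepared complex's box is used.
#' @return An object of class \code{engine_config}.
#' @export
engine_config <- function(exhaustiveness = 8, num_modes = 25, energy_range = 10,
                          seed = 1L, runs_per_exhaustiveness = 4,
                          cluster_rmsd = 1.0, box = NULL) {
  exhaustiveness <- stopifnot_scalar_int(exhaustiveness, "exhaustiveness")
  num_modes <- stopifnot_scalar_int(num_modes, "num_modes")
  if (energy_range < 0) stop("energy_range must be >= 0", call. = FALSE)
  structure(list(exhaustiveness = exhaustiveness, num_modes = num_modes,
                 energy_range = energy_range, seed = as.integer(seed),
                 runs_per_exhaustiveness = as.integer(runs_per_exhaustiveness),
                 cluster_rmsd = cluster_rmsd, box = box),
            class = "engine_config")
}

new_pose <- function(coords, atoms, score, torsions = numeric(),
                     provenance = list()) {
  structure(list(coords = unname(coords), atoms = atoms, score = score,
                 torsions = torsions, provenance = provenance),
            class = "dock_pose")
}

#' Pose pool constructor
#'
#' @param poses list of \code{dock_pose} objects over a common atom set.
#' @param fragment the \code{fragment_state} the poses cover (may be NULL).
#' @param log data.frame run log (one row per engine call).
#' @return An object of class \code{pose_pool}.
#' @export
pose_pool <- function(poses, fragment = NULL, log = NULL) {
  if (length(poses)) {
    at <- poses[[1]]$atoms
    ok <- vapply(poses, function(p) identical(p$atoms, at), logical(1))
    if (!all(ok)) stop("poses in a pool must cover the same atom set", call. = FALSE)
  }
  structure(list(poses = poses, fragment = fragment, log = log),
            class = "pose_pool")
}

#' @export
sort_pool <- function(pool) {
  pool$poses <- pool$poses[order(vapply(pool$poses, `[[`, 0, "score"))]
  pool
}

merge_pools <- function(pools, fragment = NULL) {
  poses <- do.call(c, lapply(pools, `[[`, "poses"))
  logs <- Filter(Negate(is.null), lapply(pools, `[[`, "log"))
  log <- if (length(logs)) do.call(rbind, logs) else NULL
  sort_pool(pose_pool(poses, fragment = fragment %||% pools[[1]]$fragment,
                      log = log))
}

# Precomputed scoring context for one receptor + fragment pairing.
score_context <- function(rec, lig, fragment) {
  rec_heavy <- which(is_heavy(rec))
  rec_xyz <- atom_coords(rec$atoms)[rec_heavy, , drop = FALSE]
  rec_rad <- element_radius(rec$atoms$element[rec_heavy])
  atoms <- fragment$atoms
  heavy_local <- which(is_heavy(lig)[atoms])
  lig_rad <- element_radius(lig$atoms$element[atoms[heavy_local]])
  # ligand-internal nonbonded pairs: heavy atoms at graph distance >= 3
  g <- ligand_graph(lig)
  gd <- igraph::distances(g, v = atoms, to = atoms)
  hv <- heavy_local
  pairs <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  if (nrow(pairs)) {
    keep <- pairs[, 1] %in% hv & pairs[, 2] %in% hv
    pairs <- pairs[keep, , drop = FALSE]
  }
  rs <- if (nrow(pairs))
    element_radius(lig$atoms$element[atoms[pairs[, 1]]]) +
    element_radius(lig$atoms$element[atoms[pairs[, 2]]])
  else numeric()
  list(rec_xyz = rec_xyz, rec_rad = rec_rad, heavy = heavy_local,
       lig_rad = lig_rad, pair_i = as.integer(pairs[, 1]),
       pair_j = as.integer(pairs[, 2]), pair_rsum = rs)
}

# Fragment-local torsion descriptors for the active bonds. `quad` holds the
# four atoms of the measurable dihedral (lowest-index heavy neighbours on
# each side), or NULL when the fragment lacks a fourth atom.
fragment_torsions <- function(lig, tree, fragment) {
  local <- function(i) match(i, fragment$atoms)
  heavy <- is_heavy(lig)
  nb_of <- function(i) {
    b <- lig$bonds
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  }
  lapply(fragment$active, function(b) {
    br <- tree$branches[[b]]
    move <- intersect(branch_subtree_atoms(tree, b), fragment$atoms)
    na <- setdiff(nb_of(br$anchor), br$pivot)
    nbp <- setdiff(nb_of(br$pivot), br$anchor)
    na <- na[heavy[na] & na %in% fragment$atoms]
    nbp <- nbp[heavy[nbp] & nbp %in% fragment$atoms]
    quad <- if (length(na) && length(nbp))
      local(c(min(na), br$anchor, br$pivot, min(nbp))) else NULL
    list(anchor = local(br$anchor), pivot = local(br$pivot),
         move = local(move), branch = b, quad = quad)
  })
}

# Fast torsion measurement from precomputed quadruples.
measure_tv <- function(xyz, tors) {
  vapply(tors, function(t) {
    if (is.null(t$quad)) return(NA_real_)
    measure_dihedral(xyz[t$quad[1], ], xyz[t$quad[2], ],
                     xyz[t$quad[3], ], xyz[t$quad[4], ])
  }, numeric(1))
}

#' Score a ligand conformation against a rigid receptor
#'
#' Deterministic empirical contact score. For every receptor/ligand
#' heavy-atom pair within 8 Angstrom, with gap \eqn{s = d - (r_i + r_j)}
#' (element radii: C 1.9, N 1.8, O 1.7, S 2.0, P 2.1, default 1.8 Angstrom),
#' the pair contributes \eqn{-0.05 e^{-(s/0.5)^2}} plus a repulsive wall
#' \eqn{0.8 s^2} when \eqn{s < 0}. Ligand-internal heavy-atom pairs at graph
#' distance >= 3 contribute \eqn{0.8 s^2} when \eqn{s < -0.5}. Lower is
#' better. The score is charge-free.
#'
#' @param rec a \code{dock_receptor}.
#' @param lig a \code{dock_ligand}.
#' @param coords n x 3 conformation (default: the ligand's reference
#'   coordinates). When scoring a fragment, rows follow \code{atoms}.
#' @param atoms optional ligand atom indices (a fragment's atom set).
#' @return Numeric score.
#' @export
score_pose <- function(rec, lig, coords = NULL, atoms = NULL) {
  frag <- if (is.null(atoms)) full_fragment(lig, build_torsion_tree(lig))
          else new_fragment_state(atoms, integer(), integer(), 1L, NULL)
  ctx <- score_context(rec, lig, frag)
  if (is.null(coords)) coords <- lig$reference_coords[frag$atoms, , drop = FALSE]
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  cpp_score(coords, ctx$heavy, ctx$lig_rad, ctx$rec_xyz, ctx$rec_rad,
            ctx$pair_i, ctx$pair_j, ctx$pair_rsum)
}

# Measure the torsion values (degrees) of the given branches in a fragment
# conformation; NA when the dihedral's fourth atom is absent from the fragment.
measure_fragment_torsions <- function(coords, lig, tree, fragment,
                                      branches = fragment$active) {
  g <- ligand_graph(lig)
  heavy <- is_heavy(lig)
  local <- function(i) match(i, fragment$atoms)
  vapply(branches, function(b) {
    br <- tree$branches[[b]]
    na <- setdiff(as.integer(igraph::neighbors(g, br$anchor)), br$pivot)
    nb <- setdiff(as.integer(igraph::neighbors(g, br$pivot)), br$anchor)
    na <- na[heavy[na] & na %in% fragment$atoms]
    nb <- nb[heavy[nb] & nb %in% fragment$atoms]
    if (!length(na) || !length(nb)) return(NA_real_)
    measure_dihedral(coords[local(min(na)), ], coords[local(br$anchor), ],
                     coords[local(br$pivot), ], coords[local(min(nb)), ])
  }, numeric(1))
}

#' Draw a random conformation of a fragment inside the docking box
#'
#' Active torsions are drawn uniformly in [-180, 180) degrees, the rigid-body
#' orientation uniformly over rotations, and the translation uniformly over
#' the positions that keep every atom inside the box. Placements with a hard
#' receptor clash (any heavy-atom pair gap below -1 Angstrom) are rejected
#' and redrawn, up to \code{max_tries} times.
#'
#' Uses the current RNG state; seed it (or use the \code{seed} argument) for
#' reproducible draws.
#'
#' @param cplx a \code{prepared_complex}.
#' @param fragment a \code{fragment_state} (default: the whole ligand).
#' @param tree the ligand's \code{torsion_tree}.
#' @param seed optional seed applied locally without disturbing the caller's
#'   RNG state.
#' @param max_tries clash-rejection budget (default 100).
#' @return A \code{dock_pose} (unscored poses carry the randomized
#'   coordinates and measured active-torsion values).
#' @export
randomize_conformation <- function(cplx, fragment = NULL, tree = NULL,
                                   seed = NULL, max_tries = 100L) {
  stopifnot(inherits(cplx, "prepared_complex"))
  lig <- cplx$ligand
  if (is.null(tree)) tree <- build_torsion_tree(lig)
  if (is.null(fragment)) fragment <- full_fragment(lig, tree)
  if (!is.null(seed))
    return(with_seed(seed, randomize_conformation(cplx, fragment, tree,
                                                  seed = NULL, max_tries)))
  ctx <- score_context(cplx$receptor, lig, fragment)
  tors <- fragment_torsions(lig, tree, fragment)
  box <- cplx$box
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  xyz <- randomize_xyz(fragment, tors, ctx, lo, hi, max_tries)
  tv <- measure_fragment_torsions(xyz, lig, tree, fragment)
  new_pose(xyz, fragment$atoms, score = NA_real_, torsions = tv)
}

# Inner randomization on precomputed context; consumes the current RNG stream.
randomize_xyz <- function(fragment, tors, ctx, lo, hi, max_tries = 100L) {
  xyz <- cpp_randomize(fragment$coords, ctx$heavy, ctx$lig_rad, ctx$rec_xyz,
                       ctx$rec_rad, tors, lo, hi, as.integer(max_tries))
  if (!nrow(xyz))
    stop(sprintf("could not place the fragment without hard clashes in %d tries ",
                 max_tries), "(box too small or occupied)", call. = FALSE)
  xyz
}

# Anchored start for the later incremental rounds: keep the carried fragment
# pose (the placement found by earlier rounds), resample only the freshly
# added torsions uniformly, and apply a small rigid-body perturbation. The
# pose is shifted back inside the box if the perturbation pushed it out.
# Consumes the current RNG stream.
anchored_xyz <- function(fragment, tors, fresh, lo, hi,
                         max_rot_deg = 20, max_shift = 0.5) {
  xyz <- fragment$coords
  for (t in tors) {
    if (!(t$branch %in% fresh)) next
    xyz[t$move, ] <- rotate_about_bond(xyz[t$move, , drop = FALSE],
                                       xyz[t$anchor, ], xyz[t$pivot, ],
                                       stats::runif(1, -pi, pi))
  }
  R <- rotation_matrix(stats::rnorm(3),
                       stats::runif(1, 0, max_rot_deg) * pi / 180)
  ctr <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, ctr, "-") %*% t(R), 2,
               ctr + stats::runif(3, -max_shift, max_shift), "+")
  shift <- pmax(lo - apply(xyz, 2, min), 0) + pmin(hi - apply(xyz, 2, max), 0)
  sweep(xyz, 2, shift, "+")
}

#' Dock a fragment with the built-in engine
#'
#' Performs \code{runs_per_exhaustiveness * exhaustiveness} independent runs
#' (randomize + local refinement), clusters the refined poses at
#' \code{cluster_rmsd} heavy-atom RMSD keeping the best-scoring
#' representative of each cluster, and returns at most \code{num_modes}
#' representatives within \code{energy_range} of the best score, sorted by
#' score. Fully deterministic given \code{config$seed}.
#'
#' With \code{anchor = TRUE} (used by the incremental protocol from its
#' second round on) every other run starts from the fragment's carried
#' coordinates instead of a fully random placement: only the freshly added
#' torsions (\code{fresh_branches}) are resampled, plus a small rigid-body
#' perturbation, so the placement information transmitted by earlier rounds
#' is exploited as well as re-explored.
#'
#' @param cplx a \code{prepared_complex}.
#' @param config an \code{engine_config}.
#' @param fragment a \code{fragment_state} (default: the whole ligand).
#' @param tree the ligand's \code{torsion_tree} (computed if missing).
#' @param instance,round,lineage provenance labels recorded in the run log.
#' @param anchor start half of the runs from the fragment's carried pose.
#' @param fresh_branches branch indices whose torsions are resampled in
#'   anchored runs (the bonds added in the current round).
#' @return A \code{pose_pool} sorted by score.
#' @export
dock <- function(cplx, config = engine_config(), fragment = NULL, tree = NULL,
                 instance = 1L, round = 1L, lineage = 0L, anchor = FALSE,
                 fresh_branches = integer()) {
  stopifnot(inherits(cplx, "prepared_complex"), inherits(config, "engine_config"))
  lig <- cplx$ligand
  if (is.null(tree)) tree <- build_torsion_tree(lig)
  if (is.null(fragment)) fragment <- full_fragment(lig, tree)
  ctx <- score_context(cplx$receptor, lig, fragment)
  tors <- fragment_torsions(lig, tree, fragment)
  box <- config$box %||% cplx$box
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  n_runs <- config$runs_per_exhaustiveness * config$exhaustiveness
  tor_args <- lapply(tors, function(t) t[c("anchor", "pivot", "move")])
  poses <- vector("list", n_runs)
  failed <- 0L
  for (j in seq_len(n_runs)) {
    run_seed <- mix_seed(config$seed, j)
    start <- if (anchor && j %% 2L == 1L)
      with_seed(run_seed, anchored_xyz(fragment, tors, fresh_branches, lo, hi))
    else tryCatch(
      with_seed(run_seed, randomize_xyz(fragment, tors, ctx, lo, hi)),
      error = function(e) NULL)
    if (is.null(start)) { failed <- failed + 1L; next }
    ref <- cpp_refine(start, ctx$heavy, ctx$lig_rad, ctx$rec_xyz,
                      ctx$rec_rad, ctx$pair_i, ctx$pair_j, ctx$pair_rsum,
                      tor_args, lo, hi)
    poses[[j]] <- new_pose(ref$coords, fragment$atoms, ref$score,
                           torsions = measure_tv(ref$coords, tors),
                           provenance = list(instance = instance, run = j,
                                             seed = run_seed))
  }
  poses <- Filter(Negate(is.null), poses)
  if (!length(poses))
    stop("no docking run survived placement (empty pose pool)", call. = FALSE)
  poses <- cluster_poses(poses, ctx$heavy, config$cluster_rmsd)
  best <- poses[[1]]$score
  keep <- vapply(poses, function(p) p$score <= best + config$energy_range,
                 logical(1))
  poses <- head(poses[keep], config$num_modes)
  log <- data.frame(round = round, lineage = lineage, instance = instance,
                    seed = config$seed, exhaustiveness = config$exhaustiveness,
                    n_runs = n_runs, n_failed = failed,
                    best_score = best)
  pose_pool(poses, fragment = fragment, log = log)
}

# Greedy score-ordered clustering: keep a pose when its heavy-atom RMSD to
# every kept representative is >= threshold.
cluster_poses <- function(poses, heavy_rows, threshold) {
  poses <- poses[order(vapply(poses, `[[`, 0, "score"))]
  if (threshold <= 0) return(poses)
  kept <- list()
  for (p in poses) {
    ok <- TRUE
    for (q in kept) {
      d <- p$coords[heavy_rows, , drop = FALSE] - q$coords[heavy_rows, , drop = FALSE]
      if (sqrt(mean(rowSums(d^2))) < threshold) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- p
  }
  kept
}
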