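# The three compared docking protocols.
#
# * single: one engine call on the whole ligand (the "just raise the
#   exhaustiveness" baseline).
# * multi: n independent engine calls with distinct seeds, pose pools merged
#   (parallelized meta-docking; results are a pure function of the seeds, so
#   concurrent and sequential execution agree).
# * incremental: dock a small fragment, select diverse well-scored poses,
#   grow them by a few bonds, re-dock, repeat until the full ligand is
#   reconstructed (parallelized incremental meta-docking).
#
# Budget accounting: one thread = one engine call per round, so the
# incremental protocol with T threads and r rounds costs r * T engine calls;
# each engine call performs runs_per_exhaustiveness * exhaustiveness internal
# runs. The per-call log carried by the returned pool makes budget-matched
# comparisons auditable.

#' Protocol configuration
#'
#' Defaults follow the conventional protocol choices for this family of
#' methods: the multi-instance baseline runs 12 instances at exhaustiveness
#' 8; the incremental protocol runs 3 rounds with 3 new bonds per round on
#' 24 threads with exhaustiveness 4; num_modes 25 and energy_range 10
#' throughout (large pose pools make the evaluation less dependent on the
#' scoring function).
#'
#' @param kind one of \code{"single"}, \code{"multi"}, \code{"incremental"}.
#' @param instances number of engine instances n (multi).
#' @param threads docking tasks per round (incremental).
#' @param rounds docking rounds r (incremental).
#' @param new_bonds new flexible bonds per round b (incremental).
#' @param engine an \code{engine_config}; its seed is overridden by seeds
#'   derived from \code{master_seed}.
#' @param expansion_size number of poses selected for expansion per round m
#'   (default: \code{threads}).
#' @param diversity_rmsd diversity threshold (Angstrom) for expansion
#'   selection (default 1.0).
#' @param master_seed integer master seed; all engine seeds derive from it.
#' @return An object of class \code{protocol_config}.
#' @export
protocol_config <- function(kind = c("incremental", "single", "multi"),
                            instances = 12L, threads = 24L, rounds = 3L,
                            new_bonds = 3L, engine = NULL,
                            expansion_size = NULL, diversity_rmsd = 1.0,
                            master_seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(engine))
    engine <- engine_config(exhaustiveness = if (kind == "incremental") 4L else 8L)
  structure(list(kind = kind,
                 instances = stopifnot_scalar_int(instances, "instances"),
                 threads = stopifnot_scalar_int(threads, "threads"),
                 rounds = stopifnot_scalar_int(rounds, "rounds"),
                 new_bonds = stopifnot_scalar_int(new_bonds, "new_bonds"),
                 engine = engine,
                 expansion_size = expansion_size %||% threads,
                 diversity_rmsd = diversity_rmsd,
                 master_seed = as.integer(master_seed)),
            class = "protocol_config")
}

engine_with_seed <- function(engine, seed) { engine$seed <- as.integer(seed); engine }

#' Run the single-call protocol
#'
#' Randomizes and docks the whole ligand in one engine call.
#'
#' @param cplx a \code{prepared_complex}.
#' @param config a \code{protocol_config}.
#' @return A \code{pose_pool} sorted by score.
#' @export
run_single <- function(cplx, config = protocol_config("single")) {
  stopifnot(inherits(cplx, "prepared_complex"))
  tree <- build_torsion_tree(cplx$ligand)
  frag <- full_fragment(cplx$ligand, tree)
  dock(cplx, engine_with_seed(config$engine, config$master_seed),
       fragment = frag, tree = tree, instance = 1L, round = 1L)
}

#' Run the multi-instance pooled protocol
#'
#' Performs \code{config$instances} independent engine calls with seeds
#' \code{master_seed + 0 .. n-1} and merges their pose pools. An instance
#' failure is logged and tolerated as long as at least one instance returns
#' poses.
#'
#' @inheritParams run_single
#' @return A merged \code{pose_pool} sorted by score.
#' @export
run_multi <- function(cplx, config = protocol_config("multi")) {
  stopifnot(inherits(cplx, "prepared_complex"))
  tree <- build_torsion_tree(cplx$ligand)
  frag <- full_fragment(cplx$ligand, tree)
  pools <- vector("list", config$instances)
  for (i in seq_len(config$instances)) {
    pools[[i]] <- tryCatch(
      dock(cplx, engine_with_seed(config$engine, config$master_seed + i - 1L),
           fragment = frag, tree = tree, instance = i, round = 1L),
      error = function(e) {
        message(sprintf("instance %d failed: %s", i, conditionMessage(e)))
        NULL
      })
  }
  pools <- Filter(Negate(is.null), pools)
  if (!length(pools))
    stop("all docking instances failed (empty pose pool)", call. = FALSE)
  merge_pools(pools, fragment = frag)
}

#' Run the incremental meta-docking protocol
#'
#' Builds the round schedule from the ligand's rotatable-bond count, docks
#' the initial fragment with \code{threads} independent engine calls, then
#' at each subsequent round selects diverse well-scored poses, grows each by
#' \code{new_bonds} bonds, and docks every grown lineage with
#' \code{ceiling(threads / m)} engine calls. Only the last round's
#' (full-ligand) poses are returned. Rigid ligands (0 rotatable bonds) are
#' routed to \code{\link{run_single}}; a single-round schedule reduces
#' exactly to \code{\link{run_multi}} with \code{n = threads}.
#'
#' @inheritParams run_single
#' @return A \code{pose_pool} of full-ligand poses sorted by score.
#' @export
run_incremental <- function(cplx, config = protocol_config("incremental")) {
  stopifnot(inherits(cplx, "prepared_complex"))
  lig <- cplx$ligand
  tree <- build_torsion_tree(lig)
  if (tree$n_dofs == 0L) {
    cfg <- config; cfg$kind <- "single"
    return(run_single(cplx, cfg))
  }
  schedule <- make_schedule(tree$n_dofs, config$rounds, config$new_bonds)
  if (schedule$rounds == 1L) {
    cfg <- config; cfg$kind <- "multi"; cfg$instances <- config$threads
    return(run_multi(cplx, cfg))
  }
  frag <- initial_fragment(lig, tree, schedule)
  pool <- dock_round(cplx, tree, list(frag), config, round = 1L)
  for (r in seq(2L, schedule$rounds)) {
    m <- min(config$expansion_size, length(pool$poses))
    sel <- select_for_expansion(pool, m, config$diversity_rmsd, lig = lig)
    if (!length(sel))
      stop(sprintf("no poses available for expansion at round %d", r),
           call. = FALSE)
    prev_frag <- pool$fragment
    frags <- lapply(sel, function(p)
      expand_fragment(prev_frag, p, lig, tree, schedule))
    fresh <- setdiff(frags[[1L]]$explored, prev_frag$explored)
    pool <- dock_round(cplx, tree, frags, config, round = r, fresh = fresh)
  }
  pool
}

# Dock all lineage fragments of one round, splitting the thread budget
# evenly (ceiling(threads / lineages) calls each), and merge the pools.
# From the second round on, each lineage is docked in a box adapted to its
# carried pose (the expanded fragment's coordinates plus a margin), and half
# of each call's runs start anchored at the carried pose with only the
# round's fresh torsions resampled: the placement found in earlier rounds is
# the information the incremental process transmits, so later rounds search
# around it instead of starting over in the full binding-site box.
dock_round <- function(cplx, tree, frags, config, round, box_margin = 3,
                       fresh = integer()) {
  n_lineages <- length(frags)
  calls_each <- ceiling(config$threads / n_lineages)
  pools <- list()
  for (li in seq_len(n_lineages)) {
    eng <- config$engine
    if (round > 1L && is.null(eng$box)) {
      lo <- apply(frags[[li]]$coords, 2, min) - box_margin
      hi <- apply(frags[[li]]$coords, 2, max) + box_margin
      eng$box <- list(center = (lo + hi) / 2, size = hi - lo)
    }
    for (ci in seq_len(calls_each)) {
      seed <- mix_seed(config$master_seed, round, li, ci)
      pools[[length(pools) + 1L]] <- tryCatch(
        dock(cplx, engine_with_seed(eng, seed), fragment = frags[[li]],
             tree = tree, instance = ci, round = round, lineage = li,
             anchor = round > 1L, fresh_branches = fresh),
        error = function(e) {
          message(sprintf("round %d lineage %d call %d failed: %s",
                          round, li, ci, conditionMessage(e)))
          NULL
        })
    }
  }
  pools <- Filter(Negate(is.null), pools)
  if (!length(pools))
    stop(sprintf("all docking calls of round %d failed (empty pose pool)", round),
         call. = FALSE)
  # poses of one round share an atom set but lineages differ in frozen
  # geometry; the merged pool keeps the first lineage's fragment state as
  # its reference (atom set and schedule position are common to all)
  merge_pools(pools, fragment = frags[[1L]])
}

#' Run a protocol by its configuration
#'
#' Dispatches on \code{config$kind}.
#'
#' @inheritParams run_single
#' @return A \code{pose_pool}.
#' @export
run_protocol <- function(cplx, config) {
  switch(config$kind,
         single = run_single(cplx, config),
         multi = run_multi(cplx, config),
         incremental = run_incremental(cplx, config))
}
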