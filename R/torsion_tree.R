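# Rotatable-bond detection and torsion-tree decomposition.
#
# Convention (AutoDockTools semantics): a bond is rotatable when it is single,
# acyclic (a bridge of the bond graph), non-terminal (each end carries at
# least one further heavy atom), and not an amide C-N bond. Without bond-order
# perception, all acyclic bonds are treated as single and "amide" is detected
# as a C-N bond whose carbon also carries a terminal O or S (carbonyl-like).

ligand_graph <- function(lig) {
  g <- igraph::graph_from_edgelist(lig$bonds, directed = FALSE)
  igraph::add_vertices(g, max(0L, nrow(lig$atoms) - igraph::vcount(g)))
}

#' Detect rotatable bonds of a ligand
#'
#' @param lig a \code{dock_ligand} with a connected bond graph.
#' @return Integer matrix with two columns of atom indices, one row per
#'   rotatable bond, ordered as in \code{lig$bonds}.
#' @export
detect_rotatable_bonds <- function(lig) {
  stopifnot(inherits(lig, "dock_ligand"))
  g <- ligand_graph(lig)
  if (nrow(lig$atoms) > 1L && igraph::components(g)$no != 1L)
    stop("ligand bond graph is not connected", call. = FALSE)
  bonds <- lig$bonds
  if (!nrow(bonds)) return(matrix(integer(), ncol = 2))
  heavy <- is_heavy(lig)
  el <- lig$atoms$element
  # acyclic bonds = bridges
  br <- igraph::bridges(g)
  bridge_pairs <- igraph::as_edgelist(g)[br, , drop = FALSE]
  bridge_key <- paste(pmin(bridge_pairs[, 1], bridge_pairs[, 2]),
                      pmax(bridge_pairs[, 1], bridge_pairs[, 2]))
  nbrs <- igraph::adjacent_vertices(g, seq_len(nrow(lig$atoms)))
  heavy_nbrs_besides <- function(i, j) {
    nb <- setdiff(as.integer(nbrs[[i]]), j)
    sum(heavy[nb])
  }
  terminal_os <- function(ci) {
    nb <- as.integer(nbrs[[ci]])
    any(el[nb] %in% c("O", "S") &
        vapply(nb, function(k) sum(heavy[setdiff(as.integer(nbrs[[k]]), ci)]) == 0L,
               logical(1)))
  }
  keep <- logical(nrow(bonds))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    if (!heavy[i] || !heavy[j]) next
    if (!(paste(min(i, j), max(i, j)) %in% bridge_key)) next
    if (heavy_nbrs_besides(i, j) < 1L || heavy_nbrs_besides(j, i) < 1L) next
    # amide: C-N where the carbon also carries a terminal O/S
    pair <- sort(c(el[i], el[j]))
    if (identical(pair, c("C", "N"))) {
      ci <- if (el[i] == "C") i else j
      if (terminal_os(ci)) next
    }
    keep[r] <- TRUE
  }
  bonds[keep, , drop = FALSE]
}

#' Build the torsion tree of a ligand
#'
#' Removing all rotatable bonds partitions the atoms into rigid groups; the
#' tree is rooted at one group and each rotatable bond becomes a branch whose
#' distal set is the rigid group on the far side. Branches are ordered by
#' breadth-first distance from the root.
#'
#' @param lig a \code{dock_ligand}.
#' @param rotatable_bonds two-column matrix of atom-index pairs; default
#'   \code{\link{detect_rotatable_bonds}(lig)}.
#' @param root_choice atom indices identifying the root rigid group (any
#'   atom of the group suffices); default is the rigid group with the most
#'   heavy atoms, ties broken by lowest minimum atom serial.
#' @return An object of class \code{torsion_tree}: list with \code{root}
#'   (atom indices), \code{branches} (each a list \code{anchor}, \code{pivot},
#'   \code{atoms}, \code{parent}, \code{depth}) and \code{n_dofs}.
#' @export
build_torsion_tree <- function(lig, rotatable_bonds = NULL, root_choice = NULL) {
  stopifnot(inherits(lig, "dock_ligand"))
  if (is.null(rotatable_bonds)) rotatable_bonds <- detect_rotatable_bonds(lig)
  rotatable_bonds <- matrix(as.integer(rotatable_bonds), ncol = 2)
  n <- nrow(lig$atoms)
  bond_key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  if (nrow(rotatable_bonds) &&
      !all(bond_key(rotatable_bonds) %in% bond_key(lig$bonds)))
    stop("rotatable_bonds must be a subset of the ligand's bonds", call. = FALSE)

  # rigid groups: connected components after deleting rotatable bonds
  keep <- !(bond_key(lig$bonds) %in% bond_key(rotatable_bonds))
  g_rigid <- igraph::graph_from_edgelist(lig$bonds[keep, , drop = FALSE],
                                         directed = FALSE)
  g_rigid <- igraph::add_vertices(g_rigid, max(0L, n - igraph::vcount(g_rigid)))
  comp <- igraph::components(g_rigid)$membership
  groups <- split(seq_len(n), comp)

  heavy <- is_heavy(lig)
  if (is.null(root_choice)) {
    nh <- vapply(groups, function(gr) sum(heavy[gr]), 0L)
    ms <- vapply(groups, function(gr) min(lig$atoms$serial[gr]), 0)
    root_gid <- order(-nh, ms)[1L]
  } else {
    root_gid <- unique(comp[root_choice])
    if (length(root_gid) != 1L)
      stop("root_choice does not identify a single rigid group", call. = FALSE)
  }
  root <- groups[[root_gid]]

  # group adjacency via rotatable bonds; BFS from the root group
  gid_of <- comp
  n_groups <- length(groups)
  edges <- lapply(seq_len(nrow(rotatable_bonds)), function(r) {
    c(gid_of[rotatable_bonds[r, 1]], gid_of[rotatable_bonds[r, 2]])
  })
  depth <- rep(NA_integer_, n_groups)
  depth[root_gid] <- 0L
  branch_of_group <- rep(NA_integer_, n_groups)
  branches <- list()
  frontier <- root_gid
  while (length(frontier)) {
    nxt <- integer()
    for (gcur in frontier) {
      for (r in seq_along(edges)) {
        e <- edges[[r]]
        other <- if (e[1] == gcur) e[2] else if (e[2] == gcur) e[1] else next
        if (!is.na(depth[other])) next
        depth[other] <- depth[gcur] + 1L
        anchor <- if (gid_of[rotatable_bonds[r, 1]] == gcur)
          rotatable_bonds[r, 1] else rotatable_bonds[r, 2]
        pivot <- if (anchor == rotatable_bonds[r, 1])
          rotatable_bonds[r, 2] else rotatable_bonds[r, 1]
        branches[[length(branches) + 1L]] <- list(
          anchor = anchor, pivot = pivot, atoms = groups[[other]],
          parent = if (is.na(branch_of_group[gcur])) 0L else branch_of_group[gcur],
          depth = depth[other])
        branch_of_group[other] <- length(branches)
        nxt <- c(nxt, other)
      }
    }
    frontier <- nxt
  }
  if (any(is.na(depth)))
    stop("rotatable bonds disconnect the ligand unexpectedly", call. = FALSE)
  structure(list(root = sort(root), branches = branches,
                 n_dofs = length(branches)),
            class = "torsion_tree")
}

#' Count rotatable bonds (degrees of freedom) of a ligand
#'
#' @param lig a \code{dock_ligand} (prepared).
#' @return Integer DoF count.
#' @export
count_dofs <- function(lig) nrow(detect_rotatable_bonds(lig))

#' Count heavy (non-hydrogen) atoms of a ligand
#'
#' @param lig a \code{dock_ligand}.
#' @return Integer heavy-atom count.
#' @export
count_heavy_atoms <- function(lig) sum(is_heavy(lig))
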