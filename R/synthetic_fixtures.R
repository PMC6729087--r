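# Synthetic test complexes: concave pocket receptors and branched flexible
# ligands with planted reference binding modes. These are abstract heavy-atom
# constructs (geometry + bond graph), not chemically valid molecules: the
# contact score and all meta-algorithms operate on geometry and connectivity
# only, which is exactly what the fixtures exercise. Planted poses play the
# role crystal structures play in real redocking benchmarks.

make_atom_table <- function(xyz, elements, resname = "REC", chain = "A",
                            resid = NULL) {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = paste0(elements, seq_len(n)),
             element = elements,
             resname = resname, resid = resid %||% seq_len(n), chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0,
             stringsAsFactors = FALSE)
}

#' Generate a concave pocket receptor
#'
#' Pseudo-atoms on a spherical shell of the given radius form a cavity whose
#' bottom points toward -z. With \code{depth = 0} the shell is an open
#' hemisphere; larger depths extend the wall past the equator so the mouth
#' narrows, emulating binding sites buried in a protein core. Deterministic
#' given the seed.
#'
#' @param seed integer seed (controls the small jitter on the shell points).
#' @param pocket_radius cavity radius in Angstrom.
#' @param depth mouth-narrowing depth in Angstrom (0 = open hemisphere).
#' @param spacing approximate atom spacing on the shell (default 2.5;
#'   neighbouring 1.9 A carbon spheres still overlap, so the wall is solid).
#' @return A \code{dock_receptor} of carbon pseudo-atoms.
#' @export
make_pocket_receptor <- function(seed, pocket_radius, depth = 0, spacing = 2.5) {
  if (pocket_radius <= 0 || depth < 0)
    stop("pocket_radius must be > 0 and depth >= 0", call. = FALSE)
  theta_max <- pi / 2 + min(atan2(depth, pocket_radius), 75 * pi / 180)
  area <- 2 * pi * pocket_radius^2 * (1 - cos(theta_max))
  n <- max(12L, round(area / spacing^2))
  with_seed(mix_seed(seed, 11L), {
    # Fibonacci spiral over the covered polar range, bottom at -z
    i <- seq_len(n) - 0.5
    cos_t <- 1 - (1 - cos(theta_max)) * i / n   # from ~1 down to cos(theta_max)
    theta <- acos(cos_t)
    phi <- i * pi * (3 - sqrt(5))
    # polar angle measured from -z: bottom of the pocket first
    xyz <- cbind(pocket_radius * sin(theta) * cos(phi),
                 pocket_radius * sin(theta) * sin(phi),
                 -pocket_radius * cos(theta))
    xyz <- xyz + matrix(runif(3 * n, -0.1, 0.1), n, 3)
    receptor(make_atom_table(xyz, rep("C", n)), id = sprintf("pocket%d", seed))
  })
}

# One deterministic topology-growth step; always consumes exactly two RNG
# draws so molecules for increasing n_dofs share a common prefix.
grow_step <- function(bonds, degree, leaves) {
  u1 <- runif(1); u2 <- runif(1)
  # cap degree at 3: adjacent quaternary-like congestion has no clash-free
  # rigid tetrahedral embedding, and real flexible ligands are sparse too
  internals <- which(degree == 2)
  n <- length(degree)
  if (u1 < 0.5 || !length(internals)) {
    # extend a leaf by one atom
    w <- leaves[1L + floor(u2 * length(leaves))]
    bonds <- rbind(bonds, c(w, n + 1L))
    degree[w] <- degree[w] + 1L
    degree <- c(degree, 1L)
    leaves <- c(setdiff(leaves, w), n + 1L)
  } else {
    # add a two-atom branch at an internal atom
    u <- internals[1L + floor(u2 * length(internals))]
    bonds <- rbind(bonds, c(u, n + 1L), c(n + 1L, n + 2L))
    degree[u] <- degree[u] + 1L
    degree <- c(degree, 2L, 1L)
    leaves <- c(leaves, n + 2L)
  }
  list(bonds = bonds, degree = degree, leaves = leaves)
}

# NeRF-style embedding of a bonded tree: standard 1.5 A bond length,
# tetrahedral angles, staggered dihedrals chosen from the RNG stream. Siblings occupy
# distinct staggered slots (-60/60/180 about the common parent axis) so
# branches never overlap; the first child of the root defines the axis and
# later root children are placed relative to it. Slot assignment is a
# backtracking search: every accepted placement must be free of hard
# clashes (gap >= -1.15 A against placed atoms at graph distance >= 3), and
# a dead end unwinds to the previous atom's next free slot. Slot preference
# orders and dihedral jitters are drawn up front so the search itself is
# deterministic given the RNG state.
embed_tree <- function(bonds, n, anti_first = FALSE) {
  parent <- rep(NA_integer_, n)
  order_bfs <- integer(0)
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  queue <- 1L; seen <- rep(FALSE, n); seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w) }
  }
  gd <- igraph::distances(igraph::graph_from_edgelist(bonds, directed = FALSE))
  ang <- 109.47 * pi / 180
  slots <- c(-60, 60, 180)
  # slot preference biased toward anti (180): extended chains are nearly
  # self-avoiding, so high-DoF molecules start from an untangled fold. The
  # first attempt is deterministic: atoms that continue a large subtree (the
  # backbone) prefer anti, small side arms prefer the gauche slots pointing
  # off the backbone
  pref <- if (anti_first) {
    sub_size <- rep(1L, n)
    for (v in rev(order_bfs)) if (!is.na(parent[v]))
      sub_size[parent[v]] <- sub_size[parent[v]] + sub_size[v]
    lapply(seq_len(n), function(i)
      if (sub_size[i] >= 3L) c(3L, 1L, 2L) else c(1L, 2L, 3L))
  } else lapply(seq_len(n), function(i)
    sample.int(3L, prob = c(0.15, 0.15, 0.7)))
  jit <- runif(n, -10, 10)                                 # dihedral jitter

  xyz <- matrix(NA_real_, n, 3)
  used_slots <- vector("list", n)      # staggered slots consumed per parent
  placed_children <- vector("list", n)
  placed <- logical(n)

  # candidate positions for atom v given the current partial embedding:
  # clash-free placements first (in preference order); NULL when stuck
  candidates <- function(v, all = FALSE) {
    p <- parent[v]
    if (is.na(p)) return(list(list(pos = c(0, 0, 0), slot = NA_real_)))
    g <- parent[p]
    if (is.na(g) && !length(placed_children[[p]]))
      return(list(list(pos = xyz[p, ] + c(1.5, 0, 0), slot = NA_real_)))
    g_eff <- if (is.na(g)) placed_children[[p]][1] else g  # sibling arm
    e1 <- xyz[p, ] - xyz[g_eff, ]; e1 <- e1 / sqrt(sum(e1^2))
    # torsion reference: a real placed substituent of g_eff other than p, so
    # slot 0 eclipses it and the staggered slots -60/60/180 interleave with
    # its actual neighbours; an arbitrary axis only when none is placed yet
    cand <- c(parent[g_eff], setdiff(placed_children[[g_eff]], p))
    cand <- cand[!is.na(cand)]
    ref <- if (!length(cand)) c(0, 0, 1) else {
      r0 <- xyz[cand[1], ] - xyz[g_eff, ]; r0 / sqrt(sum(r0^2))
    }
    v2 <- ref - sum(ref * e1) * e1
    if (sqrt(sum(v2^2)) < 1e-6) v2 <- c(0, 1, 0) - e1[2] * e1
    v2 <- v2 / sqrt(sum(v2^2))
    v3 <- c(e1[2] * v2[3] - e1[3] * v2[2],
            e1[3] * v2[1] - e1[1] * v2[3],
            e1[1] * v2[2] - e1[2] * v2[1])
    avail <- setdiff(slots[pref[[v]]], used_slots[[p]])
    others <- which(placed & gd[v, ] >= 3)
    out <- list(); gaps <- numeric()
    for (slot in avail) {
      d <- (slot + jit[v]) * pi / 180
      dir <- cos(pi - ang) * e1 + sin(pi - ang) * (cos(d) * v2 + sin(d) * v3)
      pos <- xyz[p, ] + 1.5 * dir
      gap <- if (length(others))
        min(sqrt(rowSums(sweep(xyz[others, , drop = FALSE], 2, pos, "-")^2))) - 3.8
      else Inf
      if (all | gap >= -1.15) {
        out[[length(out) + 1L]] <- list(pos = pos, slot = slot)
        gaps <- c(gaps, gap)
      }
    }
    if (all && length(out) > 1L) out <- out[order(-gaps)]
    out
  }

  place <- function(v, ch) {
    xyz[v, ] <<- ch$pos
    placed[v] <<- TRUE
    p <- parent[v]
    if (!is.na(p)) {
      used_slots[[p]] <<- c(used_slots[[p]], ch$slot)
      placed_children[[p]] <<- c(placed_children[[p]], v)
    }
  }
  unplace <- function(v) {
    xyz[v, ] <<- NA_real_
    placed[v] <<- FALSE
    p <- parent[v]
    if (!is.na(p)) {
      k <- length(used_slots[[p]])
      used_slots[[p]] <<- used_slots[[p]][-k]
      placed_children[[p]] <<- setdiff(placed_children[[p]], v)
    }
  }

  cand_stack <- vector("list", n)   # remaining candidates per depth
  depth <- 1L
  cand_stack[[1]] <- candidates(order_bfs[1])
  budget <- 50000L
  while (depth >= 1L) {
    if (depth > n) return(xyz)
    cs <- cand_stack[[depth]]
    if (!length(cs)) {                      # dead end: backtrack
      depth <- depth - 1L
      if (depth >= 1L) unplace(order_bfs[depth])
      next
    }
    budget <- budget - 1L
    if (budget <= 0L) break
    cand_stack[[depth]] <- cs[-1]
    place(order_bfs[depth], cs[[1]])
    depth <- depth + 1L
    if (depth <= n) cand_stack[[depth]] <- candidates(order_bfs[depth])
  }
  # no fully clash-free discrete assignment: best-effort greedy embedding
  # (least-clashing slot per atom); the caller relieves residual clashes by
  # continuous torsion-space minimisation
  for (v in order_bfs) if (placed[v]) unplace(v)
  for (v in order_bfs) place(v, candidates(v, all = TRUE)[[1]])
  xyz
}

# Relieve residual internal clashes by coordinate descent over the
# molecule's own rotatable-bond torsions (bond lengths and angles are
# untouched), minimising the ligand-internal score term against an empty
# receptor.
relieve_internal_clashes <- function(xyz, bonds, elements, hops = 12L) {
  lig <- ligand(make_atom_table(xyz, elements, resname = "LIG", resid = 1),
                bonds = bonds, id = "embed")
  tree <- build_torsion_tree(lig)
  frag <- full_fragment(lig, tree)
  tors <- fragment_torsions(lig, tree, frag)
  if (!length(tors)) return(xyz)
  tor_args <- lapply(tors, function(t) t[c("anchor", "pivot", "move")])
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(xyz) - igraph::vcount(g)))
  gd <- igraph::distances(g)
  pairs <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  # shift the radii sums so the internal penalty (active below s = -0.5)
  # activates exactly at the embedding clash gate s = -1.15: gauche contacts
  # then cost nothing and zero penalty coincides with a clash-free embedding
  rs0 <- element_radius(elements[pairs[, 1]]) +
    element_radius(elements[pairs[, 2]])
  descend <- function(x, shift = 0.65)
    cpp_refine(x, seq_len(nrow(x)), element_radius(elements),
               matrix(0, 0, 3), numeric(), as.integer(pairs[, 1]),
               as.integer(pairs[, 2]), rs0 - shift, tor_args,
               rep(-1e6, 3), rep(1e6, 3), conv = 1e-9, max_passes = 40L)
  # annealed descent: first push apart only the deepest overlaps, then
  # tighten the activation gap to the final embedding gate
  out <- descend(xyz, 1.35)
  out <- descend(out$coords, 1.0)
  out <- descend(out$coords, 0.65)
  # basin hopping: kick random torsions and re-descend, keeping the best
  for (hop in seq_len(hops)) {
    if (out$score <= 0) break
    kick <- out$coords
    for (k in sample(length(tor_args), min(3L, length(tor_args)))) {
      tt <- tor_args[[k]]
      kick[tt$move, ] <- rotate_about_bond(kick[tt$move, , drop = FALSE],
                                           kick[tt$anchor, ], kick[tt$pivot, ],
                                           runif(1, -pi, pi))
    }
    trial <- descend(kick)
    if (trial$score < out$score) out <- trial
  }
  out$coords
}

# Hard self-intersections only (pair gap below -1.15 A): tetrahedral gauche
# 1-4 contacts sit around s ~ -0.9 to -1.1 with these inflated contact radii
# and are legitimate covalent geometry, so the embedding gate must accept
# them while still rejecting syn-pentane-like collisions (s < -1.4).
internal_clash_count <- function(xyz, bonds, elements) {
  n <- nrow(xyz)
  if (n < 3) return(0L)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  gd <- igraph::distances(g)
  d <- as.matrix(stats::dist(xyz))
  rs <- outer(element_radius(elements), element_radius(elements), "+")
  sum(gd >= 3 & upper.tri(gd) & (d - rs) < -1.15)
}

#' Generate a branched flexible ligand
#'
#' Builds a connected heavy-atom tree (plus a fused ring when rigid) with
#' exactly \code{n_dofs} bonds classified rotatable by
#' \code{\link{detect_rotatable_bonds}}, embedded with 1.5 Angstrom bonds,
#' tetrahedral angles and seeded staggered dihedrals free of internal
#' clashes. Topology growth consumes a fixed number of random draws per
#' added bond, so for a fixed seed the molecule for \code{n_dofs} is a
#' prefix of the one for \code{n_dofs + 1} and the atom count grows
#' monotonically. Deterministic given \code{(n_dofs, seed)}.
#'
#' @param n_dofs desired rotatable-bond count (0 to 70).
#' @param seed integer seed.
#' @return A \code{dock_ligand} (carbon skeleton with terminal oxygens).
#' @export
make_branched_ligand <- function(n_dofs, seed) {
  n_dofs <- stopifnot_scalar_int(n_dofs, "n_dofs", min = 0L)
  if (n_dofs > 70) stop("n_dofs must be <= 70", call. = FALSE)
  if (n_dofs == 0L) {
    # rigid three-membered ring (smaller than any flexible molecule, so the
    # atom count stays monotone in n_dofs)
    r <- 1.5 / (2 * sin(pi / 3))
    th <- 2 * pi * (0:2) / 3
    xyz <- cbind(r * cos(th), r * sin(th), 0)
    bonds <- cbind(1:3, c(2:3, 1))
    lig <- ligand(make_atom_table(xyz, rep("C", 3), resname = "LIG", resid = 1),
                  bonds = bonds, id = sprintf("rigid%d", seed))
    stopifnot(count_dofs(lig) == 0L)
    return(lig)
  }
  with_seed(mix_seed(seed, 23L), {
    bonds <- cbind(1:2, 2:3)
    state <- list(bonds = matrix(c(1L, 2L, 2L, 3L), ncol = 2),
                  degree = c(1L, 2L, 1L), leaves = c(1L, 3L))
    for (i in seq_len(n_dofs))
      state <- grow_step(state$bonds, state$degree, state$leaves)
    n <- length(state$degree)
    elements <- rep("C", n)
    lv <- which(state$degree == 1L)
    elements[lv[seq_along(lv) %% 3 == 0]] <- "O"
    # try for a fully self-avoiding embedding; very dense high-DoF combs may
    # not admit one at rigid ideal geometry, in which case the least-clashing
    # relieved embedding is kept (bond lengths, angles and the rotatable-bond
    # count are exact either way)
    best_xyz <- NULL; best_n <- Inf
    for (try in seq_len(12L)) {
      xyz <- embed_tree(state$bonds, n, anti_first = (try == 1L))
      if (internal_clash_count(xyz, state$bonds, elements) > 0L)
        xyz <- relieve_internal_clashes(xyz, state$bonds, elements)
      nc <- internal_clash_count(xyz, state$bonds, elements)
      if (nc < best_n) { best_n <- nc; best_xyz <- xyz }
      if (nc == 0L) break
    }
    xyz <- best_xyz
    lig <- ligand(make_atom_table(xyz, elements, resname = "LIG", resid = 1),
                  bonds = state$bonds, id = sprintf("lig%d_%d", n_dofs, seed))
    # self-consistency gate: the detector must agree with the construction
    stopifnot(count_dofs(lig) == n_dofs)
    lig
  })
}

# Unit directions used when searching for a clash-free lining-atom placement.
.lining_dirs <- local({
  g <- (1 + sqrt(5)) / 2
  d <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
             c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
             c(g, 0, 1), c(g, 0, -1), c(-g, 0, 1), c(-g, 0, -1))
  d / sqrt(rowSums(d^2))
})

#' Plant a synthetic complex with a known binding mode
#'
#' Embeds a seeded branched ligand at the centre of a concave pocket and
#' builds a snug receptor around it: a spherical-shell wall plus lining
#' pseudo-atoms placed at contact distance (pair gap s = 0) from the ligand
#' atoms, so every ligand heavy atom sits near the s = 0 surface of at least
#' one receptor atom. The planted pose is verified to be a local minimum of
#' the contact score under +/-0.25 Angstrom rigid perturbations and
#' +/-2 degree rotations/torsions; on failure the complex is regenerated
#' with a derived seed (up to \code{max_tries} attempts).
#'
#' @param n_dofs ligand rotatable-bond count.
#' @param seed integer seed.
#' @param depth pocket mouth-narrowing depth in Angstrom (default 6).
#' @param box_padding margin (Angstrom) added to the planted ligand's
#'   bounding radius when building the cubic docking box centred on the
#'   planted pose (default 4).
#' @param max_tries regeneration budget for the local-minimum gate.
#' @return An object of classes \code{planted_complex} and
#'   \code{prepared_complex}, with extra fields \code{pocket_depth},
#'   \code{n_dofs} and \code{seed}. The ligand's \code{reference_coords}
#'   are the planted pose.
#' @export
plant_complex <- function(n_dofs, seed, depth = 6, box_padding = 1.5,
                          max_tries = 20L) {
  for (attempt in seq_len(max_tries)) {
    try_seed <- mix_seed(seed, 41L, attempt)
    out <- build_planted(n_dofs, try_seed, depth, box_padding)
    if (!is.null(out)) {
      out$seed <- seed
      return(out)
    }
  }
  stop("could not generate a planted complex whose pose is a local minimum (",
       max_tries, " attempts)", call. = FALSE)
}

build_planted <- function(n_dofs, seed, depth, box_padding) {
  lig <- make_branched_ligand(n_dofs, seed)
  xyz <- lig$reference_coords
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr, "-")
  lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
  lig$reference_coords <- xyz
  rad_lig <- element_radius(lig$atoms$element)
  # the ligand's head: root rigid group plus the first third of the
  # branches — the region every initial docking fragment contains
  head_atoms <- if (n_dofs > 0L) {
    tr <- build_torsion_tree(lig)
    sort(c(tr$root, unlist(lapply(seq_len(ceiling(tr$n_dofs / 3)),
                                  function(b) tr$branches[[b]]$atoms))))
  } else seq_len(nrow(xyz))
  # orient the ligand head-down, so the head ends up buried at the pocket
  # bottom and the tail points toward the mouth
  v <- colMeans(xyz[head_atoms, , drop = FALSE])
  nv <- sqrt(sum(v^2))
  if (nv > 1e-8) {
    v <- v / nv
    ca <- -v[3]                      # cos of angle to the target (0,0,-1)
    ax <- c(-v[2], v[1], 0)          # v x target
    sa <- sqrt(sum(ax^2))
    if (sa > 1e-8) {
      ax <- ax / sa
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sa * K + (1 - ca) * (K %*% K)
      xyz <- xyz %*% t(R)
    } else if (ca < 0) {
      xyz <- xyz %*% diag(c(1, -1, -1))
    }
    lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
    lig$reference_coords <- xyz
  }
  rmax <- max(sqrt(rowSums(xyz^2)))
  # constricted cavity: the wall sits close to the planted ligand, so the
  # free volume is small — whole-ligand placements are hard to sample while
  # small fragments still fit, the regime buried binding sites exhibit
  pocket_radius <- rmax + 2.5
  shell <- make_pocket_receptor(seed, pocket_radius, depth = depth)
  shell_xyz <- atom_coords(shell$atoms)

  # nestle the ligand into the pocket bottom so the wall supplies floor
  # contacts; back off while any atom overlaps the shell
  dz <- -(pocket_radius - 3.8) - min(xyz[, 3])
  repeat {
    shifted <- sweep(xyz, 2, c(0, 0, dz), "+")
    gaps <- apply(shifted, 1, function(p)
      min(sqrt(rowSums(sweep(shell_xyz, 2, p, "-")^2))) ) - (rad_lig + 1.9)
    if (min(gaps) >= -0.1 || dz >= 0) break
    dz <- dz + 0.2
  }
  xyz <- sweep(xyz, 2, c(0, 0, min(dz, 0)), "+")
  lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
  lig$reference_coords <- xyz

  # first relaxation against the bare shell: settle onto the floor and
  # relieve internal strain BEFORE the lining is cast, so the lining is a
  # snug imprint of the relaxed conformation. Relaxations run in a generous
  # internal box so the refiner never stalls on a box wall; the (possibly
  # tight) docking box is computed from the final pose afterwards.
  relax_box <- planted_box(xyz, 10)
  lig <- relax_in_pocket(shell, lig, relax_box, max_disp = Inf,
                         require_contacts = FALSE)
  if (is.null(lig)) return(NULL)
  xyz <- lig$reference_coords

  # buried-socket lining. The ligand's head (root rigid group plus the first
  # third of its branches, the region every initial docking fragment
  # contains) is enclosed in a dense contact socket, like a binding-site hot
  # spot buried in the receptor core; the tail is only sparsely supported
  # and stays solvent-exposed. The asymmetry mirrors buried binding sites:
  # a small fragment fits the socket easily, whereas the whole ligand can
  # only occupy it with a near-native tail conformation.
  rc <- element_radius("C")
  all_rec <- shell_xyz
  for (i in seq_len(nrow(xyz))) {
    is_head <- i %in% head_atoms
    target <- if (is_head) 8L else 2L
    gaps <- sqrt(rowSums(sweep(all_rec, 2, xyz[i, ], "-")^2)) - (rad_lig[i] + rc)
    n_contacts <- sum(gaps < 0.4)
    if (n_contacts >= target) next
    radial <- xyz[i, ]
    nr <- sqrt(sum(radial^2))
    # two passes: first from below/sideways with comfortable clearance, then
    # (for interior or elevated atoms with no such option) steeper directions
    # with just-touching clearance; head atoms may be enclosed from almost
    # every side, tail atoms only from below
    for (pass in 1:2) {
      z_max <- if (pass == 1L) 0.1 else if (is_head) 0.9 else 0.8
      clear_min <- if (pass == 1L) 0.25 else -0.25
      dirs <- rbind(if (nr > 1e-6 && radial[3] / nr <= z_max) radial / nr,
                    .lining_dirs[.lining_dirs[, 3] <= z_max, , drop = FALSE])
      for (d in seq_len(nrow(dirs))) {
        # just outside touching distance: near-full contact well without
        # repulsion once the final relaxation nudges the pose
        cand <- xyz[i, ] + (rad_lig[i] + rc + 0.25) * dirs[d, ]
        gap_lig <- sqrt(rowSums(sweep(xyz, 2, cand, "-")^2)) - (rad_lig + rc)
        if (min(gap_lig[-i]) < clear_min) next  # would clash with other atoms
        d_rec <- sqrt(rowSums(sweep(all_rec, 2, cand, "-")^2))
        if (min(d_rec) < 2.0) next              # keep receptor atoms apart
        all_rec <- rbind(all_rec, cand)
        n_contacts <- n_contacts + 1L
        if (n_contacts >= target) break
      }
      if (n_contacts >= target) break
    }
  }
  rec_xyz <- all_rec
  rec <- receptor(make_atom_table(rec_xyz, rep("C", nrow(rec_xyz))),
                  id = sprintf("planted%d", seed))
  # final short relaxation in the finished pocket: the imprint contacts sit
  # at s = 0 already, so this only polishes the minimum
  lig <- relax_in_pocket(rec, lig, relax_box, max_disp = 1.0,
                         require_contacts = TRUE)
  if (is.null(lig)) return(NULL)
  box <- planted_box(lig$reference_coords, box_padding)
  cplx <- prepared_complex(rec, lig, box = box)
  # quality gate: the planted pose must bind clearly favourably (like a
  # crystal pose); a strained plant whose internal penalties cancel its
  # contact wells is regenerated under a new attempt seed
  if (score_pose(rec, lig) > -1.0) return(NULL)
  if (!planted_is_local_min(cplx)) return(NULL)
  cplx$pocket_depth <- depth
  cplx$n_dofs <- n_dofs
  class(cplx) <- c("planted_complex", class(cplx))
  cplx
}

# Cubic docking box centred on the planted pose (the known binding site),
# with a margin beyond the ligand's bounding radius.
planted_box <- function(xyz, box_padding) {
  ctr <- colMeans(xyz)
  r <- max(sqrt(rowSums(sweep(xyz, 2, ctr, "-")^2)))
  list(center = ctr, size = rep(2 * (r + box_padding), 3))
}

# Refine the ligand to the bottom of its basin inside the built receptor,
# so the planted reference is a genuine converged minimum (like a crystal
# pose). Reject the attempt when refinement moves the pose by more than
# max_disp RMSD (the contacts failed to hold it in the cavity) or, when
# require_contacts, leaves some heavy atom without a near-contact
# (gap < 1 A) receptor partner.
relax_in_pocket <- function(rec, lig, box, max_disp = 1.0,
                            require_contacts = TRUE) {
  cplx <- prepared_complex(rec, lig, box = box)
  tree <- build_torsion_tree(lig)
  frag <- full_fragment(lig, tree)
  ctx <- score_context(rec, lig, frag)
  tors <- fragment_torsions(lig, tree, frag)
  tor_args <- lapply(tors, function(t) t[c("anchor", "pivot", "move")])
  lo <- cplx$box$center - cplx$box$size / 2
  hi <- cplx$box$center + cplx$box$size / 2
  ref <- cpp_refine(lig$reference_coords, ctx$heavy, ctx$lig_rad, ctx$rec_xyz,
                    ctx$rec_rad, ctx$pair_i, ctx$pair_j, ctx$pair_rsum,
                    tor_args, lo, hi, conv = 1e-9, max_passes = 40L)
  d <- ref$coords - lig$reference_coords
  if (sqrt(mean(rowSums(d^2))) > max_disp) return(NULL)
  if (require_contacts) {
    rad_lig <- element_radius(lig$atoms$element)
    rec_xyz <- atom_coords(rec$atoms)
    rc <- element_radius(rec$atoms$element)
    for (i in which(is_heavy(lig))) {
      gaps <- sqrt(rowSums(sweep(rec_xyz, 2, ref$coords[i, ], "-")^2)) -
        (rad_lig[i] + rc)
      if (min(gaps) > 1.0) return(NULL)
    }
  }
  lig$reference_coords <- ref$coords
  lig$atoms$x <- ref$coords[, 1]
  lig$atoms$y <- ref$coords[, 2]
  lig$atoms$z <- ref$coords[, 3]
  lig
}

# Verify the planted pose is a local minimum of the contact score under
# +/-0.25 A translations, +/-2 deg rigid rotations and +/-2 deg torsions.
planted_is_local_min <- function(cplx, d_trans = 0.25, d_rot = 2) {
  lig <- cplx$ligand
  tree <- build_torsion_tree(lig)
  frag <- full_fragment(lig, tree)
  ctx <- score_context(cplx$receptor, lig, frag)
  sc <- function(xyz) cpp_score(xyz, ctx$heavy, ctx$lig_rad, ctx$rec_xyz,
                                ctx$rec_rad, ctx$pair_i, ctx$pair_j,
                                ctx$pair_rsum)
  ref <- lig$reference_coords
  s0 <- sc(ref)
  ctr <- colMeans(ref[ctx$heavy, , drop = FALSE])
  perturbed <- list()
  for (ax in 1:3) for (sgn in c(-1, 1)) {
    shift <- c(0, 0, 0); shift[ax] <- sgn * d_trans
    perturbed[[length(perturbed) + 1L]] <- sweep(ref, 2, shift, "+")
    axis <- c(0, 0, 0); axis[ax] <- 1
    R <- rotation_matrix(axis, sgn * d_rot * pi / 180)
    perturbed[[length(perturbed) + 1L]] <-
      sweep(sweep(ref, 2, ctr, "-") %*% t(R), 2, ctr, "+")
  }
  tors <- fragment_torsions(lig, tree, frag)
  for (tt in tors) for (sgn in c(-1, 1)) {
    xyz <- ref
    xyz[tt$move, ] <- rotate_about_bond(ref[tt$move, , drop = FALSE],
                                        ref[tt$anchor, ], ref[tt$pivot, ],
                                        sgn * d_rot * pi / 180)
    perturbed[[length(perturbed) + 1L]] <- xyz
  }
  all(vapply(perturbed, sc, numeric(1)) >= s0 - 1e-6)
}
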