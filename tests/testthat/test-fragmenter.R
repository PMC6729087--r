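# Incremental schedule algebra, fragment construction, and growth.

test_that("schedule algebra: (N=15, r=3, b=3) -> [9, 12, 15], k = 9", {
  s <- make_schedule(15L, 3L, 3L)
  expect_equal(s$k, 9L)
  expect_equal(s$explored_counts, c(9L, 12L, 15L))
  expect_equal(s$rounds, 3L)
})

test_that("schedule clamping: (N=5, r=3, b=3) -> 2 rounds, [2, 5], k = 2", {
  expect_message(s <- make_schedule(5L, 3L, 3L), "clamped")
  expect_equal(s$rounds, 2L)
  expect_equal(s$k, 2L)
  expect_equal(s$explored_counts, c(2L, 5L))
})

test_that("schedule algebra property: k = N - (r-1)*b over a grid", {
  for (N in c(1L, 2L, 5L, 9L, 15L, 30L)) {
    for (r in 1:4) {
      for (b in 1:4) {
        s <- suppressMessages(make_schedule(N, r, b))
        expect_equal(s$k, N - (s$rounds - 1L) * b)
        expect_gte(s$k, 1L)
        expect_equal(s$explored_counts[1], s$k)
        expect_equal(s$explored_counts[length(s$explored_counts)], N)
        if (length(s$explored_counts) > 1)
          expect_true(all(diff(s$explored_counts) == b))
      }
    }
  }
})

test_that("make_schedule rejects a rigid ligand", {
  expect_error(make_schedule(0L, 3L, 3L), "rigid")
})

test_that("initial fragment of a 3-bond chain at k = 1", {
  lig <- chain_ligand(6)                      # N = 3 rotatable bonds
  tree <- build_torsion_tree(lig, root_choice = 1L)   # root group {1,2}
  s <- make_schedule(3L, 3L, 1L)              # k = 1
  frag <- initial_fragment(lig, tree, s)
  # root group + the first branch's rigid group (atom 3)
  expect_equal(frag$atoms, c(1L, 2L, 3L))
  expect_equal(frag$explored, 1L)
  expect_equal(frag$active, 1L)
  expect_equal(frag$round_index, 1L)
  expect_equal(frag$coords, lig$reference_coords[1:3, ])
})

test_that("fragment atom sets are connected in the bond graph", {
  for (seed in 1:25) {
    nd <- 4L + seed %% 8L
    lig <- make_branched_ligand(nd, seed = seed)
    tree <- build_torsion_tree(lig)
    s <- suppressMessages(make_schedule(tree$n_dofs, 3L, 2L))
    frag <- initial_fragment(lig, tree, s)
    g <- igraph::graph_from_edgelist(lig$bonds, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(lig$atoms) - igraph::vcount(g)))
    sub <- igraph::induced_subgraph(g, frag$atoms)
    expect_equal(igraph::components(sub)$no, 1)
  }
})

test_that("full_fragment covers every atom with all bonds active", {
  lig <- make_branched_ligand(6L, seed = 2L)
  tree <- build_torsion_tree(lig)
  frag <- full_fragment(lig, tree)
  expect_equal(frag$atoms, seq_len(nrow(lig$atoms)))
  expect_equal(frag$active, seq_len(tree$n_dofs))
  expect_equal(frag$coords, lig$reference_coords)
})

test_that("expansion from the reference pose reconstructs the reference", {
  # Growing a fragment whose pose equals the reference geometry must place
  # the new atoms exactly at their reference positions (rigid transplant).
  for (seed in c(5, 21, 33)) {
    lig <- make_branched_ligand(8L, seed = seed)
    tree <- build_torsion_tree(lig)
    s <- make_schedule(tree$n_dofs, 3L, 2L)
    frag <- initial_fragment(lig, tree, s)
    for (r in 2:s$rounds) {
      pose <- list(atoms = frag$atoms,
                   coords = lig$reference_coords[frag$atoms, , drop = FALSE],
                   score = 0)
      frag <- expand_fragment(frag, pose, lig, tree, s)
      expect_lt(max(abs(frag$coords -
                        lig$reference_coords[frag$atoms, , drop = FALSE])),
                1e-6)
    }
    expect_equal(frag$atoms, seq_len(nrow(lig$atoms)))
  }
})

test_that("frozen-bond torsions are preserved through expansion within 1e-6 deg", {
  lig <- make_branched_ligand(8L, seed = 9L)
  tree <- build_torsion_tree(lig)
  s <- make_schedule(tree$n_dofs, 3L, 2L)
  frag <- initial_fragment(lig, tree, s)
  # a twisted pose of the initial fragment: randomize its torsions
  tors <- incrdock:::fragment_torsions(lig, tree, frag)
  xyz <- frag$coords
  set.seed(4)
  for (tt in tors) {
    ang <- runif(1, -pi, pi)
    xyz[tt$move, ] <- incrdock:::rotate_about_bond(
      xyz[tt$move, , drop = FALSE], xyz[tt$anchor, ], xyz[tt$pivot, ], ang)
  }
  frozen <- frag$explored     # these bonds are frozen in the next round
  before <- incrdock:::measure_fragment_torsions(xyz, lig, tree, frag,
                                      branches = frozen)
  pose <- list(atoms = frag$atoms, coords = xyz, score = 0)
  grown <- expand_fragment(frag, pose, lig, tree, s)
  after <- incrdock:::measure_fragment_torsions(grown$coords, lig, tree, grown,
                                     branches = frozen)
  ok <- !is.na(before) & !is.na(after)
  expect_gt(sum(ok), 0)
  dd <- (before[ok] - after[ok] + 180) %% 360 - 180
  expect_lt(max(abs(dd)), 1e-6)
})

test_that("expand_fragment validates its pose and stops at full coverage", {
  lig <- make_branched_ligand(6L, seed = 3L)
  tree <- build_torsion_tree(lig)
  s <- make_schedule(tree$n_dofs, 3L, 2L)
  frag <- initial_fragment(lig, tree, s)
  bad_pose <- list(atoms = frag$atoms[-1], coords = frag$coords[-1, ], score = 0)
  expect_error(expand_fragment(frag, bad_pose, lig, tree, s),
               "does not cover")
  full <- full_fragment(lig, tree)
  full$round_index <- s$rounds
  pose <- list(atoms = full$atoms, coords = full$coords, score = 0)
  expect_error(expand_fragment(full, pose, lig, tree, s), "whole ligand")
})

test_that("active window: only the last k explored bonds stay active", {
  lig <- make_branched_ligand(9L, seed = 13L)
  tree <- build_torsion_tree(lig)
  s <- make_schedule(9L, 3L, 3L)     # k = 3
  frag <- initial_fragment(lig, tree, s)
  expect_equal(frag$active, 1:3)
  pose <- list(atoms = frag$atoms,
               coords = lig$reference_coords[frag$atoms, , drop = FALSE],
               score = 0)
  g2 <- expand_fragment(frag, pose, lig, tree, s)
  expect_equal(g2$explored, 1:6)
  expect_equal(g2$active, 4:6)
  pose2 <- list(atoms = g2$atoms,
                coords = lig$reference_coords[g2$atoms, , drop = FALSE],
                score = 0)
  g3 <- expand_fragment(g2, pose2, lig, tree, s)
  expect_equal(g3$active, 7:9)
})

test_that("select_for_expansion: greedy diversity then score backfill", {
  lig <- chain_ligand(4)
  xyz <- lig$reference_coords
  mk <- function(score) list(atoms = 1:4, coords = xyz, score = score,
                             torsions = numeric())
  pool <- pose_pool(list(mk(-5), mk(-4), mk(-3)))
  sel <- select_for_expansion(pool, m = 2L, diversity_rmsd = 1.0)
  expect_length(sel, 2)
  # identical coordinates: diversity keeps only the -5 pose, backfill adds -4
  expect_equal(vapply(sel, `[[`, 0, "score"), c(-5, -4))
})

test_that("select_for_expansion prefers diverse poses when available", {
  lig <- chain_ligand(4)
  xyz <- lig$reference_coords
  mk <- function(score, shift) list(atoms = 1:4,
                                    coords = sweep(xyz, 2, c(shift, 0, 0), "+"),
                                    score = score, torsions = numeric())
  # -5 and -4 nearly identical; -3 far away: with m = 2 the far pose wins
  pool <- pose_pool(list(mk(-5, 0), mk(-4, 0.01), mk(-3, 5)))
  sel <- select_for_expansion(pool, m = 2L, diversity_rmsd = 1.0)
  expect_equal(vapply(sel, `[[`, 0, "score"), c(-5, -3))
  expect_error(select_for_expansion(pose_pool(list()), 2L), "empty")
})
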