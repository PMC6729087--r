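# Built-in engine: contact score, randomization, dock contract.

test_that("contact score hand values for a single C-C pair", {
  rec <- receptor(make_lig_atoms(matrix(c(0, 0, 0), 1, 3), "C", "REC"))
  lig1 <- function(d) ligand(make_lig_atoms(matrix(c(d, 0, 0), 1, 3), "C"))
  # d = 3.8 -> s = 0 -> -0.05
  expect_equal(score_pose(rec, lig1(3.8)), -0.05)
  # d = 3.3 -> s = -0.5 -> -0.05 e^-1 + 0.8 * 0.25
  expect_equal(score_pose(rec, lig1(3.3)), -0.05 * exp(-1) + 0.8 * 0.25,
               tolerance = 1e-12)
  # far outside the 8 A cutoff -> exactly 0
  expect_equal(score_pose(rec, lig1(20)), 0)
})

test_that("contact score ignores hydrogens and counts internal pairs", {
  rec <- receptor(make_lig_atoms(matrix(c(0, 0, 0), 1, 3), "C", "REC"))
  # single H at contact distance contributes nothing
  ligH <- ligand(make_lig_atoms(matrix(c(3.8, 0, 0), 1, 3), "H"))
  expect_equal(score_pose(rec, ligH), 0)
  # internal pair: 4-atom chain folded so atoms 1 and 4 overlap hard
  lig <- chain_ligand(4)
  xyz <- lig$reference_coords
  xyz[4, ] <- xyz[1, ] + c(1.0, 0, 0)   # graph distance 3, s = 1.0 - 3.8
  far_rec <- receptor(make_lig_atoms(matrix(c(100, 0, 0), 1, 3), "C", "REC"))
  s <- score_pose(far_rec, lig, coords = xyz)
  expect_equal(s, 0.8 * (1.0 - 3.8)^2, tolerance = 1e-9)
})

test_that("score is invariant under a joint rigid transform", {
  cplx <- cached_complex(6L, 101L)
  base <- score_pose(cplx$receptor, cplx$ligand)
  # rotate receptor and ligand jointly
  ax <- c(1, 2, 3) / sqrt(14)
  R <- incrdock:::rotation_matrix(ax, 0.7)
  shift <- c(5, -3, 2)
  rot <- function(xyz) sweep(xyz %*% t(R), 2, shift, "+")
  rec2 <- cplx$receptor
  rxyz <- rot(incrdock:::atom_coords(rec2$atoms))
  rec2$atoms$x <- rxyz[, 1]; rec2$atoms$y <- rxyz[, 2]; rec2$atoms$z <- rxyz[, 3]
  lig2 <- cplx$ligand
  lxyz <- rot(lig2$reference_coords)
  expect_equal(score_pose(rec2, lig2, coords = lxyz), base, tolerance = 1e-9)
})

test_that("randomize_conformation stays in the box and is seed-deterministic", {
  cplx <- cached_complex(6L, 101L)
  p1 <- randomize_conformation(cplx, seed = 7L)
  p2 <- randomize_conformation(cplx, seed = 7L)
  expect_identical(p1$coords, p2$coords)
  lo <- cplx$box$center - cplx$box$size / 2
  hi <- cplx$box$center + cplx$box$size / 2
  expect_true(all(sweep(p1$coords, 2, lo, ">=") & sweep(p1$coords, 2, hi, "<=")))
  # clash gate: no receptor pair with gap below -1 A
  rad <- incrdock:::element_radius(cplx$ligand$atoms$element)
  rxyz <- incrdock:::atom_coords(cplx$receptor$atoms)
  rrad <- incrdock:::element_radius(cplx$receptor$atoms$element)
  hv <- which(incrdock:::is_heavy(cplx$ligand))
  gmin <- min(vapply(hv, function(i)
    min(sqrt(rowSums(sweep(rxyz, 2, p1$coords[i, ], "-")^2)) - (rad[i] + rrad)),
    numeric(1)))
  expect_gte(gmin, -1.0)
})

test_that("different seeds give different torsions >= 99% of the time", {
  # roomy box so every draw places without exhausting the clash budget
  cplx <- cached_complex(6L, 101L, box_padding = 8)
  draws <- lapply(1:201, function(s) randomize_conformation(cplx, seed = s))
  n_diff <- 0L
  for (i in 1:200) {
    a <- draws[[i]]$torsions; b <- draws[[i + 1]]$torsions
    dd <- abs((a - b + 180) %% 360 - 180)
    if (max(dd, na.rm = TRUE) > 1) n_diff <- n_diff + 1L
  }
  expect_gte(n_diff / 200, 0.99)
})

test_that("randomize errors when the box is impossibly occupied", {
  cplx <- cached_complex(6L, 101L)
  # a box buried inside the receptor wall: every placement clashes
  wall <- incrdock:::atom_coords(cplx$receptor$atoms)[1, ]
  cplx$box <- list(center = wall, size = c(0.5, 0.5, 0.5))
  expect_error(randomize_conformation(cplx, seed = 1L), "clashes")
})

test_that("dock is deterministic and honors num_modes/energy_range", {
  cplx <- cached_complex(6L, 101L)
  cfg <- engine_config(exhaustiveness = 2, seed = 42L)
  pool1 <- dock(cplx, cfg)
  pool2 <- dock(cplx, cfg)
  expect_identical(lapply(pool1$poses, `[[`, "coords"),
                   lapply(pool2$poses, `[[`, "coords"))
  s <- vapply(pool1$poses, `[[`, 0, "score")
  expect_true(all(diff(s) >= 0))
  expect_lte(length(pool1$poses), cfg$num_modes)
  expect_true(all(s <= s[1] + cfg$energy_range))
  # run accounting: 4 x exhaustiveness internal runs
  expect_equal(pool1$log$n_runs, 4 * 2)
  expect_equal(pool1$log$exhaustiveness, 2)
})

test_that("dock pool poses stay within the box up to the fragment radius", {
  cplx <- cached_complex(6L, 101L)
  pool <- dock(cplx, engine_config(exhaustiveness = 2, seed = 9L))
  lo <- cplx$box$center - cplx$box$size / 2
  hi <- cplx$box$center + cplx$box$size / 2
  ref <- cplx$ligand$reference_coords
  frad <- max(sqrt(rowSums(sweep(ref, 2, colMeans(ref), "-")^2)))
  for (p in pool$poses) {
    expect_true(all(sweep(p$coords, 2, lo - frad, ">=") &
                    sweep(p$coords, 2, hi + frad, "<=")))
  }
})

test_that("num_modes truncates the pool", {
  cplx <- cached_complex(6L, 101L)
  cfg <- engine_config(exhaustiveness = 2, num_modes = 3, seed = 12L)
  pool <- dock(cplx, cfg)
  expect_lte(length(pool$poses), 3)
})

test_that("mean best score improves with exhaustiveness (E16 vs E2)", {
  cplx <- cached_complex(6L, 101L)
  best <- function(E, s) {
    pool <- dock(cplx, engine_config(exhaustiveness = E, seed = s))
    pool$poses[[1]]$score
  }
  seeds <- 1:30
  m2 <- mean(vapply(seeds, function(s) best(2, s), numeric(1)))
  m16 <- mean(vapply(seeds, function(s) best(16, s + 1000), numeric(1)))
  expect_lte(m16, m2)
})

test_that("refinement never worsens the starting score", {
  cplx <- cached_complex(6L, 101L, box_padding = 8)
  lig <- cplx$ligand
  tree <- build_torsion_tree(lig)
  frag <- full_fragment(lig, tree)
  ctx <- incrdock:::score_context(cplx$receptor, lig, frag)
  tors <- incrdock:::fragment_torsions(lig, tree, frag)
  tor_args <- lapply(tors, function(t) t[c("anchor", "pivot", "move")])
  lo <- cplx$box$center - cplx$box$size / 2
  hi <- cplx$box$center + cplx$box$size / 2
  for (s in 1:5) {
    start <- randomize_conformation(cplx, seed = s)$coords
    s0 <- score_pose(cplx$receptor, lig, coords = start)
    ref <- incrdock:::cpp_refine(start, ctx$heavy, ctx$lig_rad, ctx$rec_xyz,
                                 ctx$rec_rad, ctx$pair_i, ctx$pair_j,
                                 ctx$pair_rsum, tor_args, lo, hi)
    expect_lte(ref$score, s0 + 1e-9)
    # the reported score matches a fresh evaluation of the final coords
    expect_equal(ref$score, score_pose(cplx$receptor, lig, coords = ref$coords),
                 tolerance = 1e-8)
  }
})

test_that("cluster_poses keeps best-scoring representatives", {
  lig <- chain_ligand(4)
  xyz <- lig$reference_coords
  mk <- function(score, shift) incrdock:::new_pose(
    sweep(xyz, 2, c(shift, 0, 0), "+"), atoms = 1:4, score = score)
  poses <- list(mk(-2, 0), mk(-5, 0.05), mk(-1, 4))   # first two cluster
  out <- incrdock:::cluster_poses(poses, heavy_rows = 1:4, threshold = 1.0)
  expect_length(out, 2)
  expect_equal(vapply(out, `[[`, 0, "score"), c(-5, -1))
})
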