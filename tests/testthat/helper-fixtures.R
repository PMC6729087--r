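# Shared hand-built fixtures. All coordinates are chosen so that the
# distance-based bond perception (d < 1.3 * (rcov_i + rcov_j)) yields exactly
# the intended bond graph: C-C bonds at 1.54 A, C-O at 1.43 A, C-H at 1.09 A.

# Linear all-anti carbon chain of n atoms (C-C 1.54 A, 109.47 deg angles),
# lying in the xz plane.
chain_ligand <- function(n, elements = rep("C", n)) {
  xyz <- matrix(0, n, 3)
  # zig-zag: step vector alternates between two directions at the
  # tetrahedral angle
  ang <- (pi - acos(-1 / 3)) / 2    # half the supplement of 109.47 deg
  step_a <- 1.54 * c(cos(ang), 0, sin(ang))
  step_b <- 1.54 * c(cos(ang), 0, -sin(ang))
  for (i in seq_len(n - 1)) {
    xyz[i + 1, ] <- xyz[i, ] + if (i %% 2 == 1) step_a else step_b
  }
  ligand(make_lig_atoms(xyz, elements), id = sprintf("chain%d", n))
}

make_lig_atoms <- function(xyz, elements, resname = "LIG") {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = paste0(elements, seq_len(n)),
             element = elements,
             resname = resname, resid = 1L, chain = "A",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0,
             stringsAsFactors = FALSE)
}

# Planted complexes are expensive to generate; cache them per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached_complex <- function(n_dofs, seed, box_padding = 2) {
  key <- sprintf("cplx_%d_%d_%g", n_dofs, seed, box_padding)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- plant_complex(n_dofs, seed = seed,
                                           box_padding = box_padding)
  .fixture_cache[[key]]
}
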