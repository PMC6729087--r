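# Structure I/O: PDB/PDBQT parsing, writing, and complex preparation.

pdb5 <- c(
  "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
  "ATOM      2  C2  LIG A   1       2.540   2.000   3.000  1.00  0.00           C",
  "ATOM      3  O1  LIG A   1       3.100   3.200   3.500  1.00  0.00           O",
  "ATOM      4  N1  LIG A   1       4.600   3.200   3.500  1.00  0.00           N",
  "ATOM      5  C3  LIG A   1       5.200   1.800   2.900  1.00  0.00           C")

test_that("read_pdb parses a single ATOM line into one atom record", {
  s <- read_pdb(pdb5[1])
  expect_length(s$models, 1)
  a <- s$models[[1]]
  expect_equal(nrow(a), 1)
  expect_equal(a$element, "C")
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
  expect_equal(a$serial, 1L)
  expect_equal(a$resname, "LIG")
})

test_that("read_pdb exposes MODEL 1 and MODEL 2 separately", {
  lines <- c("MODEL        1", pdb5[1:2], "ENDMDL",
             "MODEL        2", pdb5[3:5], "ENDMDL")
  s <- read_pdb(lines)
  expect_length(s$models, 2)
  expect_equal(nrow(s$models[[1]]), 2)
  expect_equal(nrow(s$models[[2]]), 3)
  expect_equal(s$models[[2]]$element, c("O", "N", "C"))
})

test_that("5-atom PDB fixture round-trips byte-for-byte", {
  s <- read_pdb(pdb5)
  out <- write_pdb(s$models[[1]])
  expect_identical(out, c(pdb5, "END"))
})

test_that("read_pdb errors on malformed and empty input", {
  expect_error(read_pdb("ATOM      1  C1"), "line 1")
  expect_error(read_pdb(paste0("ATOM      1  C1  LIG A   1       x.000",
                               "   2.000   3.000")), "line 1")
  expect_error(read_pdb("REMARK nothing here"), "empty structure")
})

test_that("prepare_complex removes all waters", {
  prot <- make_lig_atoms(matrix(c(0, 0, 0,  1.54, 0, 0,  3, 1, 0,  4.5, 1, 0),
                                4, 3, byrow = TRUE), rep("C", 4), "PRO")
  prot$resid <- c(1L, 1L, 2L, 2L)
  lig <- make_lig_atoms(matrix(c(10, 0, 0,  11.43, 0, 0), 2, 3, byrow = TRUE),
                        c("C", "O"), "LIG")
  lig$resid <- 9L
  wat <- make_lig_atoms(matrix(c(20, 0, 0,  21, 5, 0,  22, 9, 0), 3, 3,
                               byrow = TRUE), rep("O", 3), "HOH")
  wat$resid <- c(101L, 102L, 103L)
  all <- rbind(prot, lig, wat)
  all$serial <- seq_len(nrow(all))
  cplx <- suppressMessages(prepare_complex(all, "LIG"))
  expect_false(any(cplx$receptor$atoms$resname == "HOH"))
  expect_false(any(cplx$ligand$atoms$resname == "HOH"))
  expect_equal(nrow(cplx$receptor$atoms), 4)
})

test_that("prepare_complex keeps only the first model's ligand copy", {
  lig_lines <- function(x0) c(
    sprintf("HETATM    1  C1  LIG A   9    %8.3f   0.000   0.000  1.00  0.00           C", x0),
    sprintf("HETATM    2  O1  LIG A   9    %8.3f   0.000   0.000  1.00  0.00           O", x0 + 1.43))
  prot_lines <- c(
    "ATOM      3  C1  PRO A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C2  PRO A   1       1.540   0.000   0.000  1.00  0.00           C")
  s <- read_pdb(c("MODEL        1", prot_lines, lig_lines(10), "ENDMDL",
                  "MODEL        2", prot_lines, lig_lines(30), "ENDMDL"))
  cplx <- suppressMessages(prepare_complex(s, "LIG"))
  expect_equal(nrow(cplx$ligand$atoms), 2)
  expect_equal(cplx$ligand$atoms$x[1], 10)
})

test_that("ligand preparation keeps polar H, strips nonpolar H", {
  # 4 carbons in a chain, an O on C4; 1 H on the O (polar), 3 H on C1
  xyz <- matrix(c(0, 0, 0,       1.54, 0, 0,   3.08, 0, 0,  4.62, 0, 0,
                  5.4, 1.2, 0,                           # O on C4
                  5.75, 2.1, 0,                          # H on O (polar)
                  -0.6, 0.9, 0,  -0.6, -0.9, 0, -0.3, 0, 1.03),  # 3 H on C1
                ncol = 3, byrow = TRUE)
  el <- c("C", "C", "C", "C", "O", "H", "H", "H", "H")
  lig_at <- make_lig_atoms(xyz, el, "LIG")
  prot <- make_lig_atoms(matrix(c(10, 0, 0, 11.54, 0, 0), 2, 3, byrow = TRUE),
                         rep("C", 2), "PRO")
  all <- rbind(prot, lig_at)
  all$serial <- seq_len(nrow(all))
  all$resid <- c(1L, 1L, rep(9L, 9))
  cplx <- suppressMessages(prepare_complex(all, "LIG"))
  expect_equal(nrow(cplx$ligand$atoms), 6)   # 5 heavy + 1 polar H
  expect_equal(sum(cplx$ligand$atoms$element == "H"), 1)
})

test_that("prepare_complex errors on no match and on ambiguous selector", {
  prot <- make_lig_atoms(matrix(c(0, 0, 0, 1.54, 0, 0), 2, 3, byrow = TRUE),
                         rep("C", 2), "PRO")
  liga <- make_lig_atoms(matrix(c(10, 0, 0, 11.54, 0, 0), 2, 3, byrow = TRUE),
                         rep("C", 2), "LGA")
  ligb <- make_lig_atoms(matrix(c(20, 0, 0, 21.54, 0, 0), 2, 3, byrow = TRUE),
                         rep("C", 2), "LGB")
  all <- rbind(prot, liga, ligb)
  all$serial <- seq_len(nrow(all))
  all$resid <- rep(c(1L, 2L, 3L), each = 2)
  expect_error(prepare_complex(all, "XXX"), "no atoms match")
  expect_error(prepare_complex(all, c("LGA", "LGB")), "ambiguous")
})

test_that("write_pdbqt: rigid ligand has ROOT/ENDROOT, no BRANCH, TORSDOF 0", {
  lig <- chain_ligand(3)
  tree <- build_torsion_tree(lig)
  lines <- write_pdbqt(lig, tree)
  expect_equal(sum(lines == "ROOT"), 1)
  expect_equal(sum(lines == "ENDROOT"), 1)
  expect_false(any(grepl("^BRANCH", lines)))
  expect_equal(lines[length(lines)], "TORSDOF 0")
})

test_that("write_pdbqt: 2-rotatable-bond chain has 2 BRANCH pairs, TORSDOF 2", {
  lig <- chain_ligand(5)
  tree <- build_torsion_tree(lig)
  expect_equal(tree$n_dofs, 2L)
  lines <- write_pdbqt(lig, tree)
  expect_equal(sum(grepl("^BRANCH", lines)), 2)
  expect_equal(sum(grepl("^ENDBRANCH", lines)), 2)
  expect_equal(lines[length(lines)], "TORSDOF 2")
})

test_that("PDBQT write-then-read reproduces coordinates within 1e-3", {
  lig <- make_branched_ligand(5L, seed = 11L)
  tree <- build_torsion_tree(lig)
  lines <- write_pdbqt(lig, tree)
  back <- read_pdbqt(lines)
  expect_s3_class(back$ligand, "dock_ligand")
  # atoms are renumbered in tree order; compare as point sets via sorted rows
  a <- lig$reference_coords
  b <- back$ligand$reference_coords
  expect_equal(dim(b), dim(a))
  ord_a <- order(a[, 1], a[, 2], a[, 3])
  ord_b <- order(b[, 1], b[, 2], b[, 3])
  expect_true(max(abs(a[ord_a, ] - b[ord_b, ])) < 1e-3 + 1e-9)
  # torsion tree survives the round trip
  expect_equal(back$tree$n_dofs, tree$n_dofs)
})

test_that("read_pdbqt parses multi-MODEL output into one pose per model", {
  lig <- chain_ligand(6)
  tree <- build_torsion_tree(lig)
  one <- write_pdbqt(lig, tree)
  shifted <- sweep(lig$reference_coords, 2, c(1, 0, 0), "+")
  two <- write_pdbqt(lig, tree, pose_coords = shifted)
  lines <- c("MODEL 1", one, "ENDMDL", "MODEL 2", two, "ENDMDL")
  out <- read_pdbqt(lines)
  expect_length(out$poses, 2)
  expect_equal(out$poses[[2]] - out$poses[[1]],
               matrix(rep(c(1, 0, 0), each = 6), 6, 3), tolerance = 1e-3)
})

test_that("read_pdbqt warns on unknown records but still parses", {
  lig <- chain_ligand(4)
  tree <- build_torsion_tree(lig)
  lines <- c(write_pdbqt(lig, tree), "WEIRDREC something")
  expect_warning(out <- read_pdbqt(lines), "WEIRDREC")
  expect_equal(nrow(out$ligand$atoms), 4)
})

test_that("prepared_complex validates its box", {
  lig <- chain_ligand(4)
  rec <- receptor(make_lig_atoms(matrix(c(9, 0, 0, 10.54, 0, 0), 2, 3,
                                        byrow = TRUE), c("C", "C"), "REC"))
  expect_error(prepared_complex(rec, lig, box = list(center = c(0, 0, 0),
                                                     size = c(0, 5, 5))),
               "strictly positive")
  expect_error(prepared_complex(rec, lig, box = list(center = c(50, 0, 0),
                                                     size = c(2, 2, 2))),
               "outside the docking box")
  cplx <- prepared_complex(rec, lig, box_padding = 5)
  expect_s3_class(cplx, "prepared_complex")
  # default box is the ligand bounding box + padding on each side
  ref <- lig$reference_coords
  expect_equal(cplx$box$size,
               apply(ref, 2, max) - apply(ref, 2, min) + 10)
})
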