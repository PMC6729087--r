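# Molecular structure containers and PDB / PDBQT (torsion-tree dialect) I/O.

# Covalent radii (Angstrom) for distance-based bond perception.
.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39, Se = 1.20)

covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  r[is.na(r)] <- 0.77
  unname(r)
}

empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resname = character(), resid = integer(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(), charge = numeric(),
             stringsAsFactors = FALSE)
}

atom_coords <- function(atoms) unname(as.matrix(atoms[, c("x", "y", "z")]))

#' Construct a ligand object
#'
#' A ligand is an atom table plus a covalent bond graph and a reference
#' (crystal) conformation. The bond graph must be connected.
#'
#' @param atoms data.frame with columns \code{serial, name, element, resname,
#'   resid, chain, x, y, z, charge}.
#' @param bonds two-column integer matrix of atom indices (1-based rows of
#'   \code{atoms}); if \code{NULL}, bonds are perceived from interatomic
#'   distances against covalent radii.
#' @param reference_coords n x 3 matrix of reference coordinates (Angstrom);
#'   defaults to the coordinates in \code{atoms}.
#' @param id character label.
#' @return An object of class \code{dock_ligand}.
#' @export
ligand <- function(atoms, bonds = NULL, reference_coords = NULL, id = "ligand") {
  atoms <- validate_atoms(atoms)
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  bonds <- validate_bonds(bonds, nrow(atoms))
  if (is.null(reference_coords)) reference_coords <- atom_coords(atoms)
  reference_coords <- as.matrix(reference_coords)
  if (!identical(dim(reference_coords), c(nrow(atoms), 3L)) &&
      !all(dim(reference_coords) == c(nrow(atoms), 3)))
    stop("reference_coords must be an n x 3 matrix matching the atom count",
         call. = FALSE)
  if (nrow(atoms) > 1L) {
    g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(atoms) - igraph::vcount(g)))
    if (igraph::components(g)$no != 1L)
      stop("ligand bond graph is not connected", call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds,
                 reference_coords = unname(reference_coords), id = id),
            class = "dock_ligand")
}

#' Construct a receptor object
#'
#' Receptors are rigid: their coordinates are never transformed.
#'
#' @inheritParams ligand
#' @return An object of class \code{dock_receptor}.
#' @export
receptor <- function(atoms, id = "receptor") {
  atoms <- validate_atoms(atoms)
  if (nrow(atoms) == 0L) stop("receptor must contain at least one atom", call. = FALSE)
  structure(list(atoms = atoms, id = id), class = "dock_receptor")
}

validate_atoms <- function(atoms) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z", "charge")
  missing <- setdiff(req, names(atoms))
  if ("charge" %in% missing) { atoms$charge <- 0; missing <- setdiff(missing, "charge") }
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!all(is.finite(atom_coords(atoms))))
    stop("atom coordinates must be finite", call. = FALSE)
  el <- normalize_element(atoms$element)
  if (anyNA(el))
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[is.na(el)]), collapse = ", "), call. = FALSE)
  atoms$element <- el
  rownames(atoms) <- NULL
  atoms[req]
}

validate_bonds <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n_atoms)))
    stop("bond indices out of range", call. = FALSE)
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond in bond list", call. = FALSE)
  bonds
}

# Distance-based bond perception: i-j bonded when d < 1.3 * (rcov_i + rcov_j).
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  xyz <- atom_coords(atoms)
  rc <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- 1.3 * outer(rc, rc, "+")
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(hit[order(hit[, 1], hit[, 2]), , drop = FALSE]), ncol = 2)
}

is_heavy <- function(x) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  is_heavy_element(atoms$element)
}

# --- PDB ----------------------------------------------------------------------

parse_atom_line <- function(line, lineno, pdbqt = FALSE) {
  if (nchar(line) < 54)
    stop(sprintf("malformed ATOM/HETATM record at line %d: too short", lineno),
         call. = FALSE)
  f <- function(a, b) substr(line, a, b)
  coords <- suppressWarnings(as.numeric(c(f(31, 38), f(39, 46), f(47, 54))))
  serial <- suppressWarnings(as.integer(trimws(f(7, 11))))
  resid  <- suppressWarnings(as.integer(trimws(f(23, 26))))
  if (anyNA(coords) || is.na(serial))
    stop(sprintf("malformed ATOM/HETATM record at line %d: non-numeric field", lineno),
         call. = FALSE)
  name <- trimws(f(13, 16))
  el <- trimws(f(77, 78))
  if (pdbqt || is.na(normalize_element(el)) || el == "") {
    # PDBQT carries an AutoDock type, not an element column; fall back to the
    # atom name (first alphabetic character(s)).
    guess <- sub("^[0-9]*", "", name)
    el2 <- normalize_element(substr(guess, 1, 2))
    if (is.na(el2)) el2 <- normalize_element(substr(guess, 1, 1))
    if (!pdbqt && !is.na(normalize_element(el))) el2 <- normalize_element(el)
    el <- el2
  } else el <- normalize_element(el)
  if (is.na(el))
    stop(sprintf("cannot infer element at line %d", lineno), call. = FALSE)
  charge <- 0
  if (pdbqt && nchar(line) >= 76)
    charge <- suppressWarnings(as.numeric(trimws(f(71, 76))))
  if (is.na(charge)) charge <- 0
  data.frame(serial = serial, name = name, element = el,
             resname = trimws(f(18, 20)),
             resid = ifelse(is.na(resid), 0L, resid),
             chain = trimws(f(22, 22)),
             x = coords[1], y = coords[2], z = coords[3],
             charge = charge, stringsAsFactors = FALSE)
}

#' Read a PDB file or text
#'
#' Parses fixed-column ATOM/HETATM/MODEL/ENDMDL records into a structure
#' holding one atom table per model.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @return An object of class \code{pdb_structure}: a list with element
#'   \code{models}, a list of atom data.frames (columns \code{serial, name,
#'   element, resname, resid, chain, x, y, z, charge}).
#' @export
read_pdb <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input) else unlist(strsplit(input, "\n", fixed = TRUE))
  models <- list()
  cur <- list()
  in_model <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    rec <- substr(line, 1, 6)
    if (rec == "MODEL ") {
      in_model <- TRUE
      cur <- list()
    } else if (rec == "ENDMDL") {
      models[[length(models) + 1L]] <- do.call(rbind, cur)
      cur <- list()
      in_model <- FALSE
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      cur[[length(cur) + 1L]] <- parse_atom_line(line, i)
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- do.call(rbind, cur)
  models <- Filter(Negate(is.null), models)
  if (!length(models))
    stop("no ATOM/HETATM records found (empty structure)", call. = FALSE)
  models <- lapply(models, function(m) { rownames(m) <- NULL; m })
  structure(list(models = models), class = "pdb_structure")
}

format_atom_line <- function(atoms, record = "ATOM", pdbqt = FALSE) {
  n <- nrow(atoms)
  rec <- rep_len(record, n)
  name <- ifelse(nchar(atoms$name) <= 3, paste0(" ", atoms$name), atoms$name)
  base <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  rec, atoms$serial, name, atoms$resname,
                  ifelse(atoms$chain == "", " ", atoms$chain), atoms$resid,
                  atoms$x, atoms$y, atoms$z, 1, 0)
  if (pdbqt) {
    type <- toupper(atoms$element)
    paste0(base, sprintf("    %6.3f %-2s", atoms$charge, type))
  } else {
    paste0(base, sprintf("          %2s", toupper(atoms$element)))
  }
}

#' Write a PDB file
#'
#' @param x a \code{pdb_structure}, \code{dock_ligand}, \code{dock_receptor}
#'   or atom data.frame.
#' @param path output path; if \code{NULL} the lines are returned invisibly.
#' @param record record type, \code{"ATOM"} or \code{"HETATM"}.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(x, path = NULL, record = "ATOM") {
  models <- if (inherits(x, "pdb_structure")) x$models
            else if (is.data.frame(x)) list(x)
            else list(x$atoms)
  multi <- length(models) > 1L
  out <- character()
  for (i in seq_along(models)) {
    if (multi) out <- c(out, sprintf("MODEL %8d", i))
    out <- c(out, format_atom_line(models[[i]], record))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# --- complex preparation ------------------------------------------------------

.water_names <- c("HOH", "WAT", "DOD")

#' Prepare a receptor/ligand complex for redocking
#'
#' Applies the standard preparation rules to a raw crystal structure: waters
#' are removed, only the first model and the first matching ligand instance
#' are kept, the ligand is separated from the protein, lone non-polymer
#' single-atom residues (stray ions) are dropped from the receptor, nonpolar
#' hydrogens are removed from the ligand while polar hydrogens (bonded to
#' N/O/S) are retained, and a docking box is placed around the ligand's
#' reference pose.
#'
#' Partial charges are kept if present in the input and default to 0
#' otherwise; the built-in docking engine is charge-free, so defaulted
#' charges do not affect its results.
#'
#' @param structure a \code{pdb_structure} from \code{\link{read_pdb}} (or a
#'   single atom data.frame).
#' @param ligand_selector residue name of the ligand (character), or a
#'   predicate \code{function(atoms) -> logical} over the atom table.
#' @param box_padding box padding in Angstrom added on each side of the
#'   ligand bounding box (default 5).
#' @return An object of class \code{prepared_complex}: list with elements
#'   \code{receptor}, \code{ligand} and \code{box} (list of \code{center} and
#'   \code{size}, Angstrom).
#' @export
prepare_complex <- function(structure, ligand_selector, box_padding = 5) {
  atoms <- if (inherits(structure, "pdb_structure")) structure$models[[1L]]
           else as.data.frame(structure)
  atoms <- atoms[!(toupper(atoms$resname) %in% .water_names), , drop = FALSE]
  sel <- if (is.function(ligand_selector)) ligand_selector(atoms)
         else atoms$resname %in% ligand_selector
  if (!any(sel)) stop("no atoms match the ligand selector", call. = FALSE)
  lig_res <- unique(atoms[sel, c("resname", "chain", "resid")])
  if (length(unique(lig_res$resname)) > 1L)
    stop("ligand selector is ambiguous: matches more than one ligand species (",
         paste(unique(lig_res$resname), collapse = ", "), ")", call. = FALSE)
  # first instance only
  first <- lig_res[1L, ]
  lig_idx <- which(atoms$resname == first$resname &
                   atoms$chain == first$chain & atoms$resid == first$resid)
  lig_atoms <- atoms[lig_idx, , drop = FALSE]
  rec_atoms <- atoms[-c(which(sel)), , drop = FALSE]
  # drop lone atoms: single-atom residues outside the receptor polymer
  key <- paste(rec_atoms$resname, rec_atoms$chain, rec_atoms$resid)
  counts <- table(key)
  rec_atoms <- rec_atoms[counts[key] > 1L, , drop = FALSE]
  if (nrow(rec_atoms) == 0L)
    stop("receptor is empty after preparation", call. = FALSE)
  lig_atoms <- strip_nonpolar_hydrogens(lig_atoms)
  rownames(lig_atoms) <- rownames(rec_atoms) <- NULL
  if (all(lig_atoms$charge == 0))
    message("no partial charges in input; ligand charges default to 0 ",
            "(the built-in engine score is charge-free)")
  lig <- ligand(lig_atoms, id = first$resname)
  rec <- receptor(rec_atoms)
  prepared_complex(rec, lig, box_padding = box_padding)
}

# Keep heavy atoms and hydrogens whose nearest heavy atom is N, O or S.
strip_nonpolar_hydrogens <- function(atoms) {
  h <- !is_heavy_element(atoms$element)
  if (!any(h)) return(atoms)
  heavy <- atoms[!h, , drop = FALSE]
  keep_h <- vapply(which(h), function(i) {
    d2 <- (heavy$x - atoms$x[i])^2 + (heavy$y - atoms$y[i])^2 +
          (heavy$z - atoms$z[i])^2
    heavy$element[which.min(d2)] %in% c("N", "O", "S")
  }, logical(1))
  keep <- rep(TRUE, nrow(atoms))
  keep[which(h)[!keep_h]] <- FALSE
  atoms[keep, , drop = FALSE]
}

#' Assemble a prepared complex from ready-made parts
#'
#' @param receptor a \code{dock_receptor}.
#' @param lig a \code{dock_ligand} whose reference coordinates are the
#'   crystal (or planted) pose.
#' @param box optional list with \code{center} and \code{size} (Angstrom);
#'   default is the ligand reference bounding box padded by
#'   \code{box_padding} on each side.
#' @param box_padding padding in Angstrom (default 5).
#' @return An object of class \code{prepared_complex}.
#' @export
prepared_complex <- function(receptor, lig, box = NULL, box_padding = 5) {
  stopifnot(inherits(receptor, "dock_receptor"), inherits(lig, "dock_ligand"))
  ref <- lig$reference_coords
  if (is.null(box)) {
    lo <- apply(ref, 2, min) - box_padding
    hi <- apply(ref, 2, max) + box_padding
    box <- list(center = (lo + hi) / 2, size = hi - lo)
  }
  if (any(box$size <= 0)) stop("box extents must be strictly positive", call. = FALSE)
  lo <- box$center - box$size / 2; hi <- box$center + box$size / 2
  inside <- all(sweep(ref, 2, lo, ">=") & sweep(ref, 2, hi, "<="))
  if (!inside)
    stop("ligand reference pose lies outside the docking box", call. = FALSE)
  structure(list(receptor = receptor, ligand = lig, box = box),
            class = "prepared_complex")
}

# --- PDBQT --------------------------------------------------------------------

#' Write a ligand as PDBQT (torsion-tree dialect)
#'
#' Emits ROOT/ENDROOT and nested BRANCH/ENDBRANCH blocks matching the torsion
#' tree, with TORSDOF equal to the rotatable-bond count. Atoms are renumbered
#' in tree order; BRANCH records carry the new serials.
#'
#' @param lig a \code{dock_ligand}.
#' @param tree a \code{torsion_tree} built for \code{lig}.
#' @param pose_coords optional n x 3 coordinate matrix overriding the
#'   ligand's reference coordinates.
#' @param path output path; if \code{NULL}, lines are returned invisibly.
#' @return Character vector of PDBQT lines, invisibly.
#' @export
write_pdbqt <- function(lig, tree, pose_coords = NULL, path = NULL) {
  stopifnot(inherits(lig, "dock_ligand"), inherits(tree, "torsion_tree"))
  n <- nrow(lig$atoms)
  covered <- sort(c(tree$root, unlist(lapply(tree$branches, `[[`, "atoms"))))
  if (!identical(covered, seq_len(n)))
    stop("torsion tree does not cover the ligand's atoms", call. = FALSE)
  xyz <- if (is.null(pose_coords)) lig$reference_coords else as.matrix(pose_coords)
  if (nrow(xyz) != n) stop("pose_coords/ligand atom-count mismatch", call. = FALSE)

  new_serial <- integer(n)
  counter <- 0L
  atom_block <- function(idx) {
    a <- lig$atoms[idx, , drop = FALSE]
    a$x <- xyz[idx, 1]; a$y <- xyz[idx, 2]; a$z <- xyz[idx, 3]
    a$serial <- counter + seq_len(nrow(a))
    counter <<- counter + nrow(a)
    new_serial[idx] <<- a$serial
    format_atom_line(a, "ATOM", pdbqt = TRUE)
  }

  children_of <- lapply(seq_along(tree$branches), function(b)
    which(vapply(tree$branches, function(x) x$parent, 0L) == b))
  root_children <- which(vapply(tree$branches, function(x) x$parent, 0L) == 0L)

  emit_branch <- function(b) {
    br <- tree$branches[[b]]
    lines <- atom_block(br$atoms)
    for (ch in children_of[[b]]) lines <- c(lines, emit_child(ch))
    lines
  }
  emit_child <- function(b) {
    br <- tree$branches[[b]]
    inner <- emit_branch(b)
    c(sprintf("BRANCH %3d %3d", new_serial[br$anchor], new_serial[br$pivot]),
      inner,
      sprintf("ENDBRANCH %3d %3d", new_serial[br$anchor], new_serial[br$pivot]))
  }

  lines <- c("ROOT", atom_block(tree$root), "ENDROOT")
  for (ch in root_children) lines <- c(lines, emit_child(ch))
  lines <- c(lines, sprintf("TORSDOF %d", tree$n_dofs))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a PDBQT file or text
#'
#' Single-model files yield the ligand and its torsion tree; multi-MODEL
#' files (engine output) yield one coordinate set per model. Unknown record
#' types are ignored with a warning.
#'
#' @param input path or character vector of PDBQT lines.
#' @return For a single model, a list with elements \code{ligand}
#'   (\code{dock_ligand}; bonds are the BRANCH bonds plus distance-perceived
#'   intra-group bonds), \code{tree} (\code{torsion_tree}) and \code{scores}.
#'   For multi-MODEL input, additionally \code{poses}: a list of n x 3
#'   coordinate matrices, and \code{scores} (one per model, \code{NA} when
#'   absent).
#' @export
read_pdbqt <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input) else unlist(strsplit(input, "\n", fixed = TRUE))
  known <- c("ROOT", "ENDROO", "BRANCH", "ENDBRA", "TORSDO", "ATOM  ",
             "HETATM", "MODEL ", "ENDMDL", "REMARK", "END", "ENDJNK")
  models <- list()
  scores <- numeric()
  cur_atoms <- list()
  # torsion structure captured on the first model only
  rot_bonds <- list()           # serial pairs
  stack <- list()
  root_serials <- integer()
  in_root <- FALSE
  group_of <- integer()         # per-atom: 0 root, else branch index at top of stack
  branch_count <- 0L
  branch_stack <- integer()
  atom_branch <- integer()
  torsdof <- NA_integer_
  first_model_done <- FALSE
  unknown <- character()

  flush_model <- function() {
    if (length(cur_atoms)) {
      models[[length(models) + 1L]] <<- do.call(rbind, cur_atoms)
      cur_atoms <<- list()
      first_model_done <<- TRUE
    }
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    rec <- substr(line, 1, 6)
    key <- sub("\\s.*$", "", line)
    if (rec %in% c("ATOM  ", "HETATM")) {
      cur_atoms[[length(cur_atoms) + 1L]] <- parse_atom_line(line, i, pdbqt = TRUE)
      if (!first_model_done) {
        atom_branch[length(cur_atoms)] <-
          if (length(branch_stack)) branch_stack[length(branch_stack)] else 0L
      }
    } else if (key == "MODEL") {
      flush_model()
      scores[length(models) + 1L] <- NA_real_
    } else if (key == "ENDMDL") {
      flush_model()
    } else if (key == "ROOT") {
      in_root <- TRUE
    } else if (key == "ENDROOT") {
      in_root <- FALSE
    } else if (key == "BRANCH") {
      if (!first_model_done) {
        nums <- as.integer(strsplit(trimws(substr(line, 7, nchar(line))), "\\s+")[[1]])
        branch_count <- branch_count + 1L
        rot_bonds[[branch_count]] <- nums
        branch_stack <- c(branch_stack, branch_count)
        stack[[length(stack) + 1L]] <- list(line = i, nums = nums)
      }
    } else if (key == "ENDBRANCH") {
      if (!first_model_done) {
        if (!length(stack))
          stop(sprintf("ENDBRANCH without matching BRANCH at line %d", i),
               call. = FALSE)
        stack[[length(stack)]] <- NULL
        branch_stack <- branch_stack[-length(branch_stack)]
      }
    } else if (key == "TORSDOF") {
      torsdof <- as.integer(trimws(substr(line, 8, nchar(line))))
    } else if (grepl("VINA RESULT", line)) {
      val <- suppressWarnings(as.numeric(
        strsplit(trimws(sub(".*VINA RESULT:", "", line)), "\\s+")[[1]][1]))
      scores[length(models) + 1L] <- val
    } else if (!(key %in% c("REMARK", "END", "")) && nzchar(key)) {
      unknown <- c(unknown, key)
    }
  }
  if (length(stack))
    stop(sprintf("BRANCH at line %d has no matching ENDBRANCH", stack[[1]]$line),
         call. = FALSE)
  flush_model()
  if (length(unknown))
    warning("ignoring unknown PDBQT record type(s): ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (!length(models)) stop("no atoms found in PDBQT input", call. = FALSE)

  first <- models[[1L]]
  rownames(first) <- NULL
  serial_to_idx <- match(vapply(rot_bonds, `[`, 0L, 1), first$serial)
  pivot_idx <- match(vapply(rot_bonds, `[`, 0L, 2), first$serial)
  bonds <- infer_bonds(first)
  extra <- cbind(serial_to_idx, pivot_idx)
  if (length(rot_bonds)) {
    have <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    want <- paste(pmin(extra[, 1], extra[, 2]), pmax(extra[, 1], extra[, 2]))
    add <- extra[!(want %in% have), , drop = FALSE]
    if (nrow(add)) bonds <- rbind(bonds, add)
  }
  lig <- ligand(first, bonds = bonds, id = "pdbqt")
  rb <- if (length(rot_bonds)) cbind(serial_to_idx, pivot_idx)
        else matrix(integer(), ncol = 2)
  tree <- build_torsion_tree(lig, rotatable_bonds = rb,
                             root_choice = which(atom_branch[seq_len(nrow(first))] == 0L))
  out <- list(ligand = lig, tree = tree, torsdof = torsdof)
  if (length(models) > 1L) {
    nc <- vapply(models, nrow, 0L)
    if (length(unique(nc)) != 1L)
      stop("models differ in atom count", call. = FALSE)
    out$poses <- lapply(models, atom_coords)
    out$scores <- rep_len(scores, length(models))
  }
  out
}
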