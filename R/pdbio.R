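#' Write a system or molecule to PDB
#'
#' Emits a CRYST1 record carrying the periodic box (for systems) followed
#' by fixed-column ATOM records via bio3d. Residue numbers above 9999 wrap
#' modulo 10000 as usual for large PDB files.
#'
#' @param x A [mol_system] or [molecule].
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
write_pdb <- function(x, file) {
  if (inherits(x, "molecule")) {
    atoms <- x$atoms
    atoms$mol_id <- 1L
    box <- NULL
  } else {
    atoms <- x$atoms
    box <- x$box
  }
  n <- nrow(atoms)
  resno <- make_pdb_resno(atoms)
  pdb_atom <- data.frame(
    type = rep("ATOM", n), eleno = seq_len(n), elety = atoms$name,
    alt = "", resid = atoms$resname, chain = "A",
    resno = resno %% 10000L, insert = "",
    x = round(atoms$x, 3), y = round(atoms$y, 3), z = round(atoms$z, 3),
    o = 1, b = 0, segid = "", elesy = atoms$element, charge = "",
    stringsAsFactors = FALSE)
  xyz <- as.numeric(t(as.matrix(pdb_atom[, c("x", "y", "z")])))
  pdbobj <- structure(list(atom = pdb_atom, xyz = xyz), class = "pdb")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(pdbobj, file = tmp)
  body <- readLines(tmp)
  header <- if (!is.null(box)) {
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            box[1], box[2], box[3], 90, 90, 90)
  } else {
    character(0)
  }
  writeLines(c(header, body), file)
  invisible(file)
}

# unique residue number per (molecule, residue) so each water/lipid gets
# its own residue
make_pdb_resno <- function(atoms) {
  key <- paste(atoms$mol_id, atoms$resid)
  if ("resid" %in% names(atoms) &&
      length(unique(atoms$mol_id)) == 1L) {
    return(as.integer(atoms$resid))
  }
  as.integer(factor(key, levels = unique(key)))
}

#' Read a PDB file into a molecular system
#'
#' Parses ATOM/HETATM records with bio3d and the CRYST1 record for the
#' box. Molecules are recovered from residue-number runs; roles are
#' inferred from residue names (HOH = water, MLP/POP = lipid, amino acids
#' = peptide). Bonds are re-derived by a per-molecule distance criterion.
#'
#' @param file PDB path.
#' @param bond_cutoff Maximum interatomic distance treated as a bond,
#'   Angstrom.
#' @return A [mol_system] (box = bounding box if no CRYST1 present).
#' @export
read_pdb <- function(file, bond_cutoff = 1.95) {
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) {
                    stop("malformed PDB '", file, "': ", conditionMessage(e))
                  })
  a <- pdb$atom
  ele <- ifelse(is.na(a$elesy) | a$elesy == "",
                substr(gsub("[0-9]", "", a$elety), 1, 1), trimws(a$elesy))
  atoms <- data.frame(
    name = a$elety, element = ele, resname = a$resid,
    resid = a$resno, x = a$x, y = a$y, z = a$z, charge = 0,
    stringsAsFactors = FALSE)
  lines <- readLines(file, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cl)) {
    as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                 substr(cl[1], 25, 33)))
  } else {
    apply(coords_matrix(atoms), 2, function(v) diff(range(v)) + 2)
  }
  # split into molecules at residue-number changes, merging amino-acid
  # runs into single peptide molecules
  aa_res <- unname(AA3)
  is_aa <- atoms$resname %in% aa_res
  run_id <- cumsum(c(1, diff(atoms$resid) != 0 |
                        atoms$resname[-1] != atoms$resname[-nrow(atoms)]))
  mol_of_run <- integer(max(run_id))
  mol_counter <- 0L
  prev_was_aa <- FALSE
  for (r in seq_len(max(run_id))) {
    first <- which(run_id == r)[1]
    if (is_aa[first] && prev_was_aa) {
      mol_of_run[r] <- mol_counter
    } else {
      mol_counter <- mol_counter + 1L
      mol_of_run[r] <- mol_counter
    }
    prev_was_aa <- is_aa[first]
  }
  mol_id <- mol_of_run[run_id]
  role <- ifelse(atoms$resname == "HOH", "water",
          ifelse(atoms$resname %in% c("MLP", "POP", "POPC"), "lipid",
          ifelse(is_aa, "peptide", "other")))
  mols <- lapply(split(seq_len(nrow(atoms)), mol_id), function(idx) {
    m <- atoms[idx, ]
    rownames(m) <- NULL
    molecule(m, infer_bonds(m, bond_cutoff))
  })
  roles <- vapply(split(role, mol_id), `[`, "", 1)
  mol_system(mols, roles, box = box)
}

infer_bonds <- function(atoms, cutoff = 1.95) {
  xyz <- coords_matrix(atoms)
  n <- nrow(xyz)
  if (n < 2) return(NULL)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  # heavier elements bond longer (C-S, P-O up to ~1.9; allow margin)
  hit <- which(upper.tri(d2) & d2 < cutoff^2 & d2 > 1e-6, arr.ind = TRUE)
  if (nrow(hit) == 0) NULL else unname(hit)
}

#' Write an XYZ snapshot file
#'
#' @param x A [mol_system] or [molecule].
#' @param file Output path.
#' @param comment Comment line.
#' @export
write_xyz <- function(x, file, comment = "pepsmd") {
  atoms <- x$atoms
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(atoms)), comment), con)
  writeLines(sprintf("%-2s %12.5f %12.5f %12.5f", atoms$element,
                     atoms$x, atoms$y, atoms$z), con)
  invisible(file)
}
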