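#' Molecule and molecular-system containers
#'
#' A `molecule` holds an atom table (name, element, residue name/index,
#' coordinates in Angstrom) and a bond list (pairs of atom indices). A
#' `mol_system` additionally carries molecule ids, role tags
#' (`"lipid"`, `"peptide"`, `"water"`), per-atom masses and charges, and a
#' parallelepiped periodic box.
#'
#' @param atoms Data.frame with columns `name, element, resname, resid, x,
#'   y, z` (optionally `charge`).
#' @param bonds Two-column integer matrix of 1-based atom indices, or NULL.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL) {
  need <- c("name", "element", "resname", "resid", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (max(bonds) > nrow(atoms) || min(bonds) < 1)) {
    stop("bond indices out of range")
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  structure(list(atoms = atoms, bonds = bonds), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, %d bonds, %d residues\n",
              nrow(x$atoms), nrow(x$bonds),
              length(unique(x$atoms$resid))))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Number of residues in a molecule
#' @param mol A `molecule`.
#' @return Integer count of distinct residue indices.
#' @export
n_residues <- function(mol) length(unique(mol$atoms$resid))

translate_molecule <- function(mol, shift) {
  mol$atoms$x <- mol$atoms$x + shift[1]
  mol$atoms$y <- mol$atoms$y + shift[2]
  mol$atoms$z <- mol$atoms$z + shift[3]
  mol
}

transform_molecule <- function(mol, rot, center = c(0, 0, 0)) {
  xyz <- coords_matrix(mol$atoms)
  xyz <- sweep(xyz, 2, center)
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, center, `+`)
  mol$atoms <- set_coords(mol$atoms, xyz)
  mol
}

#' Assemble molecules into a simulation system
#'
#' @param molecules List of `molecule` objects.
#' @param roles Character vector of role tags, one per molecule
#'   (`"lipid"`, `"peptide"`, `"water"`, ...).
#' @param box Numeric length-3 box edge lengths (Lx, Ly, Lz) in Angstrom.
#' @param periodic Logical; apply periodic boundary conditions.
#' @return An object of class `mol_system` with a flat atom table
#'   (including `mol_id` and `role`), a global bond matrix and the box.
#' @export
mol_system <- function(molecules, roles, box, periodic = TRUE) {
  stopifnot(length(molecules) == length(roles), length(box) == 3)
  offset <- 0L
  atoms <- list()
  bonds <- list()
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    a <- m$atoms
    a$mol_id <- i
    a$role <- roles[i]
    atoms[[i]] <- a
    if (nrow(m$bonds) > 0) bonds[[i]] <- m$bonds + offset
    offset <- offset + nrow(a)
  }
  atoms <- if (length(atoms)) do.call(rbind, atoms) else
    data.frame(name = character(0), element = character(0),
               resname = character(0), resid = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               charge = numeric(0), mol_id = integer(0),
               role = character(0))
  rownames(atoms) <- NULL
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(0), ncol = 2)
  structure(list(atoms = atoms, bonds = bonds,
                 box = as.numeric(box), periodic = isTRUE(periodic)),
            class = "mol_system")
}

#' @export
print.mol_system <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat(sprintf("<mol_system> %d atoms (%s), %d molecules\n", nrow(x$atoms),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$atoms$mol_id))))
  cat(sprintf("  box %.2f x %.2f x %.2f A, periodic = %s\n",
              x$box[1], x$box[2], x$box[3], x$periodic))
  invisible(x)
}

system_molecule_ids <- function(sys, role) {
  unique(sys$atoms$mol_id[sys$atoms$role == role])
}

#' Count molecules of a given role
#' @param sys A `mol_system`.
#' @param role Role tag, e.g. `"lipid"`.
#' @return Integer count.
#' @export
count_molecules <- function(sys, role) length(system_molecule_ids(sys, role))

#' Shift and wrap a system into its periodic cell
#'
#' Translates the system so its bounding box is centered in the cell, then
#' wraps any atom still outside into `[0, L)` per axis.
#'
#' @param sys A `mol_system`.
#' @return The wrapped system.
#' @export
wrap_system <- function(sys) {
  if (nrow(sys$atoms) == 0) return(sys)
  xyz <- coords_matrix(sys$atoms)
  mid <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  xyz <- sweep(xyz, 2, mid - sys$box / 2, `-`)
  if (sys$periodic) xyz <- sweep(xyz, 2, sys$box, `%%`)
  sys$atoms <- set_coords(sys$atoms, xyz)
  sys
}
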