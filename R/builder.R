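#' Build configuration for membrane system construction
#'
#' @param n_y,n_z Lipid copies along the OY and OZ axes (default 8 x 8).
#' @param lipid_spacing Grid spacing between lipid copies, Angstrom.
#' @param peptide_gap Gap between the upper leaflet head plane and the
#'   lowest peptide atom, Angstrom.
#' @param water_padding Extra box height above/below the solute, Angstrom.
#' @param clash_cutoff Minimum allowed interatomic distance when placing
#'   copies, the peptide and waters, Angstrom.
#' @param water_spacing Cubic lattice constant for water placement,
#'   Angstrom (3.1 approximates bulk density).
#' @param tail_gap Gap between the tail planes of the two leaflets,
#'   Angstrom.
#' @param box_height Optional fixed box length along x (the membrane
#'   normal); computed from contents when NULL.
#' @return A list of class `build_config`.
#' @export
build_config <- function(n_y = 8L, n_z = 8L, lipid_spacing = 6,
                         peptide_gap = 3, water_padding = 6,
                         clash_cutoff = 2.0, water_spacing = 3.1,
                         tail_gap = 3.0, box_height = NULL) {
  stopifnot(n_y >= 1, n_z >= 1, lipid_spacing > 0, water_spacing > 0)
  structure(list(n_y = as.integer(n_y), n_z = as.integer(n_z),
                 lipid_spacing = lipid_spacing, peptide_gap = peptide_gap,
                 water_padding = water_padding, clash_cutoff = clash_cutoff,
                 water_spacing = water_spacing, tail_gap = tail_gap,
                 box_height = box_height),
            class = "build_config")
}

min_intermolecular_distance <- function(mol_a, mol_b) {
  xa <- coords_matrix(mol_a$atoms)
  xb <- coords_matrix(mol_b$atoms)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Replicate a lipid template into a monolayer
#'
#' Places `n_y` x `n_z` translated copies of the template on a rectangular
#' grid in the OY-OZ plane (the membrane plane; OX is the normal).
#'
#' @param template A lipid [molecule] with its head toward +x.
#' @param cfg A [build_config].
#' @param check_clashes Verify that neighboring copies keep at least the
#'   clash cutoff apart.
#' @return List of `n_y * n_z` molecules.
#' @examples
#' layer <- replicate_layer(make_minilipid_template(),
#'                          build_config(n_y = 2, n_z = 2))
#' length(layer)
#' @export
replicate_layer <- function(template, cfg = build_config(),
                            check_clashes = TRUE) {
  stopifnot(inherits(template, "molecule"), nrow(template$atoms) > 0)
  s <- cfg$lipid_spacing
  copies <- list()
  for (iz in seq_len(cfg$n_z) - 1L) {
    for (iy in seq_len(cfg$n_y) - 1L) {
      copies[[length(copies) + 1L]] <-
        translate_molecule(template, c(0, iy * s, iz * s))
    }
  }
  if (check_clashes && length(copies) > 1L) {
    # neighboring grid copies are congruent translates; checking one
    # nearest and one diagonal pair covers all by translational symmetry
    d_near <- min_intermolecular_distance(copies[[1]], copies[[2]])
    if (d_near < cfg$clash_cutoff) {
      stop(sprintf(paste0("lipid copies 1 and 2 clash: min distance ",
                          "%.2f A < cutoff %.2f A"), d_near,
                   cfg$clash_cutoff))
    }
    if (cfg$n_y > 1 && cfg$n_z > 1) {
      diag_idx <- cfg$n_y + 2L
      d_diag <- min_intermolecular_distance(copies[[1]], copies[[diag_idx]])
      if (d_diag < cfg$clash_cutoff) {
        stop(sprintf("diagonal lipid copies clash: %.2f A < %.2f A",
                     d_diag, cfg$clash_cutoff))
      }
    }
  }
  copies
}

#' Fold a monolayer into a tail-to-tail bilayer
#'
#' The second leaflet is a copy of the first rotated 180 degrees about the
#' OY axis through the layer's geometric center -- a proper rotation
#' ((x, y, z) -> (-x, y, -z), determinant +1), not a reflection, so lipid
#' chirality/topology is preserved -- then translated along -x so the tail
#' planes face each other at the configured tail gap.
#'
#' @param layer List of molecules from [replicate_layer] (heads toward +x).
#' @param cfg A [build_config].
#' @return List of `2 * length(layer)` molecules; the original leaflet
#'   keeps its coordinates (upper leaflet, heads at +x).
#' @export
make_bilayer <- function(layer, cfg = build_config()) {
  stopifnot(is.list(layer), length(layer) >= 1)
  all_xyz <- do.call(rbind, lapply(layer, function(m) coords_matrix(m$atoms)))
  ctr <- (apply(all_xyz, 2, min) + apply(all_xyz, 2, max)) / 2
  extent_x <- max(all_xyz[, 1]) - min(all_xyz[, 1])
  rot <- rotation_matrix("y", 180)
  shift <- c(-(extent_x + cfg$tail_gap), 0, 0)
  lower <- lapply(layer, function(m) {
    translate_molecule(transform_molecule(m, rot, center = ctr), shift)
  })
  lower_max_x <- max(vapply(lower,
                            function(m) max(m$atoms$x), numeric(1)))
  upper_min_x <- min(all_xyz[, 1])
  if (lower_max_x > upper_min_x - cfg$tail_gap + 1e-6) {
    stop("leaflet overlap after rotation: check tail_gap")
  }
  c(layer, lower)
}

#' Assemble a bilayer into a periodic simulation system
#'
#' @param bilayer List of lipid molecules from [make_bilayer].
#' @param cfg A [build_config].
#' @return A [mol_system] with role `"lipid"` for every molecule; box
#'   dimensions `Ly = n_y * spacing`, `Lz = n_z * spacing` (periodic
#'   continuity of the lattice) and `Lx` from the lipid extent plus water
#'   padding (or `cfg$box_height`).
#' @export
membrane_system <- function(bilayer, cfg = build_config()) {
  all_x <- unlist(lapply(bilayer, function(m) m$atoms$x))
  lx <- if (!is.null(cfg$box_height)) cfg$box_height else
    (max(all_x) - min(all_x)) + 2 * cfg$water_padding
  box <- c(lx, cfg$n_y * cfg$lipid_spacing, cfg$n_z * cfg$lipid_spacing)
  mol_system(bilayer, rep("lipid", length(bilayer)), box = box)
}

#' Insert a peptide above the membrane
#'
#' Positions the peptide with its long axis along the membrane normal
#' (OX), centered in the membrane plane, at `cfg$peptide_gap` above the
#' upper leaflet head plane, and verifies no peptide-lipid atom pair is
#' closer than the clash cutoff. The box is extended along x if needed.
#'
#' @param sys A [mol_system] containing the bilayer.
#' @param peptide A peptide [molecule] (already axis-aligned by
#'   [build_extended_peptide]).
#' @param cfg A [build_config].
#' @return The system with the peptide added (role `"peptide"`).
#' @export
insert_peptide <- function(sys, peptide, cfg = build_config()) {
  stopifnot(inherits(sys, "mol_system"), inherits(peptide, "molecule"))
  lip <- sys$atoms[sys$atoms$role == "lipid", ]
  if (nrow(lip) == 0) stop("system contains no lipid bilayer")
  head_plane <- max(lip$x)
  target_y <- mean(range(lip$y))
  target_z <- mean(range(lip$z))
  pep <- peptide
  shift <- c(head_plane + cfg$peptide_gap - min(pep$atoms$x),
             target_y - mean(range(pep$atoms$y)),
             target_z - mean(range(pep$atoms$z)))
  pep <- translate_molecule(pep, shift)
  # brute-force clash scan against all lipid atoms
  if (cfg$clash_cutoff > 0) {
    dmin <- min_intermolecular_distance(pep, molecule(lip))
    if (dmin < cfg$clash_cutoff) {
      stop(sprintf("peptide placement clashes with lipid: %.2f A < %.2f A",
                   dmin, cfg$clash_cutoff))
    }
  }
  mols <- c(system_to_molecules(sys), list(pep))
  roles <- c(system_roles(sys), "peptide")
  all_x <- c(sys$atoms$x, pep$atoms$x)
  lx <- max(sys$box[1], diff(range(all_x)) + 2 * cfg$water_padding)
  mol_system(mols, roles, box = c(lx, sys$box[2], sys$box[3]),
             periodic = sys$periodic)
}

system_to_molecules <- function(sys) {
  lapply(split(seq_len(nrow(sys$atoms)), sys$atoms$mol_id), function(idx) {
    a <- sys$atoms[idx, setdiff(names(sys$atoms), c("mol_id", "role"))]
    rownames(a) <- NULL
    keep <- sys$bonds[, 1] %in% idx & sys$bonds[, 2] %in% idx
    b <- sys$bonds[keep, , drop = FALSE]
    b[, 1] <- match(b[, 1], idx); b[, 2] <- match(b[, 2], idx)
    molecule(a, b)
  })
}

system_roles <- function(sys) {
  vapply(split(sys$atoms$role, sys$atoms$mol_id), `[`, "", 1)
}

#' Solvate a system with lattice water
#'
#' Places 3-site waters on a cubic lattice filling the periodic cell and
#' deletes any water whose oxygen lies within the clash cutoff of a solute
#' atom. The system is first centered in its box.
#'
#' @param sys A [mol_system].
#' @param cfg A [build_config].
#' @return The solvated, wrapped system; the number of waters added is
#'   reported via `attr(, "n_waters")`.
#' @export
solvate <- function(sys, cfg = build_config()) {
  sys <- wrap_system(sys)
  s <- cfg$water_spacing
  box <- sys$box
  npts <- pmax(0L, floor(box / s))
  if (any(npts == 0L)) {
    warning("box too small for any water at this lattice spacing")
  }
  grid <- expand.grid(
    x = (seq_len(npts[1]) - 0.5) * s,
    y = (seq_len(npts[2]) - 0.5) * s,
    z = (seq_len(npts[3]) - 0.5) * s)
  solute <- coords_matrix(sys$atoms)
  keep <- rep(TRUE, nrow(grid))
  if (nrow(solute) > 0 && nrow(grid) > 0 && cfg$clash_cutoff > 0) {
    g <- as.matrix(grid)
    # chunked distance scan (minimum image) to bound memory
    cut2 <- cfg$clash_cutoff^2
    chunk <- 2000L
    for (start in seq(1, nrow(g), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(g))
      d2min <- rep(Inf, length(idx))
      for (ax in 1:3) {
        dd <- outer(g[idx, ax], solute[, ax], `-`)
        if (sys$periodic) dd <- dd - box[ax] * round(dd / box[ax])
        if (ax == 1) d2 <- dd^2 else d2 <- d2 + dd^2
      }
      keep[idx] <- apply(d2, 1, min) >= cut2
    }
  }
  g <- as.matrix(grid)[keep, , drop = FALSE]
  n_w <- nrow(g)
  if (n_w == 0 && cfg$water_padding > 0) {
    warning("no waters placed")
  }
  wt <- make_water_template()
  waters <- lapply(seq_len(n_w), function(i) {
    w <- wt
    # alternate orientation with lattice parity (deterministic)
    if (i %% 2 == 0) w <- transform_molecule(w, rotation_matrix("x", 90))
    translate_molecule(w, g[i, ])
  })
  mols <- c(system_to_molecules(sys), waters)
  roles <- c(system_roles(sys), rep("water", n_w))
  out <- mol_system(mols, roles, box = box, periodic = sys$periodic)
  out <- wrap_system(out)
  attr(out, "n_waters") <- n_w
  out
}

#' Build a complete peptide-membrane system from a sequence
#'
#' End-to-end construction: replicate the lipid template into a monolayer,
#' fold it into a tail-to-tail bilayer, insert the extended peptide
#' perpendicular to the membrane, and (optionally) solvate.
#'
#' @param seq Peptide sequence ([pep_seq] or string), or NULL for a bare
#'   membrane.
#' @param cfg A [build_config].
#' @param template Lipid template [molecule]; default the 12-site
#'   mini-lipid.
#' @param solvent Add lattice water (default TRUE).
#' @return A wrapped [mol_system].
#' @examples
#' sys <- build_system("GAV", build_config(n_y = 2, n_z = 2),
#'                     solvent = FALSE)
#' count_molecules(sys, "lipid")
#' @export
build_system <- function(seq = NULL, cfg = build_config(),
                         template = make_minilipid_template(),
                         solvent = TRUE) {
  layer <- replicate_layer(template, cfg)
  bilayer <- make_bilayer(layer, cfg)
  sys <- membrane_system(bilayer, cfg)
  if (!is.null(seq)) {
    pep <- if (inherits(seq, "molecule")) seq else
      build_extended_peptide(seq)
    sys <- insert_peptide(sys, pep, cfg)
  }
  if (solvent) sys <- solvate(sys, cfg) else sys <- wrap_system(sys)
  sys
}
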