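#' Toy forcefield parameter set
#'
#' A minimal parameter set for desk-scale runs: one Lennard-Jones type per
#' element class, a single harmonic force constant for bonds and one for
#' angles (equilibrium values taken from the as-built geometry), a small
#' threefold torsion barrier, and partial charges from the structure
#' templates with name-based backbone overrides. Real parameter files can
#' be supplied in the same format ([read_forcefield]).
#'
#' @param cutoff Nonbonded cutoff radius, Angstrom.
#' @return A list of class `forcefield`.
#' @export
toy_forcefield <- function(cutoff = 10.5) {
  structure(list(
    cutoff = cutoff,
    coulomb_constant = 332.0636,  # kcal A / (mol e^2)
    lj = list(
      H = list(eps = 0.03, sigma = 2.50),
      C = list(eps = 0.10, sigma = 3.40),
      N = list(eps = 0.17, sigma = 3.25),
      O = list(eps = 0.16, sigma = 3.00),
      P = list(eps = 0.20, sigma = 3.70),
      S = list(eps = 0.25, sigma = 3.60)),
    # coarse head beads of the mini-lipid stand for whole choline /
    # phosphate / ester groups, so they carry group-sized radii
    lj_by_name = list(
      NH = list(eps = 0.25, sigma = 4.3),
      PH = list(eps = 0.30, sigma = 4.6),
      OE = list(eps = 0.20, sigma = 3.4)),
    bond_k = 300,      # kcal/mol/A^2
    angle_k = 50,      # kcal/mol/rad^2
    torsion = list(v = 0.3, n = 3, gamma = 0),  # kcal/mol, multiplicity, rad
    charges_by_name = list(N = -0.3, C = 0.6, O = -0.3, OXT = -0.3,
                           H = 0.3)),
    class = "forcefield")
}

#' Read a forcefield from a YAML key-value file
#'
#' The file mirrors the structure of [toy_forcefield]: `cutoff`,
#' `coulomb_constant`, `lj` (per-element `eps`/`sigma`), `bond_k`,
#' `angle_k`, `torsion` (`v`, `n`, `gamma`), `charges_by_name`.
#'
#' @param file YAML path.
#' @return A `forcefield` object.
#' @export
read_forcefield <- function(file) {
  ff <- yaml::read_yaml(file)
  need <- c("cutoff", "coulomb_constant", "lj", "bond_k", "angle_k",
            "torsion")
  miss <- setdiff(need, names(ff))
  if (length(miss)) stop("forcefield file missing fields: ",
                         paste(miss, collapse = ", "))
  structure(ff, class = "forcefield")
}

#' Write a forcefield to YAML
#' @param ff A `forcefield` object.
#' @param file Output path.
#' @export
write_forcefield <- function(ff, file) {
  yaml::write_yaml(unclass(ff), file)
  invisible(file)
}

#' Assign a topology for the MD engine
#'
#' Maps a built system onto engine arrays: per-atom masses (by element),
#' LJ parameters and charges; harmonic bonds with equilibrium lengths from
#' the built geometry; angles enumerated from the bond graph (equilibrium
#' from geometry); threefold torsions on every connected quadruple; 1-2
#' and 1-3 nonbonded exclusions.
#'
#' @param sys A [mol_system].
#' @param ff A `forcefield`.
#' @return A list of class `md_topology` understood by the integrator.
#' @export
assign_topology <- function(sys, ff = toy_forcefield()) {
  atoms <- sys$atoms
  n <- nrow(atoms)
  ele <- atoms$element
  missing_lj <- setdiff(unique(ele), names(ff$lj))
  if (length(missing_lj)) {
    stop("forcefield lacks LJ parameters for element(s): ",
         paste(missing_lj, collapse = ", "))
  }
  eps <- vapply(ele, function(e) ff$lj[[e]]$eps, numeric(1))
  sigma <- vapply(ele, function(e) ff$lj[[e]]$sigma, numeric(1))
  if (!is.null(ff$lj_by_name)) {
    hit <- atoms$name %in% names(ff$lj_by_name)
    if (any(hit)) {
      eps[hit] <- vapply(atoms$name[hit],
                         function(nm) ff$lj_by_name[[nm]]$eps, numeric(1))
      sigma[hit] <- vapply(atoms$name[hit],
                           function(nm) ff$lj_by_name[[nm]]$sigma,
                           numeric(1))
    }
  }
  mass <- ELEMENT_MASS[ele]
  if (anyNA(mass)) stop("unknown element(s): ",
                        paste(unique(ele[is.na(mass)]), collapse = ", "))
  charge <- atoms$charge
  if (!is.null(ff$charges_by_name)) {
    zero <- charge == 0
    nm <- atoms$name
    ov <- unlist(ff$charges_by_name)
    hit <- zero & nm %in% names(ov)
    charge[hit] <- ov[nm[hit]]
  }

  xyz <- coords_matrix(atoms)
  b <- sys$bonds
  mimg <- function(d) {
    if (sys$periodic) d - rep(sys$box, each = nrow(d)) *
      round(d / rep(sys$box, each = nrow(d))) else d
  }
  bond_r0 <- if (nrow(b)) {
    sqrt(rowSums(mimg(xyz[b[, 1], , drop = FALSE] -
                      xyz[b[, 2], , drop = FALSE])^2))
  } else {
    numeric(0)
  }

  # adjacency for angle/torsion enumeration
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
    adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
  }
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (q in seq_len(ncol(cmb))) {
        ang[[length(ang) + 1L]] <- c(cmb[1, q], j, cmb[2, q])
      }
    }
  }
  ang <- if (length(ang)) do.call(rbind, ang) else
    matrix(integer(0), ncol = 3)
  angle_t0 <- apply(ang, 1, function(ijk) {
    va <- xyz[ijk[1], ] - xyz[ijk[2], ]
    vb <- xyz[ijk[3], ] - xyz[ijk[2], ]
    acos(max(-1, min(1, sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)))))
  })

  tor <- list()
  for (r in seq_len(nrow(b))) {
    j <- b[r, 1]; k <- b[r, 2]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i != l) tor[[length(tor) + 1L]] <- c(i, j, k, l)
      }
    }
  }
  tor <- if (length(tor)) do.call(rbind, tor) else
    matrix(integer(0), ncol = 4)

  excl <- unique(rbind(b, ang[, c(1, 3), drop = FALSE]))

  structure(list(
    charge = charge, eps = unname(eps), sigma = unname(sigma),
    mass = unname(mass),
    bond_i = b[, 1], bond_j = b[, 2],
    bond_k = rep(ff$bond_k, nrow(b)), bond_r0 = bond_r0,
    angle_i = ang[, 1], angle_j = ang[, 2],
    angle_k = ang[, 3],
    angle_kf = rep(ff$angle_k, nrow(ang)), angle_t0 = as.numeric(angle_t0),
    tor_i = tor[, 1], tor_j = tor[, 2],
    tor_k = tor[, 3], tor_l = tor[, 4],
    tor_v = rep(ff$torsion$v, nrow(tor)),
    tor_n = rep(ff$torsion$n, nrow(tor)),
    tor_g = rep(ff$torsion$gamma, nrow(tor)),
    imp_i = integer(0), imp_j = integer(0), imp_k = integer(0),
    imp_l = integer(0), imp_kf = numeric(0), imp_x0 = numeric(0),
    excl = matrix(as.integer(excl), ncol = 2),
    box = sys$box, periodic = sys$periodic,
    cutoff = ff$cutoff, coulk = ff$coulomb_constant,
    xyz = xyz),
    class = "md_topology")
}
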