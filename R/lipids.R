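#' Simplified 12-site lipid template
#'
#' A single-chain coarse lipid used for fast desk-scale dynamics: three
#' head sites (choline-like N, phosphate-like P, ester-like O, with
#' compensating partial charges) and a nine-carbon tail. The head points
#' toward +x (the membrane normal); the tail extends toward -x with a
#' small zigzag.
#'
#' @param site_spacing Distance between successive sites along x, Angstrom.
#' @return A [molecule] of 12 atoms bonded in a chain.
#' @examples
#' n_atoms_in <- nrow(make_minilipid_template()$atoms)
#' @export
make_minilipid_template <- function(site_spacing = 1.25) {
  n <- 12L
  names <- c("NH", "PH", "OE", paste0("T", 1:9))
  elements <- c("N", "P", "O", rep("C", 9))
  charges <- c(0.4, 0.4, -0.8, rep(0, 9))
  x <- seq(0, by = -site_spacing, length.out = n)
  y <- rep(c(0, 0.45), length.out = n)  # zigzag
  atoms <- data.frame(name = names, element = elements, resname = "MLP",
                      resid = 1L, x = x, y = y, z = 0, charge = charges,
                      stringsAsFactors = FALSE)
  bonds <- cbind(1:(n - 1), 2:n)
  molecule(atoms, bonds)
}

#' Synthetic idealized POPC template
#'
#' Heavy-atom (52-site) model of
#' 1-palmitoyl-2-oleoyl-sn-glycero-3-phosphatidylcholine with idealized
#' zigzag geometry, generated in code: phosphocholine head toward +x,
#' glycerol linker, palmitoyl (16 C) and oleoyl (18 C) tails toward -x.
#' The coordinates are synthetic (not an experimental or equilibrated
#' structure); the template exists so the builder can be exercised at
#' full atom counts.
#'
#' @return A [molecule] of 52 atoms.
#' @export
make_popc_template <- function() {
  rows <- list()
  bonds <- list()
  add <- function(name, element, xyz, charge = 0, parent = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = "POP", resid = 1L,
      x = xyz[1], y = xyz[2], z = xyz[3], charge = charge,
      stringsAsFactors = FALSE)
    idx <- length(rows)
    if (!is.na(parent)) bonds[[length(bonds) + 1L]] <<- c(parent, idx)
    idx
  }
  # choline
  iN <- add("N", "N", c(9.0, 0.0, 0.0), charge = 0.6)
  add("C1A", "C", c(9.9, 1.1, 0.3), parent = iN)
  add("C1B", "C", c(9.6, -1.2, 0.5), parent = iN)
  add("C1C", "C", c(9.1, 0.2, -1.5), parent = iN)
  iC2 <- add("C2H", "C", c(7.6, 0.4, 0.4), parent = iN)
  iC3 <- add("C3H", "C", c(6.5, -0.5, -0.1), parent = iC2)
  iOP1 <- add("OP1", "O", c(5.2, 0.0, 0.3), charge = -0.4, parent = iC3)
  iP <- add("P", "P", c(3.9, -0.6, -0.2), charge = 1.0, parent = iOP1)
  add("OP2", "O", c(3.9, -2.0, 0.2), charge = -0.6, parent = iP)
  add("OP3", "O", c(3.8, -0.4, -1.7), charge = -0.6, parent = iP)
  iOP4 <- add("OP4", "O", c(2.7, 0.2, 0.5), charge = -0.4, parent = iP)
  iG1 <- add("GC1", "C", c(1.4, -0.2, 0.1), parent = iOP4)
  iG2 <- add("GC2", "C", c(0.3, 0.7, 0.6), parent = iG1)
  iG3 <- add("GC3", "C", c(-1.0, 0.4, -0.1), parent = iG2)
  # sn-1 palmitoyl: ester O + carbonyl C(=O) + 15 tail carbons
  iO11 <- add("O11", "O", c(-1.1, 1.6, 1.3), charge = -0.3, parent = iG3)
  iC11 <- add("C11", "C", c(-2.2, 1.9, 2.0), charge = 0.5, parent = iO11)
  add("O12", "O", c(-3.2, 1.2, 2.0), charge = -0.2, parent = iC11)
  prev <- iC11
  for (k in 1:15) {
    xyz <- c(-2.2 - 1.25 * k, 1.9 + 0.45 * (k %% 2), 2.0)
    prev <- add(sprintf("C1%X", k + 1), "C", xyz, parent = prev)
  }
  # sn-2 oleoyl: ester O + carbonyl C(=O) + 17 tail carbons
  iO21 <- add("O21", "O", c(0.5, 0.8, 2.0), charge = -0.3, parent = iG2)
  iC21 <- add("C21", "C", c(-0.2, 1.3, 3.0), charge = 0.5, parent = iO21)
  add("O22", "O", c(-1.3, 1.8, 3.0), charge = -0.2, parent = iC21)
  prev <- iC21
  for (k in 1:17) {
    xyz <- c(-0.2 - 1.25 * k, 1.3 + 0.45 * (k %% 2), 3.2)
    prev <- add(sprintf("C2%X", k + 1), "C", xyz, parent = prev)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  molecule(atoms, do.call(rbind, bonds))
}

#' Three-site water template
#'
#' Rigid-geometry (TIP3P-like) water: O-H 0.9572 Angstrom, H-O-H 104.52
#' degrees, charges -0.834 / +0.417.
#'
#' @return A [molecule] of 3 atoms.
#' @export
make_water_template <- function() {
  a <- 104.52 / 2 * pi / 180
  d <- 0.9572
  atoms <- data.frame(
    name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    resname = "HOH", resid = 1L,
    x = c(0, d * sin(a), -d * sin(a)),
    y = c(0, d * cos(a), d * cos(a)),
    z = 0,
    charge = c(-0.834, 0.417, 0.417),
    stringsAsFactors = FALSE)
  molecule(atoms, rbind(c(1, 2), c(1, 3)))
}
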