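#' Build a peptide in extended conformation
#'
#' Constructs an all-residue heavy-atom chain from a sequence: backbone
#' placed by natural extension at the configured (phi, psi) with omega =
#' 180 degrees, side chains from idealized internal-coordinate templates,
#' an H atom capping the free N-terminus and an OXT (hydroxyl) oxygen
#' capping the free C-terminus. The chain's principal axis is aligned with
#' the x axis (the membrane normal used by the bilayer builder).
#'
#' @param seq A [pep_seq] or sequence string.
#' @param phi,psi Backbone dihedrals in degrees; the default (-135, 135)
#'   gives a beta-strand-like extended ("linear") chain.
#' @return A [molecule] with one residue per amino acid.
#' @examples
#' p <- build_extended_peptide("GAV")
#' n_residues(p)
#' @export
build_extended_peptide <- function(seq, phi = -135, psi = 135) {
  s <- as_pep_seq(seq)
  ch <- seq_chars(s)
  L <- length(ch)

  rows <- list()
  bonds <- list()
  # index bookkeeping: position of named atom within residue i
  res_index <- vector("list", L)
  pos <- list()   # atom index -> coordinates
  add_atom <- function(name, element, resid, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = AA3[[ch[resid]]],
      resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
    idx <- length(rows)
    pos[[idx]] <<- xyz
    res_index[[resid]][[name]] <<- idx
    idx
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)

  b_CN <- 1.329; b_NCA <- 1.458; b_CAC <- 1.525; b_CO <- 1.231
  a_CACN <- 116.2; a_CNCA <- 121.7; a_NCAC <- 111.2; a_CACO <- 120.5

  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(L)) {
    tmpl <- residue_templates[[ch[i]]]
    if (is.null(tmpl)) stop("no residue template for '", ch[i], "'")
    if (i == 1L) {
      N <- add_atom("N", "N", i, c(0, 0, 0))
      CA <- add_atom("CA", "C", i, c(b_NCA, 0, 0))
      ang <- (180 - a_NCAC) * pi / 180
      C <- add_atom("C", "C", i,
                    pos[[CA]] + b_CAC * c(cos(ang), sin(ang), 0))
    } else {
      N <- add_atom("N", "N", i,
        place_atom(pos[[prevC]], pos[[prevCA]], pos[[prevN]],
                   b_CN, a_CACN, psi))
      CA <- add_atom("CA", "C", i,
        place_atom(pos[[N]], pos[[prevC]], pos[[prevCA]],
                   b_NCA, a_CNCA, 180))          # omega
      C <- add_atom("C", "C", i,
        place_atom(pos[[CA]], pos[[N]], pos[[prevC]],
                   b_CAC, a_NCAC, phi))
      add_bond(prevC, N)
    }
    add_bond(N, CA); add_bond(CA, C)
    if (i == 1L) {
      # H cap on the free N-terminus
      ref3 <- if (L > 1 || TRUE) pos[[C]]
      H <- add_atom("H", "H", i,
        place_atom(pos[[N]], pos[[CA]], ref3, 1.01, 109.5, 180))
      add_bond(N, H)
    }
    # carbonyl O anti to the next N (placed at psi + 180)
    O <- add_atom("O", "O", i,
      place_atom(pos[[C]], pos[[CA]], pos[[N]], b_CO, a_CACO, psi + 180))
    add_bond(C, O)
    if (isTRUE(tmpl$has_cb)) {
      CB <- add_atom("CB", "C", i,
        place_atom(pos[[CA]], pos[[N]], pos[[C]], 1.53, 110.5, 122.5))
      add_bond(CA, CB)
      for (at in tmpl$atoms) {
        refs <- vapply(at$refs, function(nm) res_index[[i]][[nm]], 1L)
        idx <- add_atom(at$name, at$element, i,
          place_atom(pos[[refs[1]]], pos[[refs[2]]], pos[[refs[3]]],
                     at$bond, at$angle, at$dihedral))
        add_bond(refs[1], idx)
      }
      for (eb in tmpl$extra_bonds) {
        a1 <- res_index[[i]][[eb[1]]]
        a2 <- if (eb[2] == "N") res_index[[i]][["N"]] else
          res_index[[i]][[eb[2]]]
        add_bond(a1, a2)
      }
    }
    if (i == L) {
      # OH cap (OXT) on the free C-terminus
      OXT <- add_atom("OXT", "O", i,
        place_atom(pos[[C]], pos[[CA]], pos[[N]], 1.25, 117, psi))
      add_bond(C, OXT)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }

  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  mol <- molecule(atoms, do.call(rbind, bonds))
  attr(mol, "id") <- seq_id(s)
  align_principal_axis(mol, axis = c(1, 0, 0))
}

# rotate so the largest-variance direction of the coordinates lies along
# `axis`; proper rotation only (determinant +1)
align_principal_axis <- function(mol, axis = c(1, 0, 0)) {
  xyz <- coords_matrix(mol$atoms)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3) return(mol)
  sv <- svd(xc)
  v <- sv$v[, 1]
  axis <- axis / sqrt(sum(axis^2))
  cosang <- sum(v * axis)
  if (cosang < 0) { v <- -v; cosang <- -cosang }
  rotax <- vcross(v, axis)
  s <- sqrt(sum(rotax^2))
  if (s < 1e-10) return(translate_molecule(mol, -ctr))
  rotax <- rotax / s
  ang <- atan2(s, cosang)
  K <- matrix(c(0, rotax[3], -rotax[2],
                -rotax[3], 0, rotax[1],
                rotax[2], -rotax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  xyz <- xc %*% t(R)
  mol$atoms <- set_coords(mol$atoms, xyz)
  mol
}
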