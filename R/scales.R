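#' Residue-level scale tables for descriptor computation
#'
#' Bundles the per-residue data every descriptor needs: average residue
#' masses (Da), an ionizable-group pKa set, a hydrophobicity scale, the
#' 20 x 20 dipeptide instability weight matrix (DIWV) and the aliphatic-index
#' coefficients. All tables are data-driven so alternative conventions can
#' be swapped in.
#'
#' The default pKa set is Sillero--Ribeiro; `"bjellqvist"`, `"emboss"` and
#' `"ipc_peptide"` are also packaged. The default hydrophobicity scale is
#' the Eisenberg consensus scale (normalized).
#'
#' @param pka_set Name of a packaged pKa column, or a named numeric vector
#'   with entries `Nterm`, `Cterm`, `D`, `E`, `C`, `Y`, `H`, `K`, `R`.
#' @param hydrophobicity Named numeric vector over the 20 residues, or
#'   `"eisenberg"` for the packaged scale.
#' @param diwv 20 x 20 numeric matrix with residue dimnames, or `NULL` for
#'   the packaged Guruprasad weights.
#' @param aliphatic_coeffs Numeric `c(a =, b =)` multipliers for Val and
#'   Ile/Leu mole fractions.
#' @return A list of class `scale_tables`.
#' @examples
#' sc <- scale_tables()
#' sc$residue_avg_mass[["G"]]
#' @export
scale_tables <- function(pka_set = "sillero", hydrophobicity = "eisenberg",
                         diwv = NULL, aliphatic_coeffs = c(a = 2.9, b = 3.9)) {
  mass_tab <- read.delim(pepsmd_extdata("residue_masses.tsv"))
  residue_avg_mass <- setNames(mass_tab$avg_mass_da, mass_tab$residue)

  if (is.character(pka_set)) {
    pka_tab <- read.delim(pepsmd_extdata("pka_sets.tsv"), check.names = FALSE)
    if (!pka_set %in% names(pka_tab)) {
      stop("unknown pKa set '", pka_set, "'; packaged sets: ",
           paste(setdiff(names(pka_tab), "group"), collapse = ", "))
    }
    pka <- setNames(pka_tab[[pka_set]], pka_tab$group)
  } else {
    pka <- pka_set
  }
  needed <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(needed %in% names(pka))) {
    stop("pKa set must name groups: ", paste(needed, collapse = ", "))
  }

  if (identical(hydrophobicity, "eisenberg")) {
    h_tab <- read.delim(pepsmd_extdata("hydrophobicity_eisenberg.tsv"))
    hydro <- setNames(h_tab$h, h_tab$residue)
  } else {
    hydro <- hydrophobicity
  }
  if (!all(AA_CODES %in% names(hydro))) {
    stop("hydrophobicity scale must cover all 20 residues")
  }

  if (is.null(diwv)) {
    d_tab <- read.delim(pepsmd_extdata("diwv.tsv"), check.names = FALSE)
    diwv <- as.matrix(d_tab[, -1])
    rownames(diwv) <- d_tab$first
  }
  if (!all(AA_CODES %in% rownames(diwv)) || !all(AA_CODES %in% colnames(diwv))) {
    stop("DIWV matrix must be complete over the 400 dipeptides")
  }

  structure(list(residue_avg_mass = residue_avg_mass,
                 pka_set = pka,
                 hydrophobicity_scale = hydro,
                 diwv = diwv,
                 aliphatic_coeffs = aliphatic_coeffs,
                 water_mass = 18.01524),
            class = "scale_tables")
}

pepsmd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepsmd")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}
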