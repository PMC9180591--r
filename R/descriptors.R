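#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (18.02 Da) for the free
#' termini.
#'
#' @param seq A [pep_seq] or plain sequence string.
#' @param scales A [scale_tables] object.
#' @return Molecular weight in Da.
#' @examples
#' molecular_weight("EMEVVVLNID")  # 1160.3
#' @export
molecular_weight <- function(seq, scales = scale_tables()) {
  ch <- seq_chars(seq)
  sum(scales$residue_avg_mass[ch]) + scales$water_mass
}

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch sum over the free N-terminus, free C-terminus and
#' all ionizable side chains. A positive group contributes
#' `1 / (1 + 10^(pH - pKa))`, a negative group `-1 / (1 + 10^(pKa - pH))`.
#'
#' @inheritParams molecular_weight
#' @param pH pH in (0, 14).
#' @return Net charge in elementary charges.
#' @examples
#' net_charge("RRRRRRRRRR", 7)  # about +10
#' @export
net_charge <- function(seq, pH = 7, scales = scale_tables()) {
  if (!is.numeric(pH) || pH <= 0 || pH >= 14) {
    stop("pH must lie strictly between 0 and 14")
  }
  ch <- seq_chars(seq)
  pka <- scales$pka_set
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  q <- pos_frac(pka[["Nterm"]]) + neg_frac(pka[["Cterm"]])
  for (grp in c("K", "R", "H")) {
    n <- sum(ch == grp)
    if (n > 0) q <- q + n * pos_frac(pka[[grp]])
  }
  for (grp in c("D", "E", "C", "Y")) {
    n <- sum(ch == grp)
    if (n > 0) q <- q + n * neg_frac(pka[[grp]])
  }
  unname(q)
}

#' Theoretical isoelectric point
#'
#' pH at which [net_charge] vanishes, located by bisection on (0, 14).
#' The net charge is strictly decreasing in pH, so the root is unique.
#'
#' @inheritParams molecular_weight
#' @param tol Convergence tolerance on |charge|.
#' @return pI in pH units.
#' @examples
#' isoelectric_point("EMEVVVLNID")  # about 3.4
#' @export
isoelectric_point <- function(seq, scales = scale_tables(), tol = 1e-4) {
  lo <- 1e-6
  hi <- 14 - 1e-6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, scales)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Mean (normalized) hydrophobicity
#'
#' Arithmetic mean of per-residue values on the configured scale
#' (Eisenberg consensus by default).
#'
#' @inheritParams molecular_weight
#' @return Dimensionless mean hydrophobicity.
#' @export
hydrophobicity <- function(seq, scales = scale_tables()) {
  ch <- seq_chars(seq)
  h <- scales$hydrophobicity_scale[ch]
  if (anyNA(h)) stop("residue missing from hydrophobicity scale")
  mean(h)
}

#' Hydrophobic moment
#'
#' Modulus of the vector sum of per-residue hydrophobicities placed at
#' successive angular increments `delta_deg` around the chain axis, divided
#' by the number of residues:
#' `sqrt((sum h_n sin(n d))^2 + (sum h_n cos(n d))^2) / N`.
#' The default 100 degrees is the alpha-helical periodicity.
#'
#' @inheritParams molecular_weight
#' @param delta_deg Angular increment per residue, degrees in (0, 360).
#' @return Dimensionless hydrophobic moment.
#' @export
hydrophobic_moment <- function(seq, scales = scale_tables(), delta_deg = 100) {
  if (delta_deg <= 0 || delta_deg >= 360) {
    stop("delta_deg must lie strictly between 0 and 360")
  }
  ch <- seq_chars(seq)
  h <- scales$hydrophobicity_scale[ch]
  if (anyNA(h)) stop("residue missing from hydrophobicity scale")
  n <- seq_along(h)
  d <- delta_deg * pi / 180
  sqrt(sum(h * sin(n * d))^2 + sum(h * cos(n * d))^2) / length(h)
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains (Ikai):
#' `X_Ala + a * X_Val + b * (X_Ile + X_Leu)` with mole percentages X and
#' coefficients a = 2.9, b = 3.9.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless aliphatic index (>= 0).
#' @examples
#' aliphatic_index("LLLLLLLLLL")  # 390
#' @export
aliphatic_index <- function(seq, scales = scale_tables()) {
  ch <- seq_chars(seq)
  molepct <- function(res) 100 * sum(ch == res) / length(ch)
  a <- scales$aliphatic_coeffs[["a"]]
  b <- scales$aliphatic_coeffs[["b"]]
  molepct("A") + a * molepct("V") + b * (molepct("I") + molepct("L"))
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic
#' `II = (10 / L) * sum_i DIWV(x_i, x_{i+1})` over the L - 1 dipeptides of
#' an L-residue sequence.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless instability index.
#' @examples
#' instability_index("RKKRRQRRR")
#' @export
instability_index <- function(seq, scales = scale_tables()) {
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L < 2L) stop("instability index needs at least 2 residues (no dipeptides)")
  w <- scales$diwv[cbind(ch[-L], ch[-1])]
  (10 / L) * sum(w)
}

#' Full descriptor set for one or more peptides
#'
#' @param seqs A [pep_seq], a named character vector, or a list of either.
#' @param scales A [scale_tables] object.
#' @param pH pH for the net-charge column.
#' @param delta_deg Angular increment for the hydrophobic moment.
#' @return A data.frame with one row per peptide and columns
#'   `id, sequence, length, mw, z, pI, Hn, muHn, alpha, II`.
#' @examples
#' peptide_descriptors(study_peptides("amyloidogenic"))
#' @export
peptide_descriptors <- function(seqs, scales = scale_tables(), pH = 7,
                                delta_deg = 100) {
  if (inherits(seqs, "pep_seq") || is.character(seqs) && length(seqs) == 1L &&
      is.null(names(seqs))) {
    seqs <- list(seqs)
  }
  if (is.character(seqs)) {
    seqs <- mapply(pep_seq, seqs, names(seqs), SIMPLIFY = FALSE)
  }
  seqs <- lapply(seqs, as_pep_seq)
  rows <- lapply(seqs, function(s) {
    data.frame(
      id = seq_id(s),
      sequence = unclass(s),
      length = nchar(s),
      mw = molecular_weight(s, scales),
      z = net_charge(s, pH, scales),
      pI = isoelectric_point(s, scales),
      Hn = hydrophobicity(s, scales),
      muHn = hydrophobic_moment(s, scales, delta_deg),
      alpha = aliphatic_index(s, scales),
      II = instability_index(s, scales),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate descriptors with force maxima
#'
#' Pearson correlation of each descriptor column against the mean force
#' maxima of every (mode, velocity) cell of an experiment table, over the
#' peptides shared by the two inputs.
#'
#' @param descriptors Data.frame from [peptide_descriptors] (needs an `id`
#'   column plus numeric descriptor columns).
#' @param forces An `experiment_table` (see [load_published_forces] or
#'   [aggregate_maxima]).
#' @param peptides Optional character vector restricting the peptide ids
#'   used (default: all shared ids).
#' @param min_n Minimum number of shared peptides per cell (default 3).
#' @return Object of class `correlation_report`: a data.frame with columns
#'   `descriptor, mode, velocity, n, r`, plus a `best` attribute holding
#'   max |r| per descriptor.
#' @export
correlate_descriptors <- function(descriptors, forces, peptides = NULL,
                                  min_n = 3L) {
  stopifnot(is.data.frame(descriptors), "id" %in% names(descriptors))
  ftab <- as.data.frame(forces)
  shared <- intersect(descriptors$id, ftab$peptide)
  if (!is.null(peptides)) shared <- intersect(shared, peptides)
  if (length(shared) < min_n) {
    stop("insufficient data: only ", length(shared),
         " peptides shared between descriptors and force table")
  }
  desc_cols <- setdiff(names(descriptors)[vapply(descriptors, is.numeric,
                                                 TRUE)], "length")
  velocities <- sort(unique(ftab$velocity), decreasing = TRUE)
  rows <- list()
  for (dcol in desc_cols) {
    for (mode in c("com", "atom")) {
      for (v in velocities) {
        cell <- ftab[ftab$velocity == v & ftab$peptide %in% shared,
                     c("peptide", mode)]
        cell <- cell[!is.na(cell[[mode]]), ]
        x <- descriptors[[dcol]][match(cell$peptide, descriptors$id)]
        y <- cell[[mode]]
        r <- if (length(y) < min_n || sd(x) == 0 || sd(y) == 0) {
          NA_real_
        } else {
          cor(x, y)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = dcol, mode = mode, velocity = v,
          n = length(y), r = r, stringsAsFactors = FALSE)
      }
    }
  }
  rep <- do.call(rbind, rows)
  best <- vapply(split(rep, rep$descriptor), function(d) {
    if (all(is.na(d$r))) NA_real_ else max(abs(d$r), na.rm = TRUE)
  }, numeric(1))
  structure(rep, best = best, peptides = shared,
            class = c("correlation_report", "data.frame"))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Descriptor-force correlation over", length(attr(x, "peptides")),
      "peptides\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat("\nmax |r| per descriptor:\n")
  print(round(attr(x, "best"), 3))
  invisible(x)
}
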