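#' Validated peptide sequences
#'
#' A `pep_seq` is a one-letter amino-acid string restricted to the 20
#' canonical residues, carrying a free-text identifier. It is the unit on
#' which descriptors are computed and from which extended-chain structures
#' are built.
#'
#' @param residues One-letter amino-acid string (characters from
#'   `ACDEFGHIKLMNPQRSTVWY`, case-insensitive).
#' @param id Label for the peptide; defaults to the sequence itself.
#' @return An object of class `pep_seq`: a character scalar with an `id`
#'   attribute.
#' @examples
#' p2 <- pep_seq("EMEVVVLNID", id = "P2")
#' nchar(p2)
#' @export
pep_seq <- function(residues, id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(trimws(residues))
  if (nchar(residues) < 1L) {
    stop("peptide sequence must contain at least one residue")
  }
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  structure(residues, id = if (is.null(id)) residues else as.character(id),
            class = "pep_seq")
}

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @export
print.pep_seq <- function(x, ...) {
  cat(sprintf("<pep_seq %s> %s (%d aa)\n", attr(x, "id"),
              unclass(x), nchar(x)))
  invisible(x)
}

as_pep_seq <- function(x, id = NULL) {
  if (inherits(x, "pep_seq")) x else pep_seq(x, id = id)
}

seq_chars <- function(seq) strsplit(unclass(as_pep_seq(seq)), "")[[1]]

seq_id <- function(seq) attr(as_pep_seq(seq), "id")

#' Peptide roster of the pulling study
#'
#' The thirteen peptides whose membrane-pulling force maxima are tabulated:
#' seven amyloidogenic fragments of ribosomal S1 proteins (P1--P7, P1 being
#' P7 fused to the HIV-1 TAT cell-penetrating fragment via a GGAG linker),
#' the 9-residue TAT fragment itself (CPP), and five 10-residue
#' homo-repeats.
#'
#' @param subset One of `"all"`, `"amyloidogenic"` (P1--P7), `"main"`
#'   (P1--P7 plus CPP) or `"homorepeats"`.
#' @return Named list of [pep_seq] objects.
#' @examples
#' names(study_peptides("main"))
#' @export
study_peptides <- function(subset = c("all", "amyloidogenic", "main",
                                      "homorepeats")) {
  subset <- match.arg(subset)
  seqs <- c(
    P1 = "RKKRRQRRRGGAGVTDFGVFVEI",
    P2 = "EMEVVVLNID",
    P3 = "DFGVFVNLG",
    P4 = "IVRGVVVAID",
    P5 = "DEITVKVLKF",
    P6 = "VVEGTVVEVT",
    P7 = "VTDFGVFVEI",
    CPP = "RKKRRQRRR",
    PolyAla = "AAAAAAAAAA",
    PolyLeu = "LLLLLLLLLL",
    PolyMet = "MMMMMMMMMM",
    PolyArg = "RRRRRRRRRR",
    PolyGlu = "EEEEEEEEEE")
  keep <- switch(subset,
    all = names(seqs),
    amyloidogenic = paste0("P", 1:7),
    main = c(paste0("P", 1:7), "CPP"),
    homorepeats = grep("^Poly", names(seqs), value = TRUE))
  lapply(setNames(keep, keep), function(k) pep_seq(seqs[[k]], id = k))
}

#' Read peptide sequences from FASTA or two-column TSV
#'
#' @param path File path. FASTA is detected by a leading `>`; otherwise the
#'   file is read as tab-separated `id<TAB>sequence` lines (no header).
#' @return Named list of [pep_seq] objects.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences in ", path)
  if (startsWith(lines[1], ">")) {
    fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
    ids <- names(fa)
    seqs <- vapply(fa, function(x) as.character(x)[1], "")
  } else {
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 2L)) {
      stop("TSV input must have two tab-separated columns: id, sequence")
    }
    ids <- vapply(parts, `[`, "", 1)
    seqs <- vapply(parts, `[`, "", 2)
  }
  mapply(function(s, i) pep_seq(s, id = i), seqs, ids,
         SIMPLIFY = FALSE, USE.NAMES = FALSE) |>
    setNames(ids)
}
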