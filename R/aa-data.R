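# Amino-acid tables shared across the package.

#' @noRd
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @noRd
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

# Kyte-Doolittle hydropathy, indexed like AA1/AA3.
#' @noRd
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Canonical Calpha -> side-chain-centroid distance (Angstrom) used when no
# side-chain atoms are available. Glycine has no side chain: distance 0.
#' @noRd
SC_DISTANCE <- c(A = 1.53, R = 4.10, N = 2.50, D = 2.48, C = 2.07,
                 Q = 3.12, E = 3.10, G = 0.00, H = 3.17, I = 2.30,
                 L = 2.60, K = 3.50, M = 2.95, F = 3.41, P = 1.87,
                 S = 1.90, T = 1.93, W = 3.86, Y = 3.80, V = 1.97)

#' Convert a three-letter residue name vector to one-letter codes
#' @param res3 character vector of three-letter residue names
#' @return character vector of one-letter codes (NA for unknown names)
#' @keywords internal
#' @noRd
aa3_to_1 <- function(res3) {
  AA1[match(toupper(res3), AA3)]
}

#' @noRd
aa1_to_3 <- function(res1) {
  AA3[match(toupper(res1), AA1)]
}

#' @noRd
aa_index <- function(res1) {
  match(toupper(res1), AA1)
}

#' Default non-standard residue-name mapping
#'
#' The mapping from non-standard (modified) residue names to their standard
#' parents is shipped as plain-text data (`inst/extdata/nonstandard_map.tsv`)
#' so it can be edited without touching code. This function loads it.
#'
#' @param path optional path to a two-column TSV (`nonstandard`, `standard`);
#'   defaults to the table shipped with the package.
#' @return named character vector mapping non-standard to standard 3-letter
#'   codes.
#' @export
default_residue_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nonstandard_map.tsv", package = "pepdock")
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stats::setNames(toupper(tab$standard), toupper(tab$nonstandard))
}
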