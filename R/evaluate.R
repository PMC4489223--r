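# Docking-quality assessment: ligand RMSD after receptor superposition,
# high/medium/low classification, peptide-receptor contact maps.

#' Ligand RMSD of a model against a reference complex
#'
#' The receptor Calpha trace of `model` is superimposed onto the reference
#' receptor (Kabsch); the RMSD is then computed on the peptide Calpha atoms
#' only, with no further fitting of the peptide.
#'
#' @param model,reference `cg_complex` (or `cg_snapshot`) objects with equal
#'   peptide length and receptor topology.
#' @return RMSD in A.
#' @export
ligand_rmsd <- function(model, reference) {
  model <- .as_complex(model); reference <- .as_complex(reference)
  if (nrow(model$receptor$ca) != nrow(reference$receptor$ca) ||
      nrow(model$peptide$ca) != nrow(reference$peptide$ca)) {
    stop("model and reference topology mismatch", call. = FALSE)
  }
  k <- .kabsch(model$receptor$ca, reference$receptor$ca)
  pep <- .apply_kabsch(k, model$peptide$ca)
  sqrt(mean(rowSums((pep - reference$peptide$ca)^2)))
}

#' Classify docking quality from ligand RMSD
#'
#' High-quality: RMSD < 3 A; medium-quality: 3 A <= RMSD <= 5.5 A;
#' low-quality: RMSD > 5.5 A. Both boundaries belong to the medium class.
#'
#' @param rmsd ligand RMSD value(s) in A.
#' @return character vector over `{"high", "medium", "low"}`.
#' @export
classify_quality <- function(rmsd) {
  stopifnot(all(rmsd >= 0))
  ifelse(rmsd < 3, "high", ifelse(rmsd <= 5.5, "medium", "low"))
}

#' Best model of a set against a reference
#'
#' @param models list of `cg_complex`/`cg_snapshot`.
#' @param reference the reference complex.
#' @return list with `rmsd` (minimum ligand RMSD), `index` (position of the
#'   best model), `class` (its quality label) and `rmsds` (all values).
#' @export
best_of_set <- function(models, reference) {
  if (length(models) == 0) {
    return(list(rmsd = NA_real_, index = NA_integer_, class = NA_character_,
                rmsds = numeric(0)))
  }
  rmsds <- vapply(models, ligand_rmsd, numeric(1), reference = reference)
  i <- which.min(rmsds)
  list(rmsd = rmsds[i], index = i, class = classify_quality(rmsds[i]),
       rmsds = rmsds)
}

#' Peptide-receptor contact map
#'
#' A peptide residue and a receptor residue are in contact when the distance
#' between their pseudo side-chain centroids is at or below the cutoff (for
#' glycine the centroid coincides with the Calpha, which acts as the
#' fallback center). The cutoff is user-defined.
#'
#' @param complex a `cg_complex` (or `cg_snapshot`).
#' @param cutoff contact distance cutoff in A (default 6.5).
#' @return a `contact_map`: list with `matrix` (logical, peptide x receptor),
#'   `contacts` (data.frame: peptide_res, receptor_chain, receptor_res,
#'   receptor_index, distance — sorted by peptide then receptor index) and
#'   `cutoff`.
#' @export
contact_map <- function(complex, cutoff = 6.5) {
  complex <- .as_complex(complex)
  p <- complex$peptide; r <- complex$receptor
  np <- nrow(p$sc); nr <- nrow(r$sc)
  d2 <- outer(rowSums(p$sc^2), rowSums(r$sc^2), `+`) - 2 * p$sc %*% t(r$sc)
  d <- sqrt(pmax(d2, 0))
  m <- d <= cutoff
  idx <- which(m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  contacts <- data.frame(
    peptide_res = as.integer(idx[, 1]),
    receptor_chain = r$chain_id[idx[, 2]],
    receptor_res = r$res_seq[idx[, 2]],
    receptor_index = as.integer(idx[, 2]),
    distance = d[idx])
  structure(list(matrix = m, contacts = contacts, cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> cutoff %.2f A, %d contact(s)\n",
              x$cutoff, nrow(x$contacts)))
  invisible(x)
}

#' Write a contact map as TSV (contact list + dense matrix)
#' @param cm a `contact_map`.
#' @param list_path path for the contact list TSV.
#' @param matrix_path optional path for the dense 0/1 matrix TSV.
#' @export
write_contact_map_tsv <- function(cm, list_path, matrix_path = NULL) {
  utils::write.table(cm$contacts, list_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(matrix_path)) {
    utils::write.table(cm$matrix * 1L, matrix_path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(list_path)
}
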