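# PDB-format reading, validation, normalization and writing.
#
# Internal representation: a `receptor_structure` is a list with
#   atoms    - data.frame of kept ATOM/HETATM records (first altloc only)
#   residues - one row per residue: chain, res_seq, icode, res_name and a
#              dense 1-based global_index used everywhere downstream
#   ca       - n x 3 matrix of Calpha coordinates in residue order
# Author (file) numbering is preserved in `residues` so output files can
# round-trip it; all internal indexing is the dense global index.

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records using the wwPDB v3.3 fixed-column layout.
#' Only the first MODEL of a multi-model file is read. For alternate
#' locations the first occurring altloc of each atom is kept and the rest are
#' dropped. HETATM records whose residue name is a standard amino acid or
#' appears in the non-standard mapping table are retained (so modified
#' residues survive until [normalize_nonstandard()]); waters and other
#' ligands are dropped. A blank chain identifier is normalized to `"A"`.
#'
#' @param path path to a PDB file, or a character vector of PDB lines.
#' @param mapping non-standard residue mapping used to decide which HETATM
#'   residues are amino acids; defaults to [default_residue_mapping()].
#' @return a `receptor_structure` object.
#' @export
read_pdb <- function(path, mapping = default_residue_mapping()) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1, 6)
  # restrict to the first model
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) stop("no ATOM records found in PDB input", call. = FALSE)
  ln <- which(keep)
  al <- lines[keep]

  parse_num <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & !grepl("^\\s*$", txt))
    if (length(bad) > 0) {
      stop(sprintf("unparseable %s field at line %d: '%s'",
                   what, ln[bad[1]], al[bad[1]]), call. = FALSE)
    }
    out
  }

  atoms <- data.frame(
    record    = substr(al, 1, 6),
    atom_name = trimws(substr(al, 13, 16)),
    altloc    = substr(al, 17, 17),
    res_name  = toupper(trimws(substr(al, 18, 20))),
    chain     = substr(al, 22, 22),
    res_seq   = as.integer(parse_num(substr(al, 23, 26), "residue number")),
    icode     = substr(al, 27, 27),
    x         = parse_num(substr(al, 31, 38), "x coordinate"),
    y         = parse_num(substr(al, 39, 46), "y coordinate"),
    z         = parse_num(substr(al, 47, 54), "z coordinate"),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    line      = ln,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$res_seq)) {
    bad <- which(is.na(atoms$res_seq))[1]
    stop(sprintf("unparseable residue number at line %d", ln[bad]),
         call. = FALSE)
  }
  bad_xyz <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad_xyz)) {
    stop(sprintf("non-finite coordinates at line %d",
                 atoms$line[which(bad_xyz)[1]]), call. = FALSE)
  }
  atoms$chain[atoms$chain == " "] <- "A"
  if (any(atoms$atom_name == "")) {
    stop(sprintf("empty atom name at line %d",
                 atoms$line[which(atoms$atom_name == "")[1]]), call. = FALSE)
  }

  # keep amino-acid residues only: standard names, or names we can normalize
  aa_like <- atoms$res_name %in% AA3 | atoms$res_name %in% names(mapping)
  atoms <- atoms[aa_like & !(atoms$res_name %in% WATER_NAMES), , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("PDB input contains no protein residues", call. = FALSE)
  }

  # residue key in file order
  rkey <- paste(atoms$chain, atoms$res_seq, atoms$icode, sep = "|")
  rid <- match(rkey, unique(rkey))
  # first-altloc rule: within a residue keep the first occurrence of each atom
  dup <- duplicated(paste(rid, atoms$atom_name, sep = "|"))
  atoms <- atoms[!dup, , drop = FALSE]
  rid <- rid[!dup]

  first <- !duplicated(rid)
  residues <- data.frame(
    chain = atoms$chain[first],
    res_seq = atoms$res_seq[first],
    icode = atoms$icode[first],
    res_name = atoms$res_name[first],
    stringsAsFactors = FALSE
  )
  residues$global_index <- seq_len(nrow(residues))
  atoms$global_index <- residues$global_index[rid]
  atoms$record <- NULL
  atoms$line <- NULL

  structure(list(atoms = atoms, residues = residues,
                 ca = .ca_matrix(atoms, residues)),
            class = "receptor_structure")
}

# n x 3 Calpha matrix in global-index order (NA rows where CA missing)
#' @noRd
.ca_matrix <- function(atoms, residues) {
  ca <- matrix(NA_real_, nrow(residues), 3)
  is_ca <- atoms$atom_name == "CA"
  idx <- atoms$global_index[is_ca]
  ca[idx, ] <- as.matrix(atoms[is_ca, c("x", "y", "z")])
  dimnames(ca) <- NULL
  ca
}

#' @export
print.receptor_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat(sprintf("<receptor_structure> %d residues in %d chain(s): %s\n",
              nrow(x$residues), length(ch),
              paste(sprintf("%s (%d)", names(ch), ch), collapse = ", ")))
  invisible(x)
}

#' List input-contract violations of a receptor structure
#'
#' The input contract requires every residue to carry a complete backbone
#' (N, CA, C, O) and every chain to be at most 500 residues long. Side-chain
#' atoms may be missing.
#'
#' @param s a `receptor_structure`.
#' @param max_chain_length maximum residues per chain (default 500).
#' @return data.frame with columns `type`, `chain`, `res_seq`, `icode`,
#'   `detail`; zero rows when the structure is valid.
#' @export
receptor_violations <- function(s, max_chain_length = 500L) {
  stopifnot(inherits(s, "receptor_structure"))
  out <- list()
  backbone <- c("N", "CA", "C", "O")
  for (k in seq_len(nrow(s$residues))) {
    gi <- s$residues$global_index[k]
    have <- s$atoms$atom_name[s$atoms$global_index == gi]
    miss <- setdiff(backbone, have)
    if (length(miss) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        type = "missing_backbone",
        chain = s$residues$chain[k], res_seq = s$residues$res_seq[k],
        icode = s$residues$icode[k],
        detail = paste("missing", paste(miss, collapse = ",")),
        stringsAsFactors = FALSE)
    }
  }
  lens <- table(s$residues$chain)
  for (ch in names(lens)[lens > max_chain_length]) {
    out[[length(out) + 1L]] <- data.frame(
      type = "chain_too_long", chain = ch, res_seq = NA_integer_,
      icode = "", detail = sprintf("%d residues (max %d)",
                                   lens[[ch]], max_chain_length),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    data.frame(type = character(), chain = character(),
               res_seq = integer(), icode = character(),
               detail = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Validate a receptor structure against the input contract
#'
#' Errors with a report of every violation (chain + author residue number);
#' returns the structure invisibly when it passes.
#'
#' @inheritParams receptor_violations
#' @return the validated structure, invisibly.
#' @export
validate_receptor <- function(s, max_chain_length = 500L) {
  v <- receptor_violations(s, max_chain_length)
  if (nrow(v) > 0) {
    msg <- paste(sprintf("  [%s] chain %s residue %s%s: %s", v$type, v$chain,
                         ifelse(is.na(v$res_seq), "-", v$res_seq),
                         trimws(v$icode), v$detail),
                 collapse = "\n")
    stop("receptor failed validation:\n", msg, call. = FALSE)
  }
  invisible(s)
}

#' Replace non-standard residue names by their standard parents
#'
#' @param s a `receptor_structure`.
#' @param mapping named character vector (non-standard -> standard 3-letter
#'   code); defaults to the shipped table.
#' @return the structure with all residue names standard. Idempotent.
#' @export
normalize_nonstandard <- function(s, mapping = default_residue_mapping()) {
  stopifnot(inherits(s, "receptor_structure"))
  nonstd <- setdiff(unique(s$residues$res_name), AA3)
  unmappable <- setdiff(nonstd, names(mapping))
  if (length(unmappable) > 0) {
    stop("unmappable non-standard residue(s): ",
         paste(unmappable, collapse = ", "), call. = FALSE)
  }
  remap <- function(nm) ifelse(nm %in% AA3, nm, unname(mapping[nm]))
  s$residues$res_name <- remap(s$residues$res_name)
  s$atoms$res_name <- remap(s$atoms$res_name)
  s
}

#' Validate a peptide sequence and optional secondary-structure string
#'
#' @param sequence one-letter amino-acid sequence, 1-30 residues, standard
#'   alphabet only (case-insensitive).
#' @param ss optional per-residue secondary structure over `{H, E, C}`
#'   (helix / extended / coil); defaults to all-coil.
#' @return a `peptide_spec` with fields `sequence` and `ss`.
#' @export
validate_peptide <- function(sequence, ss = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("\\s", "", sequence))
  n <- nchar(sequence)
  if (n < 1L || n > 30L) {
    stop(sprintf("peptide must be 1-30 residues (got %d)", n), call. = FALSE)
  }
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad) > 0) {
    stop("non-standard letter(s) in peptide sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (is.null(ss)) {
    ss <- strrep("C", n)
  } else {
    ss <- toupper(gsub("\\s", "", ss))
    if (nchar(ss) != n) {
      stop(sprintf("secondary-structure string length (%d) != sequence length (%d)",
                   nchar(ss), n), call. = FALSE)
    }
    badss <- setdiff(strsplit(ss, "")[[1]], c("H", "E", "C"))
    if (length(badss) > 0) {
      stop("secondary-structure states must be H, E or C; got: ",
           paste(unique(badss), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sequence = sequence, ss = ss), class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %s (%d aa)\n  ss: %s\n",
              x$sequence, nchar(x$sequence), x$ss))
  invisible(x)
}

# pick a chain ID not used by the receptor
#' @noRd
.free_chain_id <- function(used) {
  pool <- c("P", LETTERS, letters, as.character(0:9))
  free <- setdiff(pool, used)
  if (length(free) == 0) stop("chain-ID space exhausted", call. = FALSE)
  free[1]
}

#' Write coarse-grained models as a multi-MODEL Calpha-only PDB file
#'
#' Receptor chains keep their author numbering; the peptide is written as a
#' distinct chain ID not used by the receptor, numbered from 1.
#'
#' @param models list of `cg_complex` objects sharing one residue topology
#'   (a single `cg_complex` is also accepted).
#' @param path output file path.
#' @return invisibly, the character vector of lines written.
#' @export
write_models_pdb <- function(models, path) {
  if (inherits(models, "cg_complex")) models <- list(models)
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  stopifnot(all(vapply(models, inherits, logical(1), "cg_complex")))
  r0 <- models[[1]]$receptor
  pep_chain <- .free_chain_id(unique(r0$chain_id))
  out <- character(0)
  fmt <- function(serial, res3, chain, seqnum, icode, xyz) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, res3, chain, seqnum, icode, xyz[1], xyz[2], xyz[3])
  }
  for (m in seq_along(models)) {
    cx <- models[[m]]
    r <- cx$receptor; p <- cx$peptide
    out <- c(out, sprintf("MODEL     %4d", m))
    serial <- 0L
    res3r <- aa1_to_3(strsplit(r$sequence, "")[[1]])
    for (i in seq_len(nrow(r$ca))) {
      serial <- serial + 1L
      out <- c(out, fmt(serial, res3r[i], r$chain_id[i], r$res_seq[i],
                        r$icode[i], r$ca[i, ]))
      last_of_chain <- i == nrow(r$ca) || r$chain_id[i + 1L] != r$chain_id[i]
      if (last_of_chain) out <- c(out, "TER")
    }
    res3p <- aa1_to_3(strsplit(p$sequence, "")[[1]])
    for (i in seq_len(nrow(p$ca))) {
      serial <- serial + 1L
      out <- c(out, fmt(serial, res3p[i], pep_chain, i, " ", p$ca[i, ]))
    }
    out <- c(out, "TER", "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(out)
}

#' Read all MODEL blocks of a Calpha PDB file
#'
#' Companion reader for files produced by [write_models_pdb()] (or any
#' Calpha-trace multi-model PDB). Returns one entry per model with the CA
#' coordinate matrix and per-residue chain/sequence metadata.
#'
#' @param path PDB file path.
#' @return list of lists with fields `ca` (n x 3), `chain`, `res_seq`,
#'   `res_name`.
#' @export
read_ca_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0) {
    blocks <- list(lines)
  } else {
    ends <- which(rec == "ENDMDL")
    blocks <- mapply(function(a, b) lines[a:b], model_starts, ends,
                     SIMPLIFY = FALSE)
  }
  lapply(blocks, function(bl) {
    sel <- substr(bl, 1, 6) %in% c("ATOM  ", "HETATM") &
      trimws(substr(bl, 13, 16)) == "CA"
    al <- bl[sel]
    list(
      ca = cbind(as.numeric(substr(al, 31, 38)),
                 as.numeric(substr(al, 39, 46)),
                 as.numeric(substr(al, 47, 54))),
      chain = substr(al, 22, 22),
      res_seq = as.integer(substr(al, 23, 26)),
      res_name = toupper(trimws(substr(al, 18, 20)))
    )
  })
}
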