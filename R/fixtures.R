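# Programmatic synthetic fixtures: ideal helices, a two-helix groove bundle
# with a designed binding site, and compact random globules. These stand in
# for experimental benchmark structures so the whole pipeline is testable
# offline; none of them emulates any specific PDB entry.

# assemble a receptor_structure from a full atom table
#' @noRd
.structure_from_atoms <- function(atoms) {
  first <- !duplicated(atoms$global_index)
  residues <- data.frame(chain = atoms$chain[first],
                         res_seq = atoms$res_seq[first],
                         icode = atoms$icode[first],
                         res_name = atoms$res_name[first],
                         global_index = atoms$global_index[first],
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues,
                 ca = .ca_matrix(atoms, residues)),
            class = "receptor_structure")
}

# backbone atom coordinates of an ideal alpha-helix along +z:
# Calpha rise 1.5 A/residue, 100 degrees/residue, radius 2.3 A; N/C/O placed
# at helix-like offsets so backbone-completeness validation passes.
#' @noRd
.helix_backbone <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  pos <- function(r, dth, dz) {
    cbind(r * cos(th + dth), r * sin(th + dth), 1.5 * i + dz)
  }
  list(N = pos(1.60, -40 * pi / 180, -0.60),
       CA = pos(2.30, 0, 0),
       C = pos(1.70, 45 * pi / 180, 0.60),
       O = pos(2.90, 45 * pi / 180, 0.60))
}

#' @noRd
.backbone_atom_table <- function(coords, sequence, chain, res_seq) {
  n <- length(res_seq)
  res3 <- aa1_to_3(strsplit(sequence, "")[[1]])
  rows <- lapply(seq_len(n), function(k) {
    data.frame(atom_name = c("N", "CA", "C", "O"),
               altloc = " ",
               res_name = res3[k],
               chain = chain[k],
               res_seq = res_seq[k],
               icode = " ",
               x = c(coords$N[k, 1], coords$CA[k, 1], coords$C[k, 1], coords$O[k, 1]),
               y = c(coords$N[k, 2], coords$CA[k, 2], coords$C[k, 2], coords$O[k, 2]),
               z = c(coords$N[k, 3], coords$CA[k, 3], coords$C[k, 3], coords$O[k, 3]),
               occupancy = 1.0,
               global_index = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ideal alpha-helix receptor fixture
#'
#' Calpha helix with 1.5 A rise per residue, 100 degrees rotation per
#' residue and 2.3 A radius (consecutive Calpha distance about 3.8 A);
#' N/C/O atoms are placed at ideal helix offsets so the structure passes
#' backbone validation.
#'
#' @param n number of residues.
#' @param sequence one-letter sequence of length `n` (default poly-alanine).
#' @param chain chain identifier (default "A").
#' @return a `receptor_structure`.
#' @export
ideal_helix <- function(n, sequence = strrep("A", n), chain = "A") {
  stopifnot(n >= 2, nchar(sequence) == n)
  bb <- .helix_backbone(n)
  atoms <- .backbone_atom_table(bb, sequence, rep(chain, n), seq_len(n))
  .structure_from_atoms(atoms)
}

#' @noRd
.transform_backbone <- function(bb, rot = diag(3), shift = c(0, 0, 0)) {
  lapply(bb, function(m) sweep(m %*% t(rot), 2, shift, `+`))
}

#' Two-helix groove receptor with a designed binding site
#'
#' Two antiparallel ideal helices with parallel axes `separation` A apart
#' form a groove along z. Residues facing the groove in the central section
#' are leucines (the designed site); the rest are serines. A hand-built
#' reference peptide pose (a 150-degree zigzag lying on the groove axis) and
#' an energy model whose contact matrix makes peptide-leucine contacts
#' strongly favorable (entries scaled by `site_boost`) are returned with the
#' structure, enabling funnel-recovery tests.
#'
#' @param helix_length residues per helix (default 18).
#' @param peptide_sequence peptide sequence (default "FFFFF").
#' @param separation helix-axis separation in A (default 13).
#' @param site_boost contact-energy scale factor for peptide/site pairs.
#' @param site_halfwidth half-length (A, along z) of the designed site.
#' @return list with `receptor` (`receptor_structure`), `cg` (receptor
#'   `cg_chain`), `reference` (`cg_complex` bound pose), `peptide`
#'   (`peptide_spec`), `model` (`energy_model`), `site` (receptor residue
#'   indices of the designed site).
#' @export
groove_receptor <- function(helix_length = 18L, peptide_sequence = "FFFFF",
                            separation = 13, site_boost = 4,
                            site_halfwidth = 12) {
  n <- helix_length
  zmid <- 1.5 * (n - 1) / 2
  bbA <- .transform_backbone(.helix_backbone(n),
                             shift = c(-separation / 2, 0, -zmid))
  # antiparallel: rotate 180 degrees about the x axis
  flip <- diag(c(1, -1, -1))
  bbB <- .transform_backbone(.helix_backbone(n), rot = flip,
                             shift = c(separation / 2, 0, zmid))
  ca_all <- rbind(bbA$CA, bbB$CA)
  # residues facing the groove (|x| pulled toward 0) in the central section
  inward <- abs(ca_all[, 1]) < separation / 2 - 1.2
  central <- abs(ca_all[, 3]) < site_halfwidth
  site <- which(inward & central)
  seq1 <- rep("S", 2 * n)
  seq1[site] <- "L"
  atoms <- rbind(
    .backbone_atom_table(bbA, paste(seq1[1:n], collapse = ""),
                         rep("A", n), seq_len(n)),
    .backbone_atom_table(bbB, paste(seq1[(n + 1):(2 * n)], collapse = ""),
                         rep("B", n), seq_len(n)))
  atoms$global_index <- rep(seq_len(2 * n), each = 4)
  receptor <- .structure_from_atoms(atoms)
  cg <- build_cg(receptor)

  spec <- validate_peptide(peptide_sequence)
  np <- nchar(spec$sequence)
  # 150-degree zigzag along the groove axis, centered at z = 0
  step_z <- CA_BOND * cos(15 * pi / 180)
  step_y <- CA_BOND * sin(15 * pi / 180)
  z <- (seq_len(np) - 1) * step_z
  y <- ifelse(seq_len(np) %% 2 == 0, step_y, 0)
  ca_p <- cbind(0, y - mean(y), z - mean(z))
  pep <- cg_chain(ca_p, .sc_from_ca(ca_p, spec$sequence), spec$sequence,
                  ss = spec$ss, chain_id = rep("P", np))
  reference <- cg_complex(cg, pep)

  cmat <- default_contact_matrix()
  ptypes <- unique(strsplit(spec$sequence, "")[[1]])
  for (p in ptypes) {
    cmat[p, "L"] <- cmat["L", p] <- site_boost * cmat[p, "L"]
  }
  model <- energy_model(contact_matrix = cmat)
  list(receptor = receptor, cg = cg, reference = reference, peptide = spec,
       model = model, site = site)
}

#' Three-helix cradle receptor with a designed, localizing binding site
#'
#' Three parallel ideal helices (two walls and a floor, open at the top so
#' the peptide can enter without threading) form a channel just wide enough
#' for an extended peptide. The channel lining is leucine in the lower-z
#' half and isoleucine in the upper-z half; the outer surface is lysine.
#' With the matching peptide (phenylalanines then valines) and a contact
#' matrix in which F-L and V-I contacts are boosted, the model's global
#' minimum is an extended peptide at the channel center in a unique
#' orientation: collapse is blocked sterically, outside binding is
#' penalized, and reversal or sliding loses boosted contacts. The returned
#' reference pose is the hand-constructed zigzag at the channel center.
#'
#' @param helix_length residues per helix (default 14).
#' @param axis_distance helix-axis distance from the channel axis (A).
#' @param peptide_sequence peptide (default "FFFSVVV").
#' @param site_boost contact-energy scale factor for the F-L and V-I pairs.
#' @param contact_shell contact shell used in the returned energy model
#'   (default c(4.0, 6.5), slightly tighter than the package default so the
#'   designed site localizes the pose).
#' @return list with `receptor`, `cg`, `reference` (`cg_complex`),
#'   `peptide`, `model`, `site` (designed-site residue indices).
#' @export
cradle_receptor <- function(helix_length = 14L, axis_distance = 6.5,
                            peptide_sequence = "FFFSVVV", site_boost = 8,
                            contact_shell = c(4.0, 6.5)) {
  n <- helix_length
  zmid <- 1.5 * (n - 1) / 2
  ang <- c(0, 180, 270) * pi / 180   # walls at +-x, floor at -y
  chains <- c("A", "B", "C")
  bbs <- vector("list", 3)
  ca_all <- NULL
  for (h in 1:3) {
    sh <- c(axis_distance * cos(ang[h]), axis_distance * sin(ang[h]), -zmid)
    bbs[[h]] <- .transform_backbone(.helix_backbone(n), shift = sh)
    ca_all <- rbind(ca_all, bbs[[h]]$CA)
  }
  r_xy <- sqrt(ca_all[, 1]^2 + ca_all[, 2]^2)
  inner <- r_xy < axis_distance - 0.8
  outer <- r_xy > axis_distance + 0.8
  seq1 <- rep("S", 3 * n)
  seq1[outer] <- "K"
  seq1[inner & ca_all[, 3] < -1.5] <- "L"
  seq1[inner & ca_all[, 3] > 1.5] <- "I"
  atoms <- do.call(rbind, lapply(1:3, function(h) {
    .backbone_atom_table(bbs[[h]],
                         paste(seq1[((h - 1) * n + 1):(h * n)], collapse = ""),
                         rep(chains[h], n), seq_len(n))
  }))
  atoms$global_index <- rep(seq_len(3 * n), each = 4)
  receptor <- .structure_from_atoms(atoms)
  cg <- build_cg(receptor)

  spec <- validate_peptide(peptide_sequence)
  np <- nchar(spec$sequence)
  step_l <- CA_BOND * cos(15 * pi / 180)
  step_o <- CA_BOND * sin(15 * pi / 180)
  t <- (seq_len(np) - 1) * step_l
  o <- ifelse(seq_len(np) %% 2 == 0, step_o, 0)
  ca_p <- cbind(o - mean(o), 0, t - mean(t))
  pep <- cg_chain(ca_p, .sc_from_ca(ca_p, spec$sequence), spec$sequence,
                  ss = spec$ss, chain_id = rep("P", np))

  cmat <- default_contact_matrix()
  cmat["F", "L"] <- cmat["L", "F"] <- site_boost * cmat["F", "L"]
  cmat["V", "I"] <- cmat["I", "V"] <- site_boost * cmat["V", "I"]
  model <- energy_model(contact_matrix = cmat,
                        contact_lo = contact_shell[1],
                        contact_hi = contact_shell[2])
  list(receptor = receptor, cg = cg, reference = cg_complex(cg, pep),
       peptide = spec, model = model, site = which(seq1 %in% c("L", "I")))
}

#' Compact random-globule receptor fixture
#'
#' Self-avoiding Calpha walk with 3.8 A bonds and pseudo-bond angles in
#' [75, 150] degrees, confined to a ball so the fold is compact enough to
#' carry a dense restraint network. Backbone N/C/O atoms are placed at
#' plausible offsets so validation passes. Uses the R RNG.
#'
#' @param n number of residues (default 60).
#' @param radius confinement ball radius in A (default 11).
#' @param sequence optional one-letter sequence (default: random).
#' @return a `receptor_structure`.
#' @export
globule_receptor <- function(n = 60L, radius = 11, sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(sample(AA1, n, replace = TRUE), collapse = "")
  }
  stopifnot(nchar(sequence) == n)
  for (restart in seq_len(200)) {
    ca <- matrix(0, n, 3)
    ca[2, ] <- CA_BOND * random_rotation_matrix()[, 1]
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in seq_len(200)) {
        theta <- stats::runif(1, 75, 150) * pi / 180
        phi <- stats::runif(1, -pi, pi)
        cand <- .extend_chain(ca[max(1, i - 3):(i - 1), , drop = FALSE],
                              CA_BOND, theta, phi)
        if (sqrt(sum(cand^2)) > radius) next
        d2 <- rowSums((ca[1:(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (any(d2 < MIN_CA_SEP^2)) next
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      coords <- .globule_backbone(ca)
      atoms <- .backbone_atom_table(coords, sequence, rep("A", n), seq_len(n))
      return(.structure_from_atoms(atoms))
    }
  }
  stop("failed to generate a compact globule", call. = FALSE)
}

# plausible N/C/O placement around a bare Calpha trace
#' @noRd
.globule_backbone <- function(ca) {
  n <- nrow(ca)
  N <- C <- O <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u_prev <- if (i > 1) .unit(ca[i - 1, ] - ca[i, ]) else NULL
    u_next <- if (i < n) .unit(ca[i + 1, ] - ca[i, ]) else NULL
    if (is.null(u_prev)) u_prev <- .perp(u_next)
    if (is.null(u_next)) u_next <- .perp(u_prev)
    N[i, ] <- ca[i, ] + 1.45 * u_prev
    C[i, ] <- ca[i, ] + 1.52 * u_next
    w <- pracma_cross(u_prev, u_next)
    w <- if (sqrt(sum(w^2)) < 1e-8) .perp(u_next) else .unit(w)
    O[i, ] <- C[i, ] + 1.23 * w
  }
  list(N = N, CA = ca, C = C, O = O)
}

#' Write a receptor structure (all kept atoms) as a PDB file
#'
#' Fixed-column wwPDB v3.3 layout; used to emit fixtures and to round-trip
#' structures through [read_pdb()].
#'
#' @param s a `receptor_structure`.
#' @param path output path.
#' @export
write_receptor_pdb <- function(s, path) {
  stopifnot(inherits(s, "receptor_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$atom_name) < 4,
                  formatC(paste0(" ", a$atom_name), width = -4),
                  a$atom_name)
  elem <- substr(trimws(a$atom_name), 1, 1)
  lines <- sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
                   seq_len(nrow(a)), name4, a$altloc, a$res_name, a$chain,
                   a$res_seq, a$icode, a$x, a$y, a$z,
                   ifelse(is.na(a$occupancy), 1.0, a$occupancy), elem)
  # TER between chains
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Generate the fixture catalog on disk
#'
#' Writes PDB files for all toy receptor kinds plus a plain-text manifest of
#' assertable properties. Byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed (default 1).
#' @return invisibly, the manifest data.frame.
#' @export
make_test_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  helix <- ideal_helix(20)
  groove <- groove_receptor()
  cradle <- cradle_receptor()
  globule <- globule_receptor(60)
  write_receptor_pdb(helix, file.path(dir, "helix.pdb"))
  write_receptor_pdb(groove$receptor, file.path(dir, "groove.pdb"))
  write_receptor_pdb(cradle$receptor, file.path(dir, "cradle.pdb"))
  write_receptor_pdb(globule, file.path(dir, "globule.pdb"))
  manifest <- data.frame(
    case = c("single_helix", "two_helix_groove", "three_helix_cradle",
             "random_coil_globule"),
    file = c("helix.pdb", "groove.pdb", "cradle.pdb", "globule.pdb"),
    n_residues = c(20L, nrow(groove$receptor$residues),
                   nrow(cradle$receptor$residues), 60L),
    n_chains = c(1L, 2L, 3L, 1L),
    peptide = c("", groove$peptide$sequence, cradle$peptide$sequence, ""),
    seed = seed)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("receptor=%s", "groove.pdb"),
               sprintf("peptide=%s", groove$peptide$sequence),
               sprintf("seed=%d", seed)),
             file.path(dir, "groove_job.cfg"))
  invisible(manifest)
}
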