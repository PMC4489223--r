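# Pluggable coarse-grained energy model, receptor restraint network and
# bound-state test.
#
# The interaction model is a deliberately simple, documented stand-in for a
# full statistical force field: a residue-type contact potential acting on
# side-chain centroids in a distance shell, soft-core excluded volume,
# pseudo-bond-angle terms with a secondary-structure bias, flat-bottom
# receptor restraints and a penalty on contacts with excluded residues.
# Energies and temperatures are in reduced units throughout.

#' Default residue-pair contact energy matrix
#'
#' Hydrophobicity-based pairwise favorability: the negated, scaled outer
#' product of Kyte-Doolittle hydropathies, so that hydrophobic-hydrophobic
#' (and, more weakly, polar-polar) contacts are favorable and mixed contacts
#' are penalized. Any symmetric 20 x 20 matrix with the standard one-letter
#' codes as dimnames may be used in its place.
#'
#' @param scale multiplier applied to the outer product (default 0.1).
#' @return symmetric 20 x 20 numeric matrix, reduced units.
#' @export
default_contact_matrix <- function(scale = 0.1) {
  m <- -scale * outer(KYTE_DOOLITTLE, KYTE_DOOLITTLE)
  dimnames(m) <- list(AA1, AA1)
  m
}

#' Construct an energy model
#'
#' @param contact_matrix symmetric 20 x 20 contact energy matrix with
#'   one-letter dimnames; default [default_contact_matrix()].
#' @param contact_lo,contact_hi side-chain-centroid distance shell (A) in
#'   which the contact energy applies (default 4.5-7.0).
#' @param clash_distance nonbonded Calpha-Calpha soft-core distance (A).
#' @param k_clash excluded-volume stiffness (reduced units per A^2).
#' @param peptide_min_sep minimum separation (A) between nonconsecutive
#'   peptide Calpha atoms before the excluded-volume penalty engages
#'   (default 5.0; larger than the inter-chain clash distance, modelling the
#'   local stiffness of short peptides and preventing unphysical collapse).
#' @param ss_bias secondary-structure angle-bias strength (per rad^2).
#' @param exclusion_penalty positive energy added per contact between the
#'   peptide and a receptor residue marked "unlikely to bind".
#' @param k_restraint base restraint slope k_r (reduced units per A,
#'   default 5; stiff enough that the receptor stays within ~2 A of its
#'   input conformation at the hottest replica temperature).
#' @param bound_cutoff minimum peptide-receptor Calpha distance (A) at or
#'   below which a pose counts as bound.
#' @param angle_lo,angle_hi allowed pseudo-bond-angle band (degrees).
#' @param k_angle band-violation stiffness (per rad^2).
#' @param helix_angle,strand_angle target pseudo-bond angles (degrees) for
#'   residues assigned H and E secondary structure.
#' @return an `energy_model` object.
#' @export
energy_model <- function(contact_matrix = default_contact_matrix(),
                         contact_lo = 4.5, contact_hi = 7.0,
                         clash_distance = 4.0, k_clash = 10,
                         peptide_min_sep = 5.0,
                         ss_bias = 0.5, exclusion_penalty = 2.0,
                         k_restraint = 5.0, bound_cutoff = 8.0,
                         angle_lo = 75, angle_hi = 150, k_angle = 5,
                         helix_angle = 91, strand_angle = 124) {
  contact_matrix <- as.matrix(contact_matrix)
  stopifnot(identical(dim(contact_matrix), c(20L, 20L)),
            max(abs(contact_matrix - t(contact_matrix))) < 1e-9,
            contact_lo > 0, contact_hi > contact_lo, clash_distance > 0)
  if (is.null(dimnames(contact_matrix))) {
    dimnames(contact_matrix) <- list(AA1, AA1)
  }
  contact_matrix <- contact_matrix[AA1, AA1]
  structure(list(contact_matrix = contact_matrix,
                 contact_lo = contact_lo, contact_hi = contact_hi,
                 clash_distance = clash_distance, k_clash = k_clash,
                 peptide_min_sep = peptide_min_sep,
                 ss_bias = ss_bias, exclusion_penalty = exclusion_penalty,
                 k_restraint = k_restraint, bound_cutoff = bound_cutoff,
                 angle_lo = angle_lo, angle_hi = angle_hi, k_angle = k_angle,
                 helix_angle = helix_angle, strand_angle = strand_angle),
            class = "energy_model")
}

# parameter list handed to the compiled core (angles in radians)
#' @noRd
.energy_par <- function(m) {
  list(contact_lo = m$contact_lo, contact_hi = m$contact_hi,
       clash_distance = m$clash_distance, k_clash = m$k_clash,
       peptide_min_sep = m$peptide_min_sep,
       ss_bias = m$ss_bias, exclusion_penalty = m$exclusion_penalty,
       angle_lo = m$angle_lo * pi / 180, angle_hi = m$angle_hi * pi / 180,
       k_angle = m$k_angle,
       helix_angle = m$helix_angle * pi / 180,
       strand_angle = m$strand_angle * pi / 180)
}

#' @noRd
.ss_codes <- function(ss) {
  match(strsplit(ss, "")[[1]], c("C", "H", "E")) - 1L
}

#' Normalize flexibility marks to a per-residue factor vector
#'
#' @param n number of receptor residues.
#' @param marks `NULL` (all rigid), a length-`n` character vector over
#'   `{"rigid","moderate","full"}`, or a list with elements `moderate` and/or
#'   `full` holding residue indices.
#' @return numeric vector of slope factors (1, 0.5 or 0).
#' @export
flexibility_factors <- function(n, marks = NULL) {
  f <- rep(1, n)
  if (is.null(marks)) return(f)
  if (is.list(marks)) {
    if (!all(names(marks) %in% c("moderate", "full"))) {
      stop("marks list may only contain 'moderate' and 'full'", call. = FALSE)
    }
    idx <- unlist(marks, use.names = FALSE)
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n)) {
      stop("flexibility mark indices outside 1..n", call. = FALSE)
    }
    f[marks$moderate] <- 0.5
    f[marks$full] <- 0
  } else {
    stopifnot(length(marks) == n,
              all(marks %in% c("rigid", "moderate", "full")))
    f[marks == "moderate"] <- 0.5
    f[marks == "full"] <- 0
  }
  f
}

#' Generate the receptor restraint network from the input structure
#'
#' All unordered residue pairs whose input Calpha-Calpha distance lies in
#' `[d_min, d_max]` and whose sequence separation within a chain is at least
#' `min_gap` become flat-bottom restraints at the observed distance. Pairs in
#' different chains are always eligible (infinite sequence gap). The slope is
#' `k_restraint`, halved if either endpoint is marked moderately flexible and
#' zero if either is fully flexible (the more flexible endpoint wins).
#'
#' @param receptor a `cg_chain`.
#' @param marks flexibility marks, see [flexibility_factors()].
#' @param d_min,d_max restrained distance band (A, default 5-15).
#' @param min_gap minimum intra-chain sequence separation (default 5).
#' @param tolerance flat-bottom half-width (A, default 1).
#' @param k_restraint base slope; default from `model`.
#' @param model optional `energy_model` supplying `k_restraint`.
#' @return a `restraint_set`: data.frame with columns `i`, `j`, `d_ref`,
#'   `tolerance`, `slope` (i < j, 1-based global residue indices).
#' @export
generate_restraints <- function(receptor, marks = NULL, d_min = 5,
                                d_max = 15, min_gap = 5, tolerance = 1.0,
                                k_restraint = NULL, model = NULL) {
  stopifnot(inherits(receptor, "cg_chain"))
  if (is.null(k_restraint)) {
    k_restraint <- if (is.null(model)) 5.0 else model$k_restraint
  }
  n <- nrow(receptor$ca)
  f <- flexibility_factors(n, marks)
  dm <- as.matrix(stats::dist(receptor$ca))
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  d <- dm[pair]
  same_chain <- receptor$chain_index[i] == receptor$chain_index[j]
  keep <- d >= d_min & d <= d_max & (!same_chain | abs(i - j) >= min_gap)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  ord <- order(i, j)
  rs <- data.frame(i = i[ord], j = j[ord], d_ref = d[ord],
                   tolerance = rep(tolerance, length(ord)),
                   slope = k_restraint * pmin(f[i[ord]], f[j[ord]]))
  class(rs) <- c("restraint_set", "data.frame")
  attr(rs, "flexibility") <- f
  rs
}

#' Flat-bottom restraint energy
#'
#' `E = slope * max(0, |d - d_ref| - tolerance)`: violations smaller than the
#' tolerance (default 1 A) are not penalized; beyond it the penalty grows
#' linearly and symmetrically.
#'
#' @param d current Calpha-Calpha distance(s), A.
#' @param d_ref reference distance(s), A.
#' @param tolerance flat-bottom half-width, A.
#' @param slope penalty slope per A (0 disables the restraint).
#' @return energy in reduced units (vectorized).
#' @export
restraint_energy <- function(d, d_ref, tolerance = 1.0, slope = 1.0) {
  slope * pmax(0, abs(d - d_ref) - tolerance)
}

#' Export a restraint set as TSV
#' @param rs a `restraint_set`.
#' @param path output path.
#' @export
write_restraints_tsv <- function(rs, path) {
  utils::write.table(as.data.frame(rs), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @noRd
.empty_restraints <- function() {
  rs <- data.frame(i = integer(), j = integer(), d_ref = numeric(),
                   tolerance = numeric(), slope = numeric())
  class(rs) <- c("restraint_set", "data.frame")
  rs
}

#' Total, binding and restraint energy of a pose
#'
#' `E_total = E_intra_peptide + E_inter + E_restraint`; `E_binding` is the
#' inter-chain part only (contact potential + clashes + exclusion penalties)
#' and is the quantity used to rank bound snapshots during filtering.
#'
#' @param complex a `cg_complex`.
#' @param model an `energy_model`.
#' @param restraints a `restraint_set` (may be empty).
#' @param excluded integer vector of receptor residues marked unlikely to
#'   bind (1-based global indices), or NULL.
#' @return named numeric vector `c(total, binding, restraint, intra)`.
#' @export
total_energy <- function(complex, model = energy_model(),
                         restraints = .empty_restraints(), excluded = NULL) {
  stopifnot(inherits(complex, "cg_complex"), inherits(model, "energy_model"))
  r <- complex$receptor; p <- complex$peptide
  excl <- rep(FALSE, nrow(r$ca))
  if (!is.null(excluded)) {
    stopifnot(all(excluded >= 1), all(excluded <= nrow(r$ca)))
    excl[excluded] <- TRUE
  }
  .cpp_energy(r$ca, r$sc, p$ca, p$sc,
              aa_index(strsplit(r$sequence, "")[[1]]),
              aa_index(strsplit(p$sequence, "")[[1]]),
              model$contact_matrix,
              as.integer(restraints$i), as.integer(restraints$j),
              restraints$d_ref, restraints$tolerance, restraints$slope,
              excl, .ss_codes(p$ss), .energy_par(model))
}

#' Is a pose bound?
#'
#' A snapshot counts as bound iff the minimum distance over all
#' (peptide Calpha, receptor Calpha) pairs is at or below the cutoff
#' (closed boundary).
#'
#' @param complex a `cg_complex`.
#' @param cutoff distance cutoff in A (default 8).
#' @return logical.
#' @export
is_bound <- function(complex, cutoff = 8.0) {
  stopifnot(inherits(complex, "cg_complex"))
  min_interchain_distance(complex) <= cutoff
}

#' Minimum peptide-receptor Calpha distance of a pose
#' @param complex a `cg_complex`.
#' @return distance in A.
#' @export
min_interchain_distance <- function(complex) {
  r <- complex$receptor$ca; p <- complex$peptide$ca
  cross <- outer(rowSums(p^2), rowSums(r^2), `+`) - 2 * p %*% t(r)
  sqrt(max(0, min(cross)))
}
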