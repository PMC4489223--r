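# Coarse-grained representation: two interaction centers per residue
# (Calpha + pseudo side-chain centroid, coincident with Calpha for glycine).
# All coordinates are in Angstrom, off-lattice.

CA_BOND <- 3.8          # trans Calpha-Calpha virtual bond length
CA_BOND_TOL <- 0.4      # tolerance on the virtual bond
MIN_CA_SEP <- 4.0       # nonconsecutive Calpha excluded-volume distance

#' @noRd
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector", call. = FALSE)
  v / n
}

# any unit vector orthogonal to v (deterministic)
#' @noRd
.perp <- function(v) {
  e <- diag(3)[, which.min(abs(v))]
  .unit(pracma_cross(v, e))
}

#' @noRd
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix for axis-angle (Rodrigues)
#' @noRd
rotation_matrix <- function(axis, angle) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# uniform random rotation via normalized quaternion of 4 normals
#' @noRd
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Construct a coarse-grained chain
#'
#' @param ca n x 3 matrix of Calpha positions.
#' @param sc n x 3 matrix of pseudo side-chain centroids.
#' @param sequence one-letter amino-acid string of length n.
#' @param ss secondary-structure string over `{H,E,C}` (default all-coil).
#' @param chain_id per-residue author chain ID (default `"A"`).
#' @param res_seq per-residue author numbering (default `1:n`).
#' @param icode per-residue insertion codes (default blank).
#' @param check verify the Calpha virtual-bond invariant (3.8 +/- 0.4 A
#'   between consecutive residues of the same chain).
#' @return a `cg_chain` object.
#' @export
cg_chain <- function(ca, sc, sequence, ss = NULL, chain_id = NULL,
                     res_seq = NULL, icode = NULL, check = TRUE) {
  ca <- as.matrix(ca); sc <- as.matrix(sc)
  n <- nrow(ca)
  stopifnot(ncol(ca) == 3, identical(dim(ca), dim(sc)),
            nchar(sequence) == n)
  if (is.null(ss)) ss <- strrep("C", n)
  stopifnot(nchar(ss) == n)
  if (is.null(chain_id)) chain_id <- rep("A", n)
  if (is.null(res_seq)) res_seq <- seq_len(n)
  if (is.null(icode)) icode <- rep(" ", n)
  # 1-based dense chain index for the gap rule (chain changes = break)
  chain_index <- cumsum(c(1L, as.integer(chain_id[-1] != chain_id[-n])))
  obj <- structure(list(ca = ca, sc = sc, sequence = sequence, ss = ss,
                        chain_id = chain_id, res_seq = as.integer(res_seq),
                        icode = icode, chain_index = chain_index),
                   class = "cg_chain")
  if (check && n > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    same <- chain_index[-1] == chain_index[-n]
    bad <- same & abs(d - CA_BOND) > CA_BOND_TOL
    if (any(bad)) {
      stop(sprintf("Calpha virtual bond out of tolerance at residue %d (%.2f A)",
                   which(bad)[1], d[which(bad)[1]]), call. = FALSE)
    }
  }
  obj
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("<cg_chain> %d residues, %d chain(s)\n",
              nrow(x$ca), max(x$chain_index)))
  invisible(x)
}

#' Pair a receptor and a peptide chain into one coarse-grained complex
#' @param receptor,peptide `cg_chain` objects.
#' @return a `cg_complex`.
#' @export
cg_complex <- function(receptor, peptide) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(peptide, "cg_chain"))
  structure(list(receptor = receptor, peptide = peptide),
            class = "cg_complex")
}

#' Project a validated all-atom receptor to the coarse-grained representation
#'
#' Calpha positions are copied. The pseudo side-chain centroid is the mean of
#' the side-chain heavy atoms when any are present; for glycine it coincides
#' with the Calpha; otherwise it is placed opposite the bisector of the
#' Calpha->N and Calpha->C directions at a per-residue-type canonical
#' distance. Structures lacking N/C atoms (Calpha traces) fall back to the
#' bisector of the neighboring Calpha directions.
#'
#' @param s a `receptor_structure` with standard residue names (run
#'   [normalize_nonstandard()] first).
#' @return a `cg_chain`.
#' @export
build_cg <- function(s) {
  stopifnot(inherits(s, "receptor_structure"))
  res1 <- aa3_to_1(s$residues$res_name)
  if (anyNA(res1)) {
    stop("receptor contains non-standard residue names; ",
         "run normalize_nonstandard() first", call. = FALSE)
  }
  n <- nrow(s$residues)
  ca <- s$ca
  if (anyNA(ca)) stop("missing Calpha coordinates", call. = FALSE)
  sc <- matrix(NA_real_, n, 3)
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (k in seq_len(n)) {
    gi <- s$residues$global_index[k]
    at <- s$atoms[s$atoms$global_index == gi, , drop = FALSE]
    if (res1[k] == "G") {
      sc[k, ] <- ca[k, ]
      next
    }
    side <- at[!(at$atom_name %in% backbone) &
                 !grepl("^[0-9]*[HD]", at$atom_name), , drop = FALSE]
    if (nrow(side) > 0) {
      sc[k, ] <- colMeans(as.matrix(side[, c("x", "y", "z")]))
    } else {
      dir <- .sc_direction(ca, k,
                           nvec = .atom_xyz(at, "N"), cvec = .atom_xyz(at, "C"))
      sc[k, ] <- ca[k, ] + SC_DISTANCE[[res1[k]]] * dir
    }
  }
  cg_chain(ca, sc, paste(res1, collapse = ""),
           chain_id = s$residues$chain, res_seq = s$residues$res_seq,
           icode = s$residues$icode, check = FALSE)
}

#' @noRd
.atom_xyz <- function(at, name) {
  i <- which(at$atom_name == name)
  if (length(i) == 0) NULL else as.numeric(at[i[1], c("x", "y", "z")])
}

# unit direction for a canonical side-chain placement at residue k:
# opposite the bisector of Calpha->N and Calpha->C when backbone atoms are
# available; for bare Calpha chains, opposite the bisector of the two
# neighboring Calpha directions. Terminal residues use the two nearest
# chain bonds so the rule is covariant under rigid transforms (the sampled
# peptide recomputes side chains from the trace with this same rule).
#' @noRd
.sc_direction <- function(ca, k, nvec = NULL, cvec = NULL) {
  n <- nrow(ca)
  if (is.null(nvec) || is.null(cvec)) {
    if (n == 1) return(c(0, 0, 1))
    if (k > 1 && k < n) {
      v1 <- .unit(ca[k - 1, ] - ca[k, ])
      v2 <- .unit(ca[k + 1, ] - ca[k, ])
      b <- v1 + v2
      if (sqrt(sum(b^2)) < 1e-8) return(.perp(v1))
      return(-.unit(b))
    }
    if (k == 1) {
      u <- .unit(ca[2, ] - ca[1, ])
      if (n == 2) return(-u)
      w <- .unit(ca[3, ] - ca[2, ])
    } else {
      u <- .unit(ca[n - 1, ] - ca[n, ])
      if (n == 2) return(-u)
      w <- .unit(ca[n - 2, ] - ca[n - 1, ])
    }
    b <- u + w
    if (sqrt(sum(b^2)) < 1e-8) return(.perp(u))
    return(-.unit(b))
  }
  b <- .unit(nvec - ca[k, ]) + .unit(cvec - ca[k, ])
  if (sqrt(sum(b^2)) < 1e-8) return(.perp(.unit(nvec - ca[k, ])))
  -.unit(b)
}

# place pseudo side chains on a bare Calpha chain at canonical distances
#' @noRd
.sc_from_ca <- function(ca, sequence) {
  res1 <- strsplit(sequence, "")[[1]]
  sc <- matrix(NA_real_, nrow(ca), 3)
  for (k in seq_len(nrow(ca))) {
    d <- SC_DISTANCE[[res1[k]]]
    sc[k, ] <- if (d == 0) ca[k, ] else ca[k, ] + d * .sc_direction(ca, k)
  }
  sc
}

#' Longest dimension of a receptor
#'
#' Maximum pairwise Calpha-Calpha distance; used to size the peptide
#' initialization sphere.
#'
#' @param x a `cg_chain` or an n x 3 coordinate matrix (n >= 2).
#' @return length in Angstrom.
#' @export
longest_dimension <- function(x) {
  ca <- if (inherits(x, "cg_chain")) x$ca else as.matrix(x)
  if (nrow(ca) < 2) stop("need at least 2 atoms", call. = FALSE)
  max(stats::dist(ca))
}

#' Generate a random self-avoiding peptide conformation
#'
#' Builds a Calpha walk with fixed 3.8 A virtual bonds, pseudo-bond angles
#' drawn uniformly in [75, 150] degrees and uniform dihedrals, rejecting
#' chains in which any nonconsecutive Calpha pair comes closer than 4.0 A.
#' Pseudo side chains are attached at canonical distances. Uses the R RNG:
#' seed with [set.seed()] for reproducibility.
#'
#' @param spec a `peptide_spec` from [validate_peptide()].
#' @param max_attempts restart cap for the self-avoidance rejection loop.
#' @return a `cg_chain` for the peptide.
#' @export
random_peptide_conformation <- function(spec, max_attempts = 1000L) {
  stopifnot(inherits(spec, "peptide_spec"))
  n <- nchar(spec$sequence)
  for (attempt in seq_len(max_attempts)) {
    ca <- matrix(0, n, 3)
    if (n >= 2) {
      ca[2, ] <- CA_BOND * random_rotation_matrix()[, 1]
    }
    ok <- TRUE
    if (n >= 3) {
      for (i in 3:n) {
        theta <- stats::runif(1, 75, 150) * pi / 180
        phi <- stats::runif(1, -pi, pi)
        ca[i, ] <- .extend_chain(ca[max(1, i - 3):(i - 1), , drop = FALSE],
                                 CA_BOND, theta, phi)
        # incremental self-avoidance check against all nonconsecutive
        if (i > 2) {
          d2 <- rowSums((ca[1:(i - 2), , drop = FALSE] -
                           matrix(ca[i, ], i - 2, 3, byrow = TRUE))^2)
          if (any(d2 < MIN_CA_SEP^2)) { ok <- FALSE; break }
        }
      }
    }
    if (ok) {
      return(cg_chain(ca, .sc_from_ca(ca, spec$sequence), spec$sequence,
                      ss = spec$ss, chain_id = rep("P", n)))
    }
  }
  stop(sprintf("failed to generate a self-avoiding conformation in %d attempts",
               max_attempts), call. = FALSE)
}

# NeRF-style chain extension: place the next atom at bond length `l` from the
# last atom, with pseudo-bond angle `theta` and dihedral `phi` relative to the
# previous (up to) three atoms.
#' @noRd
.extend_chain <- function(prev, l, theta, phi) {
  m <- nrow(prev)
  C <- prev[m, ]
  B <- prev[m - 1, ]
  bc <- .unit(C - B)
  if (m >= 3) {
    A <- prev[m - 2, ]
    ab <- C - A  # only used to define the dihedral reference plane
    nref <- pracma_cross(.unit(B - A), bc)
    if (sqrt(sum(nref^2)) < 1e-8) nref <- .perp(bc)
  } else {
    nref <- .perp(bc)
  }
  nref <- .unit(nref)
  m2 <- pracma_cross(nref, bc)
  # direction making angle (pi - theta) with bc, rotated by phi about bc
  d <- -cos(theta) * bc + sin(theta) * (cos(phi) * m2 + sin(phi) * nref)
  C + l * .unit(d)
}

#' Place a peptide on the initialization sphere around a receptor
#'
#' The peptide is rigidly rotated by a uniform random rotation and translated
#' so that its centroid lies at a uniformly random direction on the sphere of
#' radius `longest_dimension(receptor) + margin` centered at the receptor's
#' Calpha centroid. Internal peptide geometry is preserved exactly.
#'
#' @param peptide,receptor `cg_chain` objects.
#' @param margin sphere radius margin beyond the receptor's longest dimension
#'   (default 20 A).
#' @return a `cg_complex` with the placed peptide.
#' @export
place_on_sphere <- function(peptide, receptor, margin = 20) {
  stopifnot(inherits(peptide, "cg_chain"), inherits(receptor, "cg_chain"))
  R <- longest_dimension(receptor) + margin
  center <- colMeans(receptor$ca)
  rot <- random_rotation_matrix()
  u <- .unit(stats::rnorm(3))
  target <- center + R * u
  pc <- colMeans(peptide$ca)
  shift <- function(m) {
    sweep(sweep(m, 2, pc) %*% t(rot), 2, target, `+`)
  }
  p2 <- peptide
  p2$ca <- shift(peptide$ca)
  p2$sc <- shift(peptide$sc)
  cg_complex(receptor, p2)
}

#' Wrap a coarse-grained complex with sampling metadata
#'
#' @param complex a `cg_complex`.
#' @param replica_index 0-based replica index.
#' @param macrocycle_index 0-based macrocycle index.
#' @param snapshot_index 0-based global snapshot index within the trajectory.
#' @param temperature reduced temperature at recording time.
#' @param energy named numeric vector `c(total=, binding=, restraint=)`.
#' @return a `cg_snapshot`.
#' @export
cg_snapshot <- function(complex, replica_index = 0L, macrocycle_index = 0L,
                        snapshot_index = 0L, temperature = NA_real_,
                        energy = c(total = NA_real_, binding = NA_real_,
                                   restraint = NA_real_)) {
  stopifnot(inherits(complex, "cg_complex"))
  structure(list(complex = complex,
                 replica_index = as.integer(replica_index),
                 macrocycle_index = as.integer(macrocycle_index),
                 snapshot_index = as.integer(snapshot_index),
                 temperature = temperature, energy = energy),
            class = "cg_snapshot")
}
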