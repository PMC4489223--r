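# Independent brute-force reference implementations used as oracles.
# Deliberately slow and literal; they never share code with the package
# internals they check.

bf_longest_dimension <- function(ca) {
  n <- nrow(ca)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, sqrt(sum((ca[i, ] - ca[j, ])^2)))
    }
  }
  best
}

# restraint enumeration under the "5-15 A, |i-j| >= gap within a chain,
# inter-chain always eligible" rules
bf_restraints <- function(ca, chain_index, d_min = 5, d_max = 15,
                          min_gap = 5) {
  n <- nrow(ca)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      same <- chain_index[i] == chain_index[j]
      if (d >= d_min && d <= d_max && (!same || j - i >= min_gap)) {
        out <- rbind(out, c(i, j, d))
      }
    }
  }
  out
}

bf_min_interchain <- function(ca_p, ca_r) {
  best <- Inf
  for (i in seq_len(nrow(ca_p))) {
    for (j in seq_len(nrow(ca_r))) {
      best <- min(best, sqrt(sum((ca_p[i, ] - ca_r[j, ])^2)))
    }
  }
  best
}

# full energy oracle mirroring the documented model, written as plain loops
bf_energy <- function(complex, model, restraints = NULL, excluded = integer(0)) {
  r <- complex$receptor; p <- complex$peptide
  ca_r <- r$ca; sc_r <- r$sc; ca_p <- p$ca; sc_p <- p$sc
  seq_r <- strsplit(r$sequence, "")[[1]]
  seq_p <- strsplit(p$sequence, "")[[1]]
  ss_p <- strsplit(p$ss, "")[[1]]
  np <- nrow(ca_p); nr <- nrow(ca_r)
  deg <- pi / 180
  angle_at <- function(i) {
    u <- ca_p[i - 1, ] - ca_p[i, ]; v <- ca_p[i + 1, ] - ca_p[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  e_intra <- 0
  if (np >= 3) {
    for (i in 2:(np - 1)) {
      th <- angle_at(i)
      lo <- model$angle_lo * deg; hi <- model$angle_hi * deg
      if (th < lo) e_intra <- e_intra + model$k_angle * (lo - th)^2
      if (th > hi) e_intra <- e_intra + model$k_angle * (th - hi)^2
      if (ss_p[i] == "H") {
        e_intra <- e_intra + model$ss_bias * (th - model$helix_angle * deg)^2
      } else if (ss_p[i] == "E") {
        e_intra <- e_intra + model$ss_bias * (th - model$strand_angle * deg)^2
      }
    }
  }
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (j > i + 1) {
        d <- sqrt(sum((ca_p[i, ] - ca_p[j, ])^2))
        if (d < model$peptide_min_sep) {
          e_intra <- e_intra + model$k_clash * (model$peptide_min_sep - d)^2
        }
      }
    }
  }
  e_inter <- 0
  for (ip in seq_len(np)) {
    best <- 0
    for (ir in seq_len(nr)) {
      dca <- sqrt(sum((ca_p[ip, ] - ca_r[ir, ])^2))
      if (dca < model$clash_distance) {
        e_inter <- e_inter + model$k_clash * (model$clash_distance - dca)^2
      }
      dsc <- sqrt(sum((sc_p[ip, ] - sc_r[ir, ])^2))
      if (dsc >= model$contact_lo && dsc <= model$contact_hi) {
        e <- model$contact_matrix[seq_p[ip], seq_r[ir]]
        if (e < best) best <- e else if (e > 0) e_inter <- e_inter + e
        if (ir %in% excluded) e_inter <- e_inter + model$exclusion_penalty
      }
    }
    e_inter <- e_inter + best
  }
  e_rest <- 0
  if (!is.null(restraints) && nrow(restraints) > 0) {
    for (k in seq_len(nrow(restraints))) {
      d <- sqrt(sum((ca_r[restraints$i[k], ] - ca_r[restraints$j[k], ])^2))
      v <- abs(d - restraints$d_ref[k]) - restraints$tolerance[k]
      if (v > 0) e_rest <- e_rest + restraints$slope[k] * v
    }
  }
  c(total = e_intra + e_inter + e_rest, binding = e_inter,
    restraint = e_rest, intra = e_intra)
}

# ligand RMSD oracle: Horn quaternion superposition of the model receptor
# onto the reference receptor, then explicit peptide RMSD sum
bf_ligand_rmsd <- function(model_cx, ref_cx) {
  x <- model_cx$receptor$ca; y <- ref_cx$receptor$ca
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  S <- t(xc) %*% yc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    w^2 + xq^2 - yq^2 - zq^2, 2 * (xq * yq - w * zq),   2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq),   w^2 - xq^2 + yq^2 - zq^2, 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq),   2 * (yq * zq + w * xq),   w^2 - xq^2 - yq^2 + zq^2),
    3, 3, byrow = TRUE)
  p <- model_cx$peptide$ca
  pt <- sweep(sweep(p, 2, cx) %*% t(R), 2, cy, `+`)
  s <- 0
  for (i in seq_len(nrow(p))) s <- s + sum((pt[i, ] - ref_cx$peptide$ca[i, ])^2)
  sqrt(s / nrow(p))
}

bf_contact_map <- function(complex, cutoff) {
  p <- complex$peptide$sc; r <- complex$receptor$sc
  m <- matrix(FALSE, nrow(p), nrow(r))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(r))) {
      m[i, j] <- sqrt(sum((p[i, ] - r[j, ])^2)) <= cutoff
    }
  }
  m
}

# exhaustive k-medoids optimum over all medoid subsets
bf_kmedoids_optimum <- function(dmat, k) {
  n <- nrow(dmat)
  sets <- utils::combn(n, k)
  best_cost <- Inf; best_set <- NULL
  for (c in seq_len(ncol(sets))) {
    med <- sets[, c]
    cost <- sum(apply(dmat[, med, drop = FALSE], 1, min))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost; best_set <- med
    }
  }
  list(medoids = best_set, cost = best_cost)
}
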