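# Two-step model selection: per-trajectory filtering of bound low-energy
# snapshots, then multi-restart k-medoids consensus clustering.

#' Filter one trajectory to its bound, lowest-binding-energy models
#'
#' All unbound snapshots are excluded; the remainder is sorted by binding
#' energy (ascending, stable tie-break by snapshot index) and at most
#' `max_models` are kept.
#'
#' @param traj a `trajectory`.
#' @param cutoff bound-state Calpha distance cutoff in A (default 8).
#' @param max_models per-trajectory cap (default 100).
#' @return a `filtered_set`: list with `models` (list of `cg_snapshot`) and
#'   `provenance` (data.frame: replica, snapshot, e_binding).
#' @export
filter_trajectory <- function(traj, cutoff = 8.0, max_models = 100L) {
  stopifnot(inherits(traj, "trajectory"))
  bound <- vapply(traj$snapshots, function(s) is_bound(s$complex, cutoff),
                  logical(1))
  if (!any(bound)) {
    warning(sprintf("trajectory %d contains no bound states",
                    traj$replica_index))
    return(structure(list(models = list(),
                          provenance = data.frame(replica = integer(),
                                                  snapshot = integer(),
                                                  e_binding = numeric())),
                     class = "filtered_set"))
  }
  idx <- which(bound)
  eb <- vapply(traj$snapshots[idx], function(s) s$energy[["binding"]],
               numeric(1))
  ord <- order(eb, idx)  # stable: energy then snapshot index
  keep <- idx[ord][seq_len(min(max_models, length(idx)))]
  structure(list(
    models = traj$snapshots[keep],
    provenance = data.frame(replica = traj$replica_index, snapshot = keep,
                            e_binding = vapply(traj$snapshots[keep],
                                               function(s) s$energy[["binding"]],
                                               numeric(1)))),
    class = "filtered_set")
}

#' Filter a list of trajectories and pool the results
#' @param trajectories list of `trajectory` objects.
#' @inheritParams filter_trajectory
#' @return pooled `filtered_set`.
#' @export
filter_models <- function(trajectories, cutoff = 8.0, max_models = 100L) {
  parts <- lapply(trajectories, filter_trajectory, cutoff = cutoff,
                  max_models = max_models)
  structure(list(
    models = do.call(c, lapply(parts, `[[`, "models")),
    provenance = do.call(rbind, lapply(parts, `[[`, "provenance"))),
    class = "filtered_set")
}

#' @export
print.filtered_set <- function(x, ...) {
  cat(sprintf("<filtered_set> %d models from %d trajectories\n",
              length(x$models), length(unique(x$provenance$replica))))
  invisible(x)
}

#' @noRd
.as_complex <- function(x) {
  if (inherits(x, "cg_snapshot")) x$complex
  else if (inherits(x, "cg_complex")) x
  else stop("expected a cg_complex or cg_snapshot", call. = FALSE)
}

# Kabsch: optimal rotation R and translations such that moving x (n x 3 rows)
# by sweep/rotate maps it onto y in the least-squares sense
#' @noRd
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  h <- t(xc) %*% yc
  sv <- svd(h)
  s <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  list(rot = rot, cx = cx, cy = cy)
}

#' @noRd
.apply_kabsch <- function(k, pts) {
  sweep(sweep(pts, 2, k$cx) %*% k$rot, 2, k$cy, `+`)
}

#' Pose distance between two models of the same complex
#'
#' Superimposes the receptor Calpha trace of `b` onto that of `a` (Kabsch)
#' and returns the peptide Calpha RMSD without further fitting — the same
#' metric used for docking-quality evaluation. Symmetric to numerical
#' precision; the triangle inequality is not guaranteed.
#'
#' @param a,b `cg_snapshot` or `cg_complex` objects sharing one topology.
#' @return distance in A.
#' @export
pose_distance <- function(a, b) {
  a <- .as_complex(a); b <- .as_complex(b)
  ligand_rmsd(b, a)
}

#' Pairwise pose-distance matrix
#'
#' Equivalent to applying [pose_distance()] to every pair; receptor traces
#' and peptides are centered once so the inner loop reduces to a 3x3 SVD
#' and an RMS sum per pair.
#'
#' @param models list of `cg_snapshot`/`cg_complex`.
#' @return symmetric n x n matrix (zero diagonal).
#' @export
pose_distance_matrix <- function(models) {
  n <- length(models)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  cx <- lapply(models, .as_complex)
  rc <- lapply(cx, function(c) {
    m <- c$receptor$ca
    cm <- colMeans(m)
    list(centered = sweep(m, 2, cm), centroid = cm)
  })
  pep <- lapply(cx, function(c) c$peptide$ca)
  np <- nrow(pep[[1]])
  for (i in seq_len(n - 1)) {
    xc <- rc[[i]]$centered
    pi_c <- sweep(pep[[i]], 2, rc[[i]]$centroid)
    for (j in (i + 1):n) {
      sv <- svd(crossprod(xc, rc[[j]]$centered))
      s <- sign(det(sv$u %*% t(sv$v)))
      rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
      pj <- sweep(pep[[j]], 2, rc[[j]]$centroid)
      diff <- pi_c %*% rot - pj
      d[i, j] <- d[j, i] <- sqrt(sum(diff * diff) / np)
    }
  }
  d
}

#' One PAM-style k-medoids run
#'
#' Random initial medoids, then alternating assignment (nearest medoid, ties
#' to the lower medoid index) and medoid update (member minimizing the sum
#' of within-cluster distances, ties to the lowest index) until the total
#' cost stops decreasing. Deterministic given the RNG state.
#'
#' @param dmat symmetric distance matrix.
#' @param k number of clusters.
#' @param init optional initial medoid indices (default: sampled).
#' @return list with `medoids` (sorted indices), `assignment` (medoid index
#'   per point) and `cost`.
#' @export
kmedoids_once <- function(dmat, k, init = NULL) {
  n <- nrow(dmat)
  stopifnot(k >= 1, k <= n)
  medoids <- if (is.null(init)) sort(sample.int(n, k)) else sort(as.integer(init))
  assign_cost <- function(med) {
    sub <- dmat[, med, drop = FALSE]
    pick <- max.col(-sub, ties.method = "first")
    list(assignment = med[pick],
         cost = sum(sub[cbind(seq_len(n), pick)]))
  }
  cur <- assign_cost(medoids)
  repeat {
    new_med <- medoids
    for (c in seq_along(medoids)) {
      members <- which(cur$assignment == medoids[c])
      if (length(members) == 0) next  # empty cluster (duplicate medoids)
      sums <- colSums(dmat[members, members, drop = FALSE])
      new_med[c] <- members[which.min(sums)]
    }
    new_med <- sort(new_med)
    nxt <- assign_cost(new_med)
    if (nxt$cost < cur$cost - 1e-12) {
      medoids <- new_med
      cur <- nxt
    } else {
      break
    }
  }
  list(medoids = medoids, assignment = cur$assignment, cost = cur$cost)
}

#' Consensus k-medoids clustering of the filtered model set
#'
#' Runs [kmedoids_once()] `n_restarts` times with different random initial
#' medoids and counts how often each model is selected as a medoid. The `k`
#' most frequently selected models become the consensus medoids (ties broken
#' by lower binding energy, then lower index); every model is then assigned
#' to its nearest consensus medoid and per-cluster statistics are computed.
#' With `method = "best_cost"` the single lowest-cost run is used instead.
#'
#' @param fs a `filtered_set` (or plain list of models).
#' @param k number of final models (default 10; reduced with a warning when
#'   fewer models are available).
#' @param n_restarts clustering restarts (default 100).
#' @param method `"consensus"` (default) or `"best_cost"`.
#' @param dmat optional precomputed pose-distance matrix.
#' @return a `final_model_set`: list with `medoid_indices`, `medoids`
#'   (list of models), `assignment`, `stats` (data.frame: cluster, medoid,
#'   size, density, diversity, e_binding) and `dmat`.
#' @export
consensus_cluster <- function(fs, k = 10L, n_restarts = 100L,
                              method = c("consensus", "best_cost"),
                              dmat = NULL) {
  method <- match.arg(method)
  models <- if (inherits(fs, "filtered_set")) fs$models else fs
  n <- length(models)
  if (n == 0) stop("no models to cluster", call. = FALSE)
  if (n < k) {
    warning(sprintf("only %d models available; reducing k from %d", n, k))
    k <- n
  }
  if (is.null(dmat)) dmat <- pose_distance_matrix(models)
  eb <- vapply(models, function(m) {
    if (inherits(m, "cg_snapshot") && is.finite(m$energy[["binding"]])) {
      m$energy[["binding"]]
    } else NA_real_
  }, numeric(1))

  runs <- vector("list", n_restarts)
  for (t in seq_len(n_restarts)) runs[[t]] <- kmedoids_once(dmat, k)

  if (method == "consensus") {
    freq <- tabulate(unlist(lapply(runs, `[[`, "medoids")), nbins = n)
    ord <- order(-freq, eb, seq_len(n), na.last = TRUE)
    medoid_idx <- sort(ord[seq_len(k)])
  } else {
    best <- which.min(vapply(runs, `[[`, numeric(1), "cost"))
    medoid_idx <- runs[[best]]$medoids
  }

  sub <- dmat[, medoid_idx, drop = FALSE]
  pick <- max.col(-sub, ties.method = "first")
  assignment <- medoid_idx[pick]
  stats_df <- do.call(rbind, lapply(seq_along(medoid_idx), function(c) {
    members <- which(assignment == medoid_idx[c])
    dmed <- dmat[members, medoid_idx[c]]
    data.frame(cluster = c, medoid = medoid_idx[c],
               size = length(members),
               density = mean(dmed), diversity = max(dmed),
               e_binding = eb[medoid_idx[c]])
  }))
  structure(list(medoid_indices = medoid_idx,
                 medoids = models[medoid_idx],
                 assignment = assignment, stats = stats_df, dmat = dmat),
            class = "final_model_set")
}

#' @export
print.final_model_set <- function(x, ...) {
  cat(sprintf("<final_model_set> %d consensus medoids\n",
              length(x$medoid_indices)))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Write the cluster report as TSV
#' @param final a `final_model_set`.
#' @param path output path.
#' @param provenance optional provenance data.frame from the filtered set.
#' @export
write_cluster_report <- function(final, path, provenance = NULL) {
  st <- final$stats
  if (!is.null(provenance)) {
    st$replica <- provenance$replica[st$medoid]
    st$snapshot <- provenance$snapshot[st$medoid]
  }
  utils::write.table(st, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
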