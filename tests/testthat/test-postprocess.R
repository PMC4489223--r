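# Filtering, pose distances, k-medoids, consensus clustering.

# build a synthetic trajectory whose snapshots place a peptide at chosen
# offsets from a fixed receptor, with prescribed binding energies
synthetic_trajectory <- function(offsets, e_binding, replica = 1L) {
  rec <- toy_receptor_chain(8)
  pep0 <- toy_peptide_chain("FKW")
  snaps <- lapply(seq_along(e_binding), function(k) {
    p <- pep0
    p$ca <- sweep(pep0$ca, 2, offsets[[k]], `+`)
    p$sc <- sweep(pep0$sc, 2, offsets[[k]], `+`)
    cg_snapshot(cg_complex(rec, p), replica_index = replica,
                snapshot_index = k,
                energy = c(total = e_binding[k], binding = e_binding[k],
                           restraint = 0))
  })
  sidecar <- data.frame(replica = replica, snapshot = seq_along(snaps))
  structure(list(replica_index = replica, snapshots = snaps,
                 sidecar = sidecar), class = "trajectory")
}

test_that("filter_trajectory drops unbound, sorts by binding energy, caps at 100", {
  set.seed(1)
  n <- 250
  # alternate bound (touching) and unbound (far) placements
  bound <- rep(c(TRUE, FALSE), length.out = n)
  offsets <- lapply(bound, function(b) if (b) c(6, 0, 0) else c(60, 0, 0))
  eb <- rnorm(n)
  tr <- synthetic_trajectory(offsets, eb)
  fs <- filter_trajectory(tr)
  expect_equal(length(fs$models), 100L)
  kept_e <- fs$provenance$e_binding
  expect_true(all(diff(kept_e) >= 0))
  # max kept <= min dropped among bound
  bound_e <- eb[bound]
  expect_lte(max(kept_e), min(setdiff(sort(bound_e), kept_e)))
  # fewer than 100 bound -> all kept
  tr2 <- synthetic_trajectory(offsets[1:80], eb[1:80])
  expect_equal(length(filter_trajectory(tr2)$models), 40L)
  # no bound states -> empty with a warning
  tr3 <- synthetic_trajectory(list(c(60, 0, 0)), 0)
  expect_warning(fs3 <- filter_trajectory(tr3), "no bound states")
  expect_length(fs3$models, 0)
  # idempotent-style stability: refiltering the kept set keeps it
  expect_equal(sum(vapply(fs$models, function(m) is_bound(m$complex),
                          logical(1))), 100L)
})

test_that("pose_distance is zero under identity and global rigid motion", {
  set.seed(2)
  cx <- random_complex(sep = 5)
  expect_equal(pose_distance(cx, cx), 0, tolerance = 1e-9)
  rot <- pepdock:::random_rotation_matrix()
  cx2 <- cx
  for (part in c("receptor", "peptide")) {
    cx2[[part]]$ca <- sweep(cx[[part]]$ca %*% t(rot), 2, c(3, 4, 5), `+`)
    cx2[[part]]$sc <- sweep(cx[[part]]$sc %*% t(rot), 2, c(3, 4, 5), `+`)
  }
  expect_equal(pose_distance(cx, cx2), 0, tolerance = 1e-6)
})

test_that("pose_distance matches the quaternion oracle and is symmetric", {
  set.seed(3)
  for (rep in 1:8) {
    a <- random_complex(sep = runif(1, 2, 10))
    b <- random_complex(sep = runif(1, 2, 10))
    # same receptor topology, slightly perturbed receptor in b
    b$receptor$ca <- a$receptor$ca + matrix(rnorm(nrow(a$receptor$ca) * 3,
                                                  sd = 0.3),
                                            ncol = 3)
    got <- pose_distance(a, b)
    expect_equal(got, bf_ligand_rmsd(b, a), tolerance = 1e-6)
    expect_equal(got, pose_distance(b, a), tolerance = 1e-6)
  }
})

test_that("pose_distance_matrix agrees with pairwise pose_distance", {
  set.seed(33)
  rec <- toy_receptor_chain(8)
  pep0 <- toy_peptide_chain("FKW")
  models <- lapply(1:7, function(k) {
    p <- pep0
    off <- rnorm(3, sd = 10)
    p$ca <- sweep(pep0$ca, 2, off, `+`)
    p$sc <- sweep(pep0$sc, 2, off, `+`)
    r <- rec
    r$ca <- rec$ca + matrix(rnorm(24, sd = 0.2), ncol = 3)
    cg_complex(r, p)
  })
  dm <- pose_distance_matrix(models)
  expect_equal(dm, t(dm), tolerance = 1e-9)
  for (i in 1:6) {
    for (j in (i + 1):7) {
      expect_equal(dm[i, j], pose_distance(models[[i]], models[[j]]),
                   tolerance = 1e-6)
    }
  }
})

test_that("kmedoids_once finds the exhaustive optimum on separable instances", {
  # two tight planar triads
  pts <- rbind(c(0, 0), c(0.4, 0), c(0, 0.4),
               c(10, 10), c(10.4, 10), c(10, 10.4))
  dmat <- as.matrix(dist(pts))
  set.seed(4)
  res <- kmedoids_once(dmat, 2)
  oracle <- bf_kmedoids_optimum(dmat, 2)
  expect_equal(res$cost, oracle$cost, tolerance = 1e-12)
  expect_setequal(res$assignment %in% res$medoids, TRUE)
  # k = n: cost 0, every point its own medoid
  res_n <- kmedoids_once(dmat, 6)
  expect_equal(res_n$cost, 0)
  expect_equal(res_n$medoids, 1:6)
  # random instances, k up to 3, n <= 8: PAM from many restarts attains the
  # exhaustive optimum
  set.seed(5)
  for (rep in 1:5) {
    pts <- matrix(runif(16), 8, 2)
    dmat <- as.matrix(dist(pts))
    k <- sample(2:3, 1)
    best <- min(vapply(1:30, function(i) kmedoids_once(dmat, k)$cost,
                       numeric(1)))
    expect_equal(best, bf_kmedoids_optimum(dmat, k)$cost, tolerance = 1e-9)
  }
})

test_that("duplicate points do not change the k-medoids cost", {
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  dmat <- as.matrix(dist(pts))
  # with one medoid per duplicate group the cost is 0 regardless of which
  # duplicate serves as the medoid
  for (init in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))) {
    expect_equal(kmedoids_once(dmat, 2, init = init)$cost, 0)
  }
  # restarted search reaches the optimum even from degenerate inits
  set.seed(6)
  best <- min(vapply(1:10, function(i) kmedoids_once(dmat, 2)$cost,
                     numeric(1)))
  expect_equal(best, 0)
})

test_that("consensus clustering recovers well-separated blobs every restart", {
  # 10 tight blobs of 5 poses each: translated copies of one peptide
  set.seed(7)
  rec <- toy_receptor_chain(8)
  pep0 <- toy_peptide_chain("FKW")
  centers <- matrix(rnorm(30, sd = 40), 10, 3)
  models <- list()
  blob_of <- integer(0)
  for (b in 1:10) {
    for (j in 1:5) {
      p <- pep0
      off <- centers[b, ] + rnorm(3, sd = 0.1)
      p$ca <- sweep(pep0$ca, 2, off, `+`)
      p$sc <- sweep(pep0$sc, 2, off, `+`)
      models[[length(models) + 1]] <-
        cg_snapshot(cg_complex(rec, p),
                    energy = c(total = 0, binding = rnorm(1), restraint = 0))
      blob_of <- c(blob_of, b)
    }
  }
  fin <- consensus_cluster(models, k = 10, n_restarts = 30)
  expect_length(fin$medoid_indices, 10)
  # one medoid per blob
  expect_setequal(unique(blob_of[fin$medoid_indices]), 1:10)
  # clusters partition the set and stats are coherent
  expect_equal(sum(fin$stats$size), 50)
  expect_true(all(fin$stats$density <= fin$stats$diversity + 1e-12))
  # medoids are members, assignment points at medoids
  expect_true(all(fin$assignment %in% fin$medoid_indices))
})

test_that("consensus clustering is invariant to input order", {
  set.seed(8)
  rec <- toy_receptor_chain(8)
  pep0 <- toy_peptide_chain("FKW")
  models <- lapply(1:12, function(k) {
    p <- pep0
    off <- rnorm(3, sd = 15)
    p$ca <- sweep(pep0$ca, 2, off, `+`)
    p$sc <- sweep(pep0$sc, 2, off, `+`)
    cg_snapshot(cg_complex(rec, p),
                energy = c(total = 0, binding = k * 0.1, restraint = 0))
  })
  set.seed(99)
  f1 <- consensus_cluster(models, k = 3, n_restarts = 20)
  perm <- c(5, 2, 9, 1, 12, 3, 7, 11, 4, 10, 8, 6)
  set.seed(99)
  f2 <- consensus_cluster(models[perm], k = 3, n_restarts = 20)
  # medoid sets agree as model identities
  expect_setequal(perm[f2$medoid_indices], f1$medoid_indices)
})

test_that("consensus_cluster reduces k with a warning when models are few", {
  set.seed(9)
  rec <- toy_receptor_chain(8)
  pep0 <- toy_peptide_chain("FKW")
  models <- lapply(1:4, function(k) {
    p <- pep0
    p$ca <- sweep(pep0$ca, 2, c(10 * k, 0, 0), `+`)
    p$sc <- sweep(pep0$sc, 2, c(10 * k, 0, 0), `+`)
    cg_snapshot(cg_complex(rec, p))
  })
  expect_warning(fin <- consensus_cluster(models, k = 10, n_restarts = 5),
                 "reducing k")
  expect_length(fin$medoid_indices, 4)
})
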