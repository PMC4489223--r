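# Ladder construction, annealing, Metropolis/exchange statistics, move
# kernel invariants, trajectory arithmetic.

test_that("temperature ladder is uniform, decreasing, and anneals proportionally", {
  t10 <- build_ladder(t_max = 2.0, t_min = 1.0, n_replicas = 10)
  expect_equal(diff(t10), rep(-1 / 9, 9), tolerance = 1e-12)
  expect_true(all(diff(t10) < 0))
  expect_equal(build_ladder(t_max = 3.5, t_min = 1.0, n_replicas = 2),
               c(3.5, 1.0))
  # final macrocycle scale is exactly the annealing factor
  expect_equal(annealing_scale(50, 50, 0.6), 0.6)
  expect_equal(annealing_scale(1, 50, 0.6), 1.0)
  expect_equal(annealing_scale(1, 1, 0.6), 1.0)
  # monotone shrinkage
  sc <- vapply(1:50, annealing_scale, numeric(1), n_macrocycles = 50)
  expect_true(all(diff(sc) < 0))
})

test_that("simulation_config enforces the macrocycle bounds", {
  expect_error(simulation_config(n_macrocycles = 0), "between 1 and 200")
  expect_error(simulation_config(n_macrocycles = 201), "between 1 and 200")
  expect_silent(simulation_config(n_macrocycles = 200))
})

test_that("Metropolis acceptance matches the closed form", {
  set.seed(101)
  # dE < 0 always accepted
  expect_true(all(metropolis_accept(rep(-1, 100), 1)))
  # dE = T ln 2 -> rate 1/2 within 0.02 at 1e4 trials
  n <- 1e4
  rate <- mean(metropolis_accept(rep(2 * log(2), n), 2))
  expect_lt(abs(rate - 0.5), 0.02)
  # generic point: exp(-dE/T)
  rate2 <- mean(metropolis_accept(rep(1.2, n), 1.5))
  expect_lt(abs(rate2 - exp(-1.2 / 1.5)), 0.02)
})

test_that("replica-exchange acceptance matches the closed form", {
  set.seed(202)
  n <- 1e4
  # equal energies or equal temperatures: always swapped
  expect_true(all(exchange_accept(rep(1, 100), rep(1, 100), 1.0, 2.0)))
  expect_true(all(exchange_accept(rnorm(100), rnorm(100), 1.5, 1.5)))
  # generic case
  e_a <- 3; e_b <- 1; t_a <- 1; t_b <- 2
  want <- min(1, exp((1 / t_a - 1 / t_b) * (e_a - e_b)))
  got <- mean(exchange_accept(rep(e_a, n), rep(e_b, n), t_a, t_b))
  expect_lt(abs(got - want), 0.02)
  # downhill direction (hotter replica holds the higher energy): certain swap
  expect_true(all(exchange_accept(rep(5, 100), rep(3, 100), 1, 2)))
})

test_that("two-well toy system reaches Boltzmann occupancy", {
  # single particle hopping between two states with dE = 1 at T = 1.3,
  # driven by the package's acceptance rule
  set.seed(303)
  dE <- 1.0; Temp <- 1.3
  n_sweep <- 1e5
  state <- 0L
  occ <- 0L
  for (i in seq_len(n_sweep)) {
    prop_dE <- if (state == 0L) dE else -dE
    if (metropolis_accept(prop_dE, Temp)) state <- 1L - state
    occ <- occ + state
  }
  p1 <- occ / n_sweep
  want <- exp(-dE / Temp) / (1 + exp(-dE / Temp))
  # binomial-style 3 sigma allowing for autocorrelation (conservative x3)
  sigma <- 3 * sqrt(want * (1 - want) / n_sweep)
  expect_lt(abs(p1 - want), 3 * sigma)
})

test_that("mc_move preserves bonds, keeps energies consistent, never rejects downhill", {
  set.seed(404)
  rec <- toy_receptor_chain(12)
  rs <- generate_restraints(rec)
  model <- energy_model()
  cx <- place_on_sphere(random_peptide_conformation(validate_peptide("FKWDE")),
                        rec)
  set.seed(405)
  res <- mc_move(cx, 2.0, model, rs, n_moves = 2000)
  # stored energy equals re-evaluation from coordinates
  e <- total_energy(res$complex, model, rs)
  expect_equal(unname(res$energy), unname(e), tolerance = 1e-9)
  # bond invariant maintained for both chains
  for (part in c("receptor", "peptide")) {
    ca <- res$complex[[part]]$ca
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    same <- res$complex[[part]]$chain_index[-1] ==
      res$complex[[part]]$chain_index[-nrow(ca)]
    expect_true(all(abs(d[same] - 3.8) <= 0.4 + 1e-9))
  }
  # determinism
  set.seed(405)
  res2 <- mc_move(cx, 2.0, model, rs, n_moves = 2000)
  expect_identical(res$complex$peptide$ca, res2$complex$peptide$ca)
})

test_that("compact receptors stay near-native under default restraints", {
  # Near-native means conformational fidelity: superimpose before the RMSD
  # (restraints control internal geometry, not the global frame). The
  # property holds for receptors whose restraint network is dense, i.e.
  # compact folds; an isolated thin helix has zero-energy bending modes
  # inside the +-1 A flat bottoms and is excluded by design (see vignette).
  set.seed(505)
  cases <- list(build_cg(globule_receptor(25)), cradle_receptor()$cg)
  for (rec in cases) {
    rs <- generate_restraints(rec)
    model <- energy_model()
    cx <- place_on_sphere(random_peptide_conformation(validate_peptide("FKW")),
                          rec)
    # hottest ladder temperature, mean RMSD over trajectory checkpoints
    st <- cx
    rmsds <- numeric(0)
    for (chunk in 1:8) {
      res <- mc_move(st, 3.5, model, rs, n_moves = 5000)
      st <- res$complex
      k <- pepdock:::.kabsch(st$receptor$ca, rec$ca)
      aligned <- pepdock:::.apply_kabsch(k, st$receptor$ca)
      rmsds <- c(rmsds, sqrt(mean(rowSums((aligned - rec$ca)^2))))
    }
    expect_lt(mean(rmsds), 2)
  }
})

test_that("run_docking obeys the trajectory arithmetic and is reproducible", {
  rec <- build_cg(ideal_helix(10))
  pep <- validate_peptide("FKW")
  cfg <- simulation_config(n_replicas = 3, n_macrocycles = 4,
                          snapshots_per_macrocycle = 5,
                          moves_per_snapshot = 10, seed = 7)
  trajs <- run_docking(rec, pep, model = energy_model(), config = cfg)
  expect_length(trajs, 3)
  for (tr in trajs) {
    expect_length(tr$snapshots, 20)            # macrocycles x snapshots
    expect_equal(nrow(tr$sidecar), 20)
    expect_equal(unique(tr$sidecar$replica), tr$replica_index)
    # stored energies match re-evaluation (no bookkeeping drift)
    for (k in c(1, 10, 20)) {
      s <- tr$snapshots[[k]]
      e <- total_energy(s$complex, energy_model(),
                        generate_restraints(rec))
      expect_equal(s$energy[["total"]], e[["total"]], tolerance = 1e-6)
    }
  }
  # temperatures decrease across replicas and shrink over macrocycles
  t_first <- vapply(trajs, function(tr) tr$sidecar$temperature[1], numeric(1))
  expect_true(all(diff(t_first) < 0))
  expect_lt(trajs[[1]]$sidecar$temperature[20], t_first[1])

  trajs2 <- run_docking(rec, pep, model = energy_model(), config = cfg)
  expect_identical(trajs[[2]]$snapshots[[20]]$complex$peptide$ca,
                   trajs2[[2]]$snapshots[[20]]$complex$peptide$ca)
})
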