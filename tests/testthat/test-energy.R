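# Restraint generation rules, flat-bottom energetics, the stand-in contact
# model, bound-state test; all checked against literal brute-force oracles.

test_that("generate_restraints applies the distance band and gap rules", {
  # pair at 4.9 A with ample gap: below the band -> no restraint
  ca <- rbind(c(0, 0, 0), matrix(c(40, 0, 0, 80, 0, 0, 120, 0, 0, 160, 0, 0,
                                   200, 0, 0), 5, 3, byrow = TRUE))
  ca <- rbind(ca, c(4.9, 0, 0))  # residue 7, 4.9 A from residue 1, gap 6
  rec <- cg_chain(ca, ca, strrep("A", 7), check = FALSE)
  rs <- generate_restraints(rec)
  expect_equal(nrow(rs), 0L)

  # pair at 10 A but gap 4 -> no restraint
  ca2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0),
               c(10, 0, 0))
  rec2 <- cg_chain(ca2, ca2, "AAAAA", check = FALSE)
  expect_equal(nrow(generate_restraints(rec2)), 0L)

  # same geometry split across two chains -> inter-chain pair is eligible
  rec3 <- cg_chain(ca2, ca2, "AAAAA", chain_id = c("A", "A", "A", "A", "B"),
                   check = FALSE)
  rs3 <- generate_restraints(rec3)
  expect_equal(nrow(rs3), 1L)
  expect_equal(rs3$d_ref, 10)
})

test_that("restraints on an ideal helix equal brute-force enumeration", {
  rec <- build_cg(ideal_helix(20))
  rs <- generate_restraints(rec)
  oracle <- bf_restraints(rec$ca, rec$chain_index)
  expect_equal(nrow(rs), nrow(oracle))
  expect_equal(rs$i, oracle[, 1])
  expect_equal(rs$j, oracle[, 2])
  expect_equal(rs$d_ref, oracle[, 3], tolerance = 1e-9)
  # the helix puts i,i+5 pairs inside the band, so the printed minimum gap
  # is realized
  expect_equal(min(rs$j - rs$i), 5L)
  expect_true(all(rs$d_ref >= 5 & rs$d_ref <= 15))
})

test_that("restraint generation is invariant under rigid motion and honors marks", {
  rec <- build_cg(ideal_helix(15))
  rot <- rotation_matrix <- pepdock:::rotation_matrix(c(1, 2, 3), 0.7)
  rec2 <- rec
  rec2$ca <- sweep(rec$ca %*% t(rot), 2, c(5, -3, 11), `+`)
  rec2$sc <- sweep(rec$sc %*% t(rot), 2, c(5, -3, 11), `+`)
  rs1 <- generate_restraints(rec)
  rs2 <- generate_restraints(rec2)
  expect_equal(rs1$i, rs2$i)
  expect_equal(rs1$d_ref, rs2$d_ref, tolerance = 1e-9)

  marks <- list(moderate = c(3L), full = c(7L))
  rs <- generate_restraints(rec, marks = marks, k_restraint = 2)
  touch3 <- rs$i == 3 | rs$j == 3
  touch7 <- rs$i == 7 | rs$j == 7
  expect_true(all(rs$slope[touch7] == 0))
  expect_true(all(rs$slope[touch3 & !touch7] == 1))   # halved from 2
  expect_true(all(rs$slope[!touch3 & !touch7] == 2))
})

test_that("flat-bottom restraint energy matches the printed rules", {
  # violation below the 1 A tolerance is free
  expect_equal(restraint_energy(10.5, 10), 0)
  expect_equal(restraint_energy(9.5, 10), 0)
  # violation of 2 A with unit slope costs 1
  expect_equal(restraint_energy(12, 10), 1)
  expect_equal(restraint_energy(8, 10), 1)
  # fully flexible (slope 0) is free anywhere
  expect_equal(restraint_energy(25, 10, slope = 0), 0)
  # piecewise-linear with slope exactly +-slope outside the bottom
  # (finite differences on both branches)
  h <- 1e-6
  for (d in c(12.5, 7.5)) {
    g <- (restraint_energy(d + h, 10, slope = 3) -
            restraint_energy(d - h, 10, slope = 3)) / (2 * h)
    expect_equal(abs(g), 3, tolerance = 1e-4)
  }
  # continuous and zero across [d_ref - 1, d_ref + 1]
  grid <- seq(9, 11, by = 0.01)
  expect_true(all(restraint_energy(grid, 10) == 0))
})

test_that("total_energy matches the brute-force oracle on random poses", {
  set.seed(21)
  model <- energy_model()
  for (rep in 1:8) {
    cx <- random_complex(sep = sample(c(2, 5, 8, 12), 1))
    rs <- generate_restraints(cx$receptor, model = model)
    excl <- if (rep %% 2 == 0) c(1L, 4L) else integer(0)
    got <- total_energy(cx, model, rs, excluded = excl)
    want <- bf_energy(cx, model, rs, excluded = excl)
    expect_equal(got[c("total", "binding", "restraint")],
                 want[c("total", "binding", "restraint")],
                 tolerance = 1e-9)
  }
})

test_that("energy is invariant under rigid motion of the whole complex", {
  set.seed(31)
  model <- energy_model()
  cx <- random_complex(sep = 4)
  rs <- generate_restraints(cx$receptor, model = model)
  e0 <- total_energy(cx, model, rs)
  for (rep in 1:5) {
    rot <- pepdock:::random_rotation_matrix()
    tr <- rnorm(3, sd = 20)
    cx2 <- cx
    for (part in c("receptor", "peptide")) {
      cx2[[part]]$ca <- sweep(cx[[part]]$ca %*% t(rot), 2, tr, `+`)
      cx2[[part]]$sc <- sweep(cx[[part]]$sc %*% t(rot), 2, tr, `+`)
    }
    expect_equal(total_energy(cx2, model, rs), e0, tolerance = 1e-9)
  }
})

test_that("binding energy vanishes for separated poses; single contact matches matrix", {
  rec <- toy_receptor_chain(10)
  pep <- toy_peptide_chain("FKWDE")
  far <- pep
  far$ca <- sweep(pep$ca, 2, c(100, 0, 0), `+`)
  far$sc <- sweep(pep$sc, 2, c(100, 0, 0), `+`)
  e <- total_energy(cg_complex(rec, far), energy_model())
  expect_equal(e[["binding"]], 0)
  expect_false(is_bound(cg_complex(rec, far)))

  # constructed single sc-sc contact inside the shell, far otherwise
  ca_r <- rbind(c(0, 0, 0))
  rec1 <- cg_chain(ca_r, rbind(c(0, 0, 1.53)), "A", check = FALSE)
  ca_p <- rbind(c(0, 0, 7))
  pep1 <- cg_chain(ca_p, rbind(c(0, 0, 7 - 1.53)), "A", chain_id = "P",
                   check = FALSE)
  m <- energy_model()
  e1 <- total_energy(cg_complex(rec1, pep1), m)  # sc-sc distance 3.94 < 4.5
  expect_equal(e1[["binding"]], 0)
  pep2 <- cg_chain(rbind(c(0, 0, 8)), rbind(c(0, 0, 8 - 1.53)), "A",
                   chain_id = "P", check = FALSE)
  e2 <- total_energy(cg_complex(rec1, pep2), m)  # sc-sc distance 4.94 in shell
  expect_equal(e2[["binding"]], m$contact_matrix["A", "A"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("is_bound uses a closed boundary and matches the min-distance oracle", {
  rec <- cg_chain(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), "A", check = FALSE)
  pep <- cg_chain(rbind(c(8, 0, 0)), rbind(c(8, 0, 0)), "A", chain_id = "P",
                  check = FALSE)
  expect_true(is_bound(cg_complex(rec, pep), cutoff = 8))
  pep$ca[1, 1] <- 8.0001
  expect_false(is_bound(cg_complex(rec, pep), cutoff = 8))

  set.seed(77)
  for (rep in 1:10) {
    cx <- random_complex(sep = runif(1, 0, 15))
    expect_equal(min_interchain_distance(cx),
                 bf_min_interchain(cx$peptide$ca, cx$receptor$ca),
                 tolerance = 1e-9)
    expect_equal(is_bound(cx), bf_min_interchain(cx$peptide$ca,
                                                 cx$receptor$ca) <= 8)
  }
})

test_that("peptide placed on the initialization sphere is never bound", {
  rec <- toy_receptor_chain(15)
  spec <- validate_peptide("FKWDE")
  set.seed(13)
  for (i in 1:5) {
    cx <- place_on_sphere(random_peptide_conformation(spec), rec)
    expect_false(is_bound(cx))
    expect_equal(total_energy(cx, energy_model())[["binding"]], 0)
  }
})

test_that("contact matrix is symmetric and the model validates inputs", {
  m <- default_contact_matrix()
  expect_equal(m, t(m))
  expect_equal(dim(m), c(20L, 20L))
  # favorable hydrophobic-hydrophobic contact, unfavorable mixed
  expect_lt(m["I", "L"], 0)
  expect_gt(m["I", "D"], 0)
  expect_error(energy_model(contact_matrix = matrix(0, 19, 19)))
  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(energy_model(contact_matrix = asym))
})
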