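# Replica-exchange Monte Carlo simulated annealing.
#
# 10 replicas uniformly spread on a reduced-temperature ladder; the whole
# ladder is annealed multiplicatively over the macrocycles so that every
# temperature ends at annealing_factor times its initial value. One thread
# of execution; all randomness flows from the R RNG seeded once per run.

#' Simulation configuration
#'
#' @param n_replicas number of replicas (default 10).
#' @param n_macrocycles outer Monte Carlo cycles, 1-200 (default 50).
#' @param snapshots_per_macrocycle snapshots recorded per macrocycle per
#'   replica (default 20, giving 1000 snapshots per trajectory at defaults).
#' @param moves_per_snapshot attempted Metropolis moves per replica between
#'   consecutive snapshots (default 300).
#' @param t_max,t_min initial temperature-ladder bounds in reduced units
#'   (defaults 3.5 and 1.0).
#' @param annealing_factor final/initial ladder scale (default 0.6); the
#'   ladder shrinks multiplicatively each macrocycle.
#' @param seed integer seed for the run.
#' @param move_par move-kernel parameters, see [default_move_par()].
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_replicas = 10L, n_macrocycles = 50L,
                              snapshots_per_macrocycle = 20L,
                              moves_per_snapshot = 300L,
                              t_max = 3.5, t_min = 1.0,
                              annealing_factor = 0.6, seed = 1L,
                              move_par = default_move_par()) {
  n_macrocycles <- as.integer(n_macrocycles)
  if (is.na(n_macrocycles) || n_macrocycles < 1L || n_macrocycles > 200L) {
    stop("n_macrocycles must be between 1 and 200", call. = FALSE)
  }
  stopifnot(n_replicas >= 1, snapshots_per_macrocycle >= 1,
            moves_per_snapshot >= 1, t_max >= t_min, t_min > 0,
            annealing_factor > 0, annealing_factor <= 1)
  structure(list(n_replicas = as.integer(n_replicas),
                 n_macrocycles = n_macrocycles,
                 snapshots_per_macrocycle = as.integer(snapshots_per_macrocycle),
                 moves_per_snapshot = as.integer(moves_per_snapshot),
                 t_max = t_max, t_min = t_min,
                 annealing_factor = annealing_factor,
                 seed = as.integer(seed), move_par = move_par),
            class = "simulation_config")
}

#' Default Monte Carlo move-kernel parameters
#'
#' @param d_single max single-residue peptide displacement (A).
#' @param d_rigid_t max rigid-body peptide translation (A).
#' @param a_rigid max rigid-body rotation angle (degrees).
#' @param a_crank max crankshaft rotation angle (degrees).
#' @param d_receptor max receptor single-Calpha displacement (A).
#' @param bond_lo,bond_hi hard virtual-bond tolerance window (A); proposals
#'   leaving it are rejected outright.
#' @param receptor_moves allow receptor Calpha moves (restraints supply the
#'   stiffness that keeps the receptor near-native).
#' @param wall_radius radius of the hard spherical wall confining the
#'   peptide centroid (the simulation volume). `Inf` disables it; during
#'   docking runs it is set to the initialization-sphere radius.
#' @param wall_center center of the wall (receptor centroid during runs).
#' @return named list.
#' @export
default_move_par <- function(d_single = 0.7, d_rigid_t = 2.0, a_rigid = 30,
                             a_crank = 60, d_receptor = 0.5,
                             bond_lo = CA_BOND - CA_BOND_TOL,
                             bond_hi = CA_BOND + CA_BOND_TOL,
                             receptor_moves = TRUE, wall_radius = Inf,
                             wall_center = c(0, 0, 0)) {
  list(d_single = d_single, d_rigid_t = d_rigid_t,
       a_rigid = a_rigid * pi / 180, a_crank = a_crank * pi / 180,
       d_receptor = d_receptor, bond_lo = bond_lo, bond_hi = bond_hi,
       receptor_moves = receptor_moves, wall_radius = wall_radius,
       wall_center = as.numeric(wall_center))
}

#' Build the replica temperature ladder
#'
#' Temperatures are linearly interpolated between `t_max` and `t_min`
#' inclusive, strictly decreasing with replica index (replica 1 is hottest).
#'
#' @param cfg a `simulation_config`, or NULL to pass bounds directly.
#' @param t_max,t_min,n_replicas used when `cfg` is NULL.
#' @return numeric vector of temperatures.
#' @export
build_ladder <- function(cfg = NULL, t_max = 3.5, t_min = 1.0,
                         n_replicas = 10L) {
  if (!is.null(cfg)) {
    t_max <- cfg$t_max; t_min <- cfg$t_min; n_replicas <- cfg$n_replicas
  }
  if (n_replicas == 1L) return((t_max + t_min) / 2)
  seq(t_max, t_min, length.out = n_replicas)
}

#' Annealing scale factor at a given macrocycle
#'
#' Multiplicative schedule: the ladder at macrocycle `m` (1-based) is the
#' initial ladder times `annealing_factor^((m-1)/(M-1))`, reaching exactly
#' `annealing_factor` at the final macrocycle.
#'
#' @param m macrocycle index, 1-based.
#' @param n_macrocycles total macrocycles M.
#' @param annealing_factor final/initial scale.
#' @return scalar scale factor.
#' @export
annealing_scale <- function(m, n_macrocycles, annealing_factor = 0.6) {
  stopifnot(m >= 1, m <= n_macrocycles)
  if (n_macrocycles == 1L) return(1.0)
  annealing_factor^((m - 1) / (n_macrocycles - 1))
}

#' Metropolis acceptance decision
#'
#' Accept with probability `min(1, exp(-delta_e / temperature))`. Vectorized;
#' consumes one uniform variate per decision.
#'
#' @param delta_e proposed energy change(s).
#' @param temperature reduced temperature(s) > 0.
#' @return logical vector.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  n <- max(length(delta_e), length(temperature))
  stats::runif(n) < pmin(1, exp(-delta_e / temperature))
}

#' Replica-exchange acceptance decision
#'
#' Swap configurations of two replicas with probability
#' `min(1, exp((1/t_a - 1/t_b) * (e_a - e_b)))`.
#'
#' @param e_a,e_b total energies of the two replicas.
#' @param t_a,t_b their temperatures.
#' @return logical vector.
#' @export
exchange_accept <- function(e_a, e_b, t_a, t_b) {
  p <- pmin(1, exp((1 / t_a - 1 / t_b) * (e_a - e_b)))
  stats::runif(length(p)) < p
}

# internal state <-> cg_complex helpers -------------------------------------

#' @noRd
.state_from_complex <- function(complex) {
  list(ca_r = complex$receptor$ca, sc_r = complex$receptor$sc,
       ca_p = complex$peptide$ca, sc_p = complex$peptide$sc,
       energy = NULL)
}

#' @noRd
.complex_from_state <- function(state, template) {
  r <- template$receptor; p <- template$peptide
  r$ca <- state$ca_r; r$sc <- state$sc_r
  p$ca <- state$ca_p; p$sc <- state$sc_p
  cg_complex(r, p)
}

# prepacked arguments for the compiled kernel
#' @noRd
.core_args <- function(template, model, restraints, excluded) {
  r <- template$receptor; p <- template$peptide
  excl <- rep(FALSE, nrow(r$ca))
  if (!is.null(excluded)) excl[excluded] <- TRUE
  list(type_r = aa_index(strsplit(r$sequence, "")[[1]]),
       type_p = aa_index(strsplit(p$sequence, "")[[1]]),
       cmat = model$contact_matrix,
       rest_i = as.integer(restraints$i), rest_j = as.integer(restraints$j),
       rest_d = as.numeric(restraints$d_ref),
       rest_tol = as.numeric(restraints$tolerance),
       rest_slope = as.numeric(restraints$slope),
       excluded = excl, ss_p = .ss_codes(p$ss),
       chain_idx_r = as.integer(r$chain_index),
       scd_p = unname(SC_DISTANCE[strsplit(p$sequence, "")[[1]]]),
       par = .energy_par(model))
}

#' Apply Metropolis Monte Carlo moves to a pose
#'
#' Runs `n_moves` attempted moves of the sampler's move kernel (peptide
#' single-residue displacement, 2-4 residue crankshaft, rigid-body peptide
#' move, receptor single-Calpha displacement) at a fixed temperature.
#' Proposals that break the virtual-bond tolerance are rejected outright.
#'
#' @param complex a `cg_complex`.
#' @param temperature reduced temperature.
#' @param model an `energy_model`.
#' @param restraints a `restraint_set`.
#' @param excluded receptor residues marked unlikely to bind (indices).
#' @param n_moves number of attempted moves (default 1).
#' @param move_par see [default_move_par()].
#' @return list with `complex` (updated pose), `energy` (named vector) and
#'   `n_accept`.
#' @export
mc_move <- function(complex, temperature, model = energy_model(),
                    restraints = .empty_restraints(), excluded = NULL,
                    n_moves = 1L, move_par = default_move_par()) {
  stopifnot(inherits(complex, "cg_complex"))
  a <- .core_args(complex, model, restraints, excluded)
  st <- .state_from_complex(complex)
  res <- .cpp_mc_run(st$ca_r, st$sc_r, st$ca_p, st$sc_p,
                     a$type_r, a$type_p, a$cmat, a$rest_i, a$rest_j,
                     a$rest_d, a$rest_tol, a$rest_slope, a$excluded, a$ss_p,
                     a$chain_idx_r, a$scd_p, a$par, temperature,
                     as.integer(n_moves), move_par)
  list(complex = .complex_from_state(res, complex),
       energy = res$energy, n_accept = res$n_accept)
}

#' Run the replica-exchange docking simulation
#'
#' Each replica starts from an independent random peptide conformation
#' placed on the initialization sphere. Per macrocycle the ladder is
#' annealed, each replica performs `moves_per_snapshot` attempted moves per
#' snapshot interval, exchanges are attempted between adjacent replicas
#' (alternating even/odd pairs) after every interval, and a snapshot is
#' recorded per replica. Returns `n_replicas` trajectories of
#' `n_macrocycles * snapshots_per_macrocycle` snapshots each.
#'
#' @param receptor a `cg_chain` (from [build_cg()]).
#' @param peptide a `peptide_spec` (from [validate_peptide()]).
#' @param restraints a `restraint_set`; default: generated from the receptor
#'   with all-rigid marks.
#' @param model an `energy_model`.
#' @param config a `simulation_config`.
#' @param excluded receptor residues marked unlikely to bind (indices).
#' @return list of `trajectory` objects, each with fields `replica_index`,
#'   `snapshots` (list of `cg_snapshot`) and `sidecar` (data.frame).
#' @export
run_docking <- function(receptor, peptide, restraints = NULL,
                        model = energy_model(),
                        config = simulation_config(), excluded = NULL) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(peptide, "peptide_spec"),
            inherits(config, "simulation_config"))
  if (is.null(restraints)) {
    restraints <- generate_restraints(receptor, model = model)
  }
  set.seed(config$seed)
  K <- config$n_replicas
  M <- config$n_macrocycles
  S <- config$snapshots_per_macrocycle
  temps0 <- build_ladder(config)
  # confine the peptide to the initialization sphere around the receptor
  move_par <- config$move_par
  if (!is.finite(move_par$wall_radius)) {
    move_par$wall_radius <- longest_dimension(receptor) + 20
    move_par$wall_center <- colMeans(receptor$ca)
  }

  # independent random start per replica
  states <- vector("list", K)
  template <- NULL
  for (r in seq_len(K)) {
    conf <- random_peptide_conformation(peptide)
    cx <- place_on_sphere(conf, receptor)
    if (is.null(template)) template <- cx
    states[[r]] <- .state_from_complex(cx)
  }
  a <- .core_args(template, model, restraints, excluded)
  for (r in seq_len(K)) {
    states[[r]]$energy <- .cpp_energy(states[[r]]$ca_r, states[[r]]$sc_r,
                                      states[[r]]$ca_p, states[[r]]$sc_p,
                                      a$type_r, a$type_p, a$cmat,
                                      a$rest_i, a$rest_j, a$rest_d,
                                      a$rest_tol, a$rest_slope,
                                      a$excluded, a$ss_p, a$par)
  }

  snapshots <- vector("list", K)
  for (r in seq_len(K)) snapshots[[r]] <- vector("list", M * S)
  sidecar <- vector("list", K)

  interval <- 0L
  for (m in seq_len(M)) {
    temps <- temps0 * annealing_scale(m, M, config$annealing_factor)
    for (s in seq_len(S)) {
      interval <- interval + 1L
      for (r in seq_len(K)) {
        st <- states[[r]]
        res <- .cpp_mc_run(st$ca_r, st$sc_r, st$ca_p, st$sc_p,
                           a$type_r, a$type_p, a$cmat, a$rest_i, a$rest_j,
                           a$rest_d, a$rest_tol, a$rest_slope, a$excluded,
                           a$ss_p, a$chain_idx_r, a$scd_p, a$par, temps[r],
                           config$moves_per_snapshot, move_par)
        states[[r]] <- list(ca_r = res$ca_r, sc_r = res$sc_r,
                            ca_p = res$ca_p, sc_p = res$sc_p,
                            energy = res$energy)
      }
      # exchange sweep over adjacent pairs, alternating even/odd
      if (K > 1) {
        first <- if (interval %% 2L == 1L) 1L else 2L
        pairs <- if (first <= K - 1L) seq(first, K - 1L, by = 2L) else integer(0)
        for (pr in pairs) {
          ea <- states[[pr]]$energy[["total"]]
          eb <- states[[pr + 1L]]$energy[["total"]]
          if (exchange_accept(ea, eb, temps[pr], temps[pr + 1L])) {
            tmp <- states[[pr]]
            states[[pr]] <- states[[pr + 1L]]
            states[[pr + 1L]] <- tmp
          }
        }
      }
      # record one snapshot per replica
      idx <- (m - 1L) * S + s
      for (r in seq_len(K)) {
        cx <- .complex_from_state(states[[r]], template)
        en <- states[[r]]$energy
        snapshots[[r]][[idx]] <- cg_snapshot(
          cx, replica_index = r, macrocycle_index = m, snapshot_index = idx,
          temperature = temps[r],
          energy = c(total = en[["total"]], binding = en[["binding"]],
                     restraint = en[["restraint"]]))
      }
    }
  }

  lapply(seq_len(K), function(r) {
    sc <- do.call(rbind, lapply(snapshots[[r]], function(s) {
      data.frame(replica = r, macrocycle = s$macrocycle_index,
                 snapshot = s$snapshot_index, temperature = s$temperature,
                 e_total = s$energy[["total"]],
                 e_binding = s$energy[["binding"]],
                 e_restraint = s$energy[["restraint"]],
                 bound = is_bound(s$complex, model$bound_cutoff))
    }))
    structure(list(replica_index = r, snapshots = snapshots[[r]],
                   sidecar = sc), class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> replica %d, %d snapshots (%d bound)\n",
              x$replica_index, length(x$snapshots), sum(x$sidecar$bound)))
  invisible(x)
}

#' Write a trajectory as a multi-MODEL Calpha PDB plus a TSV sidecar
#'
#' @param traj a `trajectory`.
#' @param pdb_path,tsv_path output paths.
#' @export
write_trajectory <- function(traj, pdb_path, tsv_path) {
  write_models_pdb(lapply(traj$snapshots, `[[`, "complex"), pdb_path)
  utils::write.table(traj$sidecar, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}
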