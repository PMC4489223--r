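# End-to-end orchestration: validated input -> coarse-graining -> restraints
# -> replica-exchange docking -> filtering -> consensus clustering ->
# evaluation outputs, plus a thin command-line surface.

#' Docking job configuration
#'
#' @param receptor_path path to the receptor PDB file.
#' @param peptide_sequence one-letter peptide sequence (<= 30 aa).
#' @param peptide_ss optional secondary-structure string over `{H,E,C}`;
#'   all-coil when omitted.
#' @param n_macrocycles Monte Carlo macrocycles, 1-200 (default 50).
#' @param seed integer seed.
#' @param flexibility optional list with elements `moderate` and/or `full`
#'   holding receptor residue indices (1-based global index).
#' @param excluded_residues receptor residues unlikely to bind (indices).
#' @param contact_cutoff contact-map cutoff in A (default 6.5).
#' @param output_dir result directory.
#' @param project_name optional label recorded in the log.
#' @param n_replicas,snapshots_per_macrocycle,moves_per_snapshot,t_max,t_min,annealing_factor
#'   sampler settings forwarded to [simulation_config()].
#' @return a `job_config` object.
#' @export
job_config <- function(receptor_path, peptide_sequence, peptide_ss = NULL,
                       n_macrocycles = 50L, seed = 1L, flexibility = NULL,
                       excluded_residues = NULL, contact_cutoff = 6.5,
                       output_dir = tempfile("pepdock_job_"),
                       project_name = NULL, n_replicas = 10L,
                       snapshots_per_macrocycle = 20L,
                       moves_per_snapshot = 300L, t_max = 3.5, t_min = 1.0,
                       annealing_factor = 0.6) {
  sim <- simulation_config(n_replicas = n_replicas,
                           n_macrocycles = n_macrocycles,
                           snapshots_per_macrocycle = snapshots_per_macrocycle,
                           moves_per_snapshot = moves_per_snapshot,
                           t_max = t_max, t_min = t_min,
                           annealing_factor = annealing_factor, seed = seed)
  peptide <- validate_peptide(peptide_sequence, peptide_ss)
  structure(list(receptor_path = receptor_path, peptide = peptide,
                 sim = sim, flexibility = flexibility,
                 excluded_residues = excluded_residues,
                 contact_cutoff = contact_cutoff, output_dir = output_dir,
                 project_name = project_name),
            class = "job_config")
}

#' @noRd
.write_log <- function(cfg, status, path, extra = character(0)) {
  sim <- cfg$sim
  fmt_idx <- function(x) paste(x, collapse = ",")
  lines <- c(
    sprintf("pepdock_version=%s", as.character(utils::packageVersion("pepdock"))),
    sprintf("r_version=%s", R.version.string),
    sprintf("project=%s", if (is.null(cfg$project_name)) "" else cfg$project_name),
    sprintf("receptor=%s", cfg$receptor_path),
    sprintf("peptide=%s", cfg$peptide$sequence),
    sprintf("peptide_ss=%s", cfg$peptide$ss),
    sprintf("seed=%d", sim$seed),
    sprintf("n_replicas=%d", sim$n_replicas),
    sprintf("n_macrocycles=%d", sim$n_macrocycles),
    sprintf("snapshots_per_macrocycle=%d", sim$snapshots_per_macrocycle),
    sprintf("moves_per_snapshot=%d", sim$moves_per_snapshot),
    sprintf("t_max=%g", sim$t_max),
    sprintf("t_min=%g", sim$t_min),
    sprintf("annealing_factor=%g", sim$annealing_factor),
    sprintf("flexible_moderate=%s", fmt_idx(cfg$flexibility$moderate)),
    sprintf("flexible_full=%s", fmt_idx(cfg$flexibility$full)),
    sprintf("excluded_residues=%s", fmt_idx(cfg$excluded_residues)),
    sprintf("contact_cutoff=%g", cfg$contact_cutoff),
    sprintf("status=%s", status),
    extra)
  writeLines(lines, path)
}

#' Read a flat key=value job log or config file
#' @param path file path.
#' @return named character vector.
#' @export
read_job_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

#' Run a complete docking job
#'
#' Executes read/validate -> coarse-graining -> restraint generation ->
#' replica-exchange annealing -> bound-state filtering -> consensus
#' clustering -> contact maps, and writes a self-describing result directory
#' (final models, cluster report, trajectories with TSV sidecars, restraint
#' list, contact maps, and a log sufficient to recreate the run).
#'
#' @param cfg a `job_config`.
#' @param model an `energy_model` (default [energy_model()]).
#' @param write_trajectories write per-replica trajectory PDBs (default TRUE;
#'   disable to save disk in large scans).
#' @return a `job_result`: list with `status` (one of `"done"`,
#'   `"failed_no_bound_states"`), `final` (`final_model_set` or NULL),
#'   `filtered`, `trajectories`, `receptor_cg`, `restraints`, `cfg`,
#'   `model`, `output_dir`.
#' @export
run_job <- function(cfg, model = energy_model(), write_trajectories = TRUE) {
  stopifnot(inherits(cfg, "job_config"))
  s <- read_pdb(cfg$receptor_path)
  s <- normalize_nonstandard(s)
  validate_receptor(s)
  receptor <- build_cg(s)
  n <- nrow(receptor$ca)
  marked <- c(unlist(cfg$flexibility, use.names = FALSE), cfg$excluded_residues)
  if (length(marked) > 0 && (min(marked) < 1 || max(marked) > n)) {
    stop("marked residue index outside receptor (1..", n, ")", call. = FALSE)
  }
  restraints <- generate_restraints(receptor, marks = cfg$flexibility,
                                    model = model)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  write_restraints_tsv(restraints, out("restraints.tsv"))

  trajectories <- run_docking(receptor, cfg$peptide, restraints, model,
                              cfg$sim, excluded = cfg$excluded_residues)
  if (write_trajectories) {
    dir.create(out("trajectories"), showWarnings = FALSE)
    for (tr in trajectories) {
      write_trajectory(tr,
                       out("trajectories", sprintf("replica_%02d.pdb",
                                                   tr$replica_index)),
                       out("trajectories", sprintf("replica_%02d.tsv",
                                                   tr$replica_index)))
    }
  }

  filtered <- filter_models(trajectories, cutoff = model$bound_cutoff)
  if (length(filtered$models) == 0) {
    .write_log(cfg, "failed_no_bound_states", out("log.txt"))
    return(structure(list(status = "failed_no_bound_states", final = NULL,
                          filtered = filtered, trajectories = trajectories,
                          receptor_cg = receptor, restraints = restraints,
                          cfg = cfg, model = model,
                          output_dir = cfg$output_dir),
                     class = "job_result"))
  }

  final <- consensus_cluster(filtered, k = 10L, n_restarts = 100L)

  # post-hoc exclusion filter: drop final models contacting excluded residues
  dropped <- integer(0)
  if (length(cfg$excluded_residues) > 0) {
    touches <- vapply(final$medoids, function(m) {
      cm <- contact_map(m, cfg$contact_cutoff)
      any(cm$contacts$receptor_index %in% cfg$excluded_residues)
    }, logical(1))
    dropped <- which(touches)
  }
  kept <- setdiff(seq_along(final$medoids), dropped)

  dir.create(out("models"), showWarnings = FALSE)
  dir.create(out("contact_maps"), showWarnings = FALSE)
  for (c_i in kept) {
    write_models_pdb(final$medoids[[c_i]]$complex,
                     out("models", sprintf("model_%02d.pdb", c_i)))
    write_contact_map_tsv(contact_map(final$medoids[[c_i]],
                                      cfg$contact_cutoff),
                          out("contact_maps",
                              sprintf("model_%02d_contacts.tsv", c_i)))
  }
  write_cluster_report(final, out("clusters.tsv"),
                       provenance = filtered$provenance)
  .write_log(cfg, "done", out("log.txt"),
             extra = c(sprintf("n_filtered_models=%d", length(filtered$models)),
                       sprintf("excluded_final_models=%s",
                               paste(dropped, collapse = ","))))
  structure(list(status = "done", final = final, filtered = filtered,
                 trajectories = trajectories, receptor_cg = receptor,
                 restraints = restraints, cfg = cfg, model = model,
                 dropped_final_models = dropped,
                 output_dir = cfg$output_dir),
            class = "job_result")
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("<job_result> status: %s, %d final model(s), output: %s\n",
              x$status,
              if (is.null(x$final)) 0L else length(x$final$medoids),
              x$output_dir))
  invisible(x)
}

#' Derive a resubmission config that excludes the binding modes of marked models
#'
#' Receptor residues contacting the peptides of the marked final models (at
#' the job's contact cutoff) are added to the unlikely-to-bind list of a new
#' job configuration; during resimulation those contacts are penalized and
#' final models touching them are filtered out.
#'
#' @param result a `job_result` with status `"done"`.
#' @param excluded_model_ids indices (1..k) of final models to exclude.
#' @param seed seed for the new job (default: previous seed + 1).
#' @return a new `job_config`.
#' @export
resubmit_with_exclusions <- function(result, excluded_model_ids,
                                     seed = NULL) {
  stopifnot(inherits(result, "job_result"), result$status == "done")
  cfg <- result$cfg
  new_excluded <- cfg$excluded_residues
  for (id in excluded_model_ids) {
    cm <- contact_map(result$final$medoids[[id]], cfg$contact_cutoff)
    if (nrow(cm$contacts) == 0) {
      warning(sprintf("marked model %d has no receptor contacts; exclusion list unchanged", id))
      next
    }
    new_excluded <- union(new_excluded, cm$contacts$receptor_index)
  }
  job_config(receptor_path = cfg$receptor_path,
             peptide_sequence = cfg$peptide$sequence,
             peptide_ss = cfg$peptide$ss,
             n_macrocycles = cfg$sim$n_macrocycles,
             seed = if (is.null(seed)) cfg$sim$seed + 1L else seed,
             flexibility = cfg$flexibility,
             excluded_residues = sort(new_excluded),
             contact_cutoff = cfg$contact_cutoff,
             output_dir = paste0(cfg$output_dir, "_resubmit"),
             project_name = cfg$project_name,
             n_replicas = cfg$sim$n_replicas,
             snapshots_per_macrocycle = cfg$sim$snapshots_per_macrocycle,
             moves_per_snapshot = cfg$sim$moves_per_snapshot,
             t_max = cfg$sim$t_max, t_min = cfg$sim$t_min,
             annealing_factor = cfg$sim$annealing_factor)
}

#' Benchmark a job result against a reference complex
#'
#' Reports the best ligand RMSD and quality class over all snapshots
#' ("all") and over the final models ("top 10").
#'
#' @param result a `job_result`.
#' @param reference a `cg_complex` reference pose, or a path to a Calpha PDB
#'   whose peptide chain is identified by `peptide_chain` (default: the
#'   chain whose length matches the peptide).
#' @param peptide_chain optional chain ID of the peptide in the reference.
#' @return one-row data.frame: `best_all_rmsd`, `class_all`,
#'   `best_top10_rmsd`, `class_top10`, `n_models_all`, `n_models_top10`.
#' @export
evaluate_against_reference <- function(result, reference,
                                       peptide_chain = NULL) {
  stopifnot(inherits(result, "job_result"))
  if (is.character(reference)) {
    reference <- .reference_from_pdb(reference, result, peptide_chain)
  }
  reference <- .as_complex(reference)
  all_models <- unlist(lapply(result$trajectories, `[[`, "snapshots"),
                       recursive = FALSE)
  best_all <- best_of_set(all_models, reference)
  top <- if (is.null(result$final)) list() else result$final$medoids
  best_top <- best_of_set(top, reference)
  data.frame(best_all_rmsd = best_all$rmsd,
             class_all = if (is.na(best_all$rmsd)) NA_character_ else best_all$class,
             best_top10_rmsd = best_top$rmsd,
             class_top10 = if (is.na(best_top$rmsd)) NA_character_ else best_top$class,
             n_models_all = length(all_models),
             n_models_top10 = length(top))
}

# rebuild a cg_complex reference from a Calpha PDB written by this package
#' @noRd
.reference_from_pdb <- function(path, result, peptide_chain = NULL) {
  m <- read_ca_models(path)[[1]]
  np <- nchar(result$cfg$peptide$sequence)
  if (is.null(peptide_chain)) {
    lens <- table(m$chain)
    cand <- names(lens)[lens == np]
    if (length(cand) != 1) {
      stop("cannot identify the peptide chain in ", path,
           "; pass peptide_chain", call. = FALSE)
    }
    peptide_chain <- cand
  }
  is_p <- m$chain == peptide_chain
  rec <- result$receptor_cg
  rec$ca <- m$ca[!is_p, , drop = FALSE]
  rec$sc <- .sc_from_ca(rec$ca, rec$sequence)
  pep_seq <- result$cfg$peptide$sequence
  pep_ca <- m$ca[is_p, , drop = FALSE]
  pep <- cg_chain(pep_ca, .sc_from_ca(pep_ca, pep_seq), pep_seq,
                  ss = result$cfg$peptide$ss, chain_id = rep("P", np),
                  check = FALSE)
  cg_complex(rec, pep)
}

# recreate a finished job in memory from its logged config + seed
#' @noRd
.rerun_from_log <- function(job_dir) {
  log <- read_job_log(file.path(job_dir, "log.txt"))
  cfg <- job_config(
    receptor_path = log[["receptor"]],
    peptide_sequence = log[["peptide"]],
    peptide_ss = log[["peptide_ss"]],
    n_macrocycles = as.integer(log[["n_macrocycles"]]),
    seed = as.integer(log[["seed"]]),
    excluded_residues = .parse_idx(log[["excluded_residues"]]),
    contact_cutoff = as.numeric(log[["contact_cutoff"]]),
    output_dir = job_dir,
    n_replicas = as.integer(log[["n_replicas"]]),
    snapshots_per_macrocycle = as.integer(log[["snapshots_per_macrocycle"]]),
    moves_per_snapshot = as.integer(log[["moves_per_snapshot"]]),
    t_max = as.numeric(log[["t_max"]]),
    t_min = as.numeric(log[["t_min"]]),
    annealing_factor = as.numeric(log[["annealing_factor"]]))
  run_job(cfg, write_trajectories = FALSE)
}

# --- command-line surface ---------------------------------------------------

#' @noRd
.parse_flags <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' @noRd
.parse_idx <- function(x) {
  if (is.null(x)) return(NULL)
  as.integer(strsplit(x, ",")[[1]])
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{dock}{`dock <receptor.pdb> <PEPTIDE> [--ss HEC...] [--macrocycles N]
#'     [--seed N] [--flexible "5:moderate,7:full"] [--exclude "3,4"]
#'     [--contact-cutoff X] [--out DIR] [--project NAME] [--replicas N]
#'     [--moves N]`}
#'   \item{evaluate}{`evaluate --job DIR --reference ref.pdb
#'     [--peptide-chain C]` — recreates the job from its log (runs are
#'     seed-reproducible) and writes `evaluation.tsv` with the best ligand
#'     RMSD and quality class over all models and over the 10 finals.}
#'   \item{resubmit}{`resubmit --job DIR --exclude-models "1,2"` — reruns the
#'     logged job with contact-derived exclusions.}
#' }
#' Run from `Rscript -e 'pepdock::pepdock_cli()' ...`.
#'
#' @param args character vector of CLI arguments (default: command line).
#' @return exit status, invisibly (0 on success).
#' @export
pepdock_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: pepdock <dock|resubmit> ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  fl <- .parse_flags(args[-1])
  if (cmd == "dock") {
    if (length(fl$positional) < 2) {
      stop("dock requires a receptor PDB path and a peptide sequence",
           call. = FALSE)
    }
    flex <- NULL
    if (!is.null(fl$flexible)) {
      parts <- strsplit(strsplit(fl$flexible, ",")[[1]], ":")
      flex <- list(
        moderate = as.integer(vapply(
          Filter(function(p) length(p) < 2 || p[2] == "moderate", parts),
          `[`, character(1), 1)),
        full = as.integer(vapply(
          Filter(function(p) length(p) == 2 && p[2] == "full", parts),
          `[`, character(1), 1)))
    }
    cfg <- job_config(
      receptor_path = fl$positional[1],
      peptide_sequence = fl$positional[2],
      peptide_ss = if (is.null(fl$ss)) NULL else fl$ss,
      n_macrocycles = if (is.null(fl$macrocycles)) 50L else as.integer(fl$macrocycles),
      seed = if (is.null(fl$seed)) 1L else as.integer(fl$seed),
      flexibility = flex,
      excluded_residues = .parse_idx(fl$exclude),
      contact_cutoff = if (is.null(fl[["contact-cutoff"]])) 6.5 else as.numeric(fl[["contact-cutoff"]]),
      output_dir = if (is.null(fl$out)) "pepdock_out" else fl$out,
      project_name = fl$project,
      n_replicas = if (is.null(fl$replicas)) 10L else as.integer(fl$replicas),
      moves_per_snapshot = if (is.null(fl$moves)) 300L else as.integer(fl$moves))
    res <- run_job(cfg)
    message(sprintf("status: %s (results in %s)", res$status, res$output_dir))
    return(invisible(if (res$status == "done") 0L else 1L))
  }
  if (cmd == "evaluate") {
    if (is.null(fl$job) || is.null(fl$reference)) {
      stop("evaluate requires --job DIR and --reference PDB", call. = FALSE)
    }
    res <- .rerun_from_log(fl$job)
    rep <- evaluate_against_reference(
      res, fl$reference,
      peptide_chain = if (is.null(fl[["peptide-chain"]])) NULL
                      else fl[["peptide-chain"]])
    utils::write.table(rep, file.path(fl$job, "evaluation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    print(rep, row.names = FALSE)
    return(invisible(0L))
  }
  if (cmd == "resubmit") {
    if (is.null(fl$job) || is.null(fl[["exclude-models"]])) {
      stop("resubmit requires --job DIR and --exclude-models ids", call. = FALSE)
    }
    res <- .rerun_from_log(fl$job)
    if (res$status != "done") {
      message("original job reproduces no bound states; nothing to resubmit")
      return(invisible(1L))
    }
    cfg2 <- resubmit_with_exclusions(res, .parse_idx(fl[["exclude-models"]]))
    res2 <- run_job(cfg2)
    message(sprintf("resubmitted status: %s (results in %s)",
                    res2$status, res2$output_dir))
    return(invisible(if (res2$status == "done") 0L else 1L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
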