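#' Experiment-matrix configuration
#'
#' Defaults mirror the published design: a main block of 8 peptides
#' (P1-P7, CPP) x 2 modes x 3 velocities x 8 replicates (384 runs); an
#' auxiliary block of 22 series x 8 replicates (5 homo-repeats x 2 modes
#' x 2 velocities = 20 series, the low 0.01 A/ps rate not being run for
#' the homo-repeats, plus lipid direct and reverse pulls = 2 series; 176
#' runs); and a control block repeating P2 and P4 over all 6 conditions
#' x 8 replicates (96 runs) -- 656 runs in total.
#'
#' @param main_peptides,aux_peptides,control_peptides Peptide id vectors.
#' @param velocities Wall velocities, A/ps.
#' @param aux_velocities Velocities for the homo-repeat block.
#' @param modes Pulling modes.
#' @param n_realizations Replicates per condition.
#' @param lipid_series Lipid-pull series ids.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(
    main_peptides = c(paste0("P", 1:7), "CPP"),
    aux_peptides = c("PolyAla", "PolyLeu", "PolyMet", "PolyArg", "PolyGlu"),
    control_peptides = c("P2", "P4"),
    velocities = c(0.1, 0.05, 0.01),
    aux_velocities = c(0.1, 0.05),
    modes = c("com", "atom"),
    n_realizations = 8L,
    lipid_series = c("LipidDirect", "LipidReverse")) {
  structure(list(main_peptides = main_peptides,
                 aux_peptides = aux_peptides,
                 control_peptides = control_peptides,
                 velocities = velocities,
                 aux_velocities = aux_velocities,
                 modes = modes,
                 n_realizations = as.integer(n_realizations),
                 lipid_series = lipid_series),
            class = "experiment_config")
}

#' Enumerate the full experiment plan
#'
#' Pure function of the configuration: a deterministic, duplicate-free
#' table of run specifications partitioned into main, auxiliary and
#' control blocks, with stable ids and per-run seeds derived from the
#' master seed.
#'
#' @param config An [experiment_config].
#' @param master_seed Integer master seed.
#' @return An `experiment_plan`: data.frame with columns `run_id, block,
#'   peptide, mode, velocity, replicate, seed`.
#' @examples
#' plan <- enumerate_plan()
#' nrow(plan)  # 656
#' @export
enumerate_plan <- function(config = experiment_config(), master_seed = 1L) {
  reps <- seq_len(config$n_realizations)
  blocks <- list(
    main = expand.grid(peptide = config$main_peptides,
                       mode = config$modes,
                       velocity = config$velocities,
                       replicate = reps, stringsAsFactors = FALSE),
    auxiliary = rbind(
      expand.grid(peptide = config$aux_peptides, mode = config$modes,
                  velocity = config$aux_velocities, replicate = reps,
                  stringsAsFactors = FALSE),
      expand.grid(peptide = config$lipid_series, mode = "com",
                  velocity = 0.1, replicate = reps,
                  stringsAsFactors = FALSE)),
    control = expand.grid(peptide = config$control_peptides,
                          mode = config$modes,
                          velocity = config$velocities,
                          replicate = reps, stringsAsFactors = FALSE))
  plan <- do.call(rbind, lapply(names(blocks), function(b) {
    d <- blocks[[b]]
    if (nrow(d) == 0) return(NULL)
    d$block <- b
    d
  }))
  if (is.null(plan) || nrow(plan) == 0) stop("empty experiment plan")
  ord <- order(match(plan$block, c("main", "auxiliary", "control")),
               match(plan$peptide, unique(plan$peptide)),
               plan$mode, -plan$velocity, plan$replicate)
  plan <- plan[ord, ]
  plan$run_id <- sprintf("%s_%s_%s_v%g_r%d",
                         substr(plan$block, 1, 4), plan$peptide,
                         plan$mode, plan$velocity, plan$replicate)
  if (anyDuplicated(plan$run_id)) stop("duplicate run ids in plan")
  plan$seed <- vapply(plan$run_id, seed_for, numeric(1),
                      master_seed = master_seed)
  plan <- plan[, c("run_id", "block", "peptide", "mode", "velocity",
                   "replicate", "seed")]
  rownames(plan) <- NULL
  class(plan) <- c("experiment_plan", "data.frame")
  plan
}

#' Stable per-run seed
#'
#' FNV-1a hash of the master seed and run id, folded to a positive
#' 31-bit integer: the same inputs give the same seed on every platform,
#' and distinct runs get distinct streams.
#'
#' @param run_id Character run identifier.
#' @param master_seed Integer master seed.
#' @return Numeric seed in [1, 2^31 - 1].
#' @export
seed_for <- function(run_id, master_seed = 1L) {
  key <- paste0(master_seed, ":", run_id)
  # polynomial rolling hash over the Mersenne prime 2^31 - 1, computed in
  # doubles (intermediates stay below 2^53, so arithmetic is exact)
  h <- 0
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% 2147483647
  }
  h + 1
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %d runs (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$block)),
                            table(x$block)), collapse = ", ")))
  invisible(x)
}

#' Execute an experiment plan
#'
#' For each run: build (or reuse a cached) system for the run's peptide,
#' execute the pulling run, and write a trace TSV plus a JSON manifest
#' into `out_dir`. Runs whose manifest already exists are skipped, so an
#' interrupted plan resumes. Individual failures are flagged in the
#' summary, not fatal.
#'
#' @param plan An `experiment_plan` (usually a small subset of one).
#' @param out_dir Output directory.
#' @param sequences Named list of [pep_seq] (default [study_peptides]).
#' @param cfg A [build_config] (desk-scale mini-membrane defaults).
#' @param ff A `forcefield`.
#' @param template Lipid template.
#' @param n_steps Steps per run.
#' @param k Spring stiffness, kJ/mol/A^2.
#' @param thermostat A [thermostat_params].
#' @param sample_every Trace sampling stride.
#' @return Data.frame summary: one row per run with `max_force` and
#'   status, invisibly also written as `summary.tsv`.
#' @export
run_pipeline <- function(plan, out_dir, sequences = study_peptides(),
                         cfg = build_config(n_y = 4, n_z = 4),
                         ff = toy_forcefield(),
                         template = make_minilipid_template(),
                         n_steps = 2000L, k = 100,
                         thermostat = thermostat_params(),
                         sample_every = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys_cache <- new.env(parent = emptyenv())
  get_system <- function(peptide) {
    if (!is.null(sys_cache[[peptide]])) return(sys_cache[[peptide]])
    sys <- if (startsWith(peptide, "Lipid")) {
      build_system(NULL, cfg, template, solvent = FALSE)
    } else {
      build_system(sequences[[peptide]], cfg, template, solvent = FALSE)
    }
    sys_cache[[peptide]] <- sys
    sys
  }
  rows <- list()
  for (r in seq_len(nrow(plan))) {
    run <- plan[r, ]
    manifest_path <- file.path(out_dir, paste0(run$run_id, ".json"))
    trace_path <- file.path(out_dir, paste0(run$run_id, ".tsv"))
    if (file.exists(manifest_path)) {
      prev <- jsonlite::read_json(manifest_path)
      rows[[r]] <- data.frame(run_id = run$run_id, peptide = run$peptide,
                              mode = run$mode, velocity = run$velocity,
                              replicate = run$replicate,
                              max_force = as.numeric(prev$max_force),
                              status = "cached")
      next
    }
    res <- tryCatch({
      sys <- get_system(run$peptide)
      is_lipid_pull <- startsWith(run$peptide, "Lipid")
      dirn <- if (identical(run$peptide, "LipidReverse")) {
        c(1, 0, 0)   # outward, toward the head side
      } else {
        c(-1, 0, 0)  # inward, through the membrane
      }
      trace <- if (is_lipid_pull) {
        run_smd(sys, ff, mode = "com", velocity = run$velocity, k = k,
                n_steps = n_steps, thermostat = thermostat,
                sample_every = sample_every, seed = run$seed,
                direction = dirn, pulled_role = "lipid",
                pulled_mol = pick_pulled_lipid(sys))
      } else {
        run_smd(sys, ff, mode = run$mode, velocity = run$velocity, k = k,
                n_steps = n_steps, thermostat = thermostat,
                sample_every = sample_every, seed = run$seed,
                direction = dirn)
      }
      mf <- max_force(trace)
      utils::write.table(as.data.frame(trace)[
        , c("time_ps", "pulled_force", "membrane_force", "pulled_com_x")],
        trace_path, sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(run_id = run$run_id, peptide = run$peptide, mode = run$mode,
             velocity = run$velocity, replicate = run$replicate,
             seed = run$seed, n_steps = n_steps, k = k,
             temperature = thermostat$temperature,
             max_force = mf$max_force, trace = basename(trace_path)),
        manifest_path, auto_unbox = TRUE, digits = NA)
      data.frame(run_id = run$run_id, peptide = run$peptide,
                 mode = run$mode, velocity = run$velocity,
                 replicate = run$replicate, max_force = mf$max_force,
                 status = "ok")
    }, error = function(e) {
      data.frame(run_id = run$run_id, peptide = run$peptide,
                 mode = run$mode, velocity = run$velocity,
                 replicate = run$replicate, max_force = NA_real_,
                 status = paste0("failed: ", conditionMessage(e)))
    })
    rows[[r]] <- res
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary
}

# a lipid from the upper leaflet near the membrane-plane center
pick_pulled_lipid <- function(sys) {
  lip <- sys$atoms[sys$atoms$role == "lipid", ]
  com <- vapply(split(seq_len(nrow(lip)), lip$mol_id), function(i) {
    mean(lip$x[i])
  }, numeric(1))
  upper <- names(com)[com > stats::median(com)]
  yz <- vapply(split(seq_len(nrow(lip)), lip$mol_id), function(i) {
    sum((mean(lip$y[i]) - mean(lip$y))^2 + (mean(lip$z[i]) - mean(lip$z))^2)
  }, numeric(1))
  as.integer(upper[which.min(yz[upper])])
}

#' Write the packaged fixtures to a directory
#'
#' Materializes the toolkit's assets -- mini-lipid template, synthetic
#' idealized POPC template, toy forcefield, toy 3-residue peptide, a
#' 4 x 4 x 2 mini-bilayer and the published force table -- as files, and
#' reports a checksum for each so drift is detectable.
#'
#' @param dir Output directory.
#' @return Data.frame `file, md5`, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- build_config(n_y = 4, n_z = 4)
  write_pdb(make_minilipid_template(), file.path(dir, "minilipid.pdb"))
  write_pdb(make_popc_template(), file.path(dir, "popc_synthetic.pdb"))
  write_forcefield(toy_forcefield(), file.path(dir, "toy_ff.yaml"))
  write_pdb(build_extended_peptide("GAV"), file.path(dir,
                                                     "toy_peptide.pdb"))
  sys <- build_system(NULL, cfg, solvent = FALSE)
  write_pdb(sys, file.path(dir, "mini_bilayer.pdb"))
  file.copy(pepsmd_extdata("published_force_maxima.tsv"),
            file.path(dir, "published_force_maxima.tsv"), overwrite = TRUE)
  files <- c("minilipid.pdb", "popc_synthetic.pdb", "toy_ff.yaml",
             "toy_peptide.pdb", "mini_bilayer.pdb", "published_force_maxima.tsv")
  sums <- vapply(file.path(dir, files), function(f) {
    unname(tools::md5sum(f))
  }, "")
  out <- data.frame(file = files, md5 = unname(sums))
  utils::write.table(out, file.path(dir, "checksums.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out)
}
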