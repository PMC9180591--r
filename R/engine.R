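#' Potential energy of a configuration
#'
#' Evaluates every term of the classical potential (bonds, angles,
#' torsions, impropers, shifted Lennard-Jones and shifted Coulomb under
#' the minimum-image convention, truncated at the cutoff) and returns
#' each component separately along with the sum.
#'
#' @param top An `md_topology` from [assign_topology].
#' @param pos Optional n x 3 coordinate matrix (defaults to the topology's
#'   build coordinates).
#' @return Named list of energy components (kcal/mol) plus `potential`.
#' @export
total_energy <- function(top, pos = NULL) {
  stopifnot(inherits(top, "md_topology"))
  if (is.null(pos)) pos <- top$xyz
  out <- .cpp_energy_forces(pos, unclass(top))
  out[c("bond", "angle", "torsion", "improper", "vdw", "coulomb",
        "potential")]
}

#' Forces on every atom
#'
#' Analytic gradients of the potential: `F_i = -dU/dr_i`. Internal forces
#' sum to zero (Newton's third law); steering and restraints are external
#' and applied separately ([steering_forces]).
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces, kcal/mol/Angstrom.
#' @export
md_forces <- function(top, pos = NULL) {
  stopifnot(inherits(top, "md_topology"))
  if (is.null(pos)) pos <- top$xyz
  .cpp_energy_forces(pos, unclass(top))$forces
}

#' Thermostat parameters
#'
#' Collisional thermostat: each atom undergoes, with probability
#' `frequency * dt` per step, an elastic collision with a virtual particle
#' of mass `virtual_mass` whose velocity is drawn from the Maxwell
#' distribution at `temperature`.
#'
#' @param temperature Target temperature, K (default 350).
#' @param frequency Per-atom collision frequency, 1/ps.
#' @param virtual_mass Virtual-particle mass, Da.
#' @return A list of class `thermostat_params`.
#' @export
thermostat_params <- function(temperature = 350, frequency = 10,
                              virtual_mass = 18) {
  stopifnot(temperature > 0, frequency >= 0, virtual_mass > 0)
  structure(list(temperature = temperature, frequency = frequency,
                 virtual_mass = virtual_mass), class = "thermostat_params")
}

#' Steering specification for constant-velocity spring pulling
#'
#' A spring of stiffness `k` connects the pulled selection to a wall that
#' moves at constant velocity `v` along `direction`. In `"atom"` mode the
#' whole spring force `k * dx` acts on one (terminal) atom; in `"com"`
#' mode it is distributed over the pulled set in proportion to atomic
#' mass, `F_i = k * dx * m_i / sum(m_j)`. The restrained (membrane)
#' selection uses the same machinery with wall velocity zero.
#'
#' @param mode `"atom"` or `"com"`.
#' @param pulled Integer atom indices (1-based); in `"atom"` mode the
#'   first index is the attachment atom.
#' @param k Spring stiffness, kJ/mol/A^2 (default 10).
#' @param velocity Wall speed, A/ps (positive; applied along `direction`).
#' @param direction Length-3 pulling direction; default `c(-1, 0, 0)`
#'   pulls down through the membrane along -x.
#' @param wall_x0 Initial wall coordinate (projection on `direction`);
#'   `NULL` starts the spring slack (dx = 0 at t = 0).
#' @param restrained Integer atom indices held by a zero-velocity spring
#'   at their center of mass (the membrane), or NULL.
#' @param k_restraint Restraint stiffness, kJ/mol/A^2 (defaults to `k`).
#' @return A list of class `steering_spec`.
#' @export
steering_spec <- function(mode = c("com", "atom"), pulled, k = 10,
                          velocity = 0.1, direction = c(-1, 0, 0),
                          wall_x0 = NULL, restrained = NULL,
                          k_restraint = k) {
  mode <- match.arg(mode)
  pulled <- as.integer(pulled)
  if (length(pulled) < 1) stop("empty pulled selection")
  if (k <= 0) stop("spring stiffness must be positive")
  if (!is.null(restrained) && length(intersect(pulled, restrained))) {
    stop("pulled and restrained selections must be disjoint")
  }
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("zero pulling direction")
  structure(list(mode = mode, pulled = pulled, k = k,
                 velocity = velocity, direction = direction / nd,
                 wall_x0 = wall_x0,
                 restrained = as.integer(restrained),
                 k_restraint = k_restraint),
            class = "steering_spec")
}

KJ_PER_KCAL <- 4.184

# internal: steering spec -> C++ lists (k converted kJ -> kcal)
steering_to_cpp <- function(spec, pos, mass) {
  if (is.null(spec)) {
    return(list(pull = list(mode = 0L), restr = list(mode = 0L)))
  }
  dirv <- spec$direction
  proj <- function(idx, com) {
    if (com) {
      sum(mass[idx] * (pos[idx, , drop = FALSE] %*% dirv)) / sum(mass[idx])
    } else {
      sum(pos[idx[1], ] * dirv)
    }
  }
  x0 <- if (is.null(spec$wall_x0)) {
    proj(spec$pulled, spec$mode == "com")
  } else {
    spec$wall_x0
  }
  pull <- list(mode = if (spec$mode == "atom") 1L else 2L,
               idx = spec$pulled, k = spec$k / KJ_PER_KCAL,
               dir = dirv, v = spec$velocity, x0 = x0)
  restr <- if (length(spec$restrained)) {
    list(mode = 2L, idx = spec$restrained,
         k = spec$k_restraint / KJ_PER_KCAL, dir = dirv, v = 0,
         x0 = proj(spec$restrained, TRUE))
  } else {
    list(mode = 0L)
  }
  list(pull = pull, restr = restr)
}

#' External steering forces at a given time
#'
#' Evaluates the spring force of a [steering_spec] on a configuration
#' (without integrating). Useful for checking the mass-weighted
#' distribution of the center-of-mass mode.
#'
#' @param top An `md_topology`.
#' @param spec A [steering_spec].
#' @param pos Optional coordinates (default: topology coordinates).
#' @param t Time, ps (moves the wall to `x0 + v t`).
#' @return n x 3 matrix of external forces, kJ/mol/Angstrom.
#' @export
steering_forces <- function(top, spec, pos = NULL, t = 0) {
  if (is.null(pos)) pos <- top$xyz
  cv <- steering_to_cpp(spec, pos, top$mass)
  f <- .cpp_steering_forces(pos, top$mass, cv$pull, t) +
       .cpp_steering_forces(pos, top$mass, cv$restr, t)
  f * KJ_PER_KCAL
}

#' Maxwell-distributed initial velocities
#'
#' @param top An `md_topology`.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return n x 3 velocity matrix, Angstrom/ps, with zero net momentum.
#' @export
init_velocities <- function(top, temperature = 350, seed = 1) {
  n <- length(top$mass)
  set.seed(seed)
  kb <- 0.83144626  # Da A^2 ps^-2 K^-1
  v <- matrix(rnorm(3 * n), n, 3) *
    sqrt(kb * temperature / top$mass)
  # remove center-of-mass drift
  p <- colSums(v * top$mass)
  sweep(v, 2, p / sum(top$mass))
}

#' Integrate molecular dynamics
#'
#' Velocity-Verlet integration (default time step 0.001 ps) with optional
#' collisional thermostat and spring steering. Coordinates are kept
#' unwrapped internally; the minimum-image convention handles periodicity
#' in every interaction.
#'
#' @param top An `md_topology` from [assign_topology].
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps.
#' @param vel Initial velocities (n x 3) or NULL for zero.
#' @param pos Initial coordinates (default: topology coordinates).
#' @param thermostat A [thermostat_params] or NULL for NVE.
#' @param spec A [steering_spec] or NULL.
#' @param sample_every Sampling stride for the trace.
#' @param seed Integer seed for the thermostat collisions.
#' @param snapshot_every Stride for coordinate snapshots (0 = none).
#' @return List with `pos`, `vel`, and `trace` (a `force_trace`
#'   data.frame: `time_ps`, `pulled_force`, `membrane_force`,
#'   `pulled_com_x` in kJ/mol/A and A, plus sampled kinetic/potential
#'   energy in kcal/mol), and `snapshots` (n x 3 x k array or NULL).
#' @export
run_md <- function(top, n_steps, dt = 0.001, vel = NULL, pos = NULL,
                   thermostat = NULL, spec = NULL, sample_every = 10L,
                   seed = 1, snapshot_every = 0L) {
  stopifnot(inherits(top, "md_topology"), n_steps >= 1)
  if (is.null(pos)) pos <- top$xyz
  n <- length(top$mass)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  temp <- if (is.null(thermostat)) 0 else thermostat$temperature
  freq <- if (is.null(thermostat)) 0 else thermostat$frequency
  cmass <- if (is.null(thermostat)) 18 else thermostat$virtual_mass
  cv <- steering_to_cpp(spec, pos, top$mass)
  out <- .cpp_run_md(pos, vel, unclass(top), dt, as.integer(n_steps),
                     as.integer(sample_every), temp, freq, cmass,
                     as.numeric(seed), cv$pull, cv$restr,
                     as.integer(snapshot_every))
  # com_coord is the projection on the pulling direction; for an
  # axis-aligned pull report the lab-frame coordinate instead
  com_lab <- out$com_coord
  if (!is.null(spec)) {
    ax <- which.max(abs(spec$direction))
    if (abs(abs(spec$direction[ax]) - 1) < 1e-9) {
      com_lab <- out$com_coord * spec$direction[ax]
    }
  }
  trace <- data.frame(
    time_ps = out$time,
    pulled_force = out$f_pull * KJ_PER_KCAL,
    membrane_force = out$f_restraint * KJ_PER_KCAL,
    pulled_com_x = com_lab,
    kinetic = out$kinetic,
    potential = out$potential)
  class(trace) <- c("force_trace", "data.frame")
  attr(trace, "spec") <- spec
  attr(trace, "seed") <- seed
  attr(trace, "dt") <- dt
  attr(trace, "complete") <- TRUE
  snaps <- NULL
  if (snapshot_every > 0 && out$n_snapshots > 0) {
    snaps <- aperm(array(out$snapshots[seq_len(out$n_snapshots * n * 3)],
                         dim = c(3, n, out$n_snapshots)), c(2, 1, 3))
  }
  list(pos = out$pos, vel = out$vel, trace = trace, snapshots = snaps)
}

#' Instantaneous kinetic temperature of a velocity set
#' @param top An `md_topology`.
#' @param vel n x 3 velocity matrix, A/ps.
#' @return Temperature, K.
#' @export
kinetic_temperature <- function(top, vel) {
  kb <- 0.83144626
  ke <- 0.5 * sum(top$mass * rowSums(vel^2))
  2 * ke / (3 * length(top$mass) * kb)
}

#' Run a steered pulling experiment
#'
#' Assembles steering for a built system (pulled peptide or lipid plus
#' center-of-mass membrane restraint), integrates with the collisional
#' thermostat, and returns the recorded force trace.
#'
#' In `"atom"` mode the attachment atom is the terminal heavy atom of the
#' pulled molecule that leads in the pulling direction; in `"com"` mode
#' the whole pulled set is attached through its center of mass.
#'
#' @param sys A built [mol_system] containing a `"peptide"` (or the
#'   molecule named by `pulled_role`).
#' @param ff A `forcefield`.
#' @param mode `"com"` or `"atom"`.
#' @param velocity Wall speed, A/ps.
#' @param k Spring stiffness, kJ/mol/A^2.
#' @param n_steps Integration steps.
#' @param thermostat A [thermostat_params].
#' @param sample_every Trace sampling stride.
#' @param seed Integer seed (thermostat + initial velocities).
#' @param direction Pulling direction (default -x, through the membrane).
#' @param pulled_role Role tag of the pulled molecule (default
#'   `"peptide"`); use `"lipid"` with `pulled_mol` for lipid pulls.
#' @param pulled_mol Molecule id to pull when several share the role.
#' @param dt Time step, ps.
#' @param snapshot_every Snapshot stride (0 = none).
#' @return A `force_trace` with the run's parameters attached; final
#'   coordinates in `attr(, "final")`.
#' @export
run_smd <- function(sys, ff = toy_forcefield(), mode = c("com", "atom"),
                    velocity = 0.1, k = 10, n_steps = 1000L,
                    thermostat = thermostat_params(),
                    sample_every = 10L, seed = 1,
                    direction = c(-1, 0, 0), pulled_role = "peptide",
                    pulled_mol = NULL, dt = 0.001, snapshot_every = 0L) {
  mode <- match.arg(mode)
  top <- assign_topology(sys, ff)
  pulled_ids <- system_molecule_ids(sys, pulled_role)
  if (length(pulled_ids) == 0) stop("no molecule with role '",
                                    pulled_role, "'")
  target <- if (is.null(pulled_mol)) pulled_ids[1] else pulled_mol
  pulled <- which(sys$atoms$mol_id == target)
  membrane <- which(sys$atoms$role == "lipid" &
                      sys$atoms$mol_id != target)
  if (mode == "atom") {
    # terminal heavy atom leading in the pulling direction
    heavy <- pulled[sys$atoms$element[pulled] != "H"]
    proj <- coords_matrix(sys$atoms)[heavy, , drop = FALSE] %*%
      (direction / sqrt(sum(direction^2)))
    pulled <- heavy[which.max(proj)]
  }
  spec <- steering_spec(mode = mode, pulled = pulled, k = k,
                        velocity = velocity, direction = direction,
                        restrained = membrane)
  vel <- init_velocities(top, thermostat$temperature, seed = seed)
  out <- run_md(top, n_steps = n_steps, dt = dt, vel = vel,
                thermostat = thermostat, spec = spec,
                sample_every = sample_every, seed = seed,
                snapshot_every = snapshot_every)
  trace <- out$trace
  attr(trace, "params") <- list(mode = mode, velocity = velocity, k = k,
                                n_steps = n_steps, dt = dt, seed = seed,
                                temperature = thermostat$temperature)
  attr(trace, "final") <- out$pos
  attr(trace, "snapshots") <- out$snapshots
  trace
}

#' @export
print.force_trace <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<force_trace> %d samples over %.3f ps\n", nrow(x),
              max(x$time_ps)))
  if (!is.null(p)) {
    cat(sprintf("  mode=%s v=%g A/ps k=%g kJ/mol/A^2 T=%g K seed=%s\n",
                p$mode, p$velocity, p$k, p$temperature, p$seed))
  }
  cat(sprintf("  max |pulled force| = %.1f kJ/mol/A\n",
              max(abs(x$pulled_force))))
  invisible(x)
}
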