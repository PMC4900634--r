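#' Langevin dynamics configuration
#'
#' Parameters of the BAOAB-discretized Langevin integrator. The defaults
#' follow the conventions of membrane-channel simulation practice: a
#' collision frequency (friction) of 5 ps^-1 and snapshots saved every 4 ps.
#' The coarse-grained timestep default is 0.01 ps. Scaffold atoms are static
#' unless selected as mobile; a multi-phase restraint schedule (relaxation
#' with a decreasing force-constant ladder, then unrestrained sampling) can
#' be given via `phases`.
#'
#' @param n_steps Number of integration steps.
#' @param timestep Timestep (ps).
#' @param temperature Temperature (K).
#' @param friction Langevin collision frequency gamma (ps^-1).
#' @param save_interval Snapshot interval (ps); must be a multiple of the
#'   timestep.
#' @param mobile Selection of mobile atoms (default: the ligand).
#' @param rigid_ligand Treat `LIG` beads among the mobile atoms as one
#'   translation-only rigid cluster.
#' @param phases Optional tibble `n_steps`, `k_scale`: the restraint force
#'   constants are multiplied by `k_scale` during each phase, run in order.
#' @param rng_seed Seed for the thermostat noise.
#' @return A `pk_dynamics_config` list.
#' @export
dynamics_config <- function(n_steps = 10000L, timestep = 0.01,
                            temperature = 300, friction = 5,
                            save_interval = 4, mobile = "resname LIG",
                            rigid_ligand = TRUE, phases = NULL,
                            rng_seed = 1L) {
  if (timestep <= 0) abort("timestep must be > 0")
  if (friction < 0) abort("friction must be >= 0")
  steps_per_save <- save_interval / timestep
  if (abs(steps_per_save - round(steps_per_save)) > 1e-9) {
    abort("save_interval must be a multiple of timestep")
  }
  if (!is.null(phases) && !all(c("n_steps", "k_scale") %in% names(phases))) {
    abort("phases needs columns n_steps, k_scale")
  }
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 temperature = temperature, friction = friction,
                 save_interval = save_interval, mobile = mobile,
                 rigid_ligand = isTRUE(rigid_ligand), phases = phases,
                 rng_seed = as.integer(rng_seed)),
            class = "pk_dynamics_config")
}

#' Default masses by element (amu)
#' @keywords internal
element_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, K = 39.098, Cl = 35.45, CL = 35.45)
  m <- tab[element]
  m[is.na(m)] <- 50 # coarse pseudo-atom fallback
  unname(m)
}

structure_masses <- function(structure) {
  m <- element_mass(structure$element)
  lig_spec <- attr(structure, "ligand_spec", exact = TRUE)
  lig <- structure$residue_name == "LIG"
  if (any(lig)) {
    m[lig] <- if (!is.null(lig_spec)) lig_spec$bead_mass else 194.5
  }
  # backbone/side-chain pseudo-atoms carry half an average residue mass
  pseudo <- structure$monomer_index >= 0L & structure$atom_name %in% c("CA", "CB")
  m[pseudo] <- 55
  m
}

#' Run Langevin dynamics
#'
#' Integrates the mobile atoms (and the rigid ligand cluster, moved as one
#' translation-only body) with the BAOAB splitting of Langevin dynamics.
#' Static atoms contribute forces but do not move. The trajectory is
#' deterministic given `config$rng_seed`. With a `phases` schedule, the
#' phases run back to back (velocities reset at each phase boundary) and
#' the returned log records the phase boundaries and the scaled restraint
#' force constants.
#'
#' @param structure A [pk_structure()] (initial configuration).
#' @param ff A [forcefield()].
#' @param config A [dynamics_config()].
#' @return A [pk_trajectory()] with attribute `log` (a tibble of phases).
#' @export
run_dynamics <- function(structure, ff = forcefield(),
                         config = dynamics_config()) {
  mobile_idx <- resolve_selection(structure, config$mobile)
  if (length(mobile_idx) == 0L) abort("mobile selection is empty")
  lig_idx <- integer(0)
  if (config$rigid_ligand) {
    lig_idx <- mobile_idx[structure$residue_name[mobile_idx] == "LIG"]
    mobile_idx <- setdiff(mobile_idx, lig_idx)
  }
  masses <- structure_masses(structure)
  kBT <- pk_constants()$kB * config$temperature
  save_every <- as.integer(round(config$save_interval / config$timestep))
  phases <- config$phases
  if (is.null(phases)) {
    phases <- tibble(n_steps = config$n_steps, k_scale = 1)
  }
  xyz <- coords(structure)
  a0 <- ff_eval_args(structure, ff)
  frames <- list()
  log_rows <- list()
  t0 <- 0
  with_preserved_seed(config$rng_seed, {
    for (ph in seq_len(nrow(phases))) {
      nst <- as.integer(phases$n_steps[ph])
      res <- baoab_cpp(xyz, structure$charge, structure$vdw_radius,
                       a0$mono, a0$resno, a0$molid, a0$exclall, masses,
                       a0$eef, a0$mask, a0$ratom, a0$rref,
                       a0$rk * phases$k_scale[ph], ff$kc, ff$wca_eps,
                       mobile_idx - 1L, lig_idx - 1L,
                       config$timestep, config$friction, kBT,
                       nst, save_every)
      nf <- res$n_frames
      arr <- array(res$frames, dim = c(nf, nrow(structure), 3))
      first <- if (ph == 1L) 1L else 2L # drop duplicated phase-start frame
      for (k in first:nf) {
        frames[[length(frames) + 1L]] <-
          matrix(arr[k, , , drop = FALSE], ncol = 3)
      }
      log_rows[[ph]] <- tibble(phase = ph, n_steps = nst,
                               k_scale = phases$k_scale[ph],
                               t_start_ps = t0,
                               t_end_ps = t0 + nst * config$timestep)
      t0 <- t0 + nst * config$timestep
      xyz <- res$final
    }
  })
  times <- (seq_along(frames) - 1) * config$save_interval
  traj <- pk_trajectory(structure, frames, times = times)
  attr(traj, "log") <- bind_rows(log_rows)
  traj
}

#' Run the field-sweep permeation protocol
#'
#' Runs one trajectory per (field strength, seed) with the EEF applied to
#' the ligand along `direction`, and summarizes first-passage times: the
#' time at which the ligand-vs-ring permeation coordinate, having started at
#' or above `z_upper`, first reaches `z_lower` (see [detect_crossings()]).
#'
#' @param system A [pk_structure()] containing a `LIG` residue.
#' @param field_strengths Numeric vector of field magnitudes (V/A).
#' @param seeds Integer vector of thermostat seeds (used for every field).
#' @param config A [dynamics_config()] template (its mobile selection should
#'   include the ligand; its seed is overridden per run).
#' @param direction Unit 3-vector of the field direction; the default
#'   pushes a positive ligand toward the cytoplasmic (-Z) exit.
#' @param ligand_sel,ring_sel Selections for the permeation coordinate.
#' @param z_upper,z_lower Crossing hysteresis thresholds (A).
#' @param keep_trajectories If `TRUE`, attach each trajectory in a list
#'   column.
#' @return A tibble: `field`, `seed`, `first_passage_ps` (`Inf` when no
#'   passage), `n_down`, `n_up` (crossing counts).
#' @export
run_permeation_protocol <- function(system, field_strengths, seeds,
                                    config = dynamics_config(),
                                    direction = c(0, 0, -1),
                                    ligand_sel = "resname LIG",
                                    ring_sel = "resnum 106 and name CA",
                                    z_upper = 10, z_lower = -5,
                                    keep_trajectories = FALSE) {
  if (length(resolve_selection(system, ligand_sel)) == 0L) {
    abort("system has no ligand atoms to drive")
  }
  direction <- normalize(direction)
  grid <- tidyr::expand_grid(field = field_strengths, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(field, seed) {
    ff <- forcefield(eef_field = field * direction, eef_mask = ligand_sel)
    cfg <- config
    cfg$rng_seed <- seed
    traj <- run_dynamics(system, ff, cfg)
    dz <- delta_z(traj, ligand_sel, ring_sel)
    ev <- detect_crossings(dz, z_upper = z_upper, z_lower = z_lower)
    down <- ev[ev$direction == "down", , drop = FALSE]
    out <- tibble(field = field, seed = seed,
                  first_passage_ps = if (nrow(down) > 0) down$t_end[1] else Inf,
                  n_down = nrow(down),
                  n_up = sum(ev$direction == "up"))
    if (keep_trajectories) out$trajectory <- list(traj)
    out
  })
  bind_rows(rows)
}
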